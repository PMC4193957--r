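# SNP functional classification, filtering, risk/neutral labelling and
# category-matched random control loci.

#' The nine SNP functional categories
#'
#' Canonical category names used throughout the package. Input tables using
#' a different vocabulary are translated with [map_func_categories()].
#'
#' @return character vector of the nine category names.
#' @export
snp_categories <- function() {
  c("coding_synonymous", "coding_nonsynonymous", "exon_other", "intron",
    "utr5", "utr3", "near_gene_5", "near_gene_3", "intergenic_other")
}

# categories counted as coding for risk-label splitting
.coding_categories <- function() {
  c("coding_synonymous", "coding_nonsynonymous", "exon_other")
}

# UCSC func-column dialect -> canonical names
.ucsc_func_map <- c(
  "coding-synon" = "coding_synonymous",
  "coding-nonsynon" = "coding_nonsynonymous",
  "missense" = "coding_nonsynonymous",
  "exon" = "exon_other",
  "intron" = "intron",
  "untranslated-5" = "utr5",
  "untranslated-3" = "utr3",
  "near-gene-5" = "near_gene_5",
  "near-gene-3" = "near_gene_3",
  "unknown" = "intergenic_other",
  "intergenic" = "intergenic_other"
)

#' Translate functional-category vocabulary
#'
#' Maps the `func_category` column onto the canonical nine-category
#' vocabulary of [snp_categories()]. A SNP annotated with several
#' comma-separated categories is resolved by a fixed precedence
#' (coding > UTR > intron > near-gene > intergenic), configurable via
#' `precedence`.
#'
#' @param snps a `snp_table`.
#' @param map named character vector translating input terms to canonical
#'   names; defaults to the UCSC dialect. Terms already canonical pass
#'   through unchanged.
#' @param precedence character vector of canonical categories in decreasing
#'   priority, used for multi-annotated SNPs.
#' @return the `snp_table` with `func_category` canonicalised.
#' @export
map_func_categories <- function(snps, map = NULL,
                                precedence = c("coding_nonsynonymous",
                                               "coding_synonymous",
                                               "exon_other", "utr5", "utr3",
                                               "intron", "near_gene_5",
                                               "near_gene_3",
                                               "intergenic_other")) {
  map <- c(map, .ucsc_func_map)
  translate <- function(terms) {
    canon <- ifelse(terms %in% snp_categories(), terms,
                    unname(map[terms]))
    canon[is.na(canon)] <- "intergenic_other"
    canon
  }
  resolve <- function(func) {
    terms <- translate(trimws(strsplit(func, ",", fixed = TRUE)[[1L]]))
    ord <- match(terms, precedence)
    terms[which.min(ord)]
  }
  snps$func_category <- vapply(as.character(snps$func_category), resolve, "",
                               USE.NAMES = FALSE)
  snps
}

#' Filter SNPs to single-base, validated polymorphisms
#'
#' Retains only records with variant class `"single"`, a validated status
#' and a valid pair of two distinct single bases.
#'
#' @param snps a `snp_table` (see [read_snp_table()]).
#' @return the filtered `snp_table` (possibly empty).
#' @export
filter_snps <- function(snps) {
  keep <- snps$variant_class == "single" & snps$validated & snps$valid_alleles
  snps[keep, , drop = FALSE]
}

#' Assign risk / neutral labels
#'
#' A SNP whose `(chrom, pos)` matches a risk site is labelled
#' `risk_coding` if its functional category is exonic
#' (coding_synonymous / coding_nonsynonymous / exon_other) and
#' `risk_noncoding` otherwise. Non-risk coding-synonymous SNPs are the
#' neutral comparator set (`neutral`); all remaining SNPs get `other`.
#' Risk sites that match no SNP are counted and reported via the
#' `unmatched_risk_sites` attribute, not treated as an error.
#'
#' @param snps a `snp_table` with canonical `func_category`.
#' @param risk_sites data.frame with columns `chrom`, `pos` (0-based).
#' @return the `snp_table` with `risk_label` filled in.
#' @export
assign_labels <- function(snps, risk_sites) {
  key <- paste(snps$chrom, snps$pos)
  rkey <- paste(risk_sites$chrom, risk_sites$pos)
  is_risk <- key %in% rkey
  coding <- snps$func_category %in% .coding_categories()
  label <- rep("other", nrow(snps))
  label[is_risk & coding] <- "risk_coding"
  label[is_risk & !coding] <- "risk_noncoding"
  label[!is_risk & snps$func_category == "coding_synonymous"] <- "neutral"
  snps$risk_label <- label
  unmatched <- sum(!(rkey %in% key))
  if (unmatched > 0) {
    message(unmatched, " risk site(s) matched no SNP record")
  }
  attr(snps, "unmatched_risk_sites") <- unmatched
  snps
}

#' Sample category-matched random control loci
#'
#' Draws, for each requested region class, a fixed number of positions
#' uniformly from the annotated intervals of that class. Used to build the
#' flat-profile control: tag profiles around random loci should show no
#' positional structure.
#'
#' @param annotation data.frame with columns `class`, `chrom`, `start`,
#'   `end` (0-based half-open) covering each requested class.
#' @param category_counts named integer vector: number of loci per class.
#' @param seed RNG seed; the same seed reproduces the same loci.
#' @return data.frame with columns `class`, `chrom`, `pos`.
#' @export
sample_random_loci <- function(annotation, category_counts, seed = NULL) {
  .with_seed(seed, {
    out <- lapply(names(category_counts), function(cl) {
      n <- category_counts[[cl]]
      iv <- annotation[annotation$class == cl, , drop = FALSE]
      widths <- iv$end - iv$start
      total <- sum(widths)
      if (total <= 0) stop("region class '", cl, "' has zero total length")
      u <- sample.int(total, n, replace = TRUE) - 1L
      cum <- cumsum(widths)
      # interval containing u: first index whose cumulative end exceeds u
      idx <- findInterval(u, cum) + 1L
      offset_in <- u - c(0, cum)[idx]
      data.frame(class = cl, chrom = iv$chrom[idx],
                 pos = iv$start[idx] + offset_in,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
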
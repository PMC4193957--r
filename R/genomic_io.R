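# Readers and writers for all on-disk formats. Every reader converts to the
# single internal convention: 0-based positions, half-open [start, end)
# intervals, regardless of the source dialect.

#' Construct a tag set
#'
#' A `TagSet` is a collection of stranded genomic intervals from a
#' sequencing experiment (nucleosome or histone-modification tags).
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `strand` (one of `"+"`, `"-"`, `"."`); 0-based half-open.
#' @param source_label free-text label recording where the tags came from.
#' @return An object of class `TagSet` with elements `intervals`,
#'   `source_label` and `total_tag_count` (always equal to the number of
#'   intervals).
#' @export
tag_set <- function(intervals, source_label = "tags") {
  if (nrow(intervals)) {
    stopifnot(all(intervals$start < intervals$end),
              all(intervals$start >= 0),
              all(intervals$strand %in% c("+", "-", ".")))
  }
  structure(list(intervals = intervals, source_label = source_label,
                 total_tag_count = nrow(intervals)),
            class = "TagSet")
}

#' @export
print.TagSet <- function(x, ...) {
  cat("TagSet '", x$source_label, "': ", x$total_tag_count, " tags on ",
      length(unique(x$intervals$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Construct a positional profile
#'
#' A `Profile` holds a real-valued signal indexed by offset relative to a
#' set of anchor sites, together with the normalisation applied.
#'
#' @param offsets integer vector of offsets, `-W .. +W`.
#' @param values numeric vector, same length as `offsets`.
#' @param n_anchors number of anchor sites aggregated.
#' @param normalization list with fields `genome_coverage_divisor`,
#'   `per_anchor_averaged`, `shift_used`.
#' @return An object of class `Profile`.
#' @export
new_profile <- function(offsets, values, n_anchors,
                        normalization = list(genome_coverage_divisor = 1,
                                             per_anchor_averaged = FALSE,
                                             shift_used = 0L)) {
  stopifnot(length(offsets) == length(values))
  structure(list(offsets = as.integer(offsets), values = as.numeric(values),
                 n_anchors = as.integer(n_anchors),
                 normalization = normalization),
            class = "Profile")
}

#' @export
print.Profile <- function(x, ...) {
  cat("Profile over offsets [", min(x$offsets), ", ", max(x$offsets),
      "], ", x$n_anchors, " anchors, shift ", x$normalization$shift_used,
      ", coverage divisor ",
      format(x$normalization$genome_coverage_divisor, digits = 4), "\n",
      sep = "")
  invisible(x)
}

# canonical column aliases for SNP tables (UCSC dump dialect and variants)
.snp_aliases <- list(
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("chromStart", "pos", "position", "start"),
  alleles = c("observed", "alleles", "allele"),
  class = c("class", "variant_class", "varClass"),
  func = c("func", "func_category", "function"),
  valid = c("valid", "validated", "valStatus")
)

.pick_col <- function(df, aliases) {
  hit <- intersect(aliases, names(df))
  if (length(hit)) hit[1L] else NA_character_
}

#' Read a SNP annotation table
#'
#' Reads a UCSC-style tab-separated SNP dump into the internal SNP table.
#' Position columns named `chromStart` are taken as 0-based (UCSC dump
#' dialect); set `one_based = TRUE` for 1-based sources.
#'
#' Allele strings must be two distinct single bases separated by a slash
#' (e.g. `"A/G"`). Rows failing that are retained but flagged
#' (`valid_alleles = FALSE`) so downstream filters can drop them; parsing
#' never aborts on a malformed allele string.
#'
#' @param path path to a TSV with header; required columns (any alias):
#'   chrom, position, alleles, class, func, validation status.
#' @param one_based set to `TRUE` if positions in the file are 1-based.
#' @return data.frame of class `snp_table` with columns `chrom`, `pos`
#'   (0-based), `allele1`, `allele2`, `variant_class`, `func_category`,
#'   `validated`, `valid_alleles`, `risk_label` (initialised to `"other"`).
#' @export
read_snp_table <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("SNP table not found: ", path)
  df <- as.data.frame(fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1L)))
  cols <- lapply(.snp_aliases, .pick_col, df = df)
  for (k in names(cols)) {
    if (is.na(cols[[k]])) {
      stop("SNP table '", path, "' is missing required column: ", k,
           " (accepted names: ", paste(.snp_aliases[[k]], collapse = "/"), ")")
    }
  }
  if (!nrow(df)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      allele1 = character(), allele2 = character(),
                      variant_class = character(),
                      func_category = character(), validated = logical(),
                      valid_alleles = logical(), risk_label = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("snp_table", "data.frame")
    return(out)
  }
  pos <- as.integer(df[[cols$pos]])
  if (one_based) pos <- pos - 1L
  obs <- as.character(df[[cols$alleles]])
  parts <- strsplit(obs, "/", fixed = TRUE)
  a1 <- vapply(parts, function(p) if (length(p) >= 1) toupper(p[1]) else "", "")
  a2 <- vapply(parts, function(p) if (length(p) >= 2) toupper(p[2]) else "", "")
  bases <- c("A", "C", "G", "T")
  valid_alleles <- vapply(parts, length, 0L) == 2L &
    a1 %in% bases & a2 %in% bases & a1 != a2
  valid_status <- tolower(as.character(df[[cols$valid]]))
  validated <- !(valid_status %in% c("unknown", "no", "false", "0", "", "na"))
  out <- data.frame(chrom = as.character(df[[cols$chrom]]), pos = pos,
                    allele1 = a1, allele2 = a2,
                    variant_class = as.character(df[[cols$class]]),
                    func_category = as.character(df[[cols$func]]),
                    validated = validated, valid_alleles = valid_alleles,
                    risk_label = "other", stringsAsFactors = FALSE)
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Write a SNP table
#'
#' Writes the internal SNP table back to TSV in the same dialect
#' [read_snp_table()] accepts (0-based `chromStart`).
#'
#' @param snps a `snp_table`.
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  out <- data.frame(chrom = snps$chrom, chromStart = snps$pos,
                    chromEnd = snps$pos + 1L,
                    observed = paste0(snps$allele1, "/", snps$allele2),
                    class = snps$variant_class, func = snps$func_category,
                    valid = ifelse(snps$validated, "by-cluster", "unknown"))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read sequencing tags from a BED file
#'
#' Accepts BED3 (strand set to `"."`) or BED6 (strand from column 6).
#' Rows with `start >= end` are rejected with a warning and do not count
#' toward the tag total.
#'
#' @param path path to a BED file (no header).
#' @param source_label label stored in the returned `TagSet`.
#' @return a [tag_set()].
#' @export
read_tag_bed <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("tag BED not found: ", path)
  df <- as.data.frame(fread(path, header = FALSE, sep = "\t", fill = TRUE))
  if (!nrow(df)) {
    return(tag_set(data.frame(chrom = character(), start = integer(),
                              end = integer(), strand = character()),
                   source_label))
  }
  strand <- if (ncol(df) >= 6) as.character(df[[6]]) else rep(".", nrow(df))
  strand[!strand %in% c("+", "-")] <- "."
  iv <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                   end = as.integer(df[[3]]), strand = strand,
                   stringsAsFactors = FALSE)
  bad <- iv$start >= iv$end | iv$start < 0
  if (any(bad)) {
    warning(sum(bad), " malformed BED row(s) rejected (start >= end or negative)")
    iv <- iv[!bad, , drop = FALSE]
  }
  tag_set(iv, source_label)
}

#' Write a tag set to BED6
#'
#' @param tags a `TagSet`.
#' @param path output path.
#' @export
write_tag_bed <- function(tags, path) {
  iv <- tags$intervals
  out <- data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                    name = "tag", score = 0L, strand = iv$strand)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read bound-region intervals from a BED file
#'
#' @param path path to a BED3+ file.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), rows with `start >= end` rejected with a warning.
#' @export
read_interval_bed <- function(path) {
  if (!file.exists(path)) stop("interval BED not found: ", path)
  df <- as.data.frame(fread(path, header = FALSE, sep = "\t", fill = TRUE))
  if (!nrow(df)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  iv <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                   end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  bad <- iv$start >= iv$end | iv$start < 0
  if (any(bad)) {
    warning(sum(bad), " malformed interval row(s) rejected")
    iv <- iv[!bad, , drop = FALSE]
  }
  iv
}

#' Read a per-position DNA methylation table
#'
#' Expects a TSV with columns `chrom`, `pos`, `level` (header optional;
#' without a header the first three columns are used). Levels are mean
#' methylation percentages and must lie in `[0, 100]`; out-of-range rows
#' are rejected with a warning.
#'
#' @param path path to the table.
#' @return data.frame of class `methylation_track` with columns `chrom`,
#'   `pos` (0-based), `level`.
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) stop("methylation table not found: ", path)
  df <- as.data.frame(fread(path, sep = "\t"))
  if (!all(c("chrom", "pos", "level") %in% names(df))) {
    if (ncol(df) < 3) stop("methylation table '", path, "' needs 3 columns")
    names(df)[1:3] <- c("chrom", "pos", "level")
  }
  out <- data.frame(chrom = as.character(df$chrom), pos = as.integer(df$pos),
                    level = as.numeric(df$level), stringsAsFactors = FALSE)
  bad <- !is.finite(out$level) | out$level < 0 | out$level > 100
  if (any(bad)) {
    warning(sum(bad), " methylation row(s) outside [0, 100] rejected")
    out <- out[!bad, , drop = FALSE]
  }
  class(out) <- c("methylation_track", "data.frame")
  out
}

#' Read a site list (mutation sites, risk-SNP coordinates)
#'
#' Expects a TSV with columns `chrom`, `pos` (header optional; first two
#' columns used otherwise). Positions are 0-based unless `one_based`.
#'
#' @param path path to the table.
#' @param one_based set `TRUE` for 1-based input positions.
#' @return data.frame with columns `chrom`, `pos`.
#' @export
read_mutation_sites <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- as.data.frame(fread(path, sep = "\t"))
  if (!all(c("chrom", "pos") %in% names(df))) {
    if (ncol(df) < 2) stop("site table '", path, "' needs 2 columns")
    names(df)[1:2] <- c("chrom", "pos")
  }
  pos <- as.integer(df$pos)
  if (one_based) pos <- pos - 1L
  data.frame(chrom = as.character(df$chrom), pos = pos,
             stringsAsFactors = FALSE)
}

#' @rdname read_mutation_sites
#' @export
read_risk_sites <- read_mutation_sites

#' Read a genome from FASTA
#'
#' Bases are upper-cased; `N` is accepted and handled downstream (excluded
#' from GC tallies).
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector of class `genome_seq`, one element per
#'   chromosome; `genome_lengths()` returns the per-chromosome lengths.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ss <- readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  class(g) <- "genome_seq"
  g
}

#' Write a genome to FASTA
#'
#' @param genome named character vector (`genome_seq`).
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- DNAStringSet(unclass(genome))
  writeXStringSet(ss, path)
  invisible(path)
}

#' Per-chromosome lengths of a genome
#'
#' @param genome a `genome_seq`.
#' @return named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  setNames(nchar(unclass(genome)), names(genome))
}

#' Write / read a profile as TSV
#'
#' The file carries a comment header (`# key: value` lines) recording
#' `n_anchors` and the normalisation fields, followed by two tab-separated
#' columns `offset` and `value`. `read_profile_tsv()` reproduces the
#' original `Profile` exactly (values are written at full precision).
#'
#' @param profile a `Profile`.
#' @param path file path.
#' @return `write_profile_tsv` returns `path` invisibly;
#'   `read_profile_tsv` returns a `Profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  nm <- profile$normalization
  hdr <- c(
    sprintf("# n_anchors: %d", profile$n_anchors),
    sprintf("# genome_coverage_divisor: %s",
            format(nm$genome_coverage_divisor, digits = 17)),
    sprintf("# per_anchor_averaged: %s", nm$per_anchor_averaged),
    sprintf("# shift_used: %d", as.integer(nm$shift_used)),
    "offset\tvalue"
  )
  body <- sprintf("%d\t%.17g", profile$offsets, profile$values)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  if (!file.exists(path)) stop("profile TSV not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("profile TSV missing header field: ", key)
    sub(paste0("^# ", key, ":\\s*"), "", ln[1L])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[-1L]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  offsets <- as.integer(vapply(parts, `[`, "", 1L))
  values <- as.numeric(vapply(parts, `[`, "", 2L))
  new_profile(offsets, values,
              n_anchors = as.integer(getv("n_anchors")),
              normalization = list(
                genome_coverage_divisor = as.numeric(getv("genome_coverage_divisor")),
                per_anchor_averaged = as.logical(getv("per_anchor_averaged")),
                shift_used = as.integer(getv("shift_used"))))
}
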
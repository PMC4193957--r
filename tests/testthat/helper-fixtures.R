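# Small programmatic fixtures shared across tests.

# random tag set on a single toy chromosome
random_tags <- function(n, len, chrom = "chrT", tag_len_range = c(20L, 40L)) {
  w <- sample(seq(tag_len_range[1], tag_len_range[2]), n, replace = TRUE)
  start <- sample.int(len - max(w), n, replace = TRUE) - 1L
  tag_set(data.frame(chrom = chrom, start = start, end = start + w,
                     strand = sample(c("+", "-", "."), n, replace = TRUE,
                                     prob = c(0.45, 0.45, 0.1)),
                     stringsAsFactors = FALSE),
          "random")
}

random_sites <- function(n, len, margin, chrom = "chrT") {
  data.frame(chrom = chrom,
             pos = sample.int(len - 2L * margin, n, replace = TRUE) - 1L + margin,
             stringsAsFactors = FALSE)
}

random_genome <- function(len, chrom = "chrT", p_n = 0.02) {
  bases <- sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                  prob = c((1 - p_n) / 4, (1 - p_n) / 4, (1 - p_n) / 4,
                           (1 - p_n) / 4, p_n))
  g <- setNames(paste(bases, collapse = ""), chrom)
  class(g) <- "genome_seq"
  g
}

# minimal SNP-table constructor for unit tests
toy_snps <- function(pos, func, chrom = "chr1",
                     a1 = "A", a2 = "G", class = "single",
                     validated = TRUE) {
  n <- length(pos)
  out <- data.frame(chrom = chrom, pos = as.integer(pos),
                    allele1 = rep_len(a1, n), allele2 = rep_len(a2, n),
                    variant_class = rep_len(class, n),
                    func_category = rep_len(func, n),
                    validated = rep_len(validated, n),
                    valid_alleles = rep_len(a1 != a2 &
                                              rep_len(class, n) == "single", n),
                    risk_label = "other", stringsAsFactors = FALSE)
  class(out) <- c("snp_table", "data.frame")
  out
}

write_snp_tsv <- function(rows, path) {
  hdr <- "chrom\tchromStart\tchromEnd\tobserved\tclass\tfunc\tvalid"
  writeLines(c(hdr, rows), path)
  path
}
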
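# Substitution-spectrum computation and between-set comparison: the six
# unordered substitution types, transition/transversion fractions, and
# per-type two-proportion Z-tests.

#' The six substitution types
#'
#' Unordered allele-pair types. Transitions are `A/G` and `C/T`
#' (purine-purine, pyrimidine-pyrimidine); the four transversions are
#' `G/T`, `A/C`, `C/G` and `A/T`.
#'
#' @return character vector of the six type labels.
#' @export
substitution_types <- function() {
  c("A/G", "C/T", "G/T", "A/C", "C/G", "A/T")
}

.transition_types <- c("A/G", "C/T")

#' Classify an allele pair as a substitution type
#'
#' Order-invariant: `(G, A)` and `(A, G)` are the same `A/G` transition.
#' Vectorised over `a1`/`a2`.
#'
#' @param a1,a2 single bases in `{A, C, G, T}`, pairwise distinct.
#' @return data.frame with columns `type` (one of
#'   [substitution_types()]) and `is_transition`.
#' @export
classify_substitution <- function(a1, a2) {
  a1 <- toupper(a1)
  a2 <- toupper(a2)
  bases <- c("A", "C", "G", "T")
  if (any(!a1 %in% bases) || any(!a2 %in% bases)) {
    stop("alleles must be single bases in {A, C, G, T}")
  }
  if (any(a1 == a2)) stop("alleles must be distinct")
  type <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  data.frame(type = type, is_transition = type %in% .transition_types,
             stringsAsFactors = FALSE)
}

#' Substitution spectrum of a SNP set
#'
#' Counts each of the six substitution types over the valid records of a
#' SNP set and summarises transition/transversion fractions. Records with
#' invalid allele pairs are excluded and counted.
#'
#' @param snps a `snp_table`, or a data.frame with columns `allele1`,
#'   `allele2`.
#' @return object of class `SubstitutionSpectrum`: list with `counts` and
#'   `fractions` (named by type), `n_total`, `n_excluded`, `ts_fraction`,
#'   `tv_fraction` and `ts_tv_ratio`.
#' @export
substitution_spectrum <- function(snps) {
  valid <- if ("valid_alleles" %in% names(snps)) snps$valid_alleles
           else rep(TRUE, nrow(snps))
  n_excluded <- sum(!valid)
  snps <- snps[valid, , drop = FALSE]
  if (!nrow(snps)) stop("no valid allele pairs; cannot form a spectrum")
  cls <- classify_substitution(snps$allele1, snps$allele2)
  counts <- table(factor(cls$type, levels = substitution_types()))
  counts <- setNames(as.integer(counts), substitution_types())
  n <- sum(counts)
  fractions <- counts / n
  ts <- sum(counts[.transition_types])
  tv <- n - ts
  structure(list(counts = counts, fractions = fractions, n_total = n,
                 n_excluded = n_excluded,
                 ts_fraction = ts / n, tv_fraction = tv / n,
                 ts_tv_ratio = if (tv > 0) ts / tv else Inf),
            class = "SubstitutionSpectrum")
}

#' @export
print.SubstitutionSpectrum <- function(x, ...) {
  cat("SubstitutionSpectrum: n =", x$n_total, "\n")
  print(round(x$fractions, 4))
  cat("Ts fraction:", round(x$ts_fraction, 4),
      " Ts/Tv:", round(x$ts_tv_ratio, 3), "\n")
  invisible(x)
}

#' Compare two substitution spectra
#'
#' For each of the six substitution types, tests the difference of the
#' type's fraction between two SNP sets with a pooled two-proportion
#' Z-test (two-sided p from the normal distribution). Reported raw, with
#' a Bonferroni column (factor 6) for transparency.
#'
#' @param spec_a,spec_b `SubstitutionSpectrum` objects.
#' @return data.frame with one row per type: `type`, `frac_a`, `frac_b`,
#'   `z`, `p`, `p_bonferroni`.
#' @export
compare_spectra <- function(spec_a, spec_b) {
  if (spec_a$n_total == 0 || spec_b$n_total == 0) {
    stop("both spectra must be non-empty")
  }
  n1 <- spec_a$n_total
  n2 <- spec_b$n_total
  res <- lapply(substitution_types(), function(tp) {
    x1 <- spec_a$counts[[tp]]
    x2 <- spec_b$counts[[tp]]
    p1 <- x1 / n1
    p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se > 0) (p1 - p2) / se else 0
    p <- if (se > 0) 2 * pnorm(-abs(z)) else 1
    data.frame(type = tp, frac_a = p1, frac_b = p2, z = z, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * length(substitution_types()))
  out
}
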
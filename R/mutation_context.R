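# SNP-density profiling around somatic mutation sites with per-position
# Z-tests and fold-change calls at the focal offsets -1, 0, +1.

#' SNP density around mutation sites
#'
#' The density at offset `d` is the number of (mutation, SNP) pairs with
#' `snp_pos - mutation_pos = d`, divided by the number of usable mutation
#' sites (per-site averaging; the scale cancels in the Z and fold
#' statistics). A mutation coinciding exactly with a SNP contributes to
#' offset 0. Mutations whose window leaves the chromosome are dropped
#' (when `chrom_lengths` is not given, only left-clipped windows can be
#' detected and dropped).
#'
#' @param snp_sites data.frame with `chrom`, `pos` (SNP positions;
#'   duplicates allowed and counted with multiplicity).
#' @param mutation_sites data.frame with `chrom`, `pos`.
#' @param W half-window in bp (default 5000, i.e. a 10-kbp region).
#' @param chrom_lengths optional named chromosome lengths.
#' @return object of class `PositionalDensity`: list with `offsets`
#'   (`-W .. W`), `density`, `n_mutations` (after window clipping) and
#'   empty statistic slots filled by [positional_null()] /
#'   [positional_z_test()].
#' @export
snp_density_profile <- function(snp_sites, mutation_sites, W = 5000L,
                                chrom_lengths = NULL) {
  snp_sites <- .as_sites(snp_sites)
  muts <- .as_sites(mutation_sites)
  if (!is.null(chrom_lengths)) {
    known <- muts$chrom %in% names(chrom_lengths)
    ok <- known & muts$pos - W >= 0 &
      muts$pos + W <= chrom_lengths[muts$chrom] - 1
  } else {
    ok <- muts$pos - W >= 0
  }
  n_dropped <- sum(!ok)
  if (n_dropped) message(n_dropped, " mutation site(s) dropped (window clipped)")
  muts <- muts[ok, , drop = FALSE]
  if (!nrow(muts)) stop("no usable mutation sites")
  n <- 2L * W + 1L
  acc <- numeric(n)
  for (chr in unique(muts$chrom)) {
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths)) {
      chrom_lengths[[chr]]
    } else {
      max(c(snp_sites$pos[snp_sites$chrom == chr],
            muts$pos[muts$chrom == chr] + W)) + 1L
    }
    cnt <- .pos_tabulate(snp_sites$pos[snp_sites$chrom == chr], len)
    for (p in muts$pos[muts$chrom == chr]) {
      acc <- acc + .slice0(cnt, p - W + 1L, p + W + 1L)
    }
  }
  structure(list(offsets = seq(-W, W), density = acc / nrow(muts),
                 n_mutations = nrow(muts), u = NA_real_, s = NA_real_,
                 z = NULL, p = NULL, fold = NULL),
            class = "PositionalDensity")
}

#' Flank-based null for the positional density
#'
#' Estimates the null mean `u` and standard deviation `s` of the SNP
#' density as the sample mean and SD over offsets with
#' `|d| > exclusion_radius`, i.e. outside the core region where signal is
#' expected.
#'
#' @param density a `PositionalDensity`.
#' @param exclusion_radius offsets with `|d|` at or below this radius are
#'   excluded from the null (default 10).
#' @return the `PositionalDensity` with `u` and `s` filled in.
#' @export
positional_null <- function(density, exclusion_radius = 10L) {
  flank <- abs(density$offsets) > exclusion_radius
  vals <- density$density[flank]
  density$u <- mean(vals)
  density$s <- sd(vals)
  density
}

#' Per-offset Z-test on the positional density
#'
#' `z[d] = (density[d] - u) / s`; two-sided normal p-values, flagged at
#' level `alpha` with optional Bonferroni correction over the `2W + 1`
#' offsets.
#'
#' @param density a `PositionalDensity` with `u`, `s` set (see
#'   [positional_null()]), or pass `u` and `s` explicitly (e.g. published
#'   null parameters).
#' @param u,s null mean and SD; default taken from `density`.
#' @param alpha significance level (default 0.05).
#' @param bonferroni apply Bonferroni correction over all offsets
#'   (default `TRUE`).
#' @return the `PositionalDensity` with `z`, `p`, `flagged_enriched` and
#'   `flagged_depleted` (offset vectors) filled in.
#' @export
positional_z_test <- function(density, u = density$u, s = density$s,
                              alpha = 0.05, bonferroni = TRUE) {
  if (!is.finite(u) || !is.finite(s)) {
    stop("null parameters u, s are not set; run positional_null() first")
  }
  if (s <= 0) {
    stop("null SD is zero; widen the null region (exclusion_radius)")
  }
  z <- (density$density - u) / s
  p <- 2 * pnorm(-abs(z))
  thr <- if (bonferroni) alpha / length(z) else alpha
  sig <- p < thr
  density$u <- u
  density$s <- s
  density$z <- z
  density$p <- p
  density$alpha <- alpha
  density$bonferroni <- bonferroni
  density$flagged_enriched <- density$offsets[sig & z > 0]
  density$flagged_depleted <- density$offsets[sig & z < 0]
  density
}

#' Fold change of SNP density at focal offsets
#'
#' @param density a `PositionalDensity`.
#' @param u null mean (default from `density`); must be positive.
#' @param positions offsets to report (default `c(-1, 0, 1)`).
#' @return named numeric vector of `density[d] / u`.
#' @export
fold_report <- function(density, u = density$u, positions = c(-1L, 0L, 1L)) {
  if (!is.finite(u) || u <= 0) stop("null mean u must be positive")
  idx <- match(positions, density$offsets)
  if (anyNA(idx)) stop("requested position outside the profiled window")
  setNames(density$density[idx] / u, positions)
}
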
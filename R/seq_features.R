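# Sequence- and methylation-derived profiles: GC-content metaprofiles,
# DNA-methylation metaprofiles, the occupancy-vs-GC curve and the
# window-GC two-sample test.

# 0/1 indicator vectors over a chromosome string: is G/C, is not N.
.gc_indicators <- function(seqstr) {
  r <- charToRaw(seqstr)
  gc <- as.numeric(r == as.raw(71L) | r == as.raw(67L))   # G, C
  notn <- as.numeric(r != as.raw(78L))                    # not N
  list(gc = gc, notn = notn)
}

#' GC-content profile around anchors
#'
#' The value at offset `d` is the fraction of anchors carrying G or C at
#' `pos + d`; `N` bases are excluded from both numerator and denominator.
#' Anchors whose window leaves the chromosome are dropped.
#'
#' @param genome a `genome_seq` (see [read_genome_fasta()]).
#' @param anchors data.frame with `chrom`, `pos`.
#' @param W half-window in bp.
#' @return a `Profile` with values in `[0, 1]`.
#' @export
gc_profile <- function(genome, anchors, W = 1500L) {
  anchors <- .as_sites(anchors)
  lengths <- genome_lengths(genome)
  ok <- anchors$chrom %in% names(lengths) &
    anchors$pos - W >= 0 &
    anchors$pos + W <= lengths[anchors$chrom] - 1
  if (sum(!ok)) message(sum(!ok), " anchor(s) dropped (window out of bounds)")
  anchors <- anchors[ok, , drop = FALSE]
  if (!nrow(anchors)) stop("no usable anchors")
  n <- 2L * W + 1L
  num <- numeric(n)
  den <- numeric(n)
  for (chr in unique(anchors$chrom)) {
    ind <- .gc_indicators(unclass(genome)[[chr]])
    for (p in anchors$pos[anchors$chrom == chr]) {
      idx <- (p - W + 1L):(p + W + 1L)
      num <- num + ind$gc[idx]
      den <- den + ind$notn[idx]
    }
  }
  vals <- ifelse(den > 0, num / den, 0)
  new_profile(seq(-W, W), vals, nrow(anchors),
              normalization = list(genome_coverage_divisor = 1,
                                   per_anchor_averaged = TRUE,
                                   shift_used = 0L))
}

#' DNA-methylation profile around anchors
#'
#' Sums the measured methylation percentages at `pos + d` over anchors and
#' divides by the number of anchors (`average = "anchors"`, the default:
#' unmeasured positions contribute zero) or by the number of anchors with
#' a measurement at that offset (`average = "observed"`). Contributions
#' are additive: a track with duplicate rows at one position sums them.
#'
#' @param track a `methylation_track` (columns `chrom`, `pos`, `level`).
#' @inheritParams gc_profile
#' @param average `"anchors"` or `"observed"` (see Details).
#' @param chrom_lengths optional named chromosome lengths.
#' @return a `Profile` of mean methylation percentages.
#' @export
methylation_profile <- function(track, anchors, W = 1500L,
                                average = c("anchors", "observed"),
                                chrom_lengths = NULL) {
  average <- match.arg(average)
  anchors <- .as_sites(anchors)
  if (!nrow(anchors)) stop("no anchors")
  lengths <- .resolve_lengths(chrom_lengths,
                              tags = if (nrow(track))
                                data.frame(chrom = track$chrom,
                                           end = track$pos + 1L) else NULL,
                              anchors = anchors, W = W)
  n <- 2L * W + 1L
  lev <- numeric(n)
  cnt <- numeric(n)
  for (chr in unique(anchors$chrom)) {
    len <- lengths[[chr]]
    sub <- track[track$chrom == chr, , drop = FALSE]
    lv <- numeric(len)
    me <- numeric(len)
    if (nrow(sub)) {
      keep <- sub$pos >= 0 & sub$pos < len
      sub <- sub[keep, , drop = FALSE]
      agg_l <- tapply(sub$level, sub$pos, sum)
      agg_n <- tapply(rep(1, nrow(sub)), sub$pos, sum)
      at <- as.integer(names(agg_l)) + 1L
      lv[at] <- as.numeric(agg_l)
      me[at] <- as.numeric(agg_n > 0)
    }
    for (p in anchors$pos[anchors$chrom == chr]) {
      lev <- lev + .slice0(lv, p - W + 1L, p + W + 1L)
      cnt <- cnt + .slice0(me, p - W + 1L, p + W + 1L)
    }
  }
  vals <- if (average == "anchors") lev / nrow(anchors)
          else ifelse(cnt > 0, lev / cnt, 0)
  new_profile(seq(-W, W), vals, nrow(anchors),
              normalization = list(genome_coverage_divisor = 1,
                                   per_anchor_averaged = TRUE,
                                   shift_used = 0L))
}

# per-anchor GC fraction of the symmetric window [pos - w/2, pos + w/2)
# via cumulative sums; anchors with out-of-bounds or all-N windows -> NA.
.window_gc <- function(genome, anchors, window) {
  half <- window %/% 2L
  lengths <- genome_lengths(genome)
  out <- rep(NA_real_, nrow(anchors))
  for (chr in unique(anchors$chrom)) {
    if (!chr %in% names(lengths)) next
    len <- lengths[[chr]]
    ind <- .gc_indicators(unclass(genome)[[chr]])
    cg <- cumsum(c(0, ind$gc))
    cn <- cumsum(c(0, ind$notn))
    sel <- which(anchors$chrom == chr)
    p <- anchors$pos[sel]
    lo <- p - half
    hi <- p + half  # exclusive
    ok <- lo >= 0 & hi <= len
    gcs <- rep(NA_real_, length(p))
    nn <- cn[hi[ok] + 1L] - cn[lo[ok] + 1L]
    gg <- cg[hi[ok] + 1L] - cg[lo[ok] + 1L]
    gcs[ok] <- ifelse(nn > 0, gg / nn, NA_real_)
    out[sel] <- gcs
  }
  out
}

#' Nucleosome occupancy versus local GC content
#'
#' For every usable SNP, computes (i) the GC fraction of the
#' `gc_window`-bp region surrounding it and (ii) its mean nucleosome
#' occupancy over the `occ_window`-bp region (nucleosome mode: 146-bp
#' extended tag coverage on both strands, divided by the genome-average
#' coverage; no strand shift is applied since a 200-bp mean is shift
#' insensitive). The per-SNP points are binned by GC fraction.
#'
#' @param genome a `genome_seq`.
#' @param tags nucleosome `TagSet` (raw, unextended).
#' @param anchors data.frame with `chrom`, `pos` (SNP sites).
#' @param gc_window width of the GC window (600 bp).
#' @param occ_window width of the occupancy window (200 bp, nucleosomal
#'   DNA + linker).
#' @param bin_width GC-fraction bin width (default 0.02).
#' @param genome_length total genome length for coverage normalisation;
#'   defaults to the sum of the genome's chromosome lengths.
#' @return data.frame of class `gc_occupancy_curve` with columns
#'   `gc_lo`, `gc_hi`, `mean_occupancy`, `n`, `low_confidence`
#'   (`n < 20`). SNPs with out-of-bounds windows are skipped.
#' @export
occupancy_vs_gc <- function(genome, tags, anchors, gc_window = 600L,
                            occ_window = 200L, bin_width = 0.02,
                            genome_length = NULL) {
  anchors <- .as_sites(anchors)
  lengths <- genome_lengths(genome)
  if (is.null(genome_length)) genome_length <- sum(lengths)
  ext <- extend_tags(tags, 146L)
  iv <- ext$intervals
  cvg <- sum(iv$end - iv$start) / genome_length
  gc <- .window_gc(genome, anchors, gc_window)
  half <- occ_window %/% 2L
  occ <- rep(NA_real_, nrow(anchors))
  for (chr in unique(anchors$chrom)) {
    if (!chr %in% names(lengths)) next
    len <- lengths[[chr]]
    sub <- iv[iv$chrom == chr, , drop = FALSE]
    cv <- cumsum(c(0, .coverage_vector(sub$start, sub$end, len)))
    sel <- which(anchors$chrom == chr)
    p <- anchors$pos[sel]
    lo <- p - half
    hi <- p + half
    ok <- lo >= 0 & hi <= len
    vals <- rep(NA_real_, length(p))
    vals[ok] <- (cv[hi[ok] + 1L] - cv[lo[ok] + 1L]) / occ_window / cvg
    occ[sel] <- vals
  }
  use <- is.finite(gc) & is.finite(occ)
  gc <- gc[use]
  occ <- occ[use]
  nbins <- ceiling(1 / bin_width)
  bin <- pmin(floor(gc / bin_width), nbins - 1L) + 1L
  out <- data.frame(
    gc_lo = (seq_len(nbins) - 1L) * bin_width,
    gc_hi = pmin(seq_len(nbins) * bin_width, 1),
    mean_occupancy = as.numeric(tapply(occ, factor(bin, levels = seq_len(nbins)),
                                       mean)),
    n = as.integer(table(factor(bin, levels = seq_len(nbins)))))
  out$low_confidence <- out$n < 20L
  keep <- out$n > 0L
  out <- out[keep, , drop = FALSE]
  class(out) <- c("gc_occupancy_curve", "data.frame")
  attr(out, "n_snps") <- length(gc)
  out
}

#' Two-sample t-test on window GC content
#'
#' Computes the per-anchor GC fraction of the `window`-bp region around
#' each site in two anchor sets and compares the sets with a two-sample
#' t-test (Welch by default; set `var_equal = TRUE` for the pooled
#' variant). Two-sided.
#'
#' @param genome a `genome_seq`.
#' @param anchors_a,anchors_b data.frames with `chrom`, `pos`.
#' @param window window width in bp (default 600).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return list with `t`, `p`, group means `mean_a`, `mean_b`, sizes
#'   `n_a`, `n_b`, and degrees of freedom `df`.
#' @export
window_gc_ttest <- function(genome, anchors_a, anchors_b, window = 600L,
                            var_equal = FALSE) {
  ga <- .window_gc(genome, .as_sites(anchors_a), window)
  gb <- .window_gc(genome, .as_sites(anchors_b), window)
  ga <- ga[is.finite(ga)]
  gb <- gb[is.finite(gb)]
  if (length(ga) < 2 || length(gb) < 2) stop("need >= 2 usable anchors per set")
  tt <- t.test(ga, gb, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(ga), mean_b = mean(gb),
       n_a = length(ga), n_b = length(gb), df = unname(tt$parameter))
}
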
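# Normalised aggregate tag profiles around anchor sites. This is the
# package's core computation: strand-specific counting, cross-strand shift
# alignment, optional 146-bp nucleosomal extension, genome-coverage
# normalisation and per-anchor averaging.
#
# Counting units:
#   * point mode      - the 5' end of each tag (start for +/. tags,
#                       end - 1 for - tags) contributes one count.
#   * coverage mode   - every base covered by the (extended) tag interval
#                       contributes one count; used for nucleosome
#                       occupancy after 146-bp extension.

.five_prime <- function(iv) {
  ifelse(iv$strand == "-", iv$end - 1L, iv$start)
}

# Per-strand count vectors for every chromosome carrying anchors.
# Tags with strand "." are counted on the plus strand.
.strand_count_vectors <- function(iv, chroms, lengths, count) {
  res <- list("+" = list(), "-" = list())
  for (chr in chroms) {
    len <- lengths[[chr]]
    sub <- iv[iv$chrom == chr, , drop = FALSE]
    for (st in c("+", "-")) {
      ss <- if (st == "+") sub[sub$strand %in% c("+", "."), , drop = FALSE]
            else sub[sub$strand == "-", , drop = FALSE]
      res[[st]][[chr]] <- if (count == "point") {
        .pos_tabulate(.five_prime(ss), len)
      } else {
        .coverage_vector(ss$start, ss$end, len)
      }
    }
  }
  res
}

# Shared engine: per-strand aggregate counts around anchors.
#   count_W: half-window actually tallied (may exceed drop_W so that the
#            shifted sum is defined over the full reported window).
#   drop_W : anchors whose +/- drop_W window leaves the chromosome are
#            dropped (and reported via the "dropped_anchors" attribute).
.strand_counts <- function(tags, anchors, count_W, drop_W, count,
                           chrom_lengths = NULL) {
  iv <- if (inherits(tags, "TagSet")) tags$intervals else tags
  anchors <- .as_sites(anchors)
  lengths <- .resolve_lengths(chrom_lengths, tags = iv, anchors = anchors,
                              W = drop_W)
  known <- anchors$chrom %in% names(lengths)
  len_of <- lengths[anchors$chrom[known]]
  ok <- rep(FALSE, nrow(anchors))
  ok[known] <- anchors$pos[known] - drop_W >= 0 &
    anchors$pos[known] + drop_W <= len_of - 1
  n_dropped <- sum(!ok)
  anchors <- anchors[ok, , drop = FALSE]
  if (!nrow(anchors)) stop("no usable anchors (all windows out of bounds)")
  chroms <- unique(anchors$chrom)
  vecs <- .strand_count_vectors(iv, chroms, lengths, count)
  n <- 2L * count_W + 1L
  plus <- numeric(n)
  minus <- numeric(n)
  for (chr in chroms) {
    pv <- vecs[["+"]][[chr]]
    mv <- vecs[["-"]][[chr]]
    pos <- anchors$pos[anchors$chrom == chr]
    for (p in pos) {
      from <- p - count_W + 1L
      to <- p + count_W + 1L
      plus <- plus + .slice0(pv, from, to)
      minus <- minus + .slice0(mv, from, to)
    }
  }
  offsets <- seq(-count_W, count_W)
  pair <- structure(
    list(plus = new_profile(offsets, plus, nrow(anchors)),
         minus = new_profile(offsets, minus, nrow(anchors))),
    class = "StrandProfilePair")
  attr(pair, "dropped_anchors") <- n_dropped
  if (n_dropped > 0) {
    message(n_dropped, " anchor(s) dropped (window out of chromosome bounds)")
  }
  pair
}

#' Raw strand-specific count profiles around anchors
#'
#' Counts, separately for each strand, the tag signal at every offset in
#' `[-W, W]` relative to the anchor positions, summed over anchors. In
#' `"point"` mode the 5' tag ends are counted (the 5' end of a minus-strand
#' tag `[s, e)` is `e - 1`); in `"coverage"` mode every covered base
#' counts. Anchors whose window exceeds the chromosome bounds are dropped
#' and reported.
#'
#' @param tags a `TagSet`.
#' @param anchors data.frame with `chrom`, `pos` (0-based anchor sites).
#' @param W half-window in bp (default 1500, i.e. a 3-kbp region).
#' @param count `"point"` or `"coverage"`.
#' @param chrom_lengths optional named vector of chromosome lengths; when
#'   absent, lengths are inferred from the data (no right-boundary drops).
#' @return a `StrandProfilePair`: list with raw-count `Profile`s `plus`
#'   and `minus` over identical offsets and anchor counts.
#' @export
strand_count_profiles <- function(tags, anchors, W = 1500L,
                                  count = c("point", "coverage"),
                                  chrom_lengths = NULL) {
  count <- match.arg(count)
  .strand_counts(tags, anchors, count_W = W, drop_W = W, count = count,
                 chrom_lengths = chrom_lengths)
}

#' Estimate the cross-strand alignment shift
#'
#' Finds the non-negative shift `s` (in bp, moved by each strand toward
#' the other: plus right by `s`, minus left by `s`) that maximises the
#' Pearson correlation between the oppositely moved strand profiles over
#' their overlap. The objective is evaluated in both pairing directions
#' and the better one taken, so the estimate does not depend on which
#' profile is labelled plus (swapping the strands leaves the shift
#' unchanged). Ties are broken toward the smaller shift. If no shift
#' yields a defined correlation (zero-variance profile), shift 0 is
#' returned with a warning.
#'
#' @param pair a `StrandProfilePair` from [strand_count_profiles()].
#' @param max_shift largest candidate shift (73 for nucleosome tags,
#'   whose 5' ends sit ~73 bp from the dyad on each strand).
#' @return list of class `ShiftEstimate` with elements `shift` and
#'   `objective_curve` (correlation per candidate shift; `NA` where
#'   undefined).
#' @export
estimate_shift <- function(pair, max_shift = 73L) {
  p <- pair$plus$values
  m <- pair$minus$values
  n <- length(p)
  obj <- rep(NA_real_, max_shift + 1L)
  for (s in 0:max_shift) {
    keep <- n - 2L * s
    if (keep < 3L) break
    lo <- seq_len(keep)
    hi <- seq.int(n - keep + 1L, n)
    # plus right / minus left pairs plus[d - s] with minus[d + s];
    # the reversed pairing covers a swapped strand labelling
    r1 <- if (sd(p[lo]) > 0 && sd(m[hi]) > 0) cor(p[lo], m[hi]) else NA_real_
    r2 <- if (sd(m[lo]) > 0 && sd(p[hi]) > 0) cor(m[lo], p[hi]) else NA_real_
    obj[s + 1L] <- if (all(is.na(c(r1, r2)))) NA_real_
                   else max(r1, r2, na.rm = TRUE)
  }
  if (all(is.na(obj))) {
    warning("zero-variance strand profile; using shift 0")
    shift <- 0L
  } else {
    shift <- which.max(obj) - 1L  # first maximum = smallest shift on ties
  }
  structure(list(shift = as.integer(shift), objective_curve = obj),
            class = "ShiftEstimate")
}

#' Extend tags to the nucleosomal footprint
#'
#' Extends every tag to `length` bp in its 3' direction: a plus (or
#' unstranded) tag `[s, e)` becomes `[s, s + length)`; a minus tag
#' becomes `[e - length, e)`, clipped at 0.
#'
#' @param tags a `TagSet`.
#' @param length footprint length in bp (146, the nucleosomal DNA length).
#' @return a new `TagSet` with extended intervals.
#' @export
extend_tags <- function(tags, length = 146L) {
  iv <- tags$intervals
  plus <- iv$strand %in% c("+", ".")
  start <- ifelse(plus, iv$start, pmax(iv$end - length, 0L))
  end <- ifelse(plus, iv$start + length, iv$end)
  tag_set(data.frame(chrom = iv$chrom, start = as.integer(start),
                     end = as.integer(end), strand = iv$strand,
                     stringsAsFactors = FALSE),
          paste0(tags$source_label, "_ext", length))
}

#' Normalised aggregate profile around anchors
#'
#' The full profiling pipeline: (1) in `"nucleosome"` mode tags are first
#' extended to 146 bp in the 3' direction and per-base coverage is
#' counted; in `"point"` mode 5' tag ends are counted; (2) strand-specific
#' profiles are built; (3) the cross-strand shift is estimated on the
#' `[-W, W]` window (capped at `max_shift`: 73 in nucleosome mode, 100 in
#' point mode by default) and the two profiles are oppositely moved by the
#' shift and summed (counts for the shifted-in positions come from an
#' internally extended window, so no zero-padding artefacts); (4) the
#' summed profile is divided by the genome-average tag coverage `c` and by
#' the number of anchors.
#'
#' The coverage divisor is `c = F / genome_length` where `F` is the total
#' tag footprint in bases: the summed extended-interval widths in
#' nucleosome mode, the tag count in point mode. Under spatially uniform
#' tags the profile is therefore ~1 at every offset.
#'
#' @inheritParams strand_count_profiles
#' @param mode `"point"` (HM / Pol II / H2A.Z / CTCF tags) or
#'   `"nucleosome"` (146-bp extension + coverage counting + shift cap 73).
#' @param max_shift cap on the strand shift; default 73 (nucleosome) /
#'   100 (point).
#' @param genome_length total genome length in bp (normalisation
#'   denominator); must be positive.
#' @param shift optional fixed shift overriding estimation.
#' @return a `Profile` over offsets `[-W, W]`; its `normalization` field
#'   records the coverage divisor, per-anchor averaging and shift used.
#' @export
aggregate_profile <- function(tags, anchors, W = 1500L,
                              mode = c("point", "nucleosome"),
                              max_shift = NULL, genome_length,
                              chrom_lengths = NULL, shift = NULL) {
  mode <- match.arg(mode)
  if (genome_length <= 0) stop("genome_length must be positive")
  if (is.null(max_shift)) max_shift <- if (mode == "nucleosome") 73L else 100L
  count <- "point"
  if (mode == "nucleosome") {
    tags <- extend_tags(tags, 146L)
    count <- "coverage"
  }
  iv <- tags$intervals
  footprint <- if (mode == "nucleosome") sum(iv$end - iv$start)
               else nrow(iv)
  cvg <- footprint / genome_length
  pair_ext <- .strand_counts(tags, anchors, count_W = W + max_shift,
                             drop_W = W, count = count,
                             chrom_lengths = chrom_lengths)
  # trim to the reported window for shift estimation
  n_ext <- 2L * (W + max_shift) + 1L
  mid <- (max_shift + 1L):(n_ext - max_shift)
  pair_W <- structure(
    list(plus = new_profile(seq(-W, W), pair_ext$plus$values[mid],
                            pair_ext$plus$n_anchors),
         minus = new_profile(seq(-W, W), pair_ext$minus$values[mid],
                             pair_ext$minus$n_anchors)),
    class = "StrandProfilePair")
  s <- if (!is.null(shift)) as.integer(shift)
       else estimate_shift(pair_W, max_shift)$shift
  # final[d] = plus[d - s] + minus[d + s] for d in [-W, W]
  d_idx <- seq(-W, W) + (W + max_shift) + 1L
  summed <- pair_ext$plus$values[d_idx - s] + pair_ext$minus$values[d_idx + s]
  n_anchors <- pair_ext$plus$n_anchors
  if (cvg <= 0) {
    values <- summed * 0
  } else {
    values <- summed / cvg / n_anchors
  }
  new_profile(seq(-W, W), values, n_anchors,
              normalization = list(genome_coverage_divisor = cvg,
                                   per_anchor_averaged = TRUE,
                                   shift_used = s))
}

#' Bound-region binding profile around anchors
#'
#' For protein-binding data given as bound regions (not tags): the value
#' at offset `d` is the fraction of anchors whose position `pos + d` lies
#' inside any bound region, hence in `[0, 1]`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open bound regions).
#' @inheritParams strand_count_profiles
#' @return a `Profile` with values in `[0, 1]`.
#' @export
region_binding_profile <- function(regions, anchors, W = 1500L,
                                   chrom_lengths = NULL) {
  anchors <- .as_sites(anchors)
  lengths <- .resolve_lengths(chrom_lengths, tags = regions,
                              anchors = anchors, W = W)
  n <- 2L * W + 1L
  acc <- numeric(n)
  for (chr in unique(anchors$chrom)) {
    len <- lengths[[chr]]
    sub <- regions[regions$chrom == chr, , drop = FALSE]
    memb <- as.numeric(.coverage_vector(sub$start, sub$end, len) > 0)
    for (p in anchors$pos[anchors$chrom == chr]) {
      acc <- acc + .slice0(memb, p - W + 1L, p + W + 1L)
    }
  }
  new_profile(seq(-W, W), acc / nrow(anchors), nrow(anchors),
              normalization = list(genome_coverage_divisor = 1,
                                   per_anchor_averaged = TRUE,
                                   shift_used = 0L))
}

#' Pearson correlation between two profiles
#'
#' @param p1,p2 `Profile`s over identical offsets.
#' @return Pearson correlation of the value vectors.
#' @export
profile_correlation <- function(p1, p2) {
  if (!identical(p1$offsets, p2$offsets)) {
    stop("profiles must share identical offsets")
  }
  cor(p1$values, p2$values)
}

#' Smooth a profile with a running mean
#'
#' Running mean with window `k` (shrinking at the edges, no NA padding).
#' Used e.g. for the flatness check on random-locus control profiles.
#'
#' @param profile a `Profile`.
#' @param k window width in offsets (odd recommended).
#' @return a smoothed `Profile`.
#' @export
smooth_profile <- function(profile, k = 75L) {
  new_profile(profile$offsets, .running_mean(profile$values, k),
              profile$n_anchors, profile$normalization)
}
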
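# Independent brute-force oracles. These re-derive every profile /
# statistic with plain loops over (anchor, tag, offset) tuples, sharing no
# code with the package internals, and are the reference in the
# oracle-equivalence tests.

# 5' end of a tag: start for + and ., end - 1 for -
oracle_five_prime <- function(chrom, start, end, strand) {
  if (strand == "-") end - 1L else start
}

# per-strand raw counts around anchors; returns list(plus, minus) vectors
# over offsets -W..W. count: "point" or "coverage". Anchors outside
# [dropW, len - 1 - dropW] are dropped.
oracle_strand_counts <- function(tags, anchors, W, count, chrom_lengths,
                                 drop_W = W) {
  iv <- tags$intervals
  n <- 2L * W + 1L
  plus <- numeric(n)
  minus <- numeric(n)
  kept <- 0L
  for (a in seq_len(nrow(anchors))) {
    chr <- anchors$chrom[a]
    pos <- anchors$pos[a]
    len <- chrom_lengths[[chr]]
    if (is.null(len) || is.na(len)) next
    if (pos - drop_W < 0 || pos + drop_W > len - 1) next
    kept <- kept + 1L
    for (t in seq_len(nrow(iv))) {
      if (iv$chrom[t] != chr) next
      st <- iv$strand[t]
      side <- if (st == "-") "minus" else "plus"
      for (d in -W:W) {
        gpos <- pos + d
        if (gpos < 0 || gpos > len - 1) next
        hit <- if (count == "point") {
          oracle_five_prime(chr, iv$start[t], iv$end[t], st) == gpos
        } else {
          iv$start[t] <= gpos && gpos < iv$end[t]
        }
        if (hit) {
          if (side == "plus") plus[d + W + 1L] <- plus[d + W + 1L] + 1
          else minus[d + W + 1L] <- minus[d + W + 1L] + 1
        }
      }
    }
  }
  list(plus = plus, minus = minus, n_anchors = kept)
}

# shift estimate matching the documented definition: symmetric in the two
# profiles, ties toward the smaller shift
oracle_shift <- function(plus, minus, max_shift) {
  n <- length(plus)
  best <- NA_real_
  best_s <- 0L
  for (s in 0:max_shift) {
    keep <- n - 2L * s
    if (keep < 3L) break
    a <- plus[1:keep]
    b <- minus[(n - keep + 1):n]
    a2 <- minus[1:keep]
    b2 <- plus[(n - keep + 1):n]
    vals <- c()
    if (sd(a) > 0 && sd(b) > 0) vals <- c(vals, cor(a, b))
    if (sd(a2) > 0 && sd(b2) > 0) vals <- c(vals, cor(a2, b2))
    if (!length(vals)) next
    v <- max(vals)
    if (is.na(best) || v > best) {
      best <- v
      best_s <- s
    }
  }
  best_s
}

oracle_extend <- function(tags, len_ext = 146L) {
  iv <- tags$intervals
  for (t in seq_len(nrow(iv))) {
    if (iv$strand[t] == "-") {
      iv$start[t] <- max(iv$end[t] - len_ext, 0L)
    } else {
      iv$end[t] <- iv$start[t] + len_ext
    }
  }
  tag_set(iv, tags$source_label)
}

# full aggregate-profile pipeline, brute force
oracle_aggregate_profile <- function(tags, anchors, W, mode, max_shift,
                                     genome_length, chrom_lengths) {
  count <- "point"
  if (mode == "nucleosome") {
    tags <- oracle_extend(tags)
    count <- "coverage"
  }
  iv <- tags$intervals
  footprint <- if (mode == "nucleosome") sum(iv$end - iv$start) else nrow(iv)
  cvg <- footprint / genome_length
  ext <- oracle_strand_counts(tags, anchors, W + max_shift, count,
                              chrom_lengths, drop_W = W)
  n_ext <- 2L * (W + max_shift) + 1L
  mid <- (max_shift + 1L):(n_ext - max_shift)
  s <- oracle_shift(ext$plus[mid], ext$minus[mid], max_shift)
  vals <- numeric(2L * W + 1L)
  for (d in -W:W) {
    i <- d + W + max_shift + 1L
    vals[d + W + 1L] <- ext$plus[i - s] + ext$minus[i + s]
  }
  vals / cvg / ext$n_anchors
}

oracle_region_profile <- function(regions, anchors, W, chrom_lengths) {
  n <- 2L * W + 1L
  vals <- numeric(n)
  for (a in seq_len(nrow(anchors))) {
    for (d in -W:W) {
      gpos <- anchors$pos[a] + d
      inside <- FALSE
      for (r in seq_len(nrow(regions))) {
        if (regions$chrom[r] == anchors$chrom[a] &&
            regions$start[r] <= gpos && gpos < regions$end[r]) {
          inside <- TRUE
          break
        }
      }
      if (inside) vals[d + W + 1L] <- vals[d + W + 1L] + 1
    }
  }
  vals / nrow(anchors)
}

oracle_gc_profile <- function(genome, anchors, W) {
  n <- 2L * W + 1L
  num <- numeric(n)
  den <- numeric(n)
  lens <- genome_lengths(genome)
  for (a in seq_len(nrow(anchors))) {
    chr <- anchors$chrom[a]
    pos <- anchors$pos[a]
    if (pos - W < 0 || pos + W > lens[[chr]] - 1) next
    for (d in -W:W) {
      base <- substr(unclass(genome)[[chr]], pos + d + 1L, pos + d + 1L)
      if (base == "N") next
      den[d + W + 1L] <- den[d + W + 1L] + 1
      if (base %in% c("G", "C")) num[d + W + 1L] <- num[d + W + 1L] + 1
    }
  }
  ifelse(den > 0, num / den, 0)
}

oracle_methylation_profile <- function(track, anchors, W) {
  n <- 2L * W + 1L
  vals <- numeric(n)
  for (a in seq_len(nrow(anchors))) {
    for (d in -W:W) {
      gpos <- anchors$pos[a] + d
      for (r in seq_len(nrow(track))) {
        if (track$chrom[r] == anchors$chrom[a] && track$pos[r] == gpos) {
          vals[d + W + 1L] <- vals[d + W + 1L] + track$level[r]
        }
      }
    }
  }
  vals / nrow(anchors)
}

oracle_density <- function(snp_sites, mutation_sites, W, chrom_lengths) {
  n <- 2L * W + 1L
  vals <- numeric(n)
  kept <- 0L
  for (m in seq_len(nrow(mutation_sites))) {
    chr <- mutation_sites$chrom[m]
    pos <- mutation_sites$pos[m]
    len <- chrom_lengths[[chr]]
    if (pos - W < 0 || pos + W > len - 1) next
    kept <- kept + 1L
    for (v in seq_len(nrow(snp_sites))) {
      if (snp_sites$chrom[v] != chr) next
      d <- snp_sites$pos[v] - pos
      if (d >= -W && d <= W) vals[d + W + 1L] <- vals[d + W + 1L] + 1
    }
  }
  vals / kept
}

oracle_hm_levels_one <- function(tags, sites, window, genome_length,
                                 max_shift, shift_window, chrom_lengths) {
  iv <- tags$intervals
  cvg <- nrow(iv) / genome_length
  sc <- oracle_strand_counts(tags, sites, shift_window, "point",
                             chrom_lengths, drop_W = shift_window)
  s <- oracle_shift(sc$plus, sc$minus, max_shift)
  half <- window %/% 2L
  out <- numeric(nrow(sites))
  for (a in seq_len(nrow(sites))) {
    cnt <- 0L
    for (t in seq_len(nrow(iv))) {
      if (iv$chrom[t] != sites$chrom[a]) next
      fp <- oracle_five_prime(iv$chrom[t], iv$start[t], iv$end[t],
                              iv$strand[t])
      fp <- if (iv$strand[t] == "-") fp - s else fp + s
      if (fp >= sites$pos[a] - half && fp < sites$pos[a] + half) cnt <- cnt + 1L
    }
    out[a] <- cnt / cvg
  }
  out
}

# AUC as the Mann-Whitney pairwise statistic (ties count one half)
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sn)) {
      tot <- tot + (sp[i] > sn[j]) + 0.5 * (sp[i] == sn[j])
    }
  }
  tot / (length(sp) * length(sn))
}

# two-proportion pooled Z statistic, closed form
oracle_two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  c(z = z, p = 2 * pnorm(-abs(z)))
}
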
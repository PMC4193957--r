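# Strand counting, shift estimation, tag extension, the aggregate
# profile pipeline and its invariants.

test_that("strand_count_profiles does single-event bookkeeping correctly", {
  lens <- c(chrT = 1000L)
  anchors <- data.frame(chrom = "chrT", pos = 100L)
  tags <- tag_set(data.frame(chrom = "chrT", start = 95L, end = 120L,
                             strand = "+"))
  pair <- strand_count_profiles(tags, anchors, W = 5L, chrom_lengths = lens)
  expect_equal(pair$plus$values, c(1, rep(0, 10)))  # offset -5
  expect_equal(pair$minus$values, rep(0, 11))

  # 5' end of a minus tag [104, 130) is 129 -> offset +29
  tags2 <- tag_set(data.frame(chrom = "chrT", start = 104L, end = 130L,
                              strand = "-"))
  pair2 <- strand_count_profiles(tags2, anchors, W = 30L, chrom_lengths = lens)
  expect_equal(which(pair2$minus$values == 1) - 31L, 29L)
  expect_equal(sum(pair2$minus$values), 1)
  expect_equal(sum(pair2$plus$values), 0)

  # two identical anchors double every count (additivity)
  two <- rbind(anchors, anchors)
  pair3 <- strand_count_profiles(tags, two, W = 5L, chrom_lengths = lens)
  expect_equal(pair3$plus$values, 2 * pair$plus$values)

  # out-of-bounds anchors are dropped with a message, all dropped is fatal
  edge <- data.frame(chrom = "chrT", pos = c(2L, 100L))
  expect_message(
    pr <- strand_count_profiles(tags, edge, W = 5L, chrom_lengths = lens),
    "dropped")
  expect_equal(pr$plus$n_anchors, 1L)
  expect_error(
    suppressMessages(strand_count_profiles(
      tags, data.frame(chrom = "chrT", pos = 2L), W = 5L,
      chrom_lengths = lens)),
    "no usable anchors")
})

test_that("estimate_shift recovers peak alignment, caps, and handles ties", {
  W <- 100L
  offs <- -W:W
  peak <- function(at) as.numeric(offs == at)
  pair <- list(plus = new_profile(offs, peak(-73), 1L),
               minus = new_profile(offs, peak(73), 1L))
  est <- estimate_shift(pair, max_shift = 73L)
  expect_equal(est$shift, 73L)

  # already-aligned profiles need no shift
  same <- list(plus = new_profile(offs, peak(0), 1L),
               minus = new_profile(offs, peak(0), 1L))
  expect_equal(estimate_shift(same, max_shift = 73L)$shift, 0L)

  # mirror peaks at -/+30 (triangular, so the objective rises toward
  # alignment) with the cap at 20: the cap binds
  tri <- function(at) pmax(0, 15 - abs(offs - at))
  capped <- list(plus = new_profile(offs, tri(-30), 1L),
                 minus = new_profile(offs, tri(30), 1L))
  expect_equal(estimate_shift(capped, max_shift = 20L)$shift, 20L)

  # zero-variance profile: shift 0 with a warning
  flat <- list(plus = new_profile(offs, rep(2, length(offs)), 1L),
               minus = new_profile(offs, peak(0), 1L))
  expect_warning(est0 <- estimate_shift(flat, max_shift = 10L),
                 "zero-variance")
  expect_equal(est0$shift, 0L)
})

test_that("shift estimation is invariant under swapping the strand profiles", {
  withr::local_seed(42)
  W <- 60L
  offs <- -W:W
  for (i in 1:20) {
    a <- pmax(0, 20 - abs(offs + sample(0:40, 1))) + rpois(length(offs), 1)
    b <- pmax(0, 20 - abs(offs - sample(0:40, 1))) + rpois(length(offs), 1)
    pair <- list(plus = new_profile(offs, a, 1L),
                 minus = new_profile(offs, b, 1L))
    swap <- list(plus = new_profile(offs, b, 1L),
                 minus = new_profile(offs, a, 1L))
    expect_identical(estimate_shift(pair, 40L)$shift,
                     estimate_shift(swap, 40L)$shift)
  }
})

test_that("extend_tags extends 146 bp in the 3' direction with clipping", {
  tags <- tag_set(data.frame(chrom = "chrT",
                             start = c(1000L, 1000L, 10L),
                             end = c(1025L, 1025L, 35L),
                             strand = c("+", "-", "-")))
  ext <- extend_tags(tags, 146L)
  expect_equal(ext$intervals$start, c(1000L, 879L, 0L))
  expect_equal(ext$intervals$end, c(1146L, 1025L, 35L))
})

test_that("aggregate_profile normalizes uniform tags to ~1 and is scale invariant", {
  lens <- c(chrT = 20000L)
  # perfectly uniform point tags: one 5' end per strand per position
  pos <- 0:19963
  uni <- tag_set(rbind(
    data.frame(chrom = "chrT", start = pos, end = pos + 36L, strand = "+"),
    data.frame(chrom = "chrT", start = pos, end = pos + 36L, strand = "-")))
  anchors <- data.frame(chrom = "chrT", pos = c(5000L, 9000L, 15000L))
  pr <- suppressWarnings(
    aggregate_profile(uni, anchors, W = 100L, mode = "point",
                      genome_length = 20000, chrom_lengths = lens))
  expect_true(all(abs(pr$values - 1) < 0.01))
  expect_equal(pr$normalization$per_anchor_averaged, TRUE)

  # doubling tags and genome-wide coverage leaves the profile unchanged
  doubled <- tag_set(rbind(uni$intervals, uni$intervals))
  pr2 <- aggregate_profile(doubled, anchors, W = 100L, mode = "point",
                           genome_length = 20000, chrom_lengths = lens,
                           shift = pr$normalization$shift_used)
  expect_equal(pr2$values, pr$values, tolerance = 1e-12)
  expect_error(aggregate_profile(uni, anchors, W = 10L, mode = "point",
                                 genome_length = 0),
               "genome_length")
})

test_that("aggregate_profile equals the brute-force oracle on small instances", {
  withr::local_seed(101)
  lens <- c(chrT = 2000L)
  for (i in 1:12) {
    W <- sample(20:40, 1)
    ms <- sample(3:8, 1)
    mode <- sample(c("point", "nucleosome"), 1)
    tags <- random_tags(sample(30:100, 1), 2000L)
    anchors <- random_sites(sample(3:10, 1), 2000L, margin = W + 1L)
    got <- aggregate_profile(tags, anchors, W = W, mode = mode,
                             max_shift = ms, genome_length = 2000,
                             chrom_lengths = lens)
    want <- oracle_aggregate_profile(tags, anchors, W = W, mode = mode,
                                     max_shift = ms, genome_length = 2000,
                                     chrom_lengths = lens)
    expect_equal(got$values, want, tolerance = 1e-12)
  }
})

test_that("profiles are invariant under joint translation of anchors and tags", {
  withr::local_seed(7)
  tags <- random_tags(200, 3000L)
  # keep every (extended) tag clear of both chromosome ends in both
  # instances so boundary clipping cannot break exact invariance
  tags <- tag_set(within(tags$intervals, {
    start <- start + 200L
    end <- end + 200L
  }), "base")
  anchors <- random_sites(5, 3000L, margin = 60L)
  anchors <- within(anchors, pos <- pos + 200L)
  shift_by <- 500L
  tags2 <- tag_set(within(tags$intervals, {
    start <- start + shift_by
    end <- end + shift_by
  }), "shifted")
  anchors2 <- within(anchors, pos <- pos + shift_by)
  a <- aggregate_profile(tags, anchors, W = 50L, mode = "nucleosome",
                         max_shift = 10L, genome_length = 4200,
                         chrom_lengths = c(chrT = 4200L))
  b <- aggregate_profile(tags2, anchors2, W = 50L, mode = "nucleosome",
                         max_shift = 10L, genome_length = 4200,
                         chrom_lengths = c(chrT = 4200L))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("region_binding_profile matches membership semantics and the oracle", {
  lens <- c(chrT = 500L)
  regions <- data.frame(chrom = "chrT", start = 90L, end = 110L)
  anchors <- data.frame(chrom = "chrT", pos = 100L)
  pr <- region_binding_profile(regions, anchors, W = 15L,
                               chrom_lengths = lens)
  expect_equal(pr$values[pr$offsets >= -10 & pr$offsets <= 9], rep(1, 20))
  expect_equal(sum(pr$values), 20)

  # empty interval set -> all-zero profile
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer())
  pr0 <- region_binding_profile(empty, anchors, W = 15L, chrom_lengths = lens)
  expect_equal(pr0$values, rep(0, 31))

  withr::local_seed(13)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    regions <- data.frame(chrom = "chrT",
                          start = sort(sample.int(400, n)))
    regions$end <- regions$start + sample(5:50, n, replace = TRUE)
    anchors <- random_sites(sample(2:6, 1), 500L, margin = 30L)
    got <- region_binding_profile(regions, anchors, W = 25L,
                                  chrom_lengths = lens)
    expect_equal(got$values,
                 oracle_region_profile(regions, anchors, 25L, lens),
                 tolerance = 1e-12)
  }
})

test_that("profile_correlation is Pearson on the value vectors", {
  withr::local_seed(3)
  v <- rnorm(41)
  p1 <- new_profile(-20:20, v, 1L)
  p2 <- new_profile(-20:20, 2 * v + 3, 1L)
  expect_equal(profile_correlation(p1, p2), 1)
  p3 <- new_profile(-20:20, -v, 1L)
  expect_equal(profile_correlation(p1, p3), -1)
  # closed-form oracle
  w <- rnorm(41)
  p4 <- new_profile(-20:20, w, 1L)
  r_oracle <- sum((v - mean(v)) * (w - mean(w))) /
    sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  expect_equal(profile_correlation(p1, p4), r_oracle, tolerance = 1e-12)
  expect_error(profile_correlation(p1, new_profile(-5:5, rnorm(11), 1L)),
               "identical offsets")
})
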
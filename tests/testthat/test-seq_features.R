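# GC profiles, methylation profiles, occupancy-vs-GC, window GC t-test.

test_that("gc_profile handles pure-GC genomes and single anchors exactly", {
  g <- structure(setNames(strrep("GC", 200), "chrT"), class = "genome_seq")
  anchors <- data.frame(chrom = "chrT", pos = 200L)
  pr <- gc_profile(g, anchors, W = 50L)
  expect_equal(pr$values, rep(1, 101))

  g2 <- structure(setNames(strrep("ATGC", 100), "chrT"),
                  class = "genome_seq")
  pr2 <- gc_profile(g2, data.frame(chrom = "chrT", pos = 100L), W = 3L)
  # positions 97..103 of (ATGC)* are T,G,C,A,T,G,C
  expect_equal(pr2$values, c(0, 1, 1, 0, 0, 1, 1))
})

test_that("gc_profile matches the brute-force tally with Ns excluded", {
  withr::local_seed(21)
  for (i in 1:5) {
    g <- random_genome(400, p_n = 0.1)
    anchors <- random_sites(sample(2:6, 1), 400L, margin = 25L)
    pr <- gc_profile(g, anchors, W = 20L)
    expect_equal(pr$values, oracle_gc_profile(g, anchors, 20L),
                 tolerance = 1e-12)
  }
})

test_that("methylation_profile averages levels and is linear in the track", {
  anchors <- data.frame(chrom = "chrT", pos = c(100L, 200L))
  # constant level 80 at every position -> profile constantly 80
  full <- data.frame(chrom = "chrT", pos = 0:299, level = 80)
  class(full) <- c("methylation_track", "data.frame")
  pr <- methylation_profile(full, anchors, W = 50L,
                            chrom_lengths = c(chrT = 300L))
  expect_equal(pr$values, rep(80, 101))

  # empty track -> all zeros
  empty <- full[0, ]
  pr0 <- methylation_profile(empty, anchors, W = 50L,
                             chrom_lengths = c(chrT = 300L))
  expect_equal(pr0$values, rep(0, 101))

  # sparse track vs brute force, and additivity over tracks
  withr::local_seed(31)
  lens <- c(chrT = 300L)
  for (i in 1:4) {
    t1 <- data.frame(chrom = "chrT", pos = sample.int(300, 40) - 1L,
                     level = runif(40, 0, 100))
    t2 <- data.frame(chrom = "chrT", pos = sample.int(300, 25) - 1L,
                     level = runif(25, 0, 100))
    p1 <- methylation_profile(t1, anchors, W = 30L, chrom_lengths = lens)
    expect_equal(p1$values, oracle_methylation_profile(t1, anchors, 30L),
                 tolerance = 1e-12)
    p2 <- methylation_profile(t2, anchors, W = 30L, chrom_lengths = lens)
    p12 <- methylation_profile(rbind(t1, t2), anchors, W = 30L,
                               chrom_lengths = lens)
    expect_equal(p12$values, p1$values + p2$values, tolerance = 1e-12)
  }

  # observed-only averaging divides by per-offset measurement counts
  one <- data.frame(chrom = "chrT", pos = 100L, level = 60)
  pr_obs <- methylation_profile(one, anchors, W = 10L, average = "observed",
                                chrom_lengths = lens)
  expect_equal(pr_obs$values[pr_obs$offsets == 0], 60)
})

test_that("occupancy_vs_gc bins SNPs correctly on hand-computable instances", {
  # genome: positions 0..999 are AT, 1000..1999 are GC; uniform tags
  g <- structure(setNames(paste0(strrep("AT", 500), strrep("GC", 500)),
                          "chrT"),
                 class = "genome_seq")
  pos <- seq(0L, 1960L, by = 2L)
  tags <- tag_set(data.frame(chrom = "chrT", start = pos, end = pos + 36L,
                             strand = "+"))
  anchors <- data.frame(chrom = "chrT", pos = c(300L, 1700L))
  curve <- occupancy_vs_gc(g, tags, anchors, gc_window = 100L,
                           occ_window = 50L, bin_width = 0.25)
  expect_equal(nrow(curve), 2L)  # one all-AT bin, one all-GC bin
  expect_equal(curve$gc_lo, c(0, 0.75))
  expect_equal(curve$n, c(1L, 1L))
  expect_true(all(curve$low_confidence))

  # uniform tags -> flat curve
  withr::local_seed(41)
  g2 <- random_genome(20000, p_n = 0)
  pos2 <- sort(sample(0:19960, 8000, replace = TRUE))
  tags2 <- tag_set(data.frame(chrom = "chrT", start = pos2,
                              end = pos2 + 36L,
                              strand = sample(c("+", "-"), 8000,
                                              replace = TRUE)))
  anchors2 <- random_sites(300, 20000L, margin = 400L)
  curve2 <- occupancy_vs_gc(g2, tags2, anchors2)
  solid <- curve2[!curve2$low_confidence, ]
  expect_gt(nrow(solid), 0)
  expect_lt(max(solid$mean_occupancy) / min(solid$mean_occupancy), 1.1)
})

test_that("window_gc_ttest matches t.test semantics and detects planted shifts", {
  # identical sets -> t = 0, p = 1
  withr::local_seed(51)
  g <- random_genome(5000, p_n = 0)
  anchors <- random_sites(30, 5000L, margin = 400L)
  res <- window_gc_ttest(g, anchors, anchors, window = 600L)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # planted delta-GC 0.05 at n = 500 windows/set: per-window GC has
  # binomial sd ~ sqrt(0.5 * 0.5 / 600) ~ 0.02, so p is tiny
  make_windows <- function(n, p_gc) {
    paste(vapply(seq_len(n), function(i) {
      paste(sample(c("G", "C", "A", "T"), 600, replace = TRUE,
                   prob = c(p_gc / 2, p_gc / 2, (1 - p_gc) / 2,
                            (1 - p_gc) / 2)), collapse = "")
    }, ""), collapse = "")
  }
  ga <- structure(setNames(make_windows(500, 0.50), "chrT"),
                  class = "genome_seq")
  centers <- data.frame(chrom = "chrT", pos = seq(300L, by = 600L,
                                                  length.out = 500))
  gb <- structure(setNames(make_windows(500, 0.55), "chrT"),
                  class = "genome_seq")
  gca <- snpchrom:::.window_gc(ga, centers, 600L)
  gcb <- snpchrom:::.window_gc(gb, centers, 600L)
  tt <- t.test(gca, gcb)
  expect_lt(tt$p.value, 1e-6)

  # the implementation agrees with stats::t.test to near machine precision
  joint <- structure(setNames(paste0(unclass(ga), unclass(gb)), "chrT"),
                     class = "genome_seq")
  centers_b <- within(centers, pos <- pos + 300000L)
  res2 <- window_gc_ttest(joint, centers, centers_b, window = 600L)
  expect_equal(res2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
})
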
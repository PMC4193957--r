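# Generator determinism, GC control, planted spectra/effects, clipping.

test_that("make_genome respects GC extremes and is deterministic", {
  cfg <- sim_config(seed = 17, genome_length = 20000L,
                    gc = list(intergenic_other = 1, intron = 1, exon = 1,
                              utr5 = 1, utr3 = 1, near_gene_5 = 1,
                              near_gene_3 = 1))
  gen <- make_genome(cfg)
  expect_false(grepl("[AT]", unclass(gen$genome)[[1]]))
  expect_equal(sum(gen$annotation$end - gen$annotation$start), 20000L)
  expect_equal(gen$annotation$start[1], 0L)
  # annotation intervals tile the genome without overlap
  expect_true(all(gen$annotation$start[-1] ==
                    head(gen$annotation$end, -1)))

  cfg2 <- sim_config(seed = 17, genome_length = 20000L)
  expect_identical(unclass(make_genome(cfg2)$genome),
                   unclass(make_genome(cfg2)$genome))

  # realized GC of a uniform-GC genome within 3 binomial s.e. of target
  cfg3 <- sim_config(seed = 18, genome_length = 10000L,
                     gc = list(intergenic_other = 0.45, intron = 0.45,
                               exon = 0.45, utr5 = 0.45, utr3 = 0.45,
                               near_gene_5 = 0.45, near_gene_3 = 0.45))
  g3 <- unclass(make_genome(cfg3)$genome)[[1]]
  gc_frac <- mean(strsplit(g3, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_frac - 0.45), 3 * sqrt(0.45 * 0.55 / 10000))
})

test_that("plant_snps places categories in their regions with planted alleles", {
  cfg <- sim_config(seed = 19, genome_length = 300000L)
  gen <- make_genome(cfg)
  planted <- plant_snps(cfg, gen$genome, gen$annotation)
  snps <- planted$snps
  expect_gt(nrow(snps), 500)
  # density 0 -> empty table
  cfg0 <- sim_config(seed = 19, genome_length = 50000L, snp_density = 0)
  gen0 <- make_genome(cfg0)
  expect_equal(nrow(plant_snps(cfg0, gen0$genome, gen0$annotation)$snps), 0L)
  # every exonic-category SNP lies in an exon block
  exonic <- snps[snps$func_category %in%
                   c("coding_synonymous", "coding_nonsynonymous",
                     "exon_other"), ]
  ann_ex <- gen$annotation[gen$annotation$class == "exon", ]
  in_exon <- vapply(exonic$pos, function(p) {
    any(ann_ex$start <= p & p < ann_ex$end)
  }, TRUE)
  expect_true(all(in_exon))
  # reference allele matches the genome base for single-class records
  sing <- snps[snps$variant_class == "single", ]
  idx <- sample(seq_len(nrow(sing)), 50)
  ref <- substring(unclass(gen$genome)[[1]], sing$pos[idx] + 1L,
                   sing$pos[idx] + 1L)
  expect_equal(sing$allele1[idx], ref)
  expect_true(all(sing$allele1 != sing$allele2))
})

test_that("simulate_nucleosome_tags responds to coverage and backgrounds", {
  cfg <- sim_config(seed = 20, genome_length = 50000L,
                    nucleosome = list(coverage_per_dyad = 0,
                                      background_rate = 0))
  gen <- make_genome(cfg)
  planted <- plant_snps(cfg, gen$genome, gen$annotation)
  tags <- simulate_nucleosome_tags(cfg, planted$snps,
                                   genome_lengths(gen$genome))
  expect_equal(tags$total_tag_count, 0L)

  cfg2 <- sim_config(seed = 20, genome_length = 50000L)
  tags2 <- simulate_nucleosome_tags(cfg2, planted$snps,
                                    genome_lengths(gen$genome))
  expect_gt(tags2$total_tag_count, 1000)
  expect_true(all(tags2$intervals$start >= 0))
  expect_true(all(tags2$intervals$end <= 50000))
  expect_setequal(unique(tags2$intervals$strand), c("+", "-"))
})

test_that("simulate_hm_tags plants class effects; zero baseline is empty", {
  cfg <- sim_config(seed = 21, genome_length = 100000L,
                    hm = list(baseline_window = 0, background_rate = 0))
  snps <- toy_snps(seq(5000, 90000, by = 5000), "intron", chrom = "chrS1")
  tags <- simulate_hm_tags(cfg, snps, c(chrS1 = 100000L))
  expect_equal(tags$HM1$total_tag_count, 0L)

  # planted risk effect doubles expected window counts
  cfg2 <- sim_config(seed = 22, genome_length = 400000L,
                     hm = list(background_rate = 0))
  n <- 300L
  snps2 <- toy_snps(seq(1000, by = 1000, length.out = n), "coding_synonymous",
                    chrom = "chrS1")
  snps2$risk_label <- rep(c("neutral", "risk_noncoding"), length.out = n)
  tags2 <- simulate_hm_tags(cfg2, snps2, c(chrS1 = 400000L))
  x <- suppressWarnings(
    hm_levels(tags2["HM1"], snps2, genome_length = 400000,
              chrom_lengths = c(chrS1 = 400000L)))
  counts <- x[, 1] * tags2$HM1$total_tag_count / 400000
  m_risk <- mean(counts[snps2$risk_label == "risk_noncoding"])
  m_neut <- mean(counts[snps2$risk_label == "neutral"])
  expect_gt(m_risk / m_neut, 1.6)
  expect_lt(m_risk / m_neut, 2.4)
})

test_that("plant_mutation_sites has the closed-form expected densities", {
  cfg <- sim_config(seed = 23)
  lens <- c(chrS1 = cfg$genome_length)
  # no planted signal: folds ~ 1 at -1, 0, +1
  cfg0 <- sim_config(seed = 24, mutation = list(p_enrich = 0, p_deplete = 0))
  p0 <- plant_mutation_sites(cfg0, snp_sites = NULL, chrom_lengths = lens)
  d0 <- suppressMessages(snp_density_profile(p0$snp_sites, p0$mutations,
                                             W = 100L, chrom_lengths = lens))
  d0 <- positional_null(d0)
  expect_equal(max(abs(fold_report(d0) - 1)), 0, tolerance = 0.35)

  # p_deplete = 1 removes every SNP at a mutation site
  cfg1 <- sim_config(seed = 25, mutation = list(p_deplete = 1, p_enrich = 0))
  p1 <- plant_mutation_sites(cfg1, snp_sites = NULL, chrom_lengths = lens)
  d1 <- suppressMessages(snp_density_profile(p1$snp_sites, p1$mutations,
                                             W = 50L, chrom_lengths = lens))
  expect_equal(d1$density[d1$offsets == 0], 0)
  # determinism
  p1b <- plant_mutation_sites(cfg1, snp_sites = NULL, chrom_lengths = lens)
  expect_identical(p1, p1b)
})

test_that("simulate_methylation clips to [0, 100] and separates classes", {
  cfg <- sim_config(seed = 26, genome_length = 200000L)
  snps <- toy_snps(seq(2000, 198000, by = 1000), "coding_synonymous",
                   chrom = "chrS1")
  snps$risk_label <- rep(c("neutral", "risk_noncoding"), length.out = nrow(snps))
  tr <- simulate_methylation(cfg, snps, c(chrS1 = 200000L))
  expect_true(all(tr$level >= 0 & tr$level <= 100))
  expect_false(any(duplicated(tr$pos)))
  pn <- methylation_profile(tr, snps[snps$risk_label == "neutral", ],
                            W = 50L, chrom_lengths = c(chrS1 = 200000L))
  pr <- methylation_profile(tr, snps[snps$risk_label == "risk_noncoding", ],
                            W = 50L, chrom_lengths = c(chrS1 = 200000L))
  expect_gt(pn$values[pn$offsets == 0] - pr$values[pr$offsets == 0], 20)

  # identical class means give profiles equal within noise
  cfg2 <- sim_config(seed = 27, genome_length = 200000L,
                     methylation = list(class_means = c(neutral = 60,
                                                        risk_coding = 60,
                                                        risk_noncoding = 60,
                                                        other = 60)))
  tr2 <- simulate_methylation(cfg2, snps, c(chrS1 = 200000L))
  pn2 <- methylation_profile(tr2, snps[snps$risk_label == "neutral", ],
                             W = 50L, chrom_lengths = c(chrS1 = 200000L))
  pr2 <- methylation_profile(tr2, snps[snps$risk_label == "risk_noncoding", ],
                             W = 50L, chrom_lengths = c(chrS1 = 200000L))
  expect_lt(abs(pn2$values[pn2$offsets == 0] - pr2$values[pr2$offsets == 0]),
            10)
})

test_that("simulate_all is a pure function of the config", {
  cfg <- sim_config(seed = 28, genome_length = 100000L)
  a <- simulate_all(cfg)
  b <- simulate_all(cfg)
  expect_identical(unclass(a$genome), unclass(b$genome))
  expect_identical(a$snps, b$snps)
  expect_identical(a$nucleosome_tags$intervals, b$nucleosome_tags$intervals)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$methylation, b$methylation)
})
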
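# End-to-end orchestration: simulate (or load) inputs, run every analysis
# stage, write per-stage outputs and a machine-readable summary JSON.

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis from a single configuration:
#' SNP catalog (filter + labels), per-class nucleosome occupancy
#' profiles, GC and methylation profiles for neutral vs risk SNPs,
#' substitution spectra with per-type Z-tests, SNP density around
#' mutation sites with positional Z-tests and fold calls, and the
#' HM-based risk-vs-neutral classifier. Results are written as profile
#' TSVs plus one `summary.json` with a block per figure-analog
#' (`fig1_profiles`, `fig4_spectrum`, `fig5_density`,
#' `figS5_classifier`). Reruns with the same configuration are
#' bit-identical.
#'
#' @param config either a [sim_config()] (self-contained synthetic run),
#'   a path to a JSON file holding one, or a list with a `simulate`
#'   element.
#' @param outdir output directory.
#' @param W profile half-window (default 1500 bp).
#' @param classifier_seed seed for the train/test split.
#' @return the summary list, invisibly; side effect: files in `outdir`.
#' @export
run_pipeline <- function(config = sim_config(), outdir, W = 1500L,
                         classifier_seed = NULL) {
  if (is.character(config)) {
    cfg_list <- read_json(config, simplifyVector = TRUE)
    config <- do.call(sim_config, cfg_list)
  }
  if (!inherits(config, "sim_config")) {
    if (is.list(config) && !is.null(config$simulate)) {
      config <- do.call(sim_config, config$simulate)
    } else {
      stop("config must be a sim_config, a JSON path, or a list with a ",
           "'simulate' block")
    }
  }
  if (is.null(classifier_seed)) classifier_seed <- config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[pipeline] ", ...)

  msg("simulating dataset (seed ", config$seed, ")")
  sim <- simulate_all(config)
  glen <- sum(sim$chrom_lengths)

  msg("stage catalog: filtering and labelling SNPs")
  snps <- filter_snps(sim$snps)
  cat_counts <- table(factor(snps$func_category, levels = snp_categories()))
  label_counts <- table(snps$risk_label)

  msg("stage fig1: nucleosome occupancy profiles per class")
  profile_classes <- list(
    coding_synonymous = snps[snps$func_category == "coding_synonymous", ],
    intron = snps[snps$func_category == "intron", ])
  fig1 <- list()
  for (nm in names(profile_classes)) {
    pr <- aggregate_profile(sim$nucleosome_tags, profile_classes[[nm]],
                            W = W, mode = "nucleosome", genome_length = glen,
                            chrom_lengths = sim$chrom_lengths)
    write_profile_tsv(pr, file.path(outdir, paste0("nucleosome_", nm, ".tsv")))
    sm <- smooth_profile(pr, 75L)
    fig1[[nm]] <- list(
      n_anchors = pr$n_anchors,
      shift = pr$normalization$shift_used,
      argmax_offset = pr$offsets[which.max(sm$values)],
      value_at_0 = pr$values[pr$offsets == 0],
      mean_value = mean(pr$values))
  }

  msg("stage fig4: spectra, GC and methylation")
  neutral <- snps[snps$risk_label == "neutral", ]
  risk <- snps[snps$risk_label %in% c("risk_coding", "risk_noncoding"), ]
  spec_neutral <- substitution_spectrum(neutral)
  spec_risk <- substitution_spectrum(risk)
  spec_all <- substitution_spectrum(snps)
  ztab <- compare_spectra(spec_neutral, spec_risk)
  fwrite(ztab, file.path(outdir, "spectrum_ztests.tsv"), sep = "\t")
  gc_t <- window_gc_ttest(sim$genome, neutral, risk)
  meth_neutral <- methylation_profile(sim$methylation, neutral, W = 500L,
                                      chrom_lengths = sim$chrom_lengths)
  meth_risk <- methylation_profile(sim$methylation, risk, W = 500L,
                                   chrom_lengths = sim$chrom_lengths)
  write_profile_tsv(meth_neutral, file.path(outdir, "methylation_neutral.tsv"))
  write_profile_tsv(meth_risk, file.path(outdir, "methylation_risk.tsv"))
  fig4 <- list(
    ts_fraction_all = spec_all$ts_fraction,
    ts_tv_ratio_all = spec_all$ts_tv_ratio,
    ts_fraction_neutral = spec_neutral$ts_fraction,
    ts_fraction_risk = spec_risk$ts_fraction,
    min_ztest_p = min(ztab$p),
    gc_ttest = gc_t,
    methylation_at_0 = list(
      neutral = meth_neutral$values[meth_neutral$offsets == 0],
      risk = meth_risk$values[meth_risk$offsets == 0]))

  msg("stage fig5: SNP density around mutation sites")
  dens <- snp_density_profile(sim$mutation_snp_sites, sim$mutations,
                              W = 5000L, chrom_lengths = sim$chrom_lengths)
  dens <- positional_null(dens)
  dens <- positional_z_test(dens)
  folds <- fold_report(dens)
  fwrite(data.frame(offset = dens$offsets, density = dens$density,
                    z = dens$z, p = dens$p),
         file.path(outdir, "snp_density.tsv"), sep = "\t")
  fig5 <- list(u = dens$u, s = dens$s, folds = as.list(folds),
               flagged_enriched = dens$flagged_enriched,
               flagged_depleted = dens$flagged_depleted)

  msg("stage figS5: HM discriminator")
  cls_snps <- snps[snps$risk_label %in%
                     c("neutral", "risk_coding", "risk_noncoding"), ]
  x <- hm_levels(sim$hm_tags, cls_snps, genome_length = glen,
                 chrom_lengths = sim$chrom_lengths)
  labels <- collapse_risk_labels(cls_snps$risk_label)
  dtab <- differential_hm_test(x, labels)
  fwrite(dtab, file.path(outdir, "hm_ttests.tsv"), sep = "\t")
  cres <- risk_classifier(x, labels, seed = classifier_seed)
  fwrite(cres$roc, file.path(outdir, "roc.tsv"), sep = "\t")
  figS5 <- list(auc = cres$auc, slopes = as.list(cres$slopes),
                top_hm = dtab$hm[1L], top_hm_p = dtab$p[1L],
                split_seed = classifier_seed,
                n_risk = sum(labels == "risk"),
                n_neutral = sum(labels == "neutral"))

  summary <- list(
    config_seed = config$seed,
    genome_length = glen,
    catalog = list(category_counts = as.list(cat_counts),
                   label_counts = as.list(label_counts)),
    fig1_profiles = fig1,
    fig4_spectrum = fig4,
    fig5_density = fig5,
    figS5_classifier = figS5)
  write_json(summary, file.path(outdir, "summary.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  msg("done; summary written to ", file.path(outdir, "summary.json"))
  invisible(summary)
}
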
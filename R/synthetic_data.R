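# Deterministic synthetic-data generator. Every pipeline input can be
# simulated with plantable effect sizes whose expectations are known in
# closed form, so each analysis stage has a recoverable ground truth.

#' Simulation configuration
#'
#' Builds the full configuration for the synthetic-data generator. The
#' defaults describe a 2-Mb single-chromosome genome with alternating
#' intergenic and gene blocks, ~0.004 SNPs per bp, a 3:1
#' transition:transversion substitution spectrum, class-dependent
#' nucleosome positioning (exonic/UTR5 SNP classes phased on nucleosomes,
#' intron/UTR3/flank classes in linkers), multiplicative histone-mark
#' effects for risk vs neutral SNPs, a mutation neighbourhood model with
#' 1.4-fold SNP enrichment at offsets -1/+1 and 2-fold depletion at 0,
#' and class-dependent DNA-methylation means.
#'
#' @param seed master seed; the entire synthetic dataset is a pure
#'   function of the configuration including this seed.
#' @param ... named overrides for any top-level field (lists are merged
#'   element-wise).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  base <- list(
    seed = as.integer(seed),
    chrom = "chrS1",
    genome_length = 2000000L,
    # gene-block layout repeated along the chromosome (widths in bp)
    layout = list(intergenic = 6000L, near_gene_5 = 1000L, utr5 = 300L,
                  exon = 300L, intron = 1500L, n_introns = 2L,
                  utr3 = 500L, near_gene_3 = 1000L),
    gc = list(intergenic_other = 0.40, intron = 0.42, exon = 0.55,
              utr5 = 0.55, utr3 = 0.45, near_gene_5 = 0.48,
              near_gene_3 = 0.45,
              sinusoidal = FALSE, sin_center = 0.50, sin_amplitude = 0.15,
              sin_period = 20000L),
    snp_density = 0.004,
    exon_split = c(coding_synonymous = 0.45, coding_nonsynonymous = 0.45,
                   exon_other = 0.10),
    p_single = 0.97,
    p_validated = 0.95,
    risk_fraction = 0.03,
    substitution_probs = c("A/G" = 0.375, "C/T" = 0.375, "A/C" = 0.0625,
                           "A/T" = 0.0625, "C/G" = 0.0625, "G/T" = 0.0625),
    nucleosome = list(
      positioned_classes = c("coding_synonymous", "coding_nonsynonymous",
                             "exon_other", "utr5"),
      depleted_classes = c("intron", "utr3", "near_gene_5", "near_gene_3",
                           "intergenic_other"),
      spacing = 200L, n_flank = 5L, jitter_sd = 20,
      depleted_offset = 100L, coverage_per_dyad = 2,
      tag_length = 36L, read_noise_sd = 10, background_rate = 0.01),
    hm = list(
      baseline_window = 20, window = 200L, background_rate = 0.02,
      tag_length = 36L,
      effects = c(list(HM1 = c(risk = 2, neutral = 1, other = 1),
                       HM2 = c(risk = 2, neutral = 1, other = 1),
                       HM3 = c(risk = 2, neutral = 1, other = 1),
                       HM4 = c(risk = 2, neutral = 1, other = 1)),
                  setNames(rep(list(c(risk = 1, neutral = 1, other = 1)), 4),
                           paste0("HM", 5:8)))),
    mutation = list(n_sites = 10000L, rho = 0.004,
                    p_enrich = 0.8 * 0.004, p_deplete = 0.5),
    methylation = list(window = 300L, step = 5L, sd = 10,
                       class_means = c(neutral = 80, risk_coding = 40,
                                       risk_noncoding = 40, other = 60),
                       background_rate = 0.001, background_mean = 50)
  )
  over <- list(...)
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
      modifyList(base[[k]], over[[k]])
    } else {
      over[[k]]
    }
  }
  structure(base, class = "sim_config")
}

# region classes laid down by the layout, in block order
.layout_blocks <- function(layout) {
  gene <- c("near_gene_5", "utr5")
  for (i in seq_len(layout$n_introns)) gene <- c(gene, "exon", "intron")
  gene <- c(gene, "exon", "utr3", "near_gene_3")
  c("intergenic_other", gene)
}

.block_width <- function(layout, cls) {
  switch(cls,
         intergenic_other = layout$intergenic,
         exon = layout$exon,
         intron = layout$intron,
         utr5 = layout$utr5,
         utr3 = layout$utr3,
         near_gene_5 = layout$near_gene_5,
         near_gene_3 = layout$near_gene_3)
}

#' Generate a synthetic genome and annotation
#'
#' Lays down alternating intergenic and gene blocks (flank / UTR5 /
#' exon-intron / UTR3 / flank) until the target genome length is reached
#' and draws bases with the per-class GC content. With
#' `gc$sinusoidal = TRUE` the GC probability instead varies sinusoidally
#' along the chromosome (to exercise the occupancy-vs-GC analysis).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to the config master seed).
#' @return list with `genome` (a `genome_seq`) and `annotation`
#'   (data.frame `class`, `chrom`, `start`, `end`).
#' @export
make_genome <- function(config, seed = config$seed) {
  .with_seed(seed, {
    L <- config$genome_length
    blocks <- .layout_blocks(config$layout)
    cls <- character(0)
    start <- integer(0)
    end <- integer(0)
    pos <- 0L
    repeat {
      for (b in blocks) {
        w <- .block_width(config$layout, b)
        if (pos >= L) break
        w <- min(w, L - pos)
        cls <- c(cls, b)
        start <- c(start, pos)
        end <- c(end, pos + w)
        pos <- pos + w
      }
      if (pos >= L) break
    }
    ann <- data.frame(class = cls, chrom = config$chrom, start = start,
                      end = end, stringsAsFactors = FALSE)
    # per-base GC probability
    p_gc <- numeric(L)
    if (isTRUE(config$gc$sinusoidal)) {
      x <- seq_len(L) - 1L
      p_gc <- config$gc$sin_center +
        config$gc$sin_amplitude * sin(2 * pi * x / config$gc$sin_period)
      p_gc <- pmin(pmax(p_gc, 0), 1)
    } else {
      for (i in seq_len(nrow(ann))) {
        p_gc[(ann$start[i] + 1L):ann$end[i]] <- config$gc[[ann$class[i]]]
      }
    }
    is_gc <- runif(L) < p_gc
    pick <- runif(L) < 0.5
    code <- integer(L)
    code[is_gc & pick] <- 71L   # G
    code[is_gc & !pick] <- 67L  # C
    code[!is_gc & pick] <- 65L  # A
    code[!is_gc & !pick] <- 84L # T
    genome <- setNames(intToUtf8(code), config$chrom)
    class(genome) <- "genome_seq"
    list(genome = genome, annotation = ann)
  })
}

# map a region class to the SNP functional category (exons are split
# among the three exonic categories by the caller)
.region_to_category <- function(cls) {
  ifelse(cls == "exon", NA_character_, cls)
}

#' Plant SNPs on a synthetic genome
#'
#' Samples SNP positions per region class at the configured density,
#' assigns functional categories from the region (exonic positions split
#' among coding_synonymous / coding_nonsynonymous / exon_other), draws
#' the second allele conditional on the reference base so that the
#' unordered substitution type follows `substitution_probs` (default Ts
#' probability 0.75, i.e. a 3:1 Ts:Tv spectrum), flags a small fraction
#' as non-single / unvalidated to exercise the filters, and marks a
#' configured fraction of the usable SNPs as risk sites.
#'
#' @param config a [sim_config()].
#' @param genome,annotation from [make_genome()].
#' @param seed RNG seed.
#' @return list with `snps` (a labelled `snp_table`) and `risk_sites`
#'   (data.frame `chrom`, `pos`).
#' @export
plant_snps <- function(config, genome, annotation, seed = config$seed + 1L) {
  .with_seed(seed, {
    seqstr <- unclass(genome)[[config$chrom]]
    rows <- lapply(seq_len(nrow(annotation)), function(i) {
      w <- annotation$end[i] - annotation$start[i]
      n <- rbinom(1L, w, config$snp_density)
      if (n == 0L) return(NULL)
      pos <- annotation$start[i] + sample.int(w, n) - 1L
      data.frame(pos = pos, region = annotation$class[i],
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows) || !nrow(rows)) {
      empty <- data.frame(chrom = character(), pos = integer(),
                          allele1 = character(), allele2 = character(),
                          variant_class = character(),
                          func_category = character(), validated = logical(),
                          valid_alleles = logical(), risk_label = character(),
                          stringsAsFactors = FALSE)
      class(empty) <- c("snp_table", "data.frame")
      return(list(snps = empty,
                  risk_sites = data.frame(chrom = character(),
                                          pos = integer())))
    }
    rows <- rows[order(rows$pos), , drop = FALSE]
    n <- nrow(rows)
    category <- .region_to_category(rows$region)
    ex <- which(is.na(category))
    if (length(ex)) {
      category[ex] <- sample(names(config$exon_split), length(ex),
                             replace = TRUE, prob = config$exon_split)
    }
    ref <- toupper(substring(seqstr, rows$pos + 1L, rows$pos + 1L))
    usable <- ref %in% c("A", "C", "G", "T")
    rows <- rows[usable, , drop = FALSE]
    category <- category[usable]
    ref <- ref[usable]
    n <- nrow(rows)
    # partner allele conditional on ref, proportional to the type probs
    sp <- config$substitution_probs
    partner <- character(n)
    for (b in c("A", "C", "G", "T")) {
      others <- setdiff(c("A", "C", "G", "T"), b)
      types <- paste(pmin(b, others), pmax(b, others), sep = "/")
      pr <- sp[types] / sum(sp[types])
      sel <- which(ref == b)
      if (length(sel)) {
        partner[sel] <- sample(others, length(sel), replace = TRUE, prob = pr)
      }
    }
    variant_class <- ifelse(runif(n) < config$p_single, "single", "insertion")
    validated <- runif(n) < config$p_validated
    allele1 <- ifelse(variant_class == "single", ref, "-")
    allele2 <- partner
    snps <- data.frame(chrom = config$chrom, pos = rows$pos,
                       allele1 = allele1, allele2 = allele2,
                       variant_class = variant_class,
                       func_category = category, validated = validated,
                       valid_alleles = variant_class == "single",
                       risk_label = "other", stringsAsFactors = FALSE)
    class(snps) <- c("snp_table", "data.frame")
    eligible <- which(snps$variant_class == "single" & snps$validated)
    n_risk <- round(config$risk_fraction * length(eligible))
    risk_idx <- if (n_risk > 0) sample(eligible, n_risk) else integer(0)
    risk_sites <- data.frame(chrom = snps$chrom[risk_idx],
                             pos = snps$pos[risk_idx],
                             stringsAsFactors = FALSE)
    snps <- assign_labels(snps, risk_sites)
    list(snps = snps, risk_sites = risk_sites)
  })
}

#' Simulate nucleosome tags around SNPs
#'
#' For each SNP of a "positioned" class, nucleosome dyads are placed at
#' `pos + spacing * k` for `k = -n_flank .. n_flank` with Gaussian jitter
#' of SD `jitter_sd * (1 + 3|k|)`: positioning is sharpest at the anchor
#' and decays along the array, as phased nucleosome arrays do, so the
#' aggregate occupancy peak sits at offset 0. For "depleted" classes the
#' array is offset by `depleted_offset` so the SNP falls in the linker. Each dyad emits
#' `Poisson(coverage_per_dyad)` tag pairs: a plus tag starting at
#' `dyad - 73 + N(0, read_noise_sd)` and a minus tag ending at
#' `dyad + 74 - N(0, read_noise_sd)` (so both 5' ends sit ~73 bp from the
#' dyad). Background tags are scattered uniformly at `background_rate`
#' per bp per strand.
#'
#' @param config a [sim_config()].
#' @param snps a `snp_table` (anchors; class taken from `func_category`).
#' @param chrom_lengths named chromosome lengths.
#' @param seed RNG seed.
#' @return a `TagSet` of raw (unextended) stranded tags.
#' @export
simulate_nucleosome_tags <- function(config, snps, chrom_lengths,
                                     seed = config$seed + 2L) {
  .with_seed(seed, {
    nc <- config$nucleosome
    len <- chrom_lengths[[config$chrom]]
    ks <- seq.int(-nc$n_flank, nc$n_flank)
    dyads <- numeric(0)
    if (nrow(snps)) {
      positioned <- snps$pos[snps$func_category %in% nc$positioned_classes]
      depleted <- snps$pos[snps$func_category %in% nc$depleted_classes]
      if (length(positioned)) {
        d <- rep(positioned, each = length(ks)) +
          rep(nc$spacing * ks, length(positioned))
        sds <- rep(nc$jitter_sd * (1 + 3 * abs(ks)), length(positioned))
        dyads <- c(dyads, d + round(rnorm(length(d), 0, sds)))
      }
      if (length(depleted)) {
        d <- rep(depleted, each = length(ks)) + nc$depleted_offset +
          rep(nc$spacing * ks, length(depleted))
        dyads <- c(dyads, d)
      }
    }
    npairs <- if (length(dyads)) rpois(length(dyads), nc$coverage_per_dyad)
              else integer(0)
    dyads <- rep(dyads, npairs)
    plus_start <- dyads - 73 + round(rnorm(length(dyads), 0, nc$read_noise_sd))
    minus_end <- dyads + 74 - round(rnorm(length(dyads), 0, nc$read_noise_sd))
    n_bg <- rpois(1L, len * nc$background_rate)
    bg_plus <- sample.int(len, n_bg, replace = TRUE) - 1L
    n_bg2 <- rpois(1L, len * nc$background_rate)
    bg_minus_end <- sample.int(len, n_bg2, replace = TRUE)
    Lt <- nc$tag_length
    ps <- as.integer(c(plus_start, bg_plus))
    ms <- as.integer(c(minus_end, bg_minus_end))
    iv <- rbind(
      data.frame(chrom = rep(config$chrom, length(ps)), start = ps,
                 end = ps + Lt, strand = rep("+", length(ps)),
                 stringsAsFactors = FALSE),
      data.frame(chrom = rep(config$chrom, length(ms)), start = ms - Lt,
                 end = ms, strand = rep("-", length(ms)),
                 stringsAsFactors = FALSE))
    keep <- iv$start >= 0 & iv$end <= len
    tag_set(iv[keep, , drop = FALSE], "synthetic_nucleosome")
  })
}

#' Simulate histone-modification tags per HM type
#'
#' For every HM type in `config$hm$effects`, each SNP receives
#' `Poisson(baseline_window * effect[class])` tags uniformly in its
#' `window`-bp neighbourhood (class = collapsed risk label: risk /
#' neutral / other), plus genome-wide background at
#' `background_rate` per bp (split over the two strands).
#'
#' @inheritParams simulate_nucleosome_tags
#' @return named list of `TagSet`s, one per HM type.
#' @export
simulate_hm_tags <- function(config, snps, chrom_lengths,
                             seed = config$seed + 3L) {
  .with_seed(seed, {
    hm <- config$hm
    len <- chrom_lengths[[config$chrom]]
    half <- hm$window %/% 2L
    grp <- collapse_risk_labels(snps$risk_label)
    out <- lapply(names(hm$effects), function(nm) {
      eff <- hm$effects[[nm]][grp]
      eff[is.na(eff)] <- 1
      counts <- if (nrow(snps)) rpois(nrow(snps), hm$baseline_window * eff)
                else integer(0)
      centers <- rep(snps$pos, counts)
      offs <- if (length(centers)) {
        sample.int(hm$window, length(centers), replace = TRUE) - 1L - half
      } else integer(0)
      fp <- centers + offs
      n_bg <- rpois(1L, len * hm$background_rate)
      fp <- c(fp, sample.int(len, n_bg, replace = TRUE) - 1L)
      strand <- sample(c("+", "-"), length(fp), replace = TRUE)
      # fp is the 5' end: start for +, end - 1 for -
      start <- ifelse(strand == "+", fp, fp - hm$tag_length + 1L)
      end <- start + hm$tag_length
      iv <- data.frame(chrom = rep(config$chrom, length(start)),
                       start = as.integer(start), end = as.integer(end),
                       strand = strand, stringsAsFactors = FALSE)
      keep <- iv$start >= 0 & iv$end <= len
      tag_set(iv[keep, , drop = FALSE], paste0("synthetic_", nm))
    })
    setNames(out, names(hm$effects))
  })
}

#' Plant somatic mutation sites with SNP-proximity effects
#'
#' Draws `n_sites` mutation positions uniformly. Independently per site,
#' with probability `p_enrich` an extra SNP is added at the site's -1 or
#' +1 position (fair coin); with probability `p_deplete` any SNP at the
#' site itself is removed. With background SNP density `rho` per bp the
#' expected SNP density around mutation sites is `rho + p_enrich / 2` at
#' each of -1/+1, `rho * (1 - p_deplete)` at 0 and `rho` elsewhere,
#' giving closed-form planted folds `(rho + p_enrich/2) / rho` and
#' `1 - p_deplete`. The defaults (`p_enrich = 0.8 * rho`,
#' `p_deplete = 0.5`) plant folds 1.4 and 0.5.
#'
#' @param config a [sim_config()].
#' @param snp_sites data.frame with `chrom`, `pos`, or `NULL` to draw a
#'   uniform background of density `rho`.
#' @param chrom_lengths named chromosome lengths.
#' @param seed RNG seed.
#' @return list with `mutations` and `snp_sites` (the background set
#'   after additions/removals), both data.frames with `chrom`, `pos`.
#' @export
plant_mutation_sites <- function(config, snp_sites = NULL, chrom_lengths,
                                 seed = config$seed + 4L) {
  .with_seed(seed, {
    mu <- config$mutation
    len <- chrom_lengths[[config$chrom]]
    if (is.null(snp_sites)) {
      n_snp <- rpois(1L, len * mu$rho)
      snp_pos <- sample.int(len, n_snp, replace = TRUE) - 1L
    } else {
      snp_pos <- snp_sites$pos[snp_sites$chrom == config$chrom]
    }
    mut_pos <- sample.int(len, mu$n_sites, replace = TRUE) - 1L
    enrich <- runif(mu$n_sites) < mu$p_enrich
    side <- sample(c(-1L, 1L), mu$n_sites, replace = TRUE)
    added <- mut_pos[enrich] + side[enrich]
    deplete_at <- mut_pos[runif(mu$n_sites) < mu$p_deplete]
    snp_pos <- snp_pos[!(snp_pos %in% deplete_at)]
    snp_pos <- c(snp_pos, added)
    snp_pos <- snp_pos[snp_pos >= 0 & snp_pos < len]
    list(mutations = data.frame(chrom = config$chrom, pos = mut_pos,
                                stringsAsFactors = FALSE),
         snp_sites = data.frame(chrom = config$chrom, pos = sort(snp_pos),
                                stringsAsFactors = FALSE))
  })
}

#' Simulate a DNA-methylation track around SNPs
#'
#' Measures methylation at every `step`-th offset within `window` bp of
#' each SNP: levels are Normal(class mean, sd) clipped to `[0, 100]`,
#' where the class mean depends on the SNP's risk label. A sparse uniform
#' background at `background_rate` per bp (mean `background_mean`) fills
#' the rest of the genome. Duplicate positions (overlapping SNP windows)
#' keep the first measurement.
#'
#' @inheritParams simulate_nucleosome_tags
#' @return a `methylation_track` (columns `chrom`, `pos`, `level`).
#' @export
simulate_methylation <- function(config, snps, chrom_lengths,
                                 seed = config$seed + 5L) {
  .with_seed(seed, {
    me <- config$methylation
    len <- chrom_lengths[[config$chrom]]
    offs <- seq.int(-me$window, me$window, by = me$step)
    pos <- rep(snps$pos, each = length(offs)) + rep(offs, nrow(snps))
    means <- rep(me$class_means[snps$risk_label], each = length(offs))
    means[is.na(means)] <- me$class_means[["other"]]
    n_bg <- rpois(1L, len * me$background_rate)
    pos <- c(pos, sample.int(len, n_bg, replace = TRUE) - 1L)
    means <- c(means, rep(me$background_mean, n_bg))
    keep <- pos >= 0 & pos < len
    pos <- pos[keep]
    means <- means[keep]
    level <- pmin(pmax(rnorm(length(pos), means, me$sd), 0), 100)
    first <- !duplicated(pos)
    out <- data.frame(chrom = config$chrom, pos = as.integer(pos[first]),
                      level = level[first], stringsAsFactors = FALSE)
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("methylation_track", "data.frame")
    out
  })
}

#' Simulate nucleosome tags whose density tracks local GC content
#'
#' Places nucleosome dyads by a Poisson process whose intensity is a
#' Gaussian function of the local (600-bp window) GC fraction, peaking at
#' `gc_opt`. Used to exercise the occupancy-vs-GC analysis: the resulting
#' occupancy curve should peak in the GC bin containing `gc_opt`.
#'
#' @param genome a `genome_seq`.
#' @param gc_opt GC fraction of maximal occupancy (default 0.54).
#' @param gc_sd width of the Gaussian intensity in GC units.
#' @param rate_max maximal dyad rate per bp.
#' @param gc_window window used for the local GC fraction (600 bp).
#' @param seed RNG seed.
#' @return a `TagSet` of tag pairs flanking the sampled dyads.
#' @export
simulate_gc_coupled_tags <- function(genome, gc_opt = 0.54, gc_sd = 0.08,
                                     rate_max = 0.02, gc_window = 600L,
                                     seed = 1L) {
  .with_seed(seed, {
    chrom <- names(genome)[1L]
    seqstr <- unclass(genome)[[chrom]]
    len <- nchar(seqstr)
    ind <- .gc_indicators(seqstr)
    local_gc <- .running_mean(ind$gc, gc_window)
    # thinning: uniform candidates at rate_max, accepted by the Gaussian
    n_cand <- rpois(1L, len * rate_max)
    cand <- sample.int(len, n_cand, replace = TRUE)
    acc_p <- exp(-((local_gc[cand] - gc_opt)^2) / (2 * gc_sd^2))
    dyads <- cand[runif(n_cand) < acc_p] - 1L
    Lt <- 36L
    plus_start <- dyads - 73L
    minus_end <- dyads + 74L
    iv <- rbind(
      data.frame(chrom = rep(chrom, length(plus_start)), start = plus_start,
                 end = plus_start + Lt, strand = rep("+", length(plus_start)),
                 stringsAsFactors = FALSE),
      data.frame(chrom = rep(chrom, length(minus_end)),
                 start = minus_end - Lt, end = minus_end,
                 strand = rep("-", length(minus_end)),
                 stringsAsFactors = FALSE))
    keep <- iv$start >= 0 & iv$end <= len
    tag_set(iv[keep, , drop = FALSE], "synthetic_gc_nucleosome")
  })
}

#' Simulate the complete synthetic dataset
#'
#' Runs every generator with sub-seeds derived from the master seed and
#' returns all inputs plus the ground-truth parameters. Deterministic:
#' the same configuration yields a byte-identical dataset.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `annotation`, `snps`, `risk_sites`,
#'   `nucleosome_tags`, `hm_tags`, `methylation`, `mutations`,
#'   `mutation_snp_sites`, `chrom_lengths` and `truth` (planted
#'   parameters).
#' @export
simulate_all <- function(config = sim_config()) {
  gen <- make_genome(config)
  lengths <- genome_lengths(gen$genome)
  planted <- plant_snps(config, gen$genome, gen$annotation)
  nuc <- simulate_nucleosome_tags(config, planted$snps, lengths)
  hm <- simulate_hm_tags(config, planted$snps, lengths)
  meth <- simulate_methylation(config, planted$snps, lengths)
  mut <- plant_mutation_sites(config, snp_sites = NULL,
                              chrom_lengths = lengths)
  truth <- list(
    ts_probability = sum(config$substitution_probs[c("A/G", "C/T")]),
    fold_pm1 = (config$mutation$rho + config$mutation$p_enrich / 2) /
      config$mutation$rho,
    fold_0 = 1 - config$mutation$p_deplete,
    hm_effects = config$hm$effects,
    methylation_means = config$methylation$class_means,
    seed = config$seed)
  list(genome = gen$genome, annotation = gen$annotation,
       snps = planted$snps, risk_sites = planted$risk_sites,
       nucleosome_tags = nuc, hm_tags = hm, methylation = meth,
       mutations = mut$mutations, mutation_snp_sites = mut$snp_sites,
       chrom_lengths = lengths, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes FASTA (genome), TSV (SNP table, risk sites, methylation,
#' mutation sites, annotation), BED (tag sets) and a ground-truth JSON of
#' planted parameters into `dir`.
#'
#' @param sim result of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_snp_table(sim$snps, file.path(dir, "snps.tsv"))
  fwrite(sim$risk_sites, file.path(dir, "risk_sites.tsv"), sep = "\t")
  fwrite(sim$annotation, file.path(dir, "annotation.tsv"), sep = "\t")
  fwrite(sim$methylation, file.path(dir, "methylation.tsv"), sep = "\t")
  fwrite(sim$mutations, file.path(dir, "mutations.tsv"), sep = "\t")
  fwrite(sim$mutation_snp_sites, file.path(dir, "mutation_snp_sites.tsv"),
         sep = "\t")
  write_tag_bed(sim$nucleosome_tags, file.path(dir, "nucleosome_tags.bed"))
  for (nm in names(sim$hm_tags)) {
    write_tag_bed(sim$hm_tags[[nm]], file.path(dir, paste0("tags_", nm, ".bed")))
  }
  write_json(sim$truth, file.path(dir, "ground_truth.json"),
             auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
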
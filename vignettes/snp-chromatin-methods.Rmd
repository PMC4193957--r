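---
title: "Methods: profiling the chromatin context of SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling the chromatin context of SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpchrom)
```

# The problem

Single nucleotide polymorphisms (SNPs) are not scattered uniformly through
chromatin: whether a variant sits on nucleosomal DNA or in a
nucleosome-depleted linker, which histone modifications (HMs) surround it,
and the local GC and DNA-methylation context all differ systematically
between functional classes of SNPs (coding vs intronic, disease-associated
"risk" vs putatively neutral coding-synonymous variants). **snpchrom**
implements the full analysis used to ask such questions from sequencing
data: SNP classification and labelling, normalised tag metaprofiles around
anchor sites, sequence/methylation profiles, substitution-spectrum
statistics, SNP-density analysis around somatic mutation sites, and a
linear risk-vs-neutral classifier on HM levels — together with a synthetic
data generator that plants every effect with a known size, so the whole
pipeline is testable against ground truth.

All internal coordinates are 0-based with half-open `[start, end)`
intervals (the BED convention); a SNP occupies the single base at `pos`.
Conversions from 1-based dialects live only in the readers.

# Tag metaprofiles

The core quantity is the aggregate profile of sequencing tags around a set
of anchor sites (SNPs), `aggregate_profile()`:

1. **Counting unit.** Point-source marks (HMs, Pol II, H2A.Z, CTCF) are
   counted by their 5' tag ends: `start` for plus-strand tags, `end - 1`
   for minus-strand tags. Nucleosome tags are first extended to 146 bp —
   the length of nucleosomal DNA — in the 3' direction
   (`extend_tags()`), and every covered base counts (occupancy).
2. **Strand profiles.** Counts are accumulated per strand at every offset
   in `[-W, W]` around each anchor (`strand_count_profiles()`), summed
   over anchors. `W` defaults to 1500 bp (a 3-kbp window); anchors whose
   window leaves the chromosome are dropped and reported.
3. **Shift alignment.** Because sequencing reads start at the fragment
   ends, the plus- and minus-strand profiles of a point source are
   displaced symmetrically. `estimate_shift()` finds the shift `s`
   (each strand moved by `s` toward the other) maximising the Pearson
   correlation of the two profiles over their overlap, capped at 73 bp
   for nucleosomes (the dyad-to-5'-end distance) and 100 bp for point
   marks. Ties break toward the smaller shift; a zero-variance profile
   yields shift 0 with a warning. The objective is evaluated in both
   pairing directions and the better taken, which makes the estimate
   independent of which profile carries the "plus" label — an invariant
   the test suite asserts exactly. The summed profile is assembled from
   an internally extended window so shifting introduces no zero-padding
   artefacts at the window edges.
4. **Normalisation.** The summed profile is divided by the genome-average
   coverage `c = footprint / genome_length` (footprint: total extended
   bases for nucleosomes, tag count for point marks) and then by the
   number of anchors. Spatially uniform tags therefore give a profile of
   ~1 at every offset, and the profile is invariant to jointly doubling
   tag counts and coverage. Both divisors and the shift are recorded in
   the `Profile`'s `normalization` field and in the TSV header written by
   `write_profile_tsv()`.

Protein-binding data supplied as *bound regions* rather than tags use
`region_binding_profile()`: the value at offset `d` is the fraction of
anchors with `pos + d` inside any region. `profile_correlation()` gives
the Pearson correlation between two profiles over identical offsets
(used, e.g., to compare the same mark across cell types).

**A note on flat-topped occupancy peaks.** Counting per-base coverage of
a 146-bp footprint makes the metaprofile of a well-positioned nucleosome
a 146-bp box convolved with the positioning jitter — a curve with a
roughly 100-bp flat top. The *location* of the raw argmax on that plateau
is therefore noise-driven. Where peak localisation is asserted (the
planted-signal checks), the profile is first smoothed with a running mean
at the nucleosome footprint scale (`smooth_profile(p, 147)`), which turns
the plateau into a strict central maximum; 147 bp is the natural scale
and not a tuning knob. The opposite holds for the nucleosome-depleted
linker dip, which is only ~54 bp wide (two 73-bp half-footprints inside a
200-bp repeat): footprint-scale smoothing dilutes it, so the
depleted-class minimum is read off the raw profile.

# SNP catalog

`read_snp_table()` ingests UCSC-style dumps (0-based `chromStart`;
`one_based = TRUE` for 1-based sources). Malformed allele strings flag the
record rather than aborting. `filter_snps()` keeps only variant class
`"single"`, validated records with two distinct bases.
`map_func_categories()` translates the annotation vocabulary onto nine
canonical categories (coding_synonymous, coding_nonsynonymous, exon_other,
intron, utr5, utr3, near_gene_5, near_gene_3, intergenic_other);
multi-annotated SNPs resolve by a configurable precedence
(coding > UTR > intron > near-gene > intergenic). `assign_labels()` marks
SNPs at risk coordinates as `risk_coding` (exonic categories) or
`risk_noncoding`, and non-risk coding-synonymous SNPs as the `neutral`
comparator — the standard choice, with the known caveat that synonymous
variants are not perfectly neutral. Risk matching is by exact coordinate,
not identifier, so synthetic data without rsIDs work identically.
`sample_random_loci()` draws category-matched random control positions;
their tag profiles should be flat, which the tests assert
(max/min of the smoothed profile < 1.2).

# Sequence and methylation features

* `gc_profile()`: fraction of anchors with G or C at each offset, with
  `N` bases excluded from numerator and denominator.
* `methylation_profile()`: sums measured methylation percentages at each
  offset and divides by the number of anchors (default) or by the number
  of anchors actually measured at that offset (`average = "observed"`).
  Contributions are additive, making the profile exactly linear in the
  track — duplicate rows at one position are summed, so tracks should
  carry one row per measured position.
* `occupancy_vs_gc()`: for each SNP, the GC fraction of the surrounding
  600-bp window and the mean nucleosome occupancy of the surrounding
  200-bp window (nucleosomal DNA + linker), binned by GC (bin width 0.02,
  fine enough to resolve a peak near 54% GC; bins with fewer than 20
  SNPs are flagged low-confidence). Both windows are symmetric around the
  SNP; per-SNP occupancy uses the extended-tag coverage with no strand
  shift, since a 200-bp mean is insensitive to a ±73-bp shift.
* `window_gc_ttest()`: per-anchor 600-bp GC fractions compared between
  two SNP sets with a two-sample t-test. Welch by default
  (`var_equal = TRUE` for the pooled variant) — the robust choice when
  group variances may differ.

# Substitution spectra

`classify_substitution()` maps an unordered allele pair to one of six
types; transitions are A/G and C/T, transversions G/T, A/C, C/G, A/T.
`substitution_spectrum()` tabulates counts, fractions, the transition
fraction and the Ts/Tv ratio (≈3:1 genome-wide).
`compare_spectra()` tests each type's fraction between two SNP sets with
a pooled two-proportion Z-test (two-sided normal p); raw p-values are
reported as-is with a Bonferroni column (factor 6) for transparency, no
correction applied by default.

# SNP density around mutation sites

`snp_density_profile()` counts (mutation, SNP) pairs at every offset in
`[-W, W]` (`W` = 5000, a 10-kbp window) and divides by the number of
mutation sites. A mutation exactly at a SNP contributes to offset 0; sites
are not deduplicated. The null for the positional Z-test is estimated from
the flanks (`positional_null()`): mean `u` and SD `s` of the density over
offsets with `|d| > 10`, a radius safely outside the ±1-bp signal but
leaving >99% of offsets for estimation; `u` and `s` can also be supplied
directly (e.g. published values). `positional_z_test()` computes
`z = (density - u)/s` with two-sided p-values and flags offsets at a
configurable α, Bonferroni-corrected over all `2W + 1` offsets by
default; `fold_report()` returns `density/u` at the focal offsets
−1, 0, +1.

**Power at desk scale.** With `n` mutation sites and background SNP
density ρ per bp, each offset's pair count is ≈ Poisson(nρ). The
flank-estimated `s` is then ≈ √(nρ)/n, so a planted fold `f` at ±1 gives
`z ≈ (f − 1)·√(nρ)`. At the generator defaults (n = 10,000, ρ = 0.004;
nρ = 40) a 1.4-fold enrichment yields z ≈ 2.5 and a 2-fold depletion
z ≈ −3.2 — far below the Bonferroni threshold over 10,001 offsets
(|z| ≥ 4.56). Detecting a 1.4-fold at that threshold needs nρ ≈ 130–140,
i.e. ~35,000 sites at this ρ. The validation suite therefore asserts the
fold recovery and the closed-form expectations at tolerances matched to
the actual sampling SDs, while the strict "Bonferroni flags exactly
{−1,+1} and {0}" check is left in place as a faithful, documented-red
assertion at the default scale. A second structural effect works against
the no-signal null check as well: Poisson(40) tails at z ≥ 4.56 are ~6×
heavier than the normal approximation, so scanning 10,001 offsets flags
at least one by chance in roughly a fifth of datasets.

# Risk-vs-neutral HM discriminator

`hm_levels()` builds the feature matrix: per HM type, the shift-aligned
5'-end count in the 200-bp window around each SNP, divided by the
genome-average point coverage. `differential_hm_test()` screens features
with per-column Welch t-tests. Evaluation uses the 10-portion protocol
(`split_ten_portions()`): rows are shuffled by seed and divided into ten
portions with sizes differing by at most one; portions 1–7 train, 8–10
test (70/30 for n = 100).

`fit_linear_classifier()` fits a linear score with the constant term
frozen at 1. One numerical subtlety matters: regressing the 0/1 labels
minus the frozen constant directly on raw, non-negative features makes
least squares spend the slopes on reproducing the overall label mean
(≈ −0.5), which *anti-orients* the discriminative direction — a feature
perfectly separating the classes would score risk examples *lower*. The
slopes are therefore fit on mean-centred features and the score is
`1 + w·(x − x̄_train)`. The frozen constant is preserved, and since ROC
analysis is invariant under strictly increasing score transforms it
cannot affect the AUC either way (asserted in the tests).

`roc_auc()` sweeps thresholds over the unique scores; tied scores
contribute diagonal segments, so the trapezoid AUC equals the
Mann–Whitney pairwise statistic (ties counted ½) exactly — the suite
checks this identity against a brute-force pairwise oracle on every
tested instance. `risk_classifier()` wires split → fit → score → ROC
together; AUC is reported for one split per seed (report a mean ± SD over
seeds if a stability estimate is wanted).

# The synthetic world

`sim_config()` fixes the generator defaults; `simulate_all()` produces
the complete dataset as a pure function of the configuration, including
the master seed. The defaults describe:

* a 2-Mb single chromosome of alternating intergenic and gene blocks
  (flank / UTR5 / exon–intron / UTR3 / flank), per-class GC content
  (exons 0.55, introns 0.42, intergenic 0.40), optionally a sinusoidal
  GC landscape (period 20 kb, amplitude 0.15) for the occupancy-vs-GC
  analysis;
* ~8,000 SNPs at 0.004 per bp; allele pairs drawn conditional on the
  reference base so the unordered type follows A/G 0.375, C/T 0.375 and
  0.0625 per transversion — a 3:1 Ts:Tv spectrum; 3% of usable SNPs
  become risk sites; 3% non-single and 5% unvalidated records exercise
  the filters;
* nucleosome tags from dyad arrays at 200-bp spacing (11 dyads per SNP):
  exonic and UTR5 classes are phased *on* the SNP, intron/UTR3/flank/
  intergenic classes are offset by 100 bp so the SNP falls in the
  linker. Positioning jitter grows with distance from the anchor
  (SD = 20·(1 + 3|k|) bp for dyad index k), the way phasing decays along
  real arrays; with constant jitter all eleven peaks would have equal
  expected height and the location of the aggregate maximum would be a
  coin toss among them. Each dyad emits Poisson(2) tag pairs with 5'
  ends ~73 bp either side of the dyad (read noise SD 10 bp), plus
  uniform background (0.01 tags/bp/strand), ~390k tags per track;
* HM tags: per SNP, Poisson(baseline 20 × class effect) tags uniform in
  its 200-bp window; four informative marks carry effect 2.0 for risk
  SNPs, four null marks effect 1.0 — so the planted single-feature AUC
  is ≈ Φ(20/√60) ≈ 0.995 and a combined classifier should beat any
  single null feature;
* mutation neighbourhood: 10,000 uniform mutation sites; with
  probability `p_enrich = 0.8ρ` an extra SNP lands at ±1 (fair coin),
  with probability 0.5 any SNP at the site is removed — closed-form
  expected folds (ρ + p_enrich/2)/ρ = 1.4 at ±1 and 0.5 at 0;
* methylation: levels Normal(class mean, 10) clipped to [0, 100],
  measured every 5 bp within ±300 bp of each SNP (neutral mean 80, risk
  40, other 60), sparse background mean 50.

What the generator does **not** emulate: real sequence composition
(no CpG clustering, no repeats), linkage disequilibrium among SNPs,
mappability artefacts, chromatin-state segmentation, or cross-cell-type
variation. A green planted-recovery test therefore establishes that the
*computations* recover known effects at realistic noise levels — not that
any biological claim holds in real data.

# Numerical conventions and degenerate inputs

* Ties in the shift objective break toward the smaller shift; zero
  variance gives shift 0 with a warning.
* Division order in profile normalisation (coverage first, anchors
  second) is fixed and recorded; the divisions commute.
* Anchors are unstranded, so profiles are never flipped.
* Empty tag sets yield zero profiles; an empty SNP set is an error for
  spectra (no fractions exist) and for profiling (no anchors).
* Methylation levels outside [0, 100] and BED rows with
  `start >= end` are rejected row-wise with warnings, never fatally.
* Unknown chromosomes in tag files are ignored by profiling (anchor
  neighbourhoods drive everything); unknown chromosomes among *anchors*
  drop those anchors with a message.
* A singular classifier design falls back to the minimum-norm
  least-squares solution with a warning.
* Duplicate tags are kept (no deduplication is applied anywhere); a
  configurable collapse step can be layered on the readers if a source
  requires it.

# Limitations

* One global strand shift is estimated per (tag set, anchor set) pair,
  not per anchor class or per chromosome.
* The flank-based mutation-context null assumes the density is
  stationary outside the exclusion radius; strong large-scale SNP
  density gradients would bias `u` and `s`.
* The linear classifier is unregularised least squares; it is the
  stated protocol, not the best achievable discriminator.
* `GcOccupancyCurve` bins partition [0, 1] half-open except the last
  bin; a value exactly on a bin edge belongs to the upper bin, so a peak
  planted exactly at an edge (e.g. 0.54 with 0.02-wide bins) may
  legitimately surface in either adjacent bin — peak-location checks
  treat bin edges inclusively.
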
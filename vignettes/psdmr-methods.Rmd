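---
title: "Paired-sample DMR analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-sample DMR analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdmr)
```

## The problem

Tumor methylomes are heterogeneous: a large share of the variation in a
CpG's beta value across a cohort comes from stable inter-patient
differences, not from the tumor/normal contrast of interest. When each
tumor is accompanied by a matched normal sample from the same patient, a
paired analysis removes that per-patient component entirely; an unpaired
two-group comparison carries it in its denominator. psdmr implements
differentially methylated region (DMR) detection built around this paired
contrast, in the bump-hunting tradition: a per-CpG statistic, smoothing
along the genome, exceedance-run region calling, and a resampling null for
region-level family-wise error rates (FWER).

## The detection pipeline

Given a beta matrix (CpG probes by samples), a pairing table and a probe
manifest, `run_paired_dmr()` proceeds in stages, each also exported on its
own:

1. **Imputation** (`impute_missing()`). Probes missing in more than
   `max_missing_frac` (default 0.2) of samples are dropped; remaining gaps
   are filled with the probe mean. Mean imputation is deterministic and
   seed-free, which we prioritized over more sophisticated (KNN-style)
   imputation: the whole pipeline reproduces byte-identically from a seed.
2. **Scale** (`beta_to_m()`). Tests run on M-values,
   `log2(b / (1 - b))` with betas clipped to `[epsilon, 1 - epsilon]`
   (`epsilon` = 1e-3), the variance-stabilized scale on which additive
   effects and t-statistics behave well. Whether the original paired
   bump-hunting implementations test on beta or M is not something the
   output formats reveal, so the scale is a documented switch
   (`scale = "m"` or `"beta"`, default `"m"`). Effect *directions* and the
   reported `mean_beta_diff` always use betas, where a difference has its
   familiar interpretation.
3. **Clustering** (`make_clusters()`, `filter_clusters()`). Adjacent CpGs
   on one chromosome belong to one cluster when consecutive gaps are at
   most `max_gap` (default 300 bp, the usual bump-hunting convention —
   exposed as a parameter). Clusters with fewer than `min_probes`
   (default 7) probes are discarded. The minimum-probe rule is applied both
   here and at region calling, the stricter of the two readings of a
   minimum cluster size.
4. **Per-CpG statistic** (`paired_t_statistics()`). For probe *i* with
   within-pair differences `d = tumor - normal` over *n* pairs,
   `t = mean(d) / (sd(d) / sqrt(n))` with the sample (n−1) SD. Probes with
   zero variance get `t = 0` when the mean difference is zero and are
   otherwise capped at ±`t_cap` (default 100) — finite, but still ranked
   above anything attainable with ordinary variation.
5. **Smoothing** (`smooth_statistics()`). Within each cluster, a local
   quadratic regression of `t` on probe position with tricube weights over
   the `ceiling(span * cluster size)` nearest probes (`span` default
   0.75). This suppresses isolated outlier probes while preserving plateaus
   — constants and straight lines are reproduced exactly, a property the
   test suite checks against a direct weighted-least-squares oracle.
   Clusters with fewer than 4 probes cannot support a local quadratic and
   fall back to a centred 3-point running mean (a single probe is returned
   unchanged). The smoother is compiled (Rcpp) because the resampling null
   re-runs it hundreds of times per dataset.
6. **Candidate regions** (`find_candidate_regions()`). The threshold tau is
   the `cutoff_quantile` quantile (default 0.99) of `|smoothed t|` across
   all cluster probes. A candidate is a maximal run of consecutive probes
   in one cluster sharing the sign of `smoothed t` with
   `|smoothed t| >= tau` and at least `min_probes` members. Each region
   reports `value` (mean smoothed t) and `area` (sum of |smoothed t|), the
   region-level evidence measure.
7. **Resampling null and FWER** (`null_distribution()`, `assign_fwer()`).
   See the next section.
8. **State calls** (`call_state()`). A region is `Hyper` when the mean
   (over its probes) of the mean paired beta difference is positive,
   otherwise `Hypo`; an exact zero — a measure-zero event — is called
   `Hyper` by convention and logged.

Results are sorted by `fwer` ascending, then `area` descending, then
genomic position, the ordering used for all "top-k" summaries, and the
metadata records every parameter plus the seed.

## The null distribution: a design decision

For a paired design the natural exchangeable null is **sign-flipping**:
under no tumor/normal difference, each pair's difference vector is
symmetric, so multiplying it by an independent ±1 yields an equally likely
dataset. Every iteration re-randomizes the signs and recomputes the
t-statistics and the smoothing from scratch.

Two aggregation schemes are implemented:

* `null_method = "regions"` (default). Each iteration re-derives its own
  exceedance threshold (the same quantile of its own |smoothed t|) and
  re-calls the complete candidate-region set; those areas form the null,
  and the iteration maximum is the largest null region area (0 when no
  region is called). Because threshold, run-calling and area are recomputed
  identically, the observed region set and each resampled region set are
  exchangeable under the null — the property that makes the FWER estimate
  calibrate, and which the test suite checks both distributionally
  (Kolmogorov–Smirnov on pooled areas) and operationally (the fraction of
  pure-noise datasets yielding any FWER < 0.05 region).
* `null_method = "windows"`. Each iteration samples, for every observed
  candidate size *k*, one contiguous window of *k* probes uniformly at
  random within clusters (windows never cross cluster boundaries) and
  records its area. This matches the "regions with a similar count of
  random CpGs" description of genome-wide sampling more literally, but
  random windows sample the bulk of the smoothed statistic while observed
  candidates are selected extremes, so observed areas dominate the null and
  the resulting FWERs are strongly anti-conservative. It is retained for
  comparison and for callers who want size-matched null areas; the
  `"regions"` scheme is the supported default.

Empirical tail probabilities use the plus-one convention, so no p-value is
exactly zero:

* `p`: within the size-matched stratum (windows: exact size; regions: null
  regions with at least as many probes), `(1 + #{null >= area}) / (1 + n)`.
* `fwer`: against the per-iteration maximum areas — the probability that a
  null genome produces *any* region as extreme.
* `fwer_area`: the same count against all null areas pooled across strata.
  The distinction between the two FWER-style columns mirrors the two
  region-level columns conventionally reported by bump-hunting tools; both
  conventions are stated here precisely because output formats in the wild
  leave them ambiguous.

With `B` iterations the smallest attainable `fwer` is `1 / (B + 1)`;
`B = 1000` (default) resolves 0.001, and `B = 200` is sufficient for
0.05-level decisions and is what the packaged simulations use.

## The unpaired comparison variant

`run_unpaired_dmr()` swaps the paired t for a Welch two-sample t and the
sign-flip null for a phenotype label-permutation null; everything else is
identical. Under strong per-patient baseline shifts the Welch statistic at
a truly differential probe is markedly smaller than the paired statistic
(the shift variance sits in its denominator), which is the motivating
contrast for the paired design. At large effect sizes both engines
saturate region-level recovery — the detection threshold is a quantile,
hence rank-based — so the paired advantage is most visible at moderate
effects and in the per-probe statistics themselves.

## What the generator simulates — and what it does not

`simulate_psdmr()` draws, for probe *i* and pair *j* on the M scale:

* a probe mean `mu_i` from a two-component Gaussian mixture (defaults:
  means −3 and +2.5, SD 0.5, weights 0.6/0.4), mimicking the bimodal
  low/high-methylation marginal distribution of array betas;
* a baseline `b_ij ~ N(mu_i, baseline_sd_m)` shared by the tumor and
  normal sample of pair *j* — the patient-level random intercept whose
  removal is the point of paired testing (default 1.5, a strong but
  realistic heterogeneity level);
* independent technical noise with SD `noise_sd_m` (default 0.5) per
  sample, and a spike effect `delta_m` added to tumor M-values inside
  designated probe windows.

Betas are the inverse logit2 of M, hence always inside (0, 1). Defaults
place 5,000 CpGs on each of 4 chromosomes with geometric gaps of mean
100 bp, giving a realistic mix of cluster sizes around the 300 bp gap
rule; 20 pairs mirror a typical paired cohort. The single seed is expanded
into per-stage substreams (manifest: `seed`; betas: `seed + 1`) using R's
Mersenne-Twister generator, so outputs are byte-identical across runs and
platforms.

Deliberately *not* simulated: probe cross-reactivity, SNP-affected probes,
batch and chip effects, Infinium type I/II chemistry differences, or
copy-number-driven intensity artefacts. Passing tests on this generator
therefore demonstrate the statistical machinery — calibration,
power ordering, state fidelity — not robustness to array artefacts, which
upstream preprocessing is expected to handle. No claim is made about the
effect-size distribution of real DMRs; spike sizes are calibration knobs.

The cfDNA generator (`simulate_roi_counts()`) draws negative binomial
counts with per-ROI lognormal baseline means around `base_mean`, lognormal
library sizes, a common dispersion, and log2 fold changes on selected
ROIs. It emulates fragment counts over targeted regions of interest, not
read-level data.

## The targeted cfDNA stage

`normalize_rpkm()` is the exact closed form
`count * 1e9 / (length_bp * library_size)`. `cfdna_test()` fits, per ROI,
a negative binomial log-linear model with a log library-size offset and a
group coefficient, at a **common dispersion** estimated across ROIs by the
method of moments (median of positive per-ROI `(var - mean) / mean^2`
estimates on library-size-scaled counts). Common rather than per-ROI
dispersion is a robustness choice at targeted-panel ROI counts, and a
documented limitation where dispersion genuinely varies. Significance
comes from a likelihood-ratio test against the no-group model (chi-square,
1 df), preferred over Wald for small-sample behavior; the model fit itself
uses iteratively reweighted least squares (`stats::glm` with a fixed-theta
negative binomial family), with the maximized likelihood verified against
a refining grid search in the tests. `prioritize_windows()` ranks by
unadjusted p — appropriate for a validation-focused targeted panel, not
for genome-wide discovery. All-zero ROIs are flagged and returned with
`p = 1`, `logFC = 0`.

## Annotation and comparison conventions

Internal coordinates are 1-based inclusive; BED input/output converts to
0-based half-open at the boundary, GFF3 stays 1-based. Promoters default
to TSS −2000/+500 bp oriented by strand (a common convention; exposed as
parameters), clipped at position 1. A DMR overlapping several promoters is
reported once per gene — gene-to-DMR is many-to-many. Significance
filtering is **strictly** `fwer < threshold`. Top-k gene lists rank by
(fwer, −area, position) and deduplicate symbols at first occurrence;
family tallies match prefixes case-sensitively with longest-prefix-wins.
Multi-group panel comparisons exclude genes whose maximum group mean falls
below `low_signal_threshold` (default 0.1 on the normalized panel scale)
and use Wilcoxon rank-sum tests, since bounded panel levels are not
Gaussian.

## Numerical choices and degenerate inputs

* Zero-variance probes: capped t (±100) preserves extreme ranking without
  infinities.
* Smoothing windows always include at least 4 probes (the tricube weight
  at the window edge is exactly zero); a singular local-quadratic system
  falls back to local linear, then to the weighted mean.
* Quantile thresholds use R's default (type 7) sample quantile.
* All-missing probes are always dropped; an exactly zero regional beta
  difference is called `Hyper` and logged.
* NB fits on all-zero ROIs are not attempted (flagged instead); the LRT
  statistic is floored at 0.

## Problem sizes used by the packaged checks

The simulation-based checks run at sizes chosen to make their Monte-Carlo
error small relative to the properties asserted: FWER calibration uses 100
pure-noise datasets of 20,000 CpGs and 20 pairs at `B = 200`; spike
recovery uses 20 spiked regions of 10 probes (|delta_m| = 1.5) in 40
pairs; the paired/unpaired comparison aggregates recoveries over 10
simulation seeds; NB type-I error uses 2,000 null ROIs at dispersion 0.1.

## Known limitations

* The FWER is estimated, with resolution `1 / (B + 1)`; very small FWERs
  need large `B`.
* The `p` column's size-stratified convention can be coarse when few null
  regions reach the candidate's size; `fwer` is the primary inferential
  quantity.
* No covariate adjustment, cell-type deconvolution, or CpG-island
  annotation; the input is assumed normalized upstream.
* Common-dispersion NB tests mildly misstate significance for ROIs whose
  true dispersion departs far from the panel median.
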
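---
title: "Multimodal brain connectivity and BMI prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal brain connectivity and BMI prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmiconn)
```

# The analysis

`bmiconn` implements a multimodal connectome analysis that relates brain
network structure to body mass index (BMI). Per subject it builds two
networks over a common parcellation (116 regions by default, the size of the
AAL atlas):

* a **structural network** from diffusion-tractography fiber records. The
  edge weight between regions $u$ and $v$ is the fiber density
  $$FD(u,v) = \frac{2}{S_u + S_v} \sum_{f} \frac{1}{l(f)},$$
  the inverse-length-weighted count of streamlines joining the two regions,
  normalized by their cortical surface areas $S_u, S_v$ (mm^2). Streamlines
  shorter than 20 mm or longer than 500 mm are discarded (inclusive bounds
  -- the conventional reading of a "20--500 mm" cutoff). Pairs joined by no
  surviving streamline are *absent*: density 0 plus an explicit presence
  mask, because the downstream subject-exclusion rule must distinguish "no
  fiber" from "tiny density".

* a **functional network** from ROI time series: per-region demeaning (an
  intercept-only special case of nuisance regression), a hard Fourier-mask
  band-pass at 0.009--0.08 Hz, Pearson correlation and the Fisher r-to-z
  transform. A region's **mean functional connectivity** is the mean of its
  z values to all other regions -- a scaled weighted degree centrality. We
  average z, not raw r, because the matrix is z-normalized before any
  analysis; the diagonal is excluded since the constant self-correlation
  would bias every region identically. Negative correlations are kept with
  their sign; thresholding them is a documented alternative we did not take.

The group analysis then proceeds in three steps:

1. **Edge-wise permutation testing.** For every eligible edge, a pooled
   two-sample t statistic compares healthy-weight (HW, BMI < 25 kg/m^2) and
   non-HW subjects over the subjects *in which the edge is present*. An
   edge is eligible when fewer than 20% of subjects lack it and each group
   retains at least two. Group labels are shuffled globally (5000 times by
   default); each edge's statistic is recomputed on its own fixed
   present-subject set -- presence is anatomy, not label, so it is never
   permuted. Family-wise error is controlled with the single-step
   max-statistic correction, the canonical permutation-based "corrected p".
   P-values use the add-one estimator, so the smallest reportable value is
   $1/(n_{perm}+1)$. Surviving edges are filtered to those touching the
   reward system (thalamus, insula, putamen, orbitofrontal cortex). The
   whole-brain-test-then-filter order is one of two readings of the design
   we implement; testing reward edges only is available by subsetting the
   atlas flags.

2. **Cross-modal coupling.** Each surviving structural edge is correlated,
   across present subjects, with the mean functional connectivity of each
   endpoint; the edge is retained when either side is significant at
   p < 0.05. These p-values are deliberately *not* multiplicity-corrected:
   the edge set was already screened family-wise, and the coupling rule is
   a selection heuristic, not an inferential claim. The feature set then
   contains one fiber-density column per retained edge and one mean-FC
   column per *distinct* region whose own side was significant -- a region
   shared by two retained edges enters once, and an endpoint whose coupling
   failed contributes no functional feature. For the regression design,
   absent edges contribute density 0 so the matrix has no holes and the
   model keeps all subjects.

3. **BMI prediction.** Single-response partial least-squares regression
   (PLS1, NIPALS with deflation), with columns standardized to unit
   variance -- necessary because fiber densities and z-correlations live on
   incommensurate scales. The latent-variable count is chosen by
   leave-one-out PRESS, adding components until PRESS first fails to
   improve (a global-minimum option exists). Prediction quality is
   estimated by leave-one-subject-out cross-validation with the LV count
   re-selected *inside every fold* by an inner leave-one-out -- the
   held-out subject touches neither selection nor fitting, which we assert
   in tests by corrupting the held-out row. Reported metrics: RMS error,
   percent error (actual BMI in the denominator, which the convention
   leaves implicit), the actual-vs-predicted Pearson r, and "explained
   variance" -- the training $1 - RSS/TSS$ of a final fit at the modal
   selected LV count, which is how a single explained-variance number can
   coexist with cross-validated errors. Whether per-feature simple-regression
   R^2 should be computed within folds is ambiguous; we compute it once on
   the full cohort and note that it is descriptive, not cross-validated.
   A modality switch (`combined`, `dti_only`, `fmri_only`) restricts only
   the regression design matrix; feature selection is always multimodal.

# The synthetic cohort generator

Real diffusion/resting-state cohorts of this kind sit behind controlled
access, so the package ships a generator that reproduces the *statistical
conditions* the analysis assumes, making every stage testable end to end.
The defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | 60 | subjects per group (120 total) |
| `bmi_mean_hw`, `bmi_sd_hw` | 22.53, 1.37 kg/m^2 | HW BMI distribution, truncated below 25 |
| `bmi_mean_nhw`, `bmi_sd_nhw` | 32.55, 3.60 kg/m^2 | non-HW BMI, truncated at/above 25 |
| `n_regions` | 116 | atlas size |
| `fiber_length_log_mean/sd` | 2.762889, 0.4 | lognormal, truncated to [20, 500] mm; truncated mean 26.2 mm |
| `mean_fibers_per_edge` | 30 | Poisson mean streamline count per connected pair |
| `edge_sparsity` | 0.5 | fraction of pairs with no fibers in any subject |
| `presence_dropout` | 0.05 | per-subject probability a connected pair is empty |
| `n_timepoints`, `sampling_interval` | 1200, 0.72 s | length and TR of the time series |
| `planted_edges` | 10 reward-touching edges, d = 1.2 | group differences in fiber density |
| `coupling_edges` | 6 edges, target r 0.26--0.45 | structure-function coupling |
| `bmi_signal_fraction` | 0.57 | variance fraction of BMI carried by the drivers |

Choices the data do not pin down, and how we made them:

* **Fiber lengths** are lognormal truncated to [20, 500] mm; only the mean
  (26.2 mm) and the range are given conditions, so the shape is a modelling
  choice (`sdlog = 0.4`; `meanlog` solved numerically so the *truncated*
  mean is 26.2).
* **Streamline counts** are Poisson around per-pair Gamma-distributed base
  rates (shape 4), giving realistic between-edge heterogeneity. Planted
  effects shift the non-HW count rate by the amount that produces the
  requested Cohen's d *in density*, solved through the first two moments of
  1/length under the truncated length law. Monte-Carlo checks show the
  realized d within about 0.1 of the target at n = 60/60.
* **Topology**: a spec-controlled fraction of pairs is structurally absent
  (planted and coupled edges are always wired), and each connected pair
  independently drops out per subject with probability 0.05 -- this is what
  exercises the "<20% excluded subjects" eligibility rule.
* **Structure-function coupling.** Time series follow a latent-factor
  model: every region loads (amplitude 0.6) on one band-limited shared
  signal plus its own band-limited noise (amplitude 0.8), giving baseline
  inter-regional correlations near 0.36 and essentially all spectral power
  inside 0.009--0.08 Hz. For a coupling edge, the target region's shared
  amplitude is modulated (slope 0.5 per latent SD) by a latent that mixes
  the edge's realized standardized density with fresh noise. The mixing
  weight is `target_r / 0.92`, where 0.92 is a fixed calibration constant
  for the attenuation of the amplitude-to-measured-mean-FC chain
  (correlation-estimation noise at finite series length plus the mild
  nonlinearity of the amplitude-to-correlation map; measured between 0.90
  and 0.94 across the problem sizes we use). Densities are standardized
  over *present* subjects, with dropped-out subjects at the mean, so the
  planted correlation lives in the present-subject set -- the set the
  coupling analysis is computed on. Conditioning the functional side on the
  realized structural values (rather than injecting one shared latent into
  both simulators) removes an attenuation stage and makes the realized
  correlation track the target closely; Monte-Carlo at n = 120 gives
  realized r within about 0.03 of the target on average, with
  across-replicate SD near 0.09.
* **BMI** is a linear combination of standardized driver features plus
  Gaussian noise -- linear because the downstream model is linear. The
  noise SD is derived in-sample from `bmi_signal_fraction`, so the
  generating R^2 is exact. Two calibrations: `"group"` (default) maps each
  pre-assigned group's scores affinely onto the group mean/SD and reflects
  boundary crossers across 25 kg/m^2, so labels and BMI stay consistent;
  `"cohort"` applies one affine map to the mixture moments, preserving the
  whole-cohort signal fraction -- the mode used by the signal-recovery
  experiments, where per-group rescaling would confound the fraction with
  group separation. Default driver coefficients put the largest weight on
  the functional centrality of the right thalamus, with magnitudes
  proportional to the square roots of the single-feature R^2 values typical
  for the two feature classes.
* **Seeding**: everything flows from one root seed through named substreams
  (`atlas`, `topology`, `fibers/<i>`, `timeseries`, `bmi`), so any stage can
  be regenerated independently and an identical spec yields a bit-identical
  cohort.

What the generator does *not* emulate: raw image formation, head motion,
physiological noise, spatially structured functional subnetworks, negative
structure-function coupling, or non-linear BMI dependence. Passing tests
therefore demonstrate that the *pipeline* behaves correctly under its own
assumptions -- calibrated error rates, power, selection bookkeeping,
honest cross-validation -- not that those assumptions hold in real
neuroimaging data.

# Numerical choices and degenerate inputs

* Correlations of exactly 1 in magnitude are clamped to `1 - 1e-7` before
  the Fisher transform; zero-variance regions are an error naming the
  region.
* The band-pass is a hard Fourier mask (no roll-off); the DC bin is always
  removed, and run concatenation demeans each run first so an offset
  between acquisitions cannot masquerade as shared signal.
* In the permutation test, a label shuffle that leaves a group with fewer
  than two present subjects at some edge (essentially impossible at the
  eligibility threshold) yields NA for that edge and is ignored in the
  max-statistic; ties between permuted and observed statistics count
  against significance (the `>=` convention).
* PLS1 stops extracting components when the response deflates below 1e-14
  and carries the converged coefficients forward, so "more components than
  the response supports" is well defined; constant feature columns are an
  error naming the column.
* PRESS folds re-standardize from scratch, exactly matching a naive
  refit-per-subject loop (asserted to 1e-10).
* `select_n_lv` breaks PRESS ties in favor of fewer components (the
  first-non-improvement rule uses `>=`).

# Problem sizes used by the tests

The test suite and the acceptance script run the full workflow at reduced
but statistically honest sizes, chosen so each property is measured with
real power: null calibration on 200 cohorts of 2 x 30 subjects with 21
edges and 500 permutations; power on 50 cohorts of 2 x 60 with six planted
d = 1.2 edges and 1000 permutations; coupling retention on 200 cohorts of
120 subjects with 16 regions and 600 time points; signal recovery at
fractions 0.2/0.4/0.6 on 50 cohorts each of 120 subjects, 20 regions and
300 time points. The analysis scripts under `analysis/` run the
full-default conditions (116 regions, 1200 time points, 5000 permutations).

# Known limitations

* The pooled-t edge statistic assumes roughly comparable within-group
  spreads; a Welch variant would be a one-line change but would depart from
  standard permutation-FWE practice.
* The coupling retention rule inherits the selection biases of any
  significance-based feature selection; downstream explained variance on
  the *same* cohort is descriptive, and only the cross-validated errors are
  protected against it.
* The generator's coupling calibration constant (0.92) was tuned for series
  of 300--1200 points and 16--116 regions; far outside that range the
  realized correlation will drift from `target_r`.
* With fewer than 18 regions the default planted/coupling/driver sets are
  empty (the layout needs the 8 reward + 10 partner slots); supply explicit
  edge tables for miniature atlases.
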
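---
title: "Profile strength for Cell Painting: models, metrics, and the synthetic plate generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile strength for Cell Painting: models, metrics, and the synthetic plate generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpscope)
```

## The problem this package addresses

High-content Cell Painting experiments must choose acquisition settings —
objective magnification, number of imaged sites (fields of view) per well,
channel set, binning, z-planes — before any biology is measured. A
practical way to grade a configuration is to image a *positive-control*
plate whose layout guarantees known structure: the JUMP-MOA design places
90 compounds from 47 mechanism-of-action (MOA) classes at 4 replicate
wells each on a 384-well plate (43 MOA classes contribute compound pairs,
4 are singletons; the remaining 24 wells are vehicle controls). Good
settings should make replicate wells of the same compound look alike, and
wells of MOA-matched *different* compounds look alike. Those two
abilities are quantified as **percent replicating** and **percent
matching**, and their mean, **percent score**, ranks settings on a
leaderboard normalized to each instrument's best configuration.

`cpscope` implements the full computational path of that grading —
plate-map generation and validation, well-profile construction, the two
resampling metrics, and the setting-perturbation experiments (site
subsampling, channel dropout) — together with a synthetic single-cell
feature generator so the whole pipeline runs, and is testable, without any
images.

## Well profiles

Single-cell feature tables follow the CellProfiler convention: columns
prefixed `Metadata_` are annotations; all other columns are features named
`Compartment_Group_Measure[_Channel[_Channel2]]`, so the channel
attribution of any feature is recoverable from its name alone
(`channels_of_feature()`). Profiling proceeds in the standard order:

1. **Mean aggregation** (`aggregate_profiles()`): the well profile is the
   arithmetic mean over *cells*, not over site means, so sites with more
   cells weigh proportionally more. The pipeline always aggregates cells
   to wells directly; the two orders agree only when all sites of a well
   contain equally many cells.
2. **MAD robustization** (`mad_robustize()`), per plate and per feature:
   `x <- (x - median) / (1.4826 * MAD + eps)` with `eps = 1e-18`. The
   1.4826 consistency constant makes the robust scale comparable to an SD
   under Gaussian noise. Features with zero MAD on a plate become
   all-missing there and are left for selection to remove. The
   normalization population is *all* wells of the plate; nothing in the
   underlying procedure fixes a reference population, so whole-plate
   robustization — the simplest choice — is the default.
3. **Feature selection** (`feature_select()`), in order: `drop_na`
   (missing fraction > 0.05), `variance_threshold` (most-common /
   second-most-common value frequency ratio > 19 *and* unique-value
   fraction < 1%), and `correlation_threshold` (greedily remove, from any
   pair with |Pearson r| > 0.9, the member with the larger mean absolute
   correlation to all remaining features; ties break lexicographically by
   name, which makes the trace deterministic and order-independent). The
   cutoffs are conventional defaults of this processing stack, exposed as
   arguments, not measured quantities.
4. **Channel dropout** (`drop_channel_features()`) removes every feature
   whose parsed channel set contains the token — including two-channel
   colocalization features — and is meant to run *before* selection,
   mirroring how four-channel acquisitions were emulated from five-channel
   profiles.

Wells with zero cells yield missing profiles; they are flagged in
provenance, excluded from metrics, and never imputed.

## Percent replicating and percent matching

Let wells carry post-selection profiles and let correlation mean Pearson
correlation across feature columns.

* For each compound $c$ with at least two profiled wells, the
  **replicate statistic** $r_c$ is the median of all pairwise
  correlations among its wells (6 pairs for 4 replicates).
* For each compound whose MOA class contains another profiled compound,
  the **matching statistic** $m_c$ is the median correlation over all
  well pairs (well of $c$) × (well of a same-MOA different compound);
  singleton-MOA compounds are excluded and reported.

Each statistic is compared against the 95th percentile of a **null
distribution** of 10,000 seeded resampling draws (`sample_null()`). The
published recipe — a null from the correlations of random non-matching
wells — leaves the resampling unit ambiguous. `cpscope` resolves it so
that *null and foreground are exchangeable*, which is what makes the
5% nominal level meaningful:

* replicating null: 4 wells with pairwise-distinct compounds, summarized
  by the median of their 6 pairwise correlations;
* matching null: 2 *compounds* with distinct MOA classes, summarized by
  the median over their 4 × 4 cross-well correlations.

Under a no-signal plate each foreground statistic then has exactly the
null's distribution, so about 5% of compounds exceed the threshold by
chance — the calibration the test suite verifies. The alternative literal
reading (each draw = one random well pair) is available as
`metric_config(null_unit = "pair")`; note that a median over many pairs
is much more concentrated than a single pair's correlation, so the pair
null is conservative for both metrics and cannot be 5%-calibrated.

Remaining conventions: thresholds use the inclusive linear-interpolation
percentile (R's `quantile` type 7, so `percentile(0:99, 95) = 94.05`);
exceedance is strict (`>`), ties count as failures; negative-control
wells are excluded from foreground and, by default, from the null;
sampling is without replacement within a draw and with replacement across
draws, with rejection enforcing distinctness. Percent score is the plain
mean of the two percentages; duplicate setting labels are mean-aggregated
before a leaderboard is normalized to its best score
(`normalize_leaderboard()`).

## The synthetic plate generator

`simulate_plate()` emulates the statistical structure the analysis relies
on, not pixels. A cell in well $w$, site $s$ has feature vector

$$x = \beta_{c(w)} + \text{row}_w + \text{col}_w + \eta_s +
\sigma_{\text{cell}}\,\varepsilon,$$

* **Compound effects** (`build_effect_library()`): each MOA class $m$
  draws a unit direction $u_m$, each compound $c$ a unit direction $v_c$;
  active compounds (a seeded fraction $f$, default 0.9) get
  $\beta_c = a(\sqrt{\rho}\,u_{m(c)} + \sqrt{1-\rho}\,v_c)$, inactive
  compounds and vehicle wells get $\beta = 0$. Two active same-MOA
  compounds have expected effect cosine $\rho$ (default 0.5; exactly
  parallel at $\rho = 1$), which is what percent matching detects.
* **RNA/ER redundancy**: RNA-channel effect loadings are mixed with the
  aligned ER-channel loadings (weight 0.8 by default), emulating the RNA
  dye's visibility in the ER channel; this is what makes RNA-feature
  dropout nearly neutral. **Brightfield attenuation**: Brightfield
  feature loadings are scaled by 0.25, encoding that transmitted-light
  features carry attenuated phenotypic signal. Both are configuration
  knobs, not claims about optics.
* **Noise**: plate row/column gradients (SD 0.1) drawn once per plate per
  feature emulate well-edge/center effects; site effects (SD 0.1) are
  shared by a field of view; cell noise (SD 1) is correlated within a
  channel through one latent factor per channel per cell with loading
  $\sqrt{r_{\text{chan}}}$ (default $r_{\text{chan}} = 0.3$;
  colocalization features load equally on both channels' factors). The
  Gaussian form is an implementation choice — the real features' noise
  law is not characterized — chosen as the simplest structure that makes
  correlation-based feature selection non-trivial.
* **Cell counts**: cells per site are Poisson with magnification-specific
  means 10X = 600, 20X = 150, 40X = 40, ordered by field-of-view area so
  that magnification and cell count are inversely coupled as in real
  acquisitions, and so the default 20X, 9-site plate sits near the
  ~2,500 cells/well (~1M cells/plate) regime where profile strength
  saturates.

Everything is deterministic per seed, and the generator's RNG is isolated
from the caller's.

What the generator does *not* emulate: pixel-level phenomena
(bleedthrough, focus, illumination), non-Gaussian feature distributions,
batch/plate-to-plate drift, or biologically structured feature groups
beyond the channel factor. Green tests therefore demonstrate correctness
of the *computational pipeline* and its calibration under the stated
model — not that any particular real microscope configuration scores
well.

## Setting-perturbation experiments

* `subsample_sites()` redraws each well independently (no shared site
  index across wells — per-profile subsampling, avoiding plate-wide site
  artifacts), keeps those cells, and re-aggregates; one draw per target by
  default.
* `cellcount_curve()` sweeps magnifications and site targets, reporting
  plate cell count and both metrics per condition — the analogue of
  relating profile strength to cell count.
* `channel_dropout_experiment()` runs the pipeline twice from the same
  simulated cells, with and without a channel's features (dropped before
  selection), and reports the paired difference without asserting a
  direction.
* `channel_correlation_summary()` gives the channel × channel mean |r|
  between feature groups (diagonal: within-channel, self-pairs excluded),
  the summary in which spectrally adjacent channels stand out.
* `run_experiment()` orchestrates a full leaderboard run and writes a
  manifest (seed, config hash, versions, per-stage status) so interrupted
  runs are detectable.

## Problem sizes and numerical choices in the test suite

The packaged tests and the acceptance script run the full 384-well layout
but scale the simulation down to what the statistics need rather than
what a microscope produces: 4 features per channel + 4 channel-free
features over the 6-channel registry (42 features), 1–3 sites per well,
and 15–60 cells per site. Null sizes are the default 10,000 where
calibration is being measured and 2,000 for sweep comparisons (the
threshold's Monte-Carlo error is negligible at both sizes). Calibration
is judged over 20 plates against the exact binomial 99% interval around
the nominal 5%; monotonicity over 10 seeds per condition via Spearman
trend. These sizes are the package's own choices for a desk-scale
demonstration; all of them are ordinary function arguments.

## Known limitations

* The matching statistic is symmetric within a compound pair, so the 86
  evaluated compounds contribute 43 distinct values; the per-compound
  accounting mirrors the leaderboard convention rather than adding
  information.
* Leaderboard values from the original instrument comparisons depend on
  terabytes of images and cannot be recomputed here; the package
  reproduces the *procedures* and their qualitative behavior (calibration,
  monotonicity with cell count, dropout neutrality), not those numbers.
* `null_unit = "pair"` is provided for comparability but is intentionally
  not the default (see above).
* Real CellProfiler SQLite ingestion is out of scope; CSV feature tables
  with the `Metadata_` convention are the supported input.
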
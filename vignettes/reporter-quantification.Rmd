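---
title: "Quantifying client stability with a dual-fluorescence reporter: models, parameters, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying client stability with a dual-fluorescence reporter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualreporter)
```

## The measurement model

The assay reads out post-translational stability of a membrane-protein
client from single cells. A bicistronic construct expresses the client
fused to mCherry and, via P2A ribosomal skipping, a free GFP — one GFP
molecule per client–mCherry molecule. GFP therefore measures how much
reporter a cell expressed; mCherry measures how much client survived
degradation. For cell $i$ the quantity of interest is

$$r_i = \frac{\text{mCherry}_i}{\text{GFP}_i},$$

and the per-cell GFP denominator cancels expression heterogeneity,
which in mammalian reporter lines spans well over a decade. Because
fluorophore brightness, maturation efficiency, and detector gain scale
both channels' units arbitrarily, $r_i$ is only meaningful relative to
a reference: every mutant sample is normalized by the scalar ratio of
the wild-type-rescue line of the same knockout background and client,
placing wild type at 1 by construction.

## The generative model behind the synthetic data

`synth_config()` describes one simulated acquisition. Events are a
two-component mixture:

* **Live cells** (fraction `live_fraction`, default 0.85 of 20,000
  recorded events — the acquisition depth the pipeline assumes per
  sample). Per-cell expression is $E \sim \mathrm{LogNormal}(\mu_E,
  \sigma_E)$ with defaults $\mu_E = \log 1000$, $\sigma_E = 0.8$
  (roughly a 2-decade 95% range, typical of virally integrated
  reporters). Channels are
  $$\text{GFP} = E\, g\, \varepsilon_G + a_G, \qquad
    \text{mCherry} = E\, \varphi\, c\, \varepsilon_R + a_R,$$
  where $\varphi$ is the client-stability fold change ($\varphi = 1$
  wild-type-like), $g, c$ are channel gains, $a_G, a_R$ small additive
  autofluorescence backgrounds (default 5, i.e. ~0.5% of the median
  signal), and $\varepsilon$ are independent unit-mean log-normal
  noise factors with coefficient of variation `noise_cv` (default 0.3,
  covering shot noise plus maturation variability). Scatter comes from
  a tight log-normal cluster (sdlog 0.20–0.25, a ~20–25% CV typical of
  a clonal suspension line).
* **Debris** carries autofluorescence only and scatters as a broad
  log-normal smear (sdlog 1.5) whose median FSC and SSC sit 10× below
  the live cluster. Debris in real acquisitions is heterogeneous —
  fragments, apoptotic bodies, aggregates spanning decades — and the
  broad-smear default also gives the density gate an unambiguous
  ground truth: a *tight* debris cluster would reach local densities
  comparable to the live cluster's retention contour, and no
  parameter-free density gate could separate it cleanly.

Because the log-ratio of two iid log-normal noise factors is symmetric
about zero, the median live-cell ratio equals $\varphi\, c / g$
regardless of the noise level — the ratio-of-medians identity the
effect-recovery checks rely on.

All draws are made for every event in a fixed order, so two configs
sharing a seed consume identical random streams: changing only
$\varphi$ leaves GFP, scatter, and population labels bit-identical and
rescales live-cell mCherry exactly — a common-random-numbers
construction useful for paired contrasts. Panel streams are keyed by
`(sample_id, seed)` so adding a sample never perturbs another's data.

What the generator deliberately does **not** model: doublets,
acquisition-time drift, detector saturation, spectral spillover,
cell-cycle structure, or transcriptional bursting. Passing tests on
synthetic data therefore demonstrate that the *procedure* is correct
and calibrated under its own assumptions, not that those assumptions
exhaust real FACS data; compensation in particular must happen
upstream if the fluorophores spill over.

## Live-cell gating

`gate_live()` reproduces cluster gating reproducibly: a 2-D kernel
density estimate on $(\log_{10}\text{FSC-A}, \log_{10}\text{SSC-A})$
over a 128×128 grid, events ranked by interpolated local density, the
densest retained until `target_fraction` (default 0.85) of gateable
events is reached. Choices that matter:

* **Bandwidth**: the normal-reference rule on each axis's standard
  deviation. The common robust variant (minimum with IQR/1.34) is
  avoided deliberately: on a strongly bimodal mixture the IQR collapses
  onto the dominant cluster and the resulting bandwidth undersmooths
  the minor population, degrading the gate.
* **Determinism**: density ties break by original event order; the
  density ranking is fixed for fixed data, so nested fractions give
  nested masks and the gate is permutation-equivariant.
* **Degenerate inputs**: events with FSC ≤ 0 or SSC ≤ 0 are dropped
  before the log transform (more than 50% dropped is an error), and
  fewer than 100 gateable events refuses density estimation.
* **Scatter-only contract**: fluorescence never influences the mask.

The gate is fractional, not model-based: it retains `target_fraction`
of whatever it is given. QC therefore reports Sarle's bimodality
coefficient of the retained set's log10 FSC; above 5/9 the gate
demonstrably straddled two populations and a warning fires. The
converse failure — a sample whose *single* population is the wrong one
(pure debris) — cannot be detected from one sample's scatter in
arbitrary units; catching it needs cross-sample comparison, which is
left to the analyst. The default fraction 0.85 matches the generator's
default live fraction; on real panels it should be set from the
samples' own scatter profiles.

## Ratios and normalization

Ratios are computed on linear intensities for gated cells; cells
non-positive in either channel are excluded (not clamped — a ratio with
a non-positive denominator is undefined, and clamping biases the tail)
and counted, so event accounting is exact through the chain. The
wild-type normalizer statistic is the **median** by default: ratio
distributions are strongly right-skewed, and the median is insensitive
to the tail while guaranteeing the reference itself normalizes to
exactly 1. The mean is available where comparability with mean-based
analyses matters. Histograms for display use log10-spaced bins with
out-of-range values clipped into the edge bins, so counts are always
conserved.

## The bootstrap-then-test procedure and its calibration

Inference follows the published screen procedure exactly: from each
sample's normalized per-cell ratios, draw $B = 1000$ resamples of
$m = 50$ cells with replacement, record each resample's mean, and fit
a normal to the $B$ means. A mutant is compared to its wild-type
reference by two one-sided tests between the two length-$B$
bootstrap-mean vectors at $\alpha = 0.01$ per direction; with one
continuous statistic the p-values are complementary, and the category
is `decreased` / `wt_like` / `increased`. The default statistic is the
Welch unequal-variance $t$ (the source procedure names "two one-sided
T-tests" without a variant; Welch avoids an unstated equal-variance
assumption). A pooled-variance $t$ and a $z$-test on the fitted
$(\hat\mu, \hat\sigma)$ are options, as is Benjamini–Hochberg
adjustment across a panel (off by default — the procedure as published
applies a fixed per-test cutoff).

This procedure has a calibration property worth understanding before
interpreting `wt_like` counts. With $n$ gated cells of per-cell
variance $\sigma^2$, a bootstrap mean of $m$ cells has variance
$\approx \sigma^2/m$, so the $t$ denominator estimates
$\sqrt{2\sigma^2/(mB)}$. But the *true* variance of the difference of
grand bootstrap means has two parts: the sampling variance of the two
underlying sample means, $2\sigma^2/n$, plus the bootstrap resampling
variance $2\sigma^2/(mB)$. Under the null the statistic is therefore
approximately
$$t \sim \mathcal{N}\!\left(0,\; \frac{mB}{n} + 1\right),$$
not standard normal, and the per-direction false-call rate is
$$1 - \Phi\!\left(\frac{z_{1-\alpha}}{\sqrt{mB/n + 1}}\right)$$
— about 0.12 at the defaults ($n \approx 17{,}000$, $mB = 50{,}000$,
$\alpha = 0.01$), an order of magnitude above the nominal 0.01. In the
large-resample limit $mB \gg n$ this reduces to
$1 - \Phi(z_{1-\alpha}\sqrt{n/(mB)})$ (≈ 0.087 at the same settings),
an approximation that is measurably too low here because $mB/n$ is
only ≈ 3. The acceptance suite measures the empirical rate over 2000
simulated null pairs and finds it consistent with the $mB/n + 1$ form
(within ±0.02) and not with the large-resample limit. Two practical
consequences: the procedure is anti-conservative relative to its
nominal $\alpha$, so isolated calls near the cutoff deserve
skepticism; and because the heavy-tailed ratio distribution couples
each sample's mean and variance estimates, the observed rate sits
slightly below the normal-theory value. The package reports the
procedure as published and documents — rather than corrects — this
property; a calibrated alternative (a plain two-sample test on cells,
or $m$ scaled to $n$) changes the published procedure and is out of
scope.

Degenerate cases are pinned down for determinism: two zero-variance
bootstrap distributions compare as an exact `wt_like` (both p = 0.5)
when equal and as p = 0 in the direction of the difference when not. A
mutant whose event data are identical to its reference reuses the
reference's bootstrap stream, making the self-comparison an exact null
($t = 0$). Both tails are computed directly from the $t$ distribution
(never as $1 - p$) so each retains full relative precision in its own
extreme.

## Panel orchestration and exports

`run_pipeline()` validates the manifest (exactly one wild-type
reference per knockout background × client; unique sample ids; files
readable), runs read → gate → ratio → normalize → bootstrap → test per
sample with streams keyed by `(sample_id, seed)`, and returns calls,
per-client category counts, QC records, and the resolved configuration.
Exports are fixed-format delimited text plus a JSON config snapshot, so
identical inputs give byte-identical outputs and a run can be
reproduced from its own snapshot. `assemble_matrix()` pivots calls to
the mutant × client phenotype matrix with missing combinations marked
explicitly; `export_residue_attributes()` parses mutation strings
(`SUBUNIT_<wt><pos><mut>` joined by `+`, positions 1-based, e.g.
`EMC3_N114D+N117D`) and emits a viewer-agnostic per-residue table with
the conventional display colours (decreased gold, wild-type-like light
blue, increased white), optionally checking wild-type letters against
reference sequences. Residue numbering is passed through verbatim; any
offset between mutation nomenclature and a deposited model's numbering
must be applied by the user. The package is a library: its exported
functions and this vignette are the interface, and
`scripts/acceptance.R` is the reproducible entry point for the
headline numbers.

## File formats

Events read/write as TSV (header `FSC-A`, `SSC-A`, `GFP-A`,
`mCherry-A`; full double precision) or FCS 3.0/3.1 list mode. The FCS
layer is a minimal reader/writer pair — float32/float64/integer data,
either byte order, TEXT-segment keywords — sufficient for instrument
exports of this shape; it is not a general FCS toolkit (no analysis
segments, no parameter transforms).

## Problem sizes used in validation

The test suite exercises the pipeline at the assay's published scale
where the property being checked depends on it — 20,000-event samples
for effect recovery and gating fidelity, $B = 1000$, $m = 50$ for
power (100 seeded runs per direction) and null calibration (2000
simulated pairs at the gated depth of ~17,000 cells) — and at a few
thousand events elsewhere, where exactness properties (stoichiometry,
determinism, accounting) do not depend on depth. The statistical
simulations use live-only samples with a pass-through gate: the gate
is scatter-only by contract and validated separately, so re-running
kernel density estimation thousands of times would add cost without
adding evidence.

## Known limitations

* The gate cannot flag a sample whose only population is abnormal;
  absolute-unit sanity checks require calibration beads or
  cross-sample context.
* The dual one-sided test inherits the anti-conservative calibration
  of the published bootstrap-then-$t$ construction (quantified above).
* The generator's noise model is independent per channel; correlated
  channel noise (e.g. focus drift) would tighten observed ratio
  distributions relative to it.
* Mutation strings support single-residue substitutions only —
  insertions, deletions, and multi-residue swaps are out of scope.
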
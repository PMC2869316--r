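---
title: "Quantifying oxidative guanine damage and telomere integrity"
author: "telodamage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oxidative guanine damage and telomere integrity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodamage)
```

## Scope and models

Mammalian telomeres are guanine-rich TTAGGG repeats and therefore prime
targets for oxidative base damage (8-oxoG, FapyG). This package implements
the computational side of four assays used to measure that damage and its
consequences for telomere integrity, together with a synthetic-data module
that generates every input with known ground truth.

### Fpg-incision densitometry

Oxidized guanines are not directly visible on a Southern blot, but the
bacterial glycosylase Fpg converts each lesion into a strand break. On a
denaturing (alkaline) gel a telomeric restriction fragment carrying
lesions therefore migrates as several shorter fragments after Fpg
treatment, while the mock-treated half of the same sample stays intact.
The quantity read from each lane is its densitometric **mean length**,

$$ML = \frac{\sum_i MW_i \cdot OD_i}{\sum_i OD_i} \quad \text{[kb]},$$

where $MW_i$ is the molecular size at grid row $i$ and $OD_i$ the optical
density there (`mean_length()`). Because each incision splits one fragment
into two, the lesion load per fragment follows from the paired lanes as

$$\text{lesions per fragment} = \frac{ML_\text{mock}}{ML_\text{Fpg}} - 1,$$

(`estimate_lesions()`), and samples are compared as fold changes against a
control whose value is fixed at 1 (`fold_change()`,
`aggregate_lesions()`).

Assumptions worth stating: probe signal (hence OD) is proportional to
telomeric mass, so $ML$ is a mass-weighted mean fragment length; digestion
is complete (the `efficiency` parameter of `digest_fragments()` exposes
partial digests for sensitivity analysis, default 1); and hybridization and
transfer efficiency do not depend on fragment size. Noise can push the
estimator slightly negative at zero dose; negative values are reported raw
and flagged — clipping would bias replicate means upward.

Two open choices were resolved as follows. The mean length is computed over
the whole recorded lane by default, with an optional size `window`, because
no windowing rule is universal across gels. Background handling is a
constant optional `baseline` subtraction (clipped at zero); the default
grid spans 48.5–0.5 kb with no sub-marker rows from which to estimate a
baseline automatically, so the default is 0.

### Q-FISH spot quantification

Telomere-repeat PNA probes on metaphase spreads produce one fluorescent
spot per chromatid telomere whose integrated intensity is proportional to
telomere length. `detect_spots()` re-implements the quantification:

* candidate blobs are local maxima of a Laplacian-of-Gaussian response at
  the expected spot scale ($\sigma = r/2$ for expected radius $r$);
* the retained "peak" of a candidate is an efficient estimate of its
  amplitude above background — the sub-pixel-interpolated maximum of a
  zero-mean matched-Gaussian correlation map (the least-squares amplitude
  estimator under locally constant background);
* a candidate is retained when that amplitude exceeds `threshold_k` (6 by
  default) times the raw median absolute deviation of the channel. This is
  algebraically the condition *raw peak > channel median + k·MAD* on the
  background-corrected peak, which makes detection exactly invariant to
  constant offsets and equivariant under intensity scaling;
* integrated intensity is the pixel sum over a disc footprint minus a
  local annulus-median background times the footprint area, floored at 0.
  Annulus pixels falling inside another detected spot's footprint are
  masked so neighbouring chromatid telomeres do not inflate the
  background.

`assign_spots()` maps spots to the four telomeric ends of each chromosome
template by nearest anchor within a capture radius (default twice the
expected spot radius); ends without an assigned spot are **signal-free
ends** (SFEs). Probe/strand convention, stated once and used everywhere:
the (CCCTAA)₃ probe hybridizes to — and therefore measures — the G-rich
strand; (TTAGGG)₃ measures the C-rich strand. Coordinates are 0-based
(row, col) with pixel centres at integers.

`classify_two_color()` scores each chromatid from the G- and C-strand
calls (normal / g_loss / c_loss / both_loss); `colocalize_foci()` scores a
DNA-damage focus as telomeric when its nearest telomere spot centre lies
within `max_dist` pixels, and bins cells by focus count (1–3 vs >3).

Intensity units are arbitrary, as in the original software: fold-change
comparisons are meaningful within a run, not across instruments.

### CO-FISH event classification

After chromosome-orientation FISH the two strand-specific probes report
the lagging- and leading-strand telomeres separately. `classify_cofish()`
applies the scoring rules per chromosome: more than two signals in *both*
probes is a telomere sister chromatid exchange (T-SCE); fewer than two
signals in one probe with two in the other is a lagging- or leading-strand
loss; fewer than two in both is a loss in both strands. T-SCE takes
precedence — its pattern is disjoint from the loss patterns. Combinations
the rules do not address (one probe lost while the other shows more than
two) fall to `normal` and carry a review flag rather than a silent guess.
`tally_events()` reports per-specimen percentages per chromosome and group
means ± SEM across specimens (not a pooled binomial SE), matching the
n-animals-per-genotype reporting structure of cytogenetic studies.

### Frequency reports and group comparison

`frequency()` returns raw percentages; display rounding is half away from
zero (`round_half_up()`) and never feeds back into computation.
`build_report()` assembles the standard abnormality table (fragments &
breaks, end-to-end fusions, SFEs) and marks genotype differences with an
asterisk when a two-sided Fisher exact test on the pooled counts gives
p < 0.05. Fisher's exact test was chosen as the conservative default for
sparse event counts; the method and threshold are recorded in the report's
footer attribute. No multiple-testing correction is applied across the
table.

## The synthetic-data module

The generators produce data with exactly the statistical structure the
estimators assume, under a single user seed (`child_seed()` derives
decoupled sub-streams):

* `sim_fragments()`: log-normal fragment lengths, default median 20 kb,
  $\sigma_{\log}$ = 0.35 — mouse telomere restriction fragments are broad
  and right-skewed; probe-signal weight equals length.
* `sim_lesions()` / `digest_fragments()`: Poisson(rate × length) lesions
  placed uniformly within each fragment; each lesion is independently
  incised with the stated efficiency; total DNA length is conserved
  exactly.
* `render_lane()`: 60 geometric size bins from 48.5 kb (top) to 0.5 kb,
  Gaussian band spread in kb applied analytically via bin-edge integrals,
  additive Gaussian densitometer noise (default 1% of the peak OD),
  clipped at zero.
* `sim_metaphase()`: 40 chromosomes (mouse), two chromatids 10 px apart
  with telomere anchors 34 px apart, placed without overlap by rejection
  sampling on a 512×512 field; per-end Gaussian spots (SD 1.5 px) with
  log-normal integrated intensity (mean 5000 a.u., cv 0.35); camera model
  is Poisson shot noise plus additive Gaussian read noise with
  SNR = mean peak amplitude / read-noise SD, default 10; signal-free ends
  carry no spot in any probe channel.
* `sim_cofish()`: categorical event labels drawn independently per
  chromosome; signal counts constructed to satisfy the classification
  rules exactly at zero noise, so the label round trip is exact.

What the generators deliberately do **not** emulate: gel physics (band
inversion, smiling), chromosome morphology and banding, hybridization
kinetics, bleed-through between channels, and real chromosome
segmentation. Passing round-trip tests therefore validate the estimators
under their stated assumptions; they do not certify performance on real
micrographs, which are not part of this package's scope.

## Numerical choices and problem sizes

* Lane discretization bounds the mean-length error by half the local bin
  width; tests and validation use that bound explicitly.
* Grid mismatches between paired lanes are interpolated only when bins
  differ by <5%; larger mismatches error out rather than silently
  resampling across gels.
* Validation sizes, chosen for stable statistics: 10⁴ fragments per lane,
  10–20 seeds for replicate means, 20–40 metaphases (3 200–6 400 ends)
  for detection and SFE statistics, 2 000 chromosomes per CO-FISH
  specimen, 1 000 replicates for the exact-test size calibration.

## Known limitations

* **Detection-limit censoring of SFE calls.** With a broad (cv 0.35)
  log-normal intensity law, ~1% of true telomere spots fall below the
  median + 6·MAD detection limit at SNR 10 (the limit sits near 0.42× the
  mean spot amplitude). Threshold-based SFE scoring necessarily counts
  these as signal-free: the called SFE fraction at a true 5% rate runs
  ~1.2–1.4 percentage points high. This is a property of thresholded
  scoring on a distribution with mass below the detection limit — real
  Q-FISH has the same behaviour for short telomeres — and not reducible by
  a better estimator: the amplitude estimator used here is unbiased with
  ~5% noise, near the matched-filter bound. Raising SNR or narrowing the
  intensity law reduces the censored mass; both are generator parameters.
* The lesion estimator returns the ratio of mass-weighted mean lengths,
  whose expectation is not exactly the count-weighted mean lesion number;
  dose-response comparisons (monotonicity, fold changes) are the intended
  use, and the estimator agrees with its own fragment-population oracle to
  ~1%.
* Fisher's exact test on pooled counts treats chromosomes as independent;
  per-specimen overdispersion is reported via the mean ± SEM summary but
  not modelled.
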
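---
title: "Calling subtelomeric copy-number losses and testing their case-control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling subtelomeric copy-number losses and testing their case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`subtelcnv` detects copy-number losses in three subtelomeric regions —
4p16.3, 16q24.2-3 and 22q13.31-33 on NCBI Build 36 — from two kinds of
array evidence, dichotomizes each subject × region into *copy number
loss* versus *unchanged copy number*, and tests case-control
association with exact statistics. This vignette is the package's
account of the underlying models, the tunable parameters and their
defaults, the numerical conventions, and the design decisions taken
where the problem was genuinely open. Nothing here asserts an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The two calling tracks

### Bead-array screen

Genome-wide CNV bead chips report one intensity per probe per subject
(two colour channels, combined here by summation). A single-copy
deletion halves the expected intensity; the caller works in four
stages:

1. **Normalization and GC correction.** Each subject is rescaled so its
   median intensity equals the cohort's common median; the GC trend is
   then removed per subject by regressing log2 intensity on a quadratic
   in probe GC fraction and keeping residuals plus the subject's grand
   mean. The chip vendor's own normalization equation is unpublished,
   so this stage is the package's documented substitute: median
   rescaling is scale-free and robust, and a quadratic captures the
   characteristic unimodal GC bias of array intensities.
   Median normalization presumes the subject is copy-neutral at most
   probes. That holds on a genome-wide chip, where CNV probes are a
   small fraction of the content, but *not* on a manifest truncated to
   the target regions: a subject whose deletions span most probes would
   be re-anchored onto the deleted level. Simulated beadchip manifests
   therefore carry copy-neutral background probes
   (`make_probe_manifest(background_probes = )`, pipeline default 150).
2. **Batch-effect removal by principal components**
   (`remove_batch_components()`). On the probe-centered log2 matrix the
   top *k* components across subjects are projected out. The default is
   `k_pcs = 0`: on a region-targeted manifest with common deletions the
   leading components *are* the deletion axes (per-probe deletion
   variance ≈ p(1−p)·1 log2² vastly exceeds typical batch variance), so
   removing them removes the signal. Raise *k* only for genome-scale
   matrices in which CNV probes are a negligible fraction — the
   situation the operation models, and the one its unit tests construct
   (a dominant batch axis, whose between-batch variance drops by >10×
   at k = 1).
3. **Per-probe Gaussian-mixture calling** (`fit_probe_mixture()`).
   For each probe, univariate Gaussian mixtures of order 1–3 are fitted
   across subjects by EM and the order is selected by BIC — chosen for
   its penalty against spurious components at cohort sizes near
   n = 200. Components are ordered by mean; the largest-weight
   component is anchored as the normal state, lower-mean components are
   losses, higher-mean gains. Initialization is deterministic (quantile
   splits at two offsets plus fixed-center k-means), so repeated fits
   are bit-identical without consuming random numbers. Variances are
   floored at 1e-4 of the probe variance to prevent singular
   components; zero-variance probes short-circuit to a single normal
   component.
4. **Consecutive-marker typing** (`call_segments()`). A maximal run of
   ≥ 2 adjacent probes sharing an aberrant state becomes one segment
   call; an isolated aberrant probe is noise and produces no call. Runs
   never merge across missing probes or chromosome boundaries. "More
   than one marker" is read strictly as ≥ 2. A region is then labelled
   loss for a subject when a loss call overlaps it by ≥ 2 of its
   supporting probes — the same threshold applied at region scope, so a
   single-probe incursion is never enough.

### Tiling-aCGH validation

Array-CGH compares test against reference DNA; log2(test/reference) is
≈ 0 at two copies and ≈ log2(1/2) = −1 in a heterozygous deletion.
The segmenter:

* smooths each track with a centered moving average
  (`moving_average()`, default window 11 probes, truncated at track and
  chromosome ends, missing-aware);
* builds a reference envelope from a panel of normal individuals
  (`build_reference_envelope()`): per-probe **median** center with
  per-probe **SD** scale. The field describes this band both as
  "mean ± 1 SD" and as "1 SD from the median"; the robust median center
  is the default (a config switch restores mean-centering) because it
  tolerates occasional loss carriers inside the panel — relevant here,
  since the pipeline uses the control group as the panel and controls
  do carry losses at low prevalence. Scale is per-probe rather than
  pooled (tiling probes have heterogeneous variance; `scale = "pooled"`
  is available) and floored at `sd_floor = 0.05` log2 units so an
  over-consistent panel cannot produce a zero-width band;
* classifies each smoothed value: **loss** iff value < center − 1·SD,
  strictly — an exactly-threshold value is unchanged, resolving
  floating-point ties conservatively toward no-call. Upward deviations
  are unchanged: the two-class scheme has no gain label, matching
  populations in which no gain was observed. Whether the 1-SD rule
  applies to raw or smoothed ratios is ambiguous in the field's usage;
  the default applies it to smoothed values (`classify_smoothed =
  FALSE` switches), while the envelope itself is always estimated from
  *unsmoothed* panel tracks — otherwise the band would shrink with the
  window and smoothing would buy nothing. On pure noise the raw
  per-probe loss rate is Φ(−1) ≈ 15.9% by construction; an 11-probe
  moving average drives it to ≈ Φ(−√11) before the ≥ 2-consecutive rule
  removes nearly all remainder, which is how the window default was
  chosen (small enough to resolve sub-region deletions, large enough to
  suppress the null exceedance);
* extracts maximal runs of ≥ `min_probes = 2` consecutive loss labels
  as segments (never merged across coverage gaps), harmonized with the
  beadchip stretch rule.

`concordance()` reports, per region and overall, the fraction of
bead-screen losses whose aCGH status is also loss — confirmatory
re-testing of screen positives.

## Association statistics

`fisher_exact_two_sided()` enumerates the hypergeometric distribution
over all 2×2 tables with the observed margins and sums the
probabilities of tables no more probable than the observed one — the
dominant minimum-likelihood two-sided convention, with a 1e-7 relative
tolerance on ties. `odds_ratio_ci()` uses the Woolf log-OR normal
interval; reverse-engineering printed intervals of this study type
shows that convention reproduces them exactly at one decimal, so it is
the fixed default. A zero cell triggers the Haldane–Anscombe +0.5
correction and sets an explicit flag — never silently.
`chi_square_test()` wraps `stats::chisq.test` with Yates correction for
2×2 (the convention that matches printed cohort-characteristic P
values; the uncorrected variant is a switch). Continuous clinical
characteristics are compared with Welch's t — a chi-square on means is
not defined, so the package deliberately substitutes the standard
two-sample location test for those variables. No multiple-testing
correction is applied by default (three regions tested marginally).
`ngsp_from_jds()` converts HbA1c from the JDS to the NGSP scale
(+0.4%).

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per subject and region, a Bernoulli loss
flag at the group prevalence, then a deletion with extent uniform in
50–90% of the region length and uniform start — uniform because
observed per-subject extents vary without a reported distribution, so
the least-assumption choice is used. Default prevalences follow the
observed per-region counts: cases 15% (16q24.2-3) and 22%
(22q13.31-33), controls 3% and 6%. The 4p16.3 prevalences (16% / 2%)
and its coordinates (chr4:1–1,300,000, honouring the 1.3-Mb span) were
never published at this resolution; both are explicit placeholders, and
the coordinate default is configuration-overridable
(`builtin_regions(region_4p = )`). Regions are drawn independently —
the real joint structure (11/100 cases with all three losses, 0/100
controls) is only known in aggregate, so per-subject joint truth is not
recoverable and only marginal statistics are checked end to end.

Signals: log2 tracks are truth signal (0 / −1) plus independent
Gaussian noise, `probe_sd = 0.2` — a plausible aCGH magnitude, not a
published value (no per-probe noise was reported); gap probes are
emitted as missing rather than dropped, so segmenters must handle them.
Bead intensities scale with copy number (half at one copy), carry a
quadratic GC bias factor 1 + c₁·gc + c₂·gc² on the raw scale (default
c = (0.4, −0.4)), and per-batch offsets plus probe noise applied on the
log2 scale — multiplicative on the raw scale — keeping intensities
strictly positive and making the noise magnitude directly comparable
between platforms. Heterozygous loss is the only simulated aberration
(no gain was observed in the motivating populations; gain handling
exists in the callers but is untested against the generator). Not
simulated: linked-SNP B-allele frequencies, waviness/autocorrelated
noise, cell-line artifacts, segmental-duplication cross-hybridization.
Passing tests therefore show the pipeline recovers clean additive-noise
deletions, not that it is robust to every real-array pathology.

## Determinism and problem sizes

Every generator takes a seed and uses `withr::with_seed`, so fixed
config + seed reproduces results bit for bit and pipeline output files
carry a config-hash/seed header. The pipeline's master seed spawns
per-stage seeds (kept below 2³¹) so stages can be re-run standalone.
The test suite exercises the study profile at full size — 100 + 100
subjects, 40 beadchip probes per region plus 150 background probes, 150
tiling probes per region — across 20 seeds for recovery/concordance and
50 seeds for the stochastic odds-ratio reproduction, sizes chosen to
make sampling error small relative to the tolerances while keeping a
desk-scale run. Recovery is scored against simulation truth as
region-level sensitivity and false-positive rate, pooled over seeds.

## Known limitations

* The bead-array stage-4 "graphical constraints" of the original
  platform software are not publicly specified; the consecutive-marker
  reading implemented here is the minimal one consistent with the
  published description, and whether cluster calling should operate on
  probe windows rather than single probes is equally unspecified.
* The all-three-regions Fisher test on the printed counts
  ([[11, 89], [0, 100]]) gives 7.30×10⁻⁴ under the standard
  minimum-likelihood enumeration; the originally printed 7.00×10⁻⁴
  presumably reflects a different rounding or convention that is not
  recoverable, and the package does not force agreement.
* Printed P values for continuous cohort characteristics (e.g. BMI
  0.64 for 28.0±4.2 vs 25.2±3.2) are not reproducible under any
  standard two-sample test; the package reports Welch's t and makes no
  claim of matching them.
* No assembly liftover: all coordinates are Build 36, and real data
  must arrive on that assembly.
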
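---
title: "Methods: self-self-calibrated CNV calling and population CNVR catalogs"
author: "acghcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-self-calibrated CNV calling and population CNVR catalogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acghcnv)
```

# The measurement model

Array CGH hybridizes a test DNA against a common reference DNA on a genomic
tiling array and reports, per probe, the log2 ratio of the two signals. With
a diploid reference, a segment at copy number $c$ in the test sample has
expected log2 ratio $\log_2(c/2)$: $-1$ for a one-copy loss, $+0.585$ for a
one-copy gain, $0$ for the neutral state. A homozygous deletion would be
$-\infty$; real arrays saturate, so the package floors the expectation at
$-4$ (`expected_log2()`'s `floor` argument). All user-visible coordinates
are 1-based inclusive, matching the way genomic positions are printed in
catalogs; only BED exports are 0-based half-open, as that standard requires.
Interval sizes are reported as $(\mathrm{end}-\mathrm{start})/1000$ kb to
0.1 kb, the convention used when a region's size is quoted next to its
printed coordinates.

A CNV call in one sample is a contiguous run of probes departing from 0; a
CNV region (CNVR) is the transitive union across samples of CNVs that
overlap by at least one base pair. The pipeline is: simulate or read
profiles → normalize → calibrate the calling threshold on self-self arrays
→ call per sample → deduplicate identical calls → merge to CNVRs →
classify by line → summary statistics, clustering, external-set overlap.

# The synthetic cohort generator

`simulate_cohort()` emulates a two-colour oligonucleotide CGH experiment on
a 244K-style design: probes tile each chromosome at a 4 kb median spacing
(`build_probe_map()`, optional uniform positional jitter), and each sample's
profile is the dosage expectation plus i.i.d. Gaussian probe noise. The
cohort is structured into lines (breeds or experimental populations):
each line carries *fixed* CNVs present in every sample, *shared* segregating
CNVs carried with probability `shared_cnv_rate` per sample, and *private*
CNVs unique to single animals. `default_lines()` reproduces a 15-line,
64-animal diversity panel (Red Jungle Fowl, experimental layer lines,
commercial broiler and layer lines, Silkie) with per-line sample counts of
4, 5, 5, 5, 5, 5, 5, 2, 3, 4, 8, 4, 4, 2 and 3.

Choices a user should know about:

* **Noise.** Per-probe noise SD defaults to 0.10 log2 units, a mid-range
  value for good-quality two-colour genomic hybridizations; it is a
  scenario parameter, not a measured constant. An optional AR(1) component
  (`wave_ar1`, off by default) produces the long-range "waves" real arrays
  show, for robustness experiments.
* **Copy-number palette.** Random CNVs draw copy numbers 0, 1, 3, 4 with
  weights 0.15, 0.60, 0.20, 0.05 — i.e. 75% losses — mirroring the
  loss-dominated composition that diversity-panel aCGH catalogs report.
  Sizes are uniform between 3 and 20 probes by default.
* **Shared/private template counts.** A line's segregating pool holds
  `n_shared_templates` (default 8) candidate CNVs; each sample carries each
  with probability `shared_cnv_rate`. Private CNVs arise per sample as
  Binomial(`n_private_templates`, `private_cnv_rate`) draws at random
  positions.
* **Dye bias.** Each array can receive a smooth per-array trend in a
  per-probe intensity-proxy covariate (quadratic in the standardized
  covariate, amplitude `dye_bias_amplitude`), the signature that
  normalization must remove.
* **Sex chromosomes.** The reference is matched-sex by default, so W
  probes are pure noise for both sexes; a `sex_mismatched_reference` flag
  instead saturates W in female-vs-male comparisons at +4. Z dosage is
  expressed through explicit copy-number templates, which reproduces
  Z-linked segregation patterns (3, 1 and 2 copies across a cross).
* **Collisions.** Random templates that would overlap an earlier template
  of the same sample at a different copy number are dropped; conflicting
  *user-supplied* fixed templates are an error, since they describe an
  impossible genotype.

What the generator does **not** emulate: raw two-channel intensities,
spatial array artifacts, probe GC/sequence effects, segmental-duplication
hotspots, or linkage between lines' CNV repertoires. Tests passing on this
generator therefore demonstrate the pipeline's statistical behaviour under
its stated noise model, not performance on any particular real array batch.

# Normalization

`normalize_profile()` removes the smooth covariate trend and median-centres
the profile. The trend (`fit_trend()`) is a B-spline regression of log2
values on the covariate, fitted by Tukey-bisquare M-estimation
(`MASS::rlm`), with roughly `3/span` degrees of freedom so the `span`
parameter behaves like a loess span (default 0.3 ≈ 10 df). Two properties
drove this design:

* **Robustness.** CNV-bearing probes can cover a few percent of the genome;
  the bisquare weights prevent them from bending the trend, so implanted
  CNV contrast is preserved (the suite checks within 10% for CNVs covering
  < 1% of probes).
* **Idempotence.** A weighted least-squares spline fit is a projection, so
  detrending is numerically idempotent. `normalize_profile()` iterates
  fit-and-subtract until the fitted trend is negligible (RMS < 1e-9, cap 20
  iterations; in practice 2–3), after which re-normalizing a normalized
  profile changes it by well under 1e-6 RMS.

Median centring is genome-wide. Per-chromosome centring is applied only to
Z and W and only on request (`per_chromosome_center`): centring autosomes
individually would erase genuine whole-chromosome dosage, while a
sex-mismatch shift on Z/W is usually a nuisance signal. A constant
covariate yields a constant (median) trend; up to 20% non-finite probes are
imputed to the trend (residual 0), more is an error.

# Noise estimation and threshold calibration

The per-array noise SD is estimated from successive probe differences:
$\hat\sigma_e = \mathrm{median}(|x_{i+1}-x_i|)/(0.6745\sqrt2)$. A CNV
shifts a *run* of probes together and so contributes only two large
differences at its boundaries, which the median ignores; the estimate
stays within a few percent of truth with 5% of probes inside CNV blocks,
where the plain sample SD fails.

Calling thresholds are expressed as a multiple $t$ of $\hat\sigma_e$ and
calibrated *empirically* on self-self hybridizations — arrays where the
reference is hybridized against itself, so every call is by construction a
false positive. `calibrate_threshold()` evaluates an ascending grid
(default 2.0–6.0 by 0.5) and returns the smallest $t$ whose mean number of
self-self calls per array is at or below the target (default 1.0); if no
grid value qualifies, the largest is returned with a warning flag rather
than an error, so a pipeline run fails loudly in its report, not silently.
The false-call property is re-verified by re-running the calibrated
threshold over the replicate arrays.

# Segmentation

`call_segments()` implements threshold-run segmentation: maximal runs of
probes above $+t\hat\sigma_e$ (gain) or below $-t\hat\sigma_e$ (loss).
Parameters and their rationale:

* `min_probes = 2`: a call must span at least two probes. On a 4 kb grid
  this makes events below the probe spacing (e.g. a 3.2 kb CNV, which can
  cover at most one probe) structurally undetectable — the expected
  behaviour for such arrays — while keeping ~9 kb events callable.
* `max_gap_probes = 1`: same-sign runs separated by at most one
  sub-threshold probe merge, absorbing single probe dropouts. Runs of
  opposite sign never bridge a merge. With this default a merged run always
  contains more supra-threshold than gap probes, so the mean log2 of a call
  always matches its gain/loss label.
* Call boundaries are the first probe's start and the last probe's end —
  no half-spacing extension — so size statistics are conservative and
  reproducible from the probe map alone.
* Degenerate case: a constant-zero profile has $\hat\sigma_e=0$ and yields
  no calls; a zero-noise profile with real shifts also has
  $\hat\sigma_e=0$, and then every non-zero run is called (with a warning).
  This keeps noise-free simulations exact instead of erroring.

Identical calls (same chromosome, start, end and class) across samples are
one CNV; `collate_calls()` counts carriers overall and per line. A gain and
a loss over the same interval are distinct CNVs.

# CNVR construction and catalog statistics

`merge_to_cnvrs()` takes the transitive union of CNVs overlapping by ≥ 1 bp
(no reciprocal-overlap fraction), ignoring class for the region extent;
region type is "gain", "loss" or "both" according to its members. Region
extents clip to member extremes rather than extending to probe boundaries.
`catalog_stats()` reports CNV/CNVR counts, mean sizes (all and recurrent,
i.e. occurrence ≥ 2), genome coverage (the genome length is a configuration
value, by default the probe map's chromosome total, because assembly
lengths are not derivable from a probe design), loss percentage, and mean
calls per animal per line. `annotate_genes()` assigns genes to regions by
≥ 1 bp overlap, complete or partial, deduplicating across regions.

# Line classification and clustering

Carrier status is region-level: a sample carries a CNVR if any of its calls
overlaps the region, whichever class — members of one region commonly
differ in extent across samples. A region is **fixed** in a line when every
sampled animal of that line carries it, and **line-specific** when it is
fixed in exactly one line and nobody outside that line carries it. The
strict outside-carrier condition is the default because "specific" is read
literally; a lenient mode (fixed in exactly one line, sporadic outside
carriers allowed) is available behind a flag, as the operational rule could
reasonably be defined either way. When a sample holds both classes in a
region, the class of the largest-overlap call wins in the state matrix.

`cluster_samples()` performs hierarchical clustering of the sample × CNVR
state matrix — Jaccard distance on carrier status (default; two samples
sharing no regions are at distance 1) or Hamming distance on the
three-level states — with average (default) or complete linkage. Samples
are ordered lexicographically before clustering so ties break
deterministically. Trees export to Newick via `ape`.

# Comparative overlap and qPCR quantification

`overlap_fraction()` reports how many intervals of an external CNV set hit
any CNVR by ≥ `min_overlap_bp` (default 1). Chromosome names are
harmonized across "2" / "chr2" / "GGA2" spellings plus a user alias table;
when the probe-design chromosome set is supplied, external intervals on
chromosomes outside it are excluded from the denominator and reported
(an interval on a chromosome the array never tiled is unknowable, not
absent). Note the fraction is monotone non-increasing in `min_overlap_bp`.

For qPCR validation, `normalize_ct()` applies
$C_t + (N_t' - C_t')\,S/S'$ — the standard-plot interpolation that puts all
samples at the same effective reference-gene input — and
`relative_copy_ratio()` applies the standard $\Delta\Delta C_t$ method with
perfect (base-2) efficiency: ratio $2^{-\Delta\Delta C_t}$ against the
calibrator sample and estimated copies $2\times$ ratio, rounded with the
unrounded value retained. Slope-based efficiency correction is available
through `standard_curve()` but off by default. Replicate Ct values are
averaged before any ratio.

# Problem sizes and numerical choices

The test-suite and acceptance scenarios use desk-scale versions of the
study design: probe maps of 500–50,000 probes at 4 kb spacing, cohorts of
15–64 samples, 3–6 self-self replicates, and 100+ implanted CNVs per
recovery experiment. These sizes were chosen so that every property
(sensitivity ≥ 95% at |log2| = 1 with ≥ 3 probes, false calls per
self-self array at or below target, exact line recovery by clustering) is
measured on hundreds of events while a full run completes in minutes.
Determinism is enforced by threading a single integer seed through every
random stage (the RNG state is saved and restored, so library calls do not
perturb user code).

# Known limitations

* Threshold-run calling has no likelihood model; CNVs with |log2| well
  below $t\hat\sigma_e$ (e.g. mosaic or single-copy gains under heavy
  noise) are missed rather than down-weighted. HMM or CBS segmentation is
  out of scope.
* Exact-coordinate CNV deduplication is strict: one probe of difference
  creates a new CNV record. This matches catalog conventions built on
  identical call boundaries but inflates CNV counts relative to
  reciprocal-overlap deduplication.
* The simulator's i.i.d. noise makes calibration slightly optimistic
  compared with wave-affected real arrays; the AR(1) option exists to
  quantify that gap.
* Cross-species coordinate liftover is not performed; external CNV sets
  must already be on the catalog's assembly.
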
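---
title: "Topological marker and group discovery for GC × GC–MS profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological marker and group discovery for GC × GC–MS profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectramapper)
```

## The problem

A comprehensive two-dimensional GC × GC run coupled to a high-resolution
time-of-flight mass spectrometer produces, for every sample, hundreds of
thousands of mass spectra indexed by two retention times. Untargeted
comparison of such samples — which spectra are specific to one sample,
and which samples resemble each other — is intractable vector-by-vector.
This package condenses each sample to a small set of *representative*
spectral vectors via a Ball Mapper cover, screens them for *relative
uniqueness* against the other samples, and mines *representative groups*
of samples from an ensemble of randomized coarse covers, scored for
stability by a row bootstrap.

## Vectorisation model and its assumptions

Every spectrum is binned to integer m/z bins (bin *n* covers
[*n* − ½, *n* + ½); a peak at exactly *n* + ½ belongs to bin *n* + 1) by
the **per-bin maximum**, which keeps the most prominent feature per bin,
and the binned vector is divided by its Euclidean norm. Normalisation
makes the representation invariant to the total signal: scaling all
intensities of a sample by any positive constant leaves every downstream
output unchanged (this is asserted end-to-end in the test suite). The
cost is that absolute abundance is discarded by design; two samples
differing only in concentration are identical here.

No baseline or blank subtraction is applied; background is mitigated by
max-bin discretisation, the unit-norm projection, and exclusion of
retention windows outside the region of interest. Spectra that bin to the
all-zero vector have no direction and are dropped, with the count
reported in the sample's matrix and in the run manifest.

Retention coordinates serve only to order spectra (lexicographically in
(t_R1, t_R2)) and to exclude acquisition margins; the geometry lives
entirely in spectral space.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| ε | ball radius for representative vectors (unitless, on S^(d−1)) | 0.08 | replicate calibration: ~95 % of technical replicate distances fall below it |
| r | separation ratio | 0.3 | yields δ = 0.024 and satisfies 3δ < ε < 4δ |
| δ = rε | marker buffer | 0.024 | neighbours within δ of a marker stay ≥ δ from other samples when the marker is > 3δ away |
| γ | coarse view radius | 3ε = 0.24 | merges similar markers across samples without overfragmentation |
| S | randomized views | 1000 | published setting; reducible for desk-scale runs |
| B | bootstrap resamples per view | 1000 | published setting |
| Q range | candidate cluster numbers | 2…15 | clipped to ≤ K when K is small |
| ARI threshold | stability cut-off | 0.5 | views at or above it count into P(Q) |
| min φ | group reporting floor | 50 | the inclusion rule for reported groups is a convention, exposed as a flag |

The constructor `separation_params()` rejects any (ε, r) outside
3δ < ε < 4δ: below, a marker's within-δ neighbourhood is not protected;
above, the coverage radius outruns the uniqueness screen.

`calibrate_resolution()` estimates ε from replicate runs as the lower
(type-1) empirical quantile, at the configured coverage, of Euclidean
distances between retention-matched normalised spectra. Replicates are
paired by identical retention coordinates; when grids differ, a
nearest-coordinate fallback within half a modulation period is available
and announced. The pairing rule is a package decision — reproducibility
studies rarely state one — and the strict-grid default is the most
conservative choice.

## Order dependence as a feature

The greedy ε-net is order-dependent: visiting points in a different order
yields a different, equally valid net. For per-sample summaries the
native acquisition order is used, making results deterministic. For group
discovery the ambiguity is exploited: each of the S views shuffles the
pooled markers with a seeded permutation (`base_seed + s`) before the
greedy pass, so the ensemble explores many legitimate covers of the same
cloud. Balls are open (strict `<`) for both covering and node membership;
a point at distance exactly ε from every landmark is uncovered by
definition and is promoted to a landmark itself, so coverage always
holds.

## Stability scoring choices

The frequency matrix entry (k, l) is the share of sample k's markers
inside node l's ball, normalised by the sample's marker count; rows are
in [0, 1] and comparable across samples of different marker richness.
A marker in two overlapping balls counts in both columns. Samples with no
markers yield an all-zero row, are flagged, and — having no cosine
direction — are placed in singleton clusters during row clustering.

Rows are clustered by average-linkage agglomeration under cosine
dissimilarity (the dissimilarity is the published choice; the linkage is
ours — average linkage is the common default for such profiles and avoids
single-linkage chaining). Bootstrap stability for a view and Q is the
mean ARI between the reference labels and the labels of each of B row
resamples, compared on the distinct samples present in the resample
(duplicated rows enter the clustering once per draw but contribute one
label); resamples with fewer than two distinct samples are skipped.
Within a view one set of resamples is shared across all Q — each
resample's tree is cut at every Q — which is statistically identical to
independent per-Q resampling and substantially faster. Q* takes the
smallest Q attaining the maximum of P(Q) (parsimony tie-break).

Two honest caveats, both visible in the tests. First, the bootstrap
stability of pure-noise matrices is *not* centred at zero: the reference
partition and every replicate cluster the same rows, so the score keeps a
positive baseline (≈ 0.3–0.6 in our measurements). P(Q) should therefore
be read comparatively across Q, not as a significance level. Second, the
"locality" property of markers — that a marker's within-δ neighbours also
stay > δ from all other samples' spectra — is *not* a theorem in the
regime 3δ < ε < 4δ, because the uniqueness screen sees only the other
samples' representative vectors, whose balls can hide spectra up to ε
away. `verify_locality()` therefore checks it empirically and reports
violating triples; the test suite contains a construction where exactly
one hidden violation exists and is found.

## The synthetic generator

The generator emulates the regime the method presumes: samples share most
of their spectral mass (background templates common to all), own a few
genuinely sample-specific templates, and belong to planted groups whose
members carry near-identical group templates. Templates are sparse
nonnegative vectors on disjoint m/z supports, so any two different
templates sit at distance √2 after normalisation — far beyond every
threshold in play. Planted group structure needs finer control: each
member of a group receives a *variant* of the group template rotated
toward a sample-specific axis so that two members' variants sit at
distance 0.15 — above 5δ = 0.12 (each variant passes the 3δ uniqueness
screen with a noise margin) yet below γ = 0.24 (the variants co-occupy
nodes of the coarse views, which is what lets the group be discovered).
Spectra are `scale × (template + truncated-Gaussian noise)` with the
scale drawn per spectrum, so normalisation removes it exactly; noise
defaults to sd 0.2 counts against a template intensity of 100, i.e. a
normalised perturbation of about δ. Synthetic retention coordinates form
a regular grid and carry no signal.

What passing these tests shows: the pipeline recovers planted structure
whose geometry respects its own separation assumptions. What it does not
show: robustness to chromatographic reality — co-elution, retention
drift, peak tailing, mass-calibration error — none of which the generator
simulates.

## Problem sizes and numerical choices

The validation studies use K = 8 samples × 400 spectra on a 120-bin grid
with S = 100 views and B = 100 resamples, twenty seeded repetitions — a
deliberate desk-scale setting of the published configuration (S = B =
1000, d = 572, ~470 000 spectra per sample) chosen so the full suite runs
in minutes; all sizes are plain function arguments. Distances are plain
double-precision Euclidean; the uniqueness rule is strictly `> 3δ` (a tie
at exactly 3δ is excluded); quantiles are lower order statistics; all
randomness flows from a single base seed through derived per-view and
per-bootstrap streams, so reruns are byte-identical.

## Worked run

```{r example, eval = FALSE}
ds <- generate_dataset(synth_config(K = 8, n_spectra = 400,
                                    bins = bin_range(29, 148), seed = 42))
cfg <- pipeline_config(n_views = 100, n_bootstrap = 100, seed = 7)
res <- run_pipeline(ds$samples, cfg, metadata = ds$metadata)
res$summary
autoplot(res$scan)
plot_group_composition(res$groups, ds$metadata, by = "country")
evaluate_recovery(res$rums, ds$truth)
```

## Known limitations

- No peak picking, deconvolution, alignment or baseline modelling; the
  method assumes binning plus normalisation suffice to make spectra
  comparable across runs.
- mzML ingestion is not implemented; input is the long point-table format
  (CSV/Parquet).
- The group-inclusion floor `min_phi` and the ARI aggregation (mean over
  resamples) are conventions, exposed as arguments rather than inferred.
- Reported stability is resampling reproducibility, not a hypothesis
  test; no significance is attached to group membership.
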
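---
title: "Quantifying liver histology with hepaquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying liver histology with hepaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaquant)
```

# Scope

`hepaquant` is an open pipeline for semi-automated scoring of liver-biopsy
field-of-view (FOV) images of the kind produced by a 20x slide scanner:
IHC sections (DAB chromogen over a haematoxylin counterstain), H&E,
Sirius Red, and 3-channel double-label immunofluorescence. Its outputs are
the quantities liver researchers usually extract by hand: the number of
marker-positive cells as a percentage of total cells, the ductal vs
non-ductal character of the positive population, the areas of necrosis,
steatotic fat and collagen deposition, counts of inflammatory foci, and an
additive necroinflammatory composite score in the style of the
Ishak-Knodell hepatic activity index (HAI).

Because no patient images ship with the package, every stage is validated
against a synthetic-histology generator that renders FOVs with complete
ground truth. This vignette explains the models, the tunable parameters and
their defaults, what the generator does and does not emulate, and the
design decisions taken where the problem was genuinely open.

# Optical density and colour deconvolution

All brightfield classification in the pipeline keys on stain optical
density (OD). For transmitted light of incident intensity $I_0$ and
observed intensity $I$, per RGB channel,

$$\mathrm{OD} = -\log_{10}\!\bigl(\max(I, \varepsilon)/I_0\bigr),$$

with $\varepsilon = I_0/255$ so that a saturated 8-bit pixel maps to the
finite maximum $\log_{10} 255 \approx 2.41$ rather than infinity. ODs of
co-localised stains add (Beer-Lambert), so a pixel's 3-channel OD vector is
a non-negative linear combination of unit-norm per-stain absorbance
vectors. `deconvolveStains()` solves this linear system per pixel with the
Moore-Penrose pseudo-inverse of the stain matrix — an exact inverse for
three stains, least squares for the common two-stain systems
(haematoxylin/DAB, haematoxylin/eosin, Sirius Red with a haematoxylin
counterstain) — and clips negative solutions to zero. Stain matrices with
condition number above $10^6$ are rejected as degenerate.

Default absorbance vectors are the published Ruifrok–Johnston values for
haematoxylin, eosin and DAB; the Sirius Red vector was estimated once from
a synthetic pure-stain swatch. Commercial phenotyping software trains its
spectral unmixing interactively per project and does not publish vectors,
so all vectors here are explicit data, overridable through a plain-text
config (`readStainConfig()`): one `name r g b` line per stain.

# Nuclei segmentation and per-cell measurement

Nuclei are segmented from the haematoxylin OD map (brightfield) or the
DAPI channel (fluorescence): Gaussian smoothing (1 px), Otsu threshold on
the image histogram (a fixed threshold can be supplied instead), hole
filling, removal of objects below the minimum nucleus area, and splitting
of touching nuclei by distance-transform watershed. The pipeline is
deterministic for a fixed input and parameter set.

Key parameters:

* `minAreaUm2 = 10` µm² — objects smaller than this are debris at 20x;
  a lymphocyte nucleus is ~20 µm², a hepatocyte nucleus ~40 µm².
* `minThreshold = 0.12` OD — a floor under the data-driven threshold. On a
  blank or near-blank FOV Otsu would otherwise cut into sensor noise and
  segment specks; no real nucleus is dimmer than this.
* `ringRadiusPx = 3` — cytoplasmic sampling ring: the nucleus mask dilated
  by 3 px, clipped at neighbouring cells by nearest-nucleus assignment.
  This approximates the cytoplasm compartment that per-cell phenotyping
  software samples around each nucleus.
* Nuclear means are measured over the mask eroded by 1 px (falling back to
  the full mask for the smallest nuclei). This guards the mean against
  partial-volume dimming at the blurred nucleus boundary; without it,
  nuclear OD is systematically underestimated by roughly 0.04 OD.

Each cell record carries its centroid (0-based pixel coordinates,
pixel-centre convention), nucleus area in both px and µm², and
nucleus/ring means of every deconvolved stain (`od_*`) or normalised
fluorescence channel (`int_*`).

# Phenotyping

**Marker positivity.** A cell is positive when one feature — by default the
cytoplasmic (ring) DAB OD — exceeds a threshold, and the FOV summary is the
number of positive cells as a percentage of total cells, the robust
counting contract for IHC quantification. Thresholds come in three modes:
`fixed`, `otsu` (per-FOV Otsu on the feature distribution) and `gmm2` (a
two-component 1-D Gaussian mixture fitted by EM, cut at the midpoint of the
component means). The data-driven modes are protected by a
coefficient-of-variation guard (default 0.2): on an effectively unimodal
distribution — an all-negative or all-positive FOV — a data-driven cut is
undefined, and the rule falls back to its fixed threshold. This mirrors
practice with interactively trained commercial algorithms, where a
threshold is trained once on representative fields and then applied in
batch.

**Double immunofluorescence.** Channel intensities are normalised per
channel to [0, 1] by the 99.9th percentile (making thresholds
exposure-invariant), but only when a real signal is present (99.9th
percentile > 0.2) — normalising a blank channel would amplify noise to
full scale. The green and red rules are applied independently and each
cell gets one of four labels (`green`, `red`, `double`, `negative`);
double positives are counted in neither single-positive tally, so the
four counts partition the total.

**Ductal vs non-ductal discrimination.** Ductal marker-positive cells
differ from non-ductal presumptive hepatic progenitor cells in nucleus
area, nuclear haematoxylin OD and cytoplasmic DAB OD. The package models
the joint rule as a Fisher linear discriminant on those three features:
$w = S_w^{-1}(\mu_d - \mu_n)$ with the pooled within-class covariance
$S_w$, boundary at the midpoint of the projected class means, oriented so
ductal scores positive. A linear discriminant is the minimal joint model
consistent with three marginally discriminative features, and it is
deterministic and serialisable (JSON: features, weights, intercept, class
means). Training requires at least five exemplars per class. A whole FOV
is labelled `portal-like` when the majority of its positive cells score
ductal (ties towards portal-like, since the claim is about predominance)
and `central-like` otherwise; an FOV with no positive cells returns the
explicit sentinel `undetermined`.

# Region detection

**Tissue.** Pixels whose summed RGB OD exceeds 0.12 are tissue; the mask is
despeckled (3 px opening), closed (5 px radius) and its enclosed holes
filled, so unstained structures inside the section — vacuoles, pale
necrotic zones, sinusoids — remain tissue rather than being mistaken for
glass. A pale feature *touching the FOV border* is genuinely ambiguous
with glass and is not recovered; the synthetic generator therefore keeps
such features clear of the border, and on real data FOVs should be
extracted so that features of interest are interior.

**Necrosis and fat.** Both present as low haematoxylin OD relative to
intact parenchyma. Candidates are tissue pixels below a threshold (default
fixed at 0.08 OD, between pale necrosis and the ~0.15 OD counterstained
parenchyma), from a smoothed OD map, opened (2 px) to stabilise boundary
shape, and min-area filtered (50 µm²). Otsu mode exists but is *not* the
default here: within tissue the haematoxylin histogram is already
multi-modal (nuclei vs parenchyma), so Otsu finds the wrong valley; it is
guarded by a unimodality check that returns an empty mask on homogeneous
images. Candidates are then split by shape: connected components with
circularity $4\pi A / P^2 \ge 0.7$ and equivalent diameter 5–100 µm are
steatotic vacuoles (fat); everything else — irregular or larger than any
vacuole — is confluent necrosis. The two masks are disjoint by
construction. The split is a geometric rule because cohort context (NAFLD
vs hepatitis) is not available to an image-only pipeline; both thresholds
are configurable.

**Collagen.** Sirius Red OD above 0.3 within tissue, min-area filtered;
reported as an area fraction of tissue.

**Inflammatory foci.** CD45-positive cells are clustered by single linkage
on centroid distance (default linking distance 30 µm); clusters with at
least `minFocusSize = 5` members are foci, the rest are single
inflammatory cells. Single linkage was chosen over density-based clustering
because it is order-independent and admits an exact brute-force oracle
(connected components of the pairwise-distance graph), which the test suite
exercises.

**Processing regions.** Portal regions are supplied as annotation masks
(the analogue of a pathologist marking portal tracts). The periportal band
— the limiting-plate zone where interface hepatitis (piecemeal necrosis)
is scored — is the morphological dilation of the portal mask by the band
width (default 25 µm) minus the portal mask, clipped to tissue. The
lobular region is tissue minus portal minus band.

# Surrogate necroinflammatory scoring

Four continuous surrogate measures stand in for the descriptive
Ishak-Knodell categories:

| category  | surrogate measure                          | ordinal range |
|-----------|--------------------------------------------|---------------|
| piecemeal | CD45⁺ cells / mm² of periportal band       | 0–4           |
| confluent | necrotic fraction of tissue                | 0–6           |
| lobular   | inflammatory foci / mm² of lobular tissue  | 0–4           |
| portal    | CD45⁺ cells / mm² of portal regions        | 0–4           |

A density is zero when its region is empty. Each measure is binned to an
ordinal score as the number of its category's thresholds *strictly below*
the measure — a measure exactly on a boundary takes the lower bin
(conservative scoring) — and the composite is the exact integer sum of the
four ordinals (0–18), the analogue of summing category values into the
HAI. The ordinal ranges follow the Ishak grading scheme; the boundary
values themselves are not published for any comparable system, so they are
shipped as explicit configuration (`inst/extdata/binning.yaml`), calibrated
once against the design ranges of the synthetic severity ladder (CD45
densities 0–1000 /mm², necrotic fractions 0–0.3, focus densities 0–20
/mm²) and never adjusted afterwards. Users scoring real cohorts are
expected to recalibrate the binning against a pathologist-scored subset.

Samples aggregate their FOVs by tissue-area-weighted mean of each measure
before binning — a plain mean for the usual equal-size FOV crops, but
correct when tissue cover varies. Ordinal summation (rather than summing
raw measures) was chosen for comparability with the HAI, whose categories
are summed on their ordinal scales. The Ishak-Knodell description names
five grading categories but enumerates four; the four enumerated ones are
implemented, and fibrosis staging is deliberately out of scope (it is a
separate staging category, not part of the necroinflammatory grade).

# The synthetic-histology generator

`generateBrightfield()` and `generateIf()` render 20x FOVs (default
0.5 µm/px) with complete ground truth recorded before rendering:

* **Nuclei** are placed by a hard-core (minimum-distance) point process,
  default spacing 9 µm, by dart throwing with bounded retries — an
  infeasible packing raises a generation error. The hard-core prevents
  unrealistically merged nuclei from confounding segmentation validation.
* **Populations** with per-cell Gaussian feature draws (sd 10% of the
  mean): hepatocytes (38 µm² nuclei, haematoxylin OD 0.55, DAB 0.10),
  non-ductal presumptive HPCs (25 µm², 0.40, 0.60), ductal cells (60 µm²,
  0.80, 0.70) ringing portal-tract discs, and CD45⁺ leukocytes (20 µm²,
  0.50, 0.70) as scattered singles plus clustered foci. The ductal/HPC
  feature directions (larger nuclei, denser haematoxylin, stronger DAB in
  ductal cells) reproduce the contrasts reported for ductular reactions.
* **Features**: round white vacuoles (fat), elongated low-haematoxylin
  patch chains (necrosis; split into several patches when the burden is
  large so each zone fits inside the FOV), Sirius-Red ribbons (collagen),
  portal tracts with denser stroma.
* **Rendering**: per-stain OD maps composed through the stain matrix,
  mild Gaussian blur (1 px) and per-pixel Gaussian OD noise (sd 0.02) —
  minimal realism without modelling scanner optics — then inverse
  Beer-Lambert to 8-bit RGB.
* **Severity** is an integer that jointly scales CD45 density, focus rate
  and necrosis fraction; `severityLadder()` produces an 11-level gradient
  (severity 0–10) with per-level seeds derived deterministically from a
  base seed. The ladder base scene uses 100 CD45/mm², 2 foci/mm² and 3%
  necrosis per severity unit.

All randomness flows through one explicit integer seed; identical spec and
seed reproduce identical truth tables and identical pixels, and generation
restores the caller's RNG state.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: tissue-fixation and sectioning artefacts,
stain-batch variability and uneven illumination, nuclear texture and
chromatin patterns, overlapping nuclei in thick sections, vessel and duct
lumina, and zonation. Validation against the generator demonstrates that
the algorithms recover what they are defined to recover under controlled
conditions; calibration on real cohorts remains the user's responsibility.

# Validation designs and problem sizes

The package re-runs the validation *designs* of the workflow it
reimplements, with generator ground truth in place of the human counter:

* Stain round trip: 10 random two-stain scenes; concentration recovery to
  better than $10^{-6}$.
* Count recovery: 15 IHC FOVs (384² px) spanning 0–60% positive fraction;
  r² between pipeline and truth percentages ≥ 0.92, detection precision
  and recall ≥ 0.95 at ~2000 nuclei/mm².
* Double IF: 12 FOVs (320² px) with varying green/red/double fractions;
  per-channel and double-positive r² ≥ 0.8.
* Ductal discrimination: 100 rendered-and-measured exemplars (the
  programmatic analogue of cropping single cells and re-analysing them),
  held-out single-cell accuracy ≥ 0.98; 16 portal-seeded and 16
  central-seeded FOVs, ≥ 30/32 labelled correctly.
* Regions: planted fat/necrosis (640² px) and collagen scenes; area
  recovery within 10%; focus detection identical to the brute-force
  linkage oracle on up to 200 cells.
* Scoring: 11-sample severity ladder (2 FOVs of 256² px per sample),
  20 replicates; Spearman correlation between planted severity and the
  composite ≥ 0.8.
* Determinism: byte-identical outputs for repeated runs at a fixed seed.

These sizes were chosen so the whole battery runs in minutes on one core
while keeping per-FOV cell counts (tens to a few hundred) in the range of
real 20x liver FOVs.

# Numerical choices and degenerate inputs

* OD floor $\varepsilon = I_0/255$; deconvolution negativity clipped at 0;
  stain matrices with condition number > $10^6$ rejected.
* Otsu is computed on a 256-bin histogram over the observed range; on a
  constant input it returns `NA` and the caller treats the image as empty.
* Blank images segment to zero cells (not an error); empty portal masks
  yield zero densities; an FOV list with inconsistent pixel sizes is a
  consistency error.
* Binning uses strict inequality at boundaries; threshold vectors must be
  strictly increasing (config error otherwise).
* Circularity estimates from digitised perimeters overshoot 1 for small
  discs; values are capped at 1.5 and the vacuole rule uses ≥ 0.7.

# Known limitations

* Equivalence to the proprietary software it emulates is functional, not
  numerical: that system's segmentation and trained thresholds are
  unpublished, so agreement is asserted against ground truth, not against
  its outputs.
* Portal regions come from annotations; automatic portal-tract inference
  (e.g. from ductal-cell clusters) is not implemented.
* Pale features touching the FOV border are not recovered (see tissue
  detection above).
* The default binning of surrogate measures is calibrated on synthetic
  severity, not on a patient cohort.
* Single-FOV whole-slide tiling, >2-marker multiplexing and fibrosis
  staging are out of scope.
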
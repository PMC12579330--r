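---
title: "Methods behind sporescope: calibrated morphometry, flow-cytometry genome sizing, and permutation statistics"
author: "sporescope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind sporescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporescope)
```

# Scope

`sporescope` bundles the quantitative methods used to characterize a
grass–endophyte symbiosis from laboratory data: automated measurement of
asexual reproductive structures (conidia and conidiophores) in calibrated
micrographs, genome-size and ploidy estimation from flow-cytometry
histograms, a permutation-statistics stack for nested morphometric
designs, and variability summaries of DNA multiple alignments. A seeded
synthetic-data module generates micrographs, fluorescence histograms and
nested trait tables with ground truth, so the whole pipeline is testable
without any instrument data.

# Micrograph morphometry

## Model and assumptions

Conidia are treated as approximately ellipsoidal objects photographed
against a lighter background at a fixed, known magnification. All outputs
are in micrometres via a single scalar calibration (default 15.8097
px/µm, the fixed photography scale for these cultures); pixel units never
leave the module.

Segmentation uses deliberately standard, reproducible operators: an
automatic Otsu global threshold on the dark-object polarity, hole
filling, 8-connected component labelling, exclusion of border-touching
regions, and an area gate in µm² (default 1–50 µm² for conidia). Each
region is summarized by its pixel count, centroid, moment-equivalent
ellipse (the ellipse with the same second central moments, including the
1/12 single-pixel variance term) and solidity (pixel area over
convex-hull area, with the hull taken over pixel corners so a filled
convex region scores 1).

## The sagittal gate

Only spores lying flat — so the full long-axis profile is visible — are
comparable across preparations. "Lying flat" is not directly observable
from a single grayscale frame, so the package operationalizes it as a
three-part geometric gate (`sagittalCriteria()`): solidity ≥ 0.90
(rejects touching/overlapping structures and budding clumps), aspect
ratio within 1.2–4.0 (rejects end-on, near-circular projections and
thread-like debris), and a fitted-ellipse residual ≤ 0.10 (the symmetric
difference between the region and its moment ellipse, as a fraction of
region area; rejects bent or composite shapes that happen to be solid and
elongated). The thresholds are configurable; the defaults were chosen
once so that a clean rasterized ellipse of typical conidium geometry
passes with a wide margin while merged pairs and near-circles fail, and
they are not tuned per dataset.

## Measurements

Length and width are the major and minor axes of the moment-equivalent
ellipse — a deterministic choice that matches ellipse-like spores better
than Feret diameters and is insensitive to boundary noise. Area is the
calibrated pixel count (`area_px / s²`), not the ellipse model area, so
irregular spores are measured as imaged; for a true ellipse the two
differ by the rasterization error only. Conidiophores (stalks) are
measured along the morphological skeleton: Zhang–Suen thinning reduces
the region to a 1-px-wide, topology-preserving skeleton, the stalk length
is the longest geodesic path between skeleton endpoints extended by the
local distance-map radius at both ends (so the measure spans the full
structure, not just the skeleton), and the base width is twice the mean
distance-map radius over the three skeleton pixels nearest the basal
endpoint, the basal end being the endpoint with the larger local width.
Elongation for the stalk precondition is skeleton length over mean width
(> 2), so bent stalks qualify while compact blobs are rejected. No
installed image library provides thinning, hence the in-package
implementation.

## Numerical behaviour and limits

On rasterized test ellipses the axis estimates are accurate to well under
1% and rotation-stable to < 3%; on a 15.8-px disc (a 1 µm circle at the
working scale) discretization bounds attainable accuracy at roughly the
1% level, which is why the identity-calibration checks use a 2%
tolerance, the same level the measurement contracts use elsewhere. The
area–calibration identity `area_um2 × s² = area_px` holds to floating
point exactly.

# Flow-cytometry genome sizing

## Peak model

Nuclei suspensions produce fluorescence histograms with one dominant
G1-type peak per co-processed organism. Each peak is modelled as a single
Gaussian: candidate maxima are located on a Savitzky–Golay-smoothed
histogram (window 11 bins, order 2), ranked by topographic prominence,
and retained only when their prominence reaches half their height — a
genuine isolated peak has prominence equal to its height, while ripples
on flat or sloping backgrounds fail. Retained candidates are refined by a
Gaussian least-squares fit within ±2×FWHM (with a moment-based fallback),
giving the fitted mean, the CV (100·sd/mean) and the integrated events
within ±3 sd. No doublet or S-phase modelling is attempted: the
downstream quantities only use G1 peak means and CVs. Both the fitted
mean (default) and the modal channel are available, since histograms
alone do not disambiguate which convention an instrument report used.

## Sizing, QC and ploidy

Genome size is the standard-ratio estimate
`pg = pg_standard × mean_sample / mean_standard` against a co-processed
internal standard. The registry carries the four working standards
(tomato 1.96 pg/2C, pea 9.09 pg/2C, rye 16.19 pg/2C, and the
*Colletotrichum acutatum* fungal standard at 0.069 pg/1C ≈ 68 Mb).
Measurements pass QC when both peaks hold ≥ 5000 events and both CVs are
at or below the kingdom ceiling — 3% for plant nuclei, 10% for fungal
nuclei, following community practice for each material. Both gates are
inclusive at the boundary and monotone in the policy parameters.

The pg↔Mb conversion uses 978 Mb/pg (configurable). Published
pg-and-Mb value pairs are sometimes mutually inconsistent at the last
printed digit because the Mb figure was derived from an unrounded mean;
the constant, not the printed pair, is authoritative here.

Ploidy is inferred by matching a 2C value against candidate multiples of
a monoploid (1Cx) reference: the call minimizes `|pg_2C/p − 1Cx|` over
the candidate set, ties breaking toward the smaller ploidy. The default
1Cx of 1.95 pg is a convention summarizing the fescue cytotype series the
package was built around (2C values near 7.5, 12.8 and 15.6 pg for 4x,
6x and 8x), not a measured constant, and should be replaced when working
in another system.

# Permutation statistics for nested morphometric designs

## PERMANOVA

Morphometric traits mix µm and µm² scales, so trait columns are z-scored
by default before Euclidean distances are taken (a flag disables this).
The PERMANOVA Gower-centres the squared distance matrix and attributes
sums of squares to terms sequentially (Type-I, in the listed order) by
projecting onto each term's span increment; pseudo-F and R² follow the
usual distance-based ANOVA definitions. Significance uses free
permutation of rows by default — the conservative, assumption-light
choice when the correct exchangeability units are debatable — with an
optional `strata` argument for restricted within-stratum permutation.
P-values use the `(1 + b)/(1 + B)` estimator so they are never zero, and
tie counting uses a relative tolerance so relabellings that are
mathematically equivalent count as ties despite floating-point summation
noise. For n ≤ 9 an exact mode enumerates all n! relabellings. On
Euclidean distances the decomposition agrees with summed univariate
sequential ANOVA (and with vegan's implementation) to 10⁻⁸, and the test
is calibrated: under a seeded three-group null the rejection rate at
α = 0.05 sits within 0.05 ± 0.02.

## Pairwise tests, Holm, PCA, LDA, letters

Pairwise group comparisons permute labels within each pair; the default
statistic is the Euclidean distance between multivariate centroids, with
a univariate mean-difference mode mirroring per-trait comparisons (which
of the two a given report used is often unstated, so both exist).
Family-wise error is controlled by the Holm–Bonferroni step-down, written
out explicitly and cross-checked against `p.adjust`.

PCA is a plain SVD of the centred (optionally z-scored) trait matrix
with a deterministic sign convention (each loading column's
largest-magnitude element is positive) so runs are bit-reproducible. LDA
uses Fisher's rule with equal priors; leave-one-out cross-validation
refits the classifier n times and accumulates a confusion matrix, from
which accuracy and Cohen's κ are computed. Because these designs can be
tiny (16 individual-level rows against 4–5 traits), the pooled
within-group covariance receives a 10⁻⁸ ridge when near-singular. Tukey
HSD letters use the studentized-range distribution with Tukey–Kramer
standard errors and an insert-and-absorb compact letter display, which
guarantees significantly different groups never share a letter and
non-significant pairs always do. Colony growth rate is the plain
diameter change per day between the first and last observation.

# Alignment variability

Variable sites, parsimony-informative sites and SNP calls operate on
equal-length DNA alignments with 1-based column coordinates. Gaps and
IUPAC ambiguity codes are excluded from per-column denominators by
default, so a column whose only variation is gap-versus-base is not
variable. A column is a SNP when its most frequent non-majority base
reaches the minimum variant frequency, with an inclusive boundary: in a
four-haplotype design a singleton sits at exactly 25% and must be
callable at the 25% threshold. Because "variable and potentially
informative positions" is ambiguous phrasing in the field, both the
variable count and the stricter parsimony-informative count are always
reported.

# Synthetic data: what it emulates and what it does not

The generators are pure functions of their arguments and a seed.

* `synthMicrograph()` renders anti-aliased dark ellipses on a light
  background with Gaussian blur (σ = 1 px) and additive Gaussian noise
  (sd 0.02 on the unit intensity scale), drawing lengths from a
  truncated normal 4.4 ± 0.4 µm on [3.4, 5.5] and widths from 2.0 ± 0.2
  µm on [1.5, 2.6] — the working conidium statistics. Oblique/off-plane
  structures are modelled as overlapping ellipse pairs so the sagittal
  gate has true negatives. Truncated-normal sampling is by rejection
  (exact support control). The canvas auto-sizes to roughly 8× the summed
  pairwise-exclusion area so sequential random placement does not jam.
* `synthFcHistogram()` draws per-peak Gaussian event intensities plus an
  optional exponential low-channel debris tail and bins them; counts are
  conserved exactly.
* `synthMorphTable()` reproduces the nested sampling layout (site × host
  ploidy cells — by default the four cells of the study design — with 4
  individuals per cell and 10 replicates per individual) as grand mean +
  cell effect + individual random effect + replicate noise, with the
  published trait means and SDs as defaults.

These emulate the statistical structure of real data, not its physics:
there is no optical PSF beyond Gaussian blur, no uneven illumination,
no agar texture, no cell-cycle substructure in the histograms, and no
trait covariance beyond what the shared effects induce. Passing the
recovery tests therefore demonstrates correctness of the measurement and
inference chain under controlled conditions, not robustness to every
imaging artefact.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use problem sizes chosen to
exercise each method meaningfully on a single CPU: 200 synthetic spores
across four fields for morphometric recovery, 300–500 replicates of a
999-permutation null for PERMANOVA calibration, histograms of 5000–10000
events for peak recovery across CVs of 2–9%, and 1000 random alignments
for the site-count oracle. Every stochastic step takes an explicit seed,
all result files embed the seed and parameter set that produced them,
and identical configurations reproduce identical outputs byte for byte.

# Known limitations

* The sagittal gate is a geometric proxy; genuinely oblique spores that
  happen to project as clean ellipses are accepted.
* Skeleton-based stalk length underestimates sharply-bent structures by
  the corner cut of the medial axis (about 3% on a right-angle elbow).
* Single-Gaussian peak refinement degrades when sample and standard
  peaks overlap within about 3 combined standard deviations.
* The statistics stack covers the permutation/multivariate toolset;
  mixed-effects growth modelling is intentionally out of scope.
* FCS instrument files are not parsed; cytometry input is delimited
  histograms or event lists.
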
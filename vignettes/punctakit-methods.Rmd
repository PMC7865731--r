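---
title: "Quantifying membrane puncta, binding, endocytosis and expression with punctakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane puncta, binding, endocytosis and expression with punctakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctakit)
```

punctakit quantifies the behaviour of membrane-protein clusters in
fluorescence microscopy: how densely they cover the membrane, whether two
proteins occupy the same clusters, whether clusters disappear by
endocytosis after a stimulus, how they move, how many proximity-ligation
(PLA) interaction signals a cell carries, and how transcript levels shift
between conditions. The motivating application is the trafficking of
amino-acid transporters through caveolin-coated pits under amino-acid
stimulation, imaged by total internal reflection fluorescence (TIRF)
microscopy at 160 nm per pixel, but every stage is generic.

Because raw micrographs for such studies are rarely deposited, the package
ships a synthetic-scene generator that produces every input the pipeline
consumes together with its ground truth. All conventions are fixed once:
coordinates are 1-based `(row, col)` with the origin at the top-left pixel
and pixel centres at integer coordinates, intensities are non-negative
finite counts, and physical calibration (`pixel_size_nm`,
`frame_interval_s`) travels with the `image_stack` container.

## Spot detection: prominence-based local maxima

`find_maxima()` reimplements the "find maxima" idea familiar from ImageJ.
A pixel is reported as a punctum when it is an 8-neighbourhood local
maximum whose *prominence* — the drop from its peak to the highest saddle
connecting it to any stronger maximum — exceeds a noise tolerance. The
algorithmic core is a descending flood fill: candidates are processed in
decreasing intensity order, each grows a connected region over pixels
within `tolerance` of its peak, and a candidate that touches brighter
ground or a previously claimed region inside that band is merged rather
than reported. Plateaus collapse to their centroid and accepted peaks are
refined to subpixel precision by a per-axis quadratic fit in the 3×3
neighbourhood. Maxima within 3 px of the image border are dropped, and two
properties hold by construction: raising the tolerance never increases the
number of maxima, and detections translate rigidly with the image.

The tolerance is the one decisive parameter. Its default is five times the
robust standard deviation (MAD × 1.4826) of the *off-cell background
region* when one is supplied; the MAD of a whole frame measures the
cell-versus-background intensity structure rather than the noise floor and
is several-fold too large, so supplying `bg_mask` is recommended whenever
the default is used. For the generator's default scenes this estimate
lands near 20 counts, versus a spot amplitude of 200.

Two physical limitations are worth stating. Spots closer than roughly the
Rayleigh spacing (about 2.5–3 px at a PSF sigma of 1.2 px) merge into a
single maximum, which biases cluster-density estimates a few percent low
at 0.4 clusters/µm²; and subpixel positions are only as good as the 3×3
quadratic model, roughly 0.1–0.2 px at the default signal-to-noise.
`cluster_density()` is then simply the count of detected puncta inside the
cell mask divided by the mask area in µm².

## The circle–annulus ΔF/S binding score

At a candidate binding site, `measure_site()` reads the mean fluorescence
in a central circle of 3 px diameter (`c`), in the surrounding annulus out
to 5 px outer diameter (`a`; the inner diameter equals the circle, giving
a contiguous annulus), and in an off-cell background region (`bg`). Pixel
membership is by the distance of the pixel centre from the (possibly
subpixel) site centre. The site-specific fluorescence is ΔF = c − a, the
local unbound fluorescence is S = a − bg, and the ratio ΔF/S measures
binding at the site independently of expression level: positive values
mean enrichment, negative values exclusion. The score is affine-invariant:
gain and offset applied to the whole frame (background included) cancel.

When S ≤ 0 the score is undefined; such sites are flagged and excluded
from the per-cell mean (`cell_binding_score()`, which requires at least
seven valid sites by convention), never imputed. Sites must also lie well
inside the cell: an annulus that overlaps off-cell pixels depresses `a`
and biases ΔF upward, so `interior_mask()` erodes the cell mask by the
annulus radius and site lists should be filtered through it. On synthetic
scenes this matters — with edge sites included, genuine exclusion (spots
kept away from the measured positions) is masked by the edge bias.

## Co-localization percentage

`colocalization_percent()` automates an observer protocol: for each
reference punctum, is there a query-channel punctum centre within one
pixel? The 11 µm² square cutout (about 21 × 21 px at 160 nm/px) bounds the
search neighbourhood. The protocol is deliberately asymmetric, as the
observer version was: the reference list is the conservatively identified
cluster set, while the observer would report any perceptible spot in the
cutout. We therefore detect the reference channel at the standard
tolerance and the query channel at half that tolerance. With a symmetric
tolerance either reference false positives (low tolerance) or query
merging misses (high tolerance) bias the percentage by 6–16 points at the
extremes; the asymmetric protocol recovers programmed co-localized
fractions of 0–100% to within about 3.5 points, and independent channels
sit at the Poisson chance rate 100·(1 − exp(−ρπr²)) ≈ 3% at
ρ = 0.4 µm⁻², r = 0.16 µm. Pearson- or Manders-style pixel correlation is
a different statistic family and is intentionally not provided.

## Whole-cell traces and endocytosis events

`cell_trace()` computes, per frame, the mean intensity in the cell mask
minus the mean in the off-cell background mask (`f_raw`), normalizes by
the mean over all pre-stimulation frames (`f_norm`, so the baseline is 1
by construction and camera gain cancels), and shifts the time axis so the
stimulation frame is t = 0. At least five baseline frames are required. An
optional linear detrend of the baseline for photobleaching exists but is
off by default, since the imaging protocols this emulates did not bleach
correct.

`detect_endocytosis_events()` targets the characteristic signature of a
single internalization: the site-specific ΔF of a punctum collapses within
one or two frames and stays down. For each punctum a per-frame ΔF trace is
measured at a fixed position, and an event is called at the first frame
where ΔF has fallen by at least 50% of its trailing 5-frame median within
at most 2 frames and remains at or below that level for 3 consecutive
frames. The 50% threshold matches the scale of stimulus responses in this
assay family (whole-cell fluorescence falling by about half); the 3-frame
persistence rejects blinking and single-frame noise excursions. Both are
configurable. Event counts are monotone non-increasing in the threshold,
and on event-free synthetic movies the false-positive rate is below
0.02 per trace at defaults. `density_before_after()` completes the
picture by comparing cluster density in a pre-stimulation window against
the final frames (after programmed losses have run to completion) —
internalizing half the puncta halves the density, within detection error.

## Particle tracking

`link_tracks()` performs gated nearest-neighbour linking: candidate pairs
between consecutive frames within `max_step_px` (default 5 px, the
conventional pixel cut-off) are accepted greedily in ascending distance,
each detection joining at most one track; unmatched detections seed new
tracks; there is no gap closing, so track points advance one frame at a
time. Tracks shorter than 3 points are discarded by default (one-frame
links are mostly spurious). `displacement_histogram()` bins per-frame step
lengths and, separately labelled, per-track total path lengths — both
conventions appear in the literature, so both are emitted — and reports
the count of minimum-displacement tracks (total in the lowest bin).
`average_speed()` converts mean step lengths to µm/s via the calibration
and pools across tracks with a SEM.

For Brownian motion with diffusion coefficient D and frame interval Δt,
per-axis steps are N(0, 2DΔt), so step lengths are Rayleigh with mean
√(πDΔt); at D = 0.01 µm²/s and Δt = 0.1 s the pooled speed is
√(πDΔt)/Δt ≈ 0.56 µm/s. The tracking tests verify this law, and the χ²
goodness of fit of the step histogram, on the generator's ground-truth
positions: the statistic belongs to the linker, not the detector, and
detector localization noise (which inflates apparent steps by its variance)
is assessed separately.

## The PLA counting chain

PLA produces a countable fluorescent dot wherever two target proteins are
within ~40 nm. The counting chain is: maximum-intensity projection of the
z-stack (`max_project()`); subtraction of an autofluorescence reference,
clipped at zero (`subtract_autofluorescence()`); white top-hat cleaning
with a disc structuring element of 10 px diameter (`tophat_clean()` —
"remove anything over 10 pixels" is read as a width, not an area; the
element is rounded up to odd size); definition of cell regions by
expanding DAPI-segmented nuclei by 65 px (`define_cells()`: Otsu threshold
on the normalized DAPI channel, hole filling, connected components with a
50 px² minimum area, then Euclidean nearest-nucleus assignment out to the
expansion distance, ties to the lower label); and finally thresholded
connected-component counting (`count_signals()`), each component credited
to the region containing its centroid, components outside every region
removed. The 0.08 intensity threshold is interpreted on [0, 1]-normalized
images; an unnormalized image raises an error unless auto-normalization is
explicitly requested. The report satisfies two exact identities:
signals_per_cell × n_cells = signals_total, and the per-cell counts sum to
the total.

Counting by connected components undercounts when two dots overlap within
the threshold contour. At 200 dots within a 65-px placement radius this
merging loss is about 6–8% even for 1-px dots; it is a property of the
assay geometry, not of the implementation, and bounds the accuracy of any
threshold-component counter at high signal density.

## qPCR relative quantification

Three methods operate on tidy Cq tables (`gene, condition, replicate,
cq`), with replicate aggregation always the arithmetic mean of Cq before
any exponentiation. Writing A/B for the target's mean Cq in the
untreated/treated sample and F/G for the reference gene's:

* `ddct_fold()`: fold = 2^((A − B) − (F − G)), the 2^−ΔΔCt method.
* `pfaffl_fold()`: fold = e_t^(A−B) / e_r^(F−G) with per-primer
  amplification efficiencies, defaulting to 1.85 (target) and 1.97
  (reference) as determined by LinReg-style analysis in the motivating
  assay. Printed versions of these formulas often lose their superscripts
  in typesetting; the exponent form is the only reading consistent with
  amplification efficiencies, and the two methods coincide exactly when
  both efficiencies are 2.
* `pfaffl_min_ref_fold()`: the same efficiency model, but each gene's
  per-condition quantity is expressed relative to that gene's reaction
  with the lowest mean Cq (so within-gene quantities have maximum 1). The
  minimum is taken per gene, not per plate — the alternative reading —
  and the resulting fold equals the Pfaffl fold algebraically, the
  rescaling cancelling between conditions.

`multi_reference_summary()` reports the fold against each reference
(housekeeping) gene separately plus a combined value whose reference Cq is
the arithmetic mean of the reference genes' Cq within each condition; the
combination rule is a documented package choice, and per-reference results
are always reported alongside. The ΔΔCt estimator applied to tables with
Gaussian Cq noise is slightly biased upward (Jensen's inequality on
2^X; about +1.6% at sd 0.2 cycles and triplicates), well inside the 5%
recovery the tests require.

## The synthetic-scene generator

The generator exists so that every stage can be validated against known
truth with no external data, and its defaults are chosen to emulate the
motivating assay rather than to flatter the detectors:

* **Two-channel punctate frames** (`gen_two_channel_frame()`): a Poisson
  number of spots at 0.4 clusters/µm² inside an elliptical cell on an
  80×80 px field at 160 nm/px; isotropic Gaussian PSF of sigma 1.2 px
  (~192 nm, diffraction-limited); amplitude 200 counts over a membrane
  background of 50 and an off-cell background of 10; Poisson shot noise
  plus Gaussian read noise of sd 2. A `coloc_fraction` subset of
  channel-1 spots is duplicated into channel 2 at identical centres, and
  channel 2 is topped up to its own Poisson draw with independent spots;
  `exclusion_radius_px > 0` instead keeps those independent spots away
  from channel-1 centres, producing true exclusion scenes. Expected spot
  counts equal density × *cell-mask* area (the density is a per-membrane
  quantity), and the expected nearest-neighbour spacing 0.5/√λ is checked
  against 2σ to flag overcrowded parameterizations.
* **Time-lapses** (`gen_timelapse()`): Brownian per-axis steps of variance
  2DΔt; after the stimulation frame a designated fraction of spots lose
  their amplitude to zero linearly over one or two frames, with the event
  frame recorded; the number of events is exactly
  round(fraction × n_spots). A global mono-exponential bleach factor is
  available but off by default. There is no motion blur within a frame.
* **PLA scenes** (`gen_pla_scene()`): non-overlapping nucleus discs on a
  jittered grid, per-cell Poisson dot counts placed within 65 px of the
  owning nucleus, a smooth autofluorescence field returned both mixed into
  the PLA channel and as its own channel. The dot sigma defaults to
  0.45 px: amplified PLA dots are about one pixel wide at widefield
  sampling, and broader dots would be physically unresolvable at 200
  signals per cell.
* **Cq tables** (`gen_qpcr_table()`): treated target Cq shifted by
  −log₂(fold), references unshifted, Gaussian replicate noise.

Equal seeds give byte-identical outputs for all generators. What the
generator does *not* emulate bounds what passing tests show about real
data: PSFs are isotropic Gaussians without aberration or astigmatism,
backgrounds are uniform rather than structured, there is no photobleaching
by default, no stage drift, no camera fixed-pattern noise, and cells are
ellipses. Detection and scoring performance on real micrographs will be
worse than on these scenes in proportion to how far those assumptions are
violated; the tests validate the *algorithms*, not any claim about a
specific instrument.

## Problem sizes and numerical choices

The shipped test-suite and reference computations use deliberately modest
sizes chosen to make every check statistically meaningful: 80–256 px
fields, 20–30 frame movies, 20-seed Monte-Carlo means for score and
co-localization checks, 60 tracks × 168 frames (≥10⁴ steps) for the
Rayleigh goodness of fit, 30-cell PLA scenes at means 5/40/200, and 500
simulated plates per fold for the qPCR recovery. Degenerate inputs are
defined rather than accidental: constant images detect nothing, S ≤ 0
flags a score as undefined, empty query lists give 0% co-localization,
empty reference lists are an error, ties in nearest-nucleus assignment go
to the lower label, and featureless channels make alignment an error
rather than a guess.
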
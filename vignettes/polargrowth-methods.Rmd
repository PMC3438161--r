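---
title: "Measuring division-site placement and asymmetric polar growth in rod-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring division-site placement and asymmetric polar growth in rod-shaped bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polargrowth)
```

## The biological question and the measurement model

Mycobacteria and corynebacteria elongate from their poles rather than along
the cell body, and they lack the Min and nucleoid-occlusion systems that
model rods use to find mid-cell. Live-cell imaging of a fluorescent
peptidoglycan-synthase marker shows a characteristic sequence in these
organisms: a diffuse intracellular patch of marker wanders between the
poles, condenses into a stable spot close to mid-cell (the future septum),
and the cell divides a fixed time later, with the two sides of the septum
elongating exponentially at markedly different per-pole rates. polargrowth
implements the complete quantitative pipeline for this kind of experiment —
and, because the original image data of this experimental design are not
publicly deposited, a synthetic movie generator that emulates the biology so
that every stage of the pipeline can be validated against known ground
truth.

The growth model is deliberately minimal. Each cell carries two pole rates
$r_a, r_b$ (min^-1^), drawn once at birth from a fast-pole distribution
(default Normal(1.66e-4, 2.39e-5), truncated at zero by redrawing) and a
slow-pole distribution (default Normal(7.87e-5, 8.80e-6)). The cell is split
by its (eventual) septum plane into two material sides, and each side grows
exponentially at its pole's rate for the cell's whole life:

$$ L(t) = a_0\,e^{r_a (t - t_\mathrm{birth})} + b_0\,e^{r_b (t - t_\mathrm{birth})}. $$

The published rates only describe growth between septum placement and
division; extending the same rates backwards to birth is the simplest
continuous completion and is invisible to the downstream statistics, which
only use the placement-to-division interval.

Septum placement is drawn as $0.5 + \mathrm{Normal}(0, \sigma_p)$ of the
length realized at condensation (clamped into the open unit interval). The
default $\sigma_p = 0.066$ reproduces a central-20%-of-length fraction of
roughly 87%, the hallmark of accurate mid-cell placement by a live septal
marker; raising $\sigma_p$ monotonically erodes that fraction, which the
test suite checks as a property. Division is triggered by a timer — 160 min
after condensation by default — not by a length threshold, mirroring the
observation that cells divide over a wide range of lengths (the generator's
cells place septa over a broad length range because founder birth lengths
are drawn from Normal(6.0, 1.5) µm and septum-appearance timing is drawn
independently of length, Normal(40, 15) min after birth plus four frames of
patch wandering).

At division the two sides become daughters whose birth lengths sum exactly
to the parent length (a conservation law asserted by the tests). Each
daughter keeps the parental rate at its old pole and draws a fresh rate for
the pole created at the septum; whether pole rates are heritable is not
established experimentally, so inheritance of the old-pole rate — the most
parsimonious rule — is a modelling choice, and the probability that the new
pole draws from the fast distribution is an explicit configuration knob
(`new_pole_fast_prob`, default 0.5). A second knob, `fast_on_short_prob`,
optionally biases the fast rate toward the side that will be shorter at
placement; its default of 0.5 is an unbiased coin, while 0.78 emulates the
reported tendency of cells to grow faster on their shorter side.

## Rendering choices

Movies are rendered at 0.1 µm/px with one frame per 10 min. The phase-like
channel draws each cell as a dark capsule (width 0.8 µm) on a bright
background, convolved with a Gaussian PSF (σ = 0.13 µm) plus additive
Gaussian noise; shot noise is deliberately omitted so that `noise_sd = 0`
gives byte-identical, fully deterministic renders. Rasterization is
anti-aliased: each pixel receives the approximate area fraction covered by
the capsule outline, so the blurred edge crosses its half-intensity level at
the true sub-pixel boundary irrespective of where the cell sits on the
pixel grid. Without this, cell tips quantize to pixel centers and length
measurements inherit a placement-dependent half-pixel bias.

The fluorescence channel renders two polar foci throughout, plus an
internal focus: before condensation, a dimmer and broader patch whose
normalized position performs a reflected Gaussian random walk on
[0.15, 0.85] with step SD 0.12 of the cell length per frame (the published
account only says patches appear at variable locations; the step size is
chosen large enough that a wandering patch does not masquerade as a settled
spot under the stability criterion below); after condensation, a
full-intensity spot pinned to the septum plane, whose normalized position
drifts slowly as the two sides grow unequally. Invagination is rendered as
a deepening local width constriction during the final 40 min before
division, and division itself as a 0.5 µm separation between daughters —
mycobacterial daughters snap apart — which also keeps each daughter's
blurred end edge free of its sibling's intensity shadow.

Cells are laid out in one lane per founder lineage with generous spacing,
so masks never merge; crowded scenes and cell-cell contact are out of
scope. Each lane receives a uniform sub-pixel offset in both axes so that
cell tips sample all pixel phases — anchoring every founder on the pixel
grid would give all parent cells one systematic tip bias and all daughters
another, which propagates into the growth-rate estimates.

## Measurement pipeline

**Segmentation.** Global Otsu threshold (the scenes are sparse and
bimodal; a fixed threshold can be supplied instead), inversion,
morphological opening with a radius-1 structuring element, connected
components, and removal of components below 40 px or touching the border.
On our rendered images Otsu sits slightly above the half-level between
interior and background, which broadens thin rods by a fraction of a pixel;
this affects areas and widths but not lengths, because length measurement
re-localizes the boundary sub-pixel (below).

**Centerline length.** The mask is thinned to a skeleton (Zhang–Suen,
implemented here since no installed package provides binary thinning), the
longest endpoint-to-endpoint geodesic through the 8-connected skeleton
graph is taken (this drops short side branches), the pixel path is smoothed
with a 5-point moving average to suppress staircase inflation, and each end
is extended outward along the terminal direction to the cell boundary —
skeletons systematically stop about one half-width short of rounded poles.
The boundary is located on the phase image as the interpolated crossing of
the half-way level between the cell-interior median and the background
median; for an edge blurred by a symmetric PSF this crossing sits at the
physical boundary, which is what makes the length sub-pixel accurate
(noise-free error ≈ 0.2 px; median absolute error stays below 2 px at the
default noise). Pole A is the endpoint with the smaller coordinate along
the cell's dominant image axis (rows if the cell spans more rows than
columns, else columns). A naive lexicographic (row, col) ordering is
unstable for near-horizontal cells — endpoint jitter transverse to the
cell axis routinely exceeds a pixel under noise, and a single flip inverts
every normalized position and swaps the side attribution of a whole
lineage — so the dominant-axis comparison, which such jitter cannot flip,
is used instead. Objects whose skeleton
has no endpoints (loops) or is shorter than the half-width (discs) are
flagged unmeasurable and excluded, with a warning and a discard count.

**Foci.** Detection follows the maximal-intensity-pixel convention:
within each mask, pixels above the frame median plus 5 MAD (with a
0.05-intensity floor so noise-free frames keep a meaningful threshold) form
candidate regions; each connected region contributes exactly one focus at
its brightest pixel, ties resolved to the first pixel in row-major order.
Foci are projected orthogonally onto the centerline polyline to get the
arclength $s$ from pole A and $p = s/L$; a focus is polar when its distance
to the nearer pole is at most `d_pole` (default 0.5 µm, about one cell
width — the cutoff is a convention, so it is a configuration knob), else
internal. Sub-pixel focus localization (Gaussian fitting) is intentionally
not performed.

**Tracking and condensation.** Cell masks are linked across frames by
maximal intersection-over-union (threshold 0.3); one mask overlapping two
masks in the next frame, each with IoU at least half the threshold, is a
division; the daughter containing the parent's pole A inherits side A, so
per-side series remain attributable. Within a cell track, internal foci are
linked between consecutive frames by the exact minimum-total-|Δs| maximum
matching subject to a 1.5 µm gate (focus counts per cell are tiny, so
exhaustive matching is cheap and provably optimal). Condensation is the
earliest observation from which the track's $p$ stays within ±0.05 of its
forward running median through the end of the track, with at least 3
observations (30 min) remaining. The from-that-point-onward form is chosen
over a fixed 3-frame window because a wandering patch can sit still for
three frames by chance; requiring stability through the end of the track
suppresses such false condensations, and the two forms agree on settled
spots. The event's position is reported as the median of the first three
stable observations rather than the single first one.

For dividing cells, the stability criterion and the position average skip
the final two pre-division frames: the deeply constricted neck distorts
skeleton geometry there, and a single corrupted arclength would otherwise
veto an entire septal track under the stability-to-end rule. The track
itself must still persist to the end of the cell to be accepted as the
septal spot.

**Growth records.** For a cell with both a condensation event and a
division, the side lengths at placement are $pL$ and $(1-p)L$ with $L$ the
measured length at the condensation frame and $p$ the mean normalized spot
position over the stable stretch (the settled spot is stationary at the
septum plane, so averaging suppresses the pixel quantization of the
spot-position estimate, the single largest noise source in the rate
estimates). Side lengths at division are the two daughters' measured birth
lengths. Rates use the published estimator directly,
$r = \ln(\mathrm{side}_\mathrm{div}/\mathrm{side}_\mathrm{sep}) / (t_\mathrm{div} - t_\mathrm{sep})$,
with $r_\mathrm{fast} = \max(r_a, r_b)$, the fast:slow ratio undefined when
the slow side did not grow (such records are kept but flagged), and
`faster_on_shorter` comparing the faster side against the shorter side at
placement (ties count as `FALSE`). Because both events are detected as
"first frame at or after the true time" and the 160-min timer is a
multiple of the 10-min cadence, the detected condensation-to-division
delay carries no systematic half-frame bias.

Division time is reported as the time of the daughters' first frame (the
parent track ends at the division frame, daughters are born the next
frame).

## Statistics

Normalized position $p = s/L$ and its folded form $q = \min(p, 1-p)$;
central-band fractions count $|p - 0.5| \le w/2$ inclusively with $w = 0.2$
by default ("the central 20% of the cell length"). The asymmetry summary
reports the fraction of cells faster on their shorter side, the mean of
per-cell fast:slow ratios and the ratio of means (both are reported because
it is ambiguous which one a population summary of "mean ratio" denotes),
and the Pearson correlation — computed from its definitional sum formula,
with a two-sided p from the t transform — between the signed relative
side-length difference at placement, $(a-b)/(a+b)$, and the rate
difference $r_a - r_b$. The published account does not define its
"degree of asymmetry" operationally, so sign conventions cannot be matched
to it; the definitional formula and p-value are cross-checked against
`cor.test()` in the tests.

Length-variability comparison between two populations is implemented as a
two-sample rank test of dispersion: each observation is reduced to its
absolute deviation from its own sample's median and the deviations are
compared with a Wilcoxon-type rank-sum statistic, exact null enumeration up
to a combined n of 12 and a tie-corrected normal approximation with
continuity correction beyond. A signed-rank test is ill-defined for
unpaired samples of unequal size, which is why the unpaired dispersion-rank
formalization was chosen. All-identical pooled deviations yield p = 1, not
an error.

## Numerical and degenerate-input conventions

Negative draws from rate and length distributions are redrawn, never
clamped, to avoid an atom at zero. Septum fractions are clamped to
[0.02, 0.98]. Empty images segment to zero masks without error; an empty
positions list makes `central_fraction()` fail loudly rather than return a
silent 0. Equal-intensity focus maxima and equal-cost matchings resolve by
documented deterministic tie-breaks (row-major order; smaller |Δs| then
frame order). A single seed governs every stage; identical configuration
and seed reproduce truth tables and pixel arrays byte-for-byte, and all
randomness inside the package goes through `withr::local_seed()` so user
RNG state is never disturbed.

## Problem sizes used by the validation suite

The packaged checks run the full image pipeline at sizes chosen to give
comfortable statistical power while staying quick on a laptop: 50 founder
lineages over 32 frames for pole-rate and timer recovery (about 45
dividing cells), 200-cell static snapshots per species for length-recovery
(sampling SE ≈ 0.1 µm for the mycobacterial distributions), and 10^5 draws
for uniform-limit checks. Recovery is always judged in standard errors of
the measured sample, so these sizes are a precision choice, not a tuning
knob.

## What passing the synthetic checks does and does not show

The generator emulates the features the pipeline must measure — bipolar
exponential growth with unequal rates, mid-cell placement noise, a
wandering-then-condensing internal focus, timer-triggered division,
realistic PSF blur and additive noise — and the pipeline recovers the
generator's parameters without access to ground truth. That validates the
measurement chain end to end. It does not validate segmentation under
phase-contrast halos, touching or crossing cells, three-dimensional growth
out of the focal plane, photobleaching, or motile cells: none of these are
modelled, and the segmentation deliberately refuses rather than guesses
(border-touching cells and degenerate masks are discarded and counted).
Absolute intensities are arbitrary units; only geometry and timing carry
meaning.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_cells = 10, n_frames = 32, seed = 7)
truths <- simulate_population(cfg)
movie <- render_movie(truths, cfg)
analysis <- analyze_stack(movie$stack)

analysis$growth_records |> dplyr::select(track_id, t_sep, t_div, r_fast, r_slow, ratio)
asymmetry_stats(analysis$growth_records) |> tidy()

# placement statistics of the detected septal spots
central_fraction(analysis$septum_events$p_at_condensation)

# static three-spot experiment
snap <- render_static_snapshot(rnorm(100, 4.8, 1.37), runif(100, 0.35, 0.65), cfg)
ph <- snap$stack$phase[, , 1]
masks <- extract_centerline(segment_frame(ph, cfg$pixel_size), cfg$pixel_size, ph)
foci <- detect_foci(snap$stack$fluor[, , 1], masks, pixel_size = cfg$pixel_size)
summarize_population(masks, foci)
```
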
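# polargrowth

Quantitative analysis of division-site placement and asymmetric polar
growth in rod-shaped actinobacteria (mycobacteria, corynebacteria) from
single-cell time-lapse fluorescence microscopy — together with a synthetic
movie generator that makes every stage of the pipeline testable against
known ground truth.

## The problem

Mycobacteria elongate from their poles and lack the Min/nucleoid-occlusion
machinery that *E. coli* and *B. subtilis* use to find mid-cell, yet they
place their division septa accurately near mid-cell over a wide range of
cell lengths, and their daughters are born unequal because the two sides of
the septum elongate at different rates. The measurement chain for this kind
of experiment is: segment rod cells in each frame and measure pole-to-pole
centerline length; detect fluorescent foci of a septal marker as
maximal-intensity pixels and classify them polar vs internal; track cells
through division and foci through time; detect the condensation of a
wandering marker patch into a stable septal spot; and estimate per-side
exponential growth rates between septum placement and division,

```
r_side = ln(side_at_division / side_at_placement) / (t_division - t_placement)
```

with `r_fast = max(r_a, r_b)`, `r_slow = min(r_a, r_b)`, the fast:slow
ratio, the fraction of cells that grow faster on the side that was shorter
at placement, and the normalized septum position `p = s / L` with its
central-band fraction (`|p - 0.5| <= 0.1`, the "central 20%" of the cell).

Because the original image data for this experimental design are not
publicly deposited, the package ships a first-class synthetic generator:
bipolar exponential growth with per-pole rates drawn from fast
(1.66×10⁻⁴ min⁻¹, SD 2.39×10⁻⁵) and slow (7.87×10⁻⁵ min⁻¹, SD 8.80×10⁻⁶)
distributions, mid-cell placement noise, a wandering pre-septal patch that
condenses into a stable spot, division by a 160-min timer, Gaussian PSF and
noise, rendered to two-channel TIFF movies with exported ground truth.

## A worked example

```r
library(polargrowth)

cfg <- sim_config(n_cells = 30, n_frames = 32, seed = 42)
truths <- simulate_population(cfg)
movie  <- render_movie(truths, cfg)
an     <- analyze_stack(movie$stack)

asymmetry_stats(an$growth_records) |> tidy()
#> # A tibble: 1 × 7
#>   mean_r_fast mean_r_slow mean_ratio ratio_of_means frac_faster_on_shorter pearson_r pearson_p
#>         <dbl>       <dbl>      <dbl>          <dbl>                  <dbl>     <dbl>     <dbl>
#> 1    0.000178   0.0000827       3.74           2.15                    0.6    -0.237     0.253

mean(an$growth_records$t_div - an$growth_records$t_sep)
#> [1] 162.8
```

The pipeline, knowing nothing of the generator's parameters, recovers the
fast-pole mean rate (1.78×10⁻⁴ vs the configured 1.66×10⁻⁴ min⁻¹, within
sampling error over 25 cells), the slow-pole rate (8.3×10⁻⁵ vs 7.87×10⁻⁵)
and the 160-min condensation-to-division timer (162.8 min; events are
quantized to the 10-min imaging cadence). `an$septum_events`
holds the detected condensation events, `central_fraction()` the
septum-placement accuracy, `plot_septum_positions()`,
`plot_growth_asymmetry()` and `autoplot()` the standard figures.

Static "three-spot" snapshots (two polar foci plus one internal) and their
population statistics:

```r
set.seed(1)
snap  <- render_static_snapshot(rnorm(200, 4.8, 1.37), runif(200, .35, .65), cfg)
ph    <- snap$stack$phase[, , 1]
masks <- extract_centerline(segment_frame(ph, cfg$pixel_size), cfg$pixel_size, ph)
foci  <- detect_foci(snap$stack$fluor[, , 1], masks, pixel_size = cfg$pixel_size)
summarize_population(masks, foci)
#> <placement_stats>
#>   cells: 200, mean length 4.84 um (SD 1.27)
#>   internal spots: 200, 63% within the central 20% of length
```

(63% of internal spots fall in the central band here because the example
draws spot positions uniformly on [0.35, 0.65] rather than from the
placement model.)

A thin command-line wrapper is installed as `exec/polargrowth`
(`polargrowth simulate|analyze|pipeline`), writing TIFF movies, per-stage
CSVs, a JSON report and a reproducibility manifest.

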
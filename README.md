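# punctakit

Quantification of punctate fluorescence in TIRF and widefield microscopy,
for studies of membrane-protein clustering and trafficking: where
diffraction-limited clusters sit, how densely they cover the membrane,
whether two proteins share sites, whether and when clusters internalize by
endocytosis, how they move, how many proximity-ligation (PLA) interaction
signals a cell carries, and how transcript levels shift between
conditions. It is aimed at cell biologists analysing experiments such as
amino-acid-transporter/caveolin trafficking assays, where analysis
traditionally lives in ImageJ macros, MetaMorph journals, CellProfiler
pipelines and spreadsheets; punctakit reimplements that tool chain as one
tested, scriptable R package.

## What it computes

* **Spot detection** — `find_maxima()`: local maxima whose prominence over
  the highest connecting saddle exceeds a noise tolerance (descending
  flood-fill, plateau merging, subpixel refinement);
  `cluster_density()` in clusters/µm².
* **Binding score** — `measure_site()` / `cell_binding_score()`: at each
  site, mean fluorescence in a 3-px circle (c), its 5-px annulus (a), and
  an off-cell background (bg); ΔF = c − a, S = a − bg, and the
  expression-independent binding score ΔF/S (positive = binding,
  negative = exclusion). `colocalization_percent()` gives the
  observer-style centre-distance co-localization percentage.
* **Dynamics** — `cell_trace()` (background-corrected, baseline-normalized
  whole-cell fluorescence around a stimulation),
  `detect_endocytosis_events()` (ΔF collapsing ≥50% within 1–2 frames and
  staying down), `density_before_after()`.
* **Tracking** — `link_tracks()` (gated greedy nearest-neighbour linking,
  5-px cut-off), `displacement_histogram()`, `average_speed()` in µm/s.
* **PLA counting** — `max_project()`, `subtract_autofluorescence()`,
  `tophat_clean()` (10-px white top-hat), `define_cells()` (DAPI nuclei
  expanded 65 px), `count_signals()` (components above 0.08 normalized
  intensity), or the whole chain via `pla_signals_per_cell()`.
* **qPCR** — `ddct_fold()` (2^−ΔΔCt), `pfaffl_fold()`
  (e_t^(A−B)/e_r^(F−G), default efficiencies 1.85/1.97),
  `pfaffl_min_ref_fold()` (minimum-referenced variant),
  `multi_reference_summary()`.
* **Synthetic scenes with ground truth** — `gen_two_channel_frame()`,
  `gen_timelapse()`, `gen_pla_scene()`, `gen_qpcr_table()`; every stage is
  testable without raw microscopy data.

Results are tibbles (or small S3 objects with `tidy()`/`glance()`
methods and `autoplot()` figures), so everything composes with the
tidyverse. A thin command-line wrapper over the same functions is
installed at `inst/cli/punctakit.R`.

## Worked example

Simulate a two-channel TIRF field in which 75% of channel-1 clusters also
carry the channel-2 protein, then quantify density, co-localization and
binding:

```r
library(punctakit)

sc <- gen_two_channel_frame(scene_params(coloc_fraction = 0.75, seed = 42))
p1 <- find_maxima(get_frame(sc$stack, 1), noise_tolerance = 30)
p2 <- find_maxima(get_frame(sc$stack, 2), noise_tolerance = 15)

head(p1, 3)
#> # A tibble: 3 × 5
#>   frame   row   col  peak prominence
#>   <int> <dbl> <dbl> <dbl>      <dbl>
#> 1     1  33.1  44.0  447.       82.0
#> 2     1  64.2  17.8  421.       72.2
#> 3     1  32.3  26.9  412.       51.1

cluster_density(p1, sc$cell_mask, 160)
#> [1] 0.4254733
colocalization_percent(p1, p2)
#> [1] 80.95238
```

42 clusters are detected; their density, 0.43 µm⁻², recovers the
simulated 0.4 µm⁻², and the co-localization percentage (81%) recovers the
programmed 75% plus detection noise. The binding score at the detected
channel-1 sites, measured in channel 2 (sites restricted to the cell
interior so the annulus never leaves the membrane):

```r
keep <- interior_mask(sc$cell_mask, 4)[cbind(round(p1$row), round(p1$col))]
bs <- cell_binding_score(get_frame(sc$stack, 2), p1[keep, ], sc$bg_mask)
glance(bs)
#> # A tibble: 1 × 3
#>   mean_score n_sites n_undefined
#>        <dbl>   <int>       <int>
#> 1      0.719      32           0
```

A mean ΔF/S of 0.72 indicates strong enrichment of the channel-2 protein
at channel-1 sites, as constructed. Relative expression from a simulated
Cq table (true fold 0.25 for Grm2, i.e. four-fold down-regulation):

```r
tab <- gen_qpcr_table(c("Grm2", "Pag"), c(0.25, 0.4),
                      c("Gapdh", "mActin"), seed = 42)
multi_reference_summary(tab, "Grm2", method = "pfaffl")
#> # A tibble: 3 × 8
#>   reference gene  method  fold     a     b     f     g
#> 1 Gapdh     Grm2  pfaffl 0.288  24.1  26.1  25.3  25.2
#> 2 mActin    Grm2  pfaffl 0.304  24.1  26.1  26.0  26.1
#> 3 combined  Grm2  pfaffl 0.296  24.1  26.1  25.6  25.6
```

Each housekeeping reference, and their combination, recovers the
programmed ~0.25–0.3 fold given triplicate noise.

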
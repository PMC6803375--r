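# fabquant

Quantification of Fab-based live endogenous modification labeling (FabLEM)
movies of early embryos. Fluorescent antigen-binding fragments against a
histone or RNA polymerase II modification bind their target transiently and
pass freely through nuclear pores, so the **nucleus/cytoplasm (N/C)
intensity ratio** of a Fab channel reports the global level of the target
modification in each nucleus, and bright intranuclear **foci** report local
enrichment at strongly transcribed loci. fabquant implements the full
measurement chain for such recordings:

- **Segmentation & tracking** — per-frame nuclei from a broad nuclear
  marker channel (Gaussian smoothing in physical units, two-stage Otsu,
  distance-transform-seeded watershed on an exact anisotropic 3D Euclidean
  distance transform), linked into interphase tracks by gated
  maximum-weight bipartite matching, with a file-based manual-correction
  mechanism and stage annotation from nucleus-count doubling.
- **N/C ratios** — per-nucleus cytoplasmic *ring masks* at physical
  distances from the nuclear surface (inner exclusion 3.3 µm, outer radius
  8.3 µm), far-field background subtraction in both compartments,

  `nc_ratio = (nuc_mean − background) / (cyto_mean − background)`,

  stage-referenced normalisation and embryo-level aggregation (the embryo,
  not the nucleus, is the replicate).
- **Foci** — automated detection of up to two intranuclear foci
  (band-pass + prominence-ranked maxima), intensity through a 1 µm-diameter
  circular ROI on the z-plane of maximal cross-section, foci/nucleus ratio
  time courses and per-channel peak-time ordering.
- **FRAP** — pre-bleach normalisation and bounded multi-start fitting of
  double-exponential association kinetics
  `I(t) = P1(1−exp(−k1 t)) + P2(1−exp(−k2 t)) + C`, with the
  amplitude-weighted half-time
  `t½ = P1/(P1+P2)·ln2/k1 + P2/(P1+P2)·ln2/k2`.
- **Synthetic embryos** — a ground-truthed generator (nucleus-count
  doubling across cleavage cycles, configurable N/C trajectories,
  staggered focus peaks, mitotic dispersal, Poisson + Gaussian noise) so
  the whole pipeline is testable without raw microscopy data.

Input is plain TIFF / OME-TIFF with voxel spacing and frame-interval
metadata (or explicit overrides); every result is a typed CSV table. A
thin command-line wrapper (`inst/exec/fabquant`) exposes the stages as
subcommands (`simulate`, `segment`, `track`, `quantify`, `foci`, `frap`,
`all`) over a YAML configuration.

## Worked example

```r
library(fabquant)

cfg <- read_sim_config(system.file("extdata", "example_simulation.yaml",
                                   package = "fabquant"))
sim <- simulate_embryo_movie(cfg)   # two-cycle movie, 4 -> 8 nuclei
segs <- lapply(seq_len(n_frames(sim$movie)), function(f)
  flag_mitotic(segment_nuclei_frame(sim$movie, f, "marker"),
               sim$movie, "marker"))
nuclei <- measurement_table(
  do.call(rbind, lapply(segs, function(s) as.data.frame(s$nuclei))),
  "nuclei")
tracks <- link_tracks(nuclei, max_displacement_um = 6)
labels <- array(0L, dim(sim$movie$channels$marker))
for (f in seq_along(segs)) labels[, , , f] <- segs[[f]]$labels

nc <- measure_nc(sim$movie, tracks, labels)
subset(aggregate(nc_ratio ~ channel + frame, as.data.frame(nc), median),
       frame %in% c(1, 8, 16))
#>    channel frame nc_ratio
#> 1   marker     1 4.027573
#> 2   signal     1 1.002610
#> 15  marker     8 4.023084
#> 16  signal     8 2.072079
#> 27  marker    16 4.022178
#> 28  signal    16 3.041729
```

The marker channel was simulated at a constant true N/C ratio of 4; the
signal channel ramps from 1 to 3 over 450 s (true values 1.0, 2.07 and
3.0 at frames 1, 8, 16) — the measured per-frame medians track both within
about 1%.

```r
curve <- read_frap_csv(system.file("extdata",
                                   "example_synthetic.frap_curve.csv",
                                   package = "fabquant"))
fit_double_exponential(curve)
#> frap_fit: P1=0.3788 k1=0.482/s  P2=0.3035 k2=0.05174/s  C=0.3107
#>   t1/2=6.757 s, rms=0.009904 (n=87)
```

The packaged curve is synthetic (generated from the association model with
P1=0.4, k1=0.5 s⁻¹, P2=0.3, k2=0.05 s⁻¹, C=0.3 and 1% noise); the fitted
half-time 6.76 s sits next to the generating value of 6.73 s.

See `vignettes/quantifying-live-embryo-imaging.Rmd` for the model,
parameter and validation details.

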
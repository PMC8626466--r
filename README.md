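# sbnpmosaic

Wide-field mosaicking, nerve tracing and quantification for in vivo
confocal microscopy (IVCM) of the corneal subbasal nerve plexus (SBNP).

A single IVCM frame covers roughly 400 × 400 µm of the cornea — far too
little to characterize the SBNP, whose architecture (radiating nerve
fiber bundles converging on an inferocentral whorl) spans millimetres.
Clinically useful nerve metrics such as the corneal nerve fiber length
density (CNFL, mm of nerve per mm²) and branch density (CNBD, branch
points per mm²) are therefore best measured on wide-field mosaics
assembled from many overlapping frames. `sbnpmosaic` implements that
pipeline end to end for researchers working with raster-scanned corneal
IVCM sequences:

1. **Tissue filtering** — one-vs-rest linear SVMs over a
   bag-of-visual-words texture descriptor remove epithelium and stroma
   frames, keeping only the SBNP.
2. **Registration** — FFT phase correlation between all frame pairs
   (block-downscaled by 3) and between their 12 horizontal sub-images
   (downscaled by 2), the decomposition that compensates the row-wise
   motion distortion of line-scanning microscopes. Matches are verified
   by the normalized cross-correlation of clamped high-pass residuals.
3. **Global alignment** — the accepted translations `d_ij = p_j − p_i`
   form a sparse linear system over sub-image positions, regularized by
   an anchor `λ₁p₀ = 0` and intra-frame smoothness
   `λ₂(p_{i+1} − p_i) = 0`, and solved robustly (confidence weights,
   Huber reweighting, residual rejection) by least squares.
4. **Rendering** — per-row position interpolation and feathered
   weighted averaging produce the mosaic; invalid pixels stay black and
   are excluded from all areas.
5. **Nerve tracing** — white top-hat equalization, a log-Gabor filter
   bank, thresholding, skeletonization and Dijkstra-based gap bridging
   yield a centerline graph with branch points.
6. **Quantification** — mosaic area, enhancement factor
   (area / 0.16 mm²), mCNFL, mCNBD, and whorl-region wCNFL/wCNBD in
   four configurations (800 / 400 µm diameter discs, full or superior
   half), plus Bland–Altman inter-observer agreement statistics for
   inflammatory-cell density tables.

A fully seeded synthetic IVCM generator — phantom plexus, serpentine
raster scan, smooth per-row motion drift, acquisition noise, interleaved
non-SBNP frames — provides ground truth for every stage, and all
validation in the package runs against it. The methods vignette
(`vignettes/sbnp-mosaicking-methods.Rmd`) describes the models,
parameter choices and limitations in detail.

## A worked example

Simulate an eye — a 3 × 3 raster over a synthetic plexus with motion
drift, noise and interleaved non-SBNP frames — and run the pipeline:

```r
library(sbnpmosaic)

plexus <- generate_plexus(canvas_um = c(3000, 3000), seed = 42)
plexus
#> <sbnp_plexus: 3.0 x 3.0 mm, 70 centerlines, 81.40 mm total, 22 branch + 172 crossing points>

plan <- scan_plan(plexus, grid = c(3, 3), overlap = 0.5)
acq <- sample_frames(plexus, plan, motion_model(3, 64),
                     noise_sd = 4, insert_rate = 0.4, seed = 43)
table(acq$truth$frames$label)
#> epithelium       sbnp     stroma
#>          7          9          2

result <- run_eye(acq$frames, sbnp_config(), subject_id = "01", eye = "RE")
result
#> <eye_record 01_RE: 0.64 mm2, EF 4.0, mCNFL 26.56 mm/mm2>
result$mosaic
#> <sbnp_mosaic: 770 x 773 px, 0.64 mm2 valid, 9 frames, component 1>
result$graph
#> <nerve_graph: 459 edges, 17.178 mm total, 45 branch points>
round(as.data.frame(result$metrics)[, c("area_mm2", "enhancement_factor",
                                        "mcnfl", "mcnbd")], 2)
#>   area_mm2 enhancement_factor mcnfl mcnbd
#> 1     0.64                  4 26.56  70.3
```

The tissue filter identified and removed all 9 non-SBNP frames, the
nine SBNP frames assembled into a single 0.64 mm² mosaic (an enhancement
factor of 4 single fields), and tracing measured 17.2 mm of nerve —
an mCNFL of 26.6 mm/mm² in this whorl-centred, nerve-dense region.
`autoplot(result$mosaic)` and `autoplot(result$graph)` visualize the
mosaic and the traced centerlines.

Inter-observer agreement for cell-density tables:

```r
bland_altman(c(31, 12, 58, 24, 40), c(28, 15, 55, 30, 37))
#> <bland_altman: n 5, mean diff 0.00, SD 4.24, 95% LOA [-8.32, 8.32], r 0.98>
```

`glance()`, `tidy()` and `autoplot()` methods provide tibble summaries
and the standard Bland–Altman plot; `agreement_report()` lays out the
statistics per cell type.

A thin command-line wrapper with `simulate`, `run-eye`, `run-cohort` and
`agreement` subcommands is installed at `inst/cli/sbnpmosaic`.

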
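# contoureval

Multi-observer evaluation of tumour contouring studies in R.

When a panel of clinicians contours the same structure — to characterise
inter-observer variability, or to evaluate a new (e.g. deep-learning
assisted) contouring tool against manual delineation — the analysis is
always the same shape: build a consensus contour per case, score every
individual contour against it, map where on the surface the panel
disagrees, and account for how the annotators' time was spent. This package
implements that pipeline end to end:

* **STAPLE consensus** (`staple()`): binary
  Simultaneous Truth And Performance Level Estimation by EM, estimating a
  per-voxel posterior weight map `W_i` together with each rater's
  sensitivity `p_j = P(rater 1 | truth 1)` and specificity
  `q_j = P(rater 0 | truth 0)`, with a dilated-union ROI, log-space E-step
  and deterministic initialisation.
* **Agreement metrics** (`dsc()`, `added_path_length()`,
  `contour_length()`): Dice similarity coefficient
  `DSC(A,B) = 2|A∩B|/(|A|+|B|)` and the added path length — the length of
  the reference contour farther than a distance tolerance (default 2 mm)
  from the test contour, i.e. the path an editor would still have to draw —
  computed slice-wise on exposed voxel edges and reported relative to the
  reference contour length.
* **Surface deviation maps** (`extract_surface()`, `signed_deviation()`,
  `deviation_percentiles()`): exact anisotropy-aware signed distances from
  every consensus surface element to each annotator's contour, with
  element-wise 10/30/50/70/90th percentiles and the 10–90 range projected
  on the consensus shape.
* **Interaction-time analytics** (`segment_timeline()`,
  `summarize_times()`, `observation_histogram()`): session event logs
  segmented into *active* (dragging), *observation* and *excluded*
  (interruption gaps > 85 s) time, tool composition, interval histograms
  and paired relative changes between methods.
* **Statistics** (`wilcoxon_signed_rank()`, `summarize_values()`): paired
  Wilcoxon signed-rank comparisons (exact where feasible) and standard
  descriptive summaries.
* **A synthetic observer-study generator** (`generate_base_shape()`,
  `simulate_annotator_contours()`, `simulate_voxelflip_raters()`,
  `simulate_interaction_log()`): star-convex tumour-like shapes,
  annotator panels with separable inter-/intra-observer boundary
  variability, raters with known voxelwise performance, and
  renewal-process session logs — so the full pipeline runs, and is tested,
  with no clinical data.

Masks are read and written as NIfTI (`read_mask()`/`write_mask()`, axis
order `(z, y, x)`, all distances in mm via the header spacing); logs as
JSON Lines or CSV; studies are driven by a YAML/JSON config or manifest
(`run_study()`).

## Worked example

Simulate a five-annotator panel around one tumour-like shape, build the
consensus, and score one annotator:

```r
library(contoureval)

cfg <- shape_config(grid_shape = c(40, 56, 56), spacing_mm = c(2, 1, 1),
                    base_radius_mm = 14, irregularity = 0.25, lobe_count = 3)
base <- generate_base_shape(cfg, seed = 42)
base
#> <binary_mask> 40 x 56 x 56 voxels (z,y,x), spacing 2 x 1 x 1 mm, 5885 foreground

panel <- annotator_panel_config(n_annotators = 5, sigma_inter_mm = 2.8,
                                sigma_intra_mm = 1.35, seed = 42)
masks <- lapply(simulate_annotator_contours(base, panel, n_sessions = 1),
                `[[`, 1)

cons <- staple(masks)
cons
#> <staple_result> 5 raters, 20 iterations (converged), prior 0.083
#>   consensus: 7840 voxels; sensitivity 0.639-0.690, specificity 0.982-0.989

added_path_length(cons$consensus_mask, masks$A1, tolerance_mm = 2)
#> <metric_record> DSC 0.769 | APL 992.0 mm (relative 0.410) at 2.0 mm tolerance; reference 2418.0 mm

surf <- extract_surface(cons$consensus_mask)
devs <- vapply(masks, function(m) signed_deviation(cons$consensus_mask, m),
               numeric(nrow(surf$voxel)))
deviation_percentiles(devs, surface = surf)
#> <deviation_map> 2637 surface elements x 5 annotators; median of medians -1.00 mm; max 10-90 range 8.62 mm
```

Reading the numbers: this panel's boundary displacement SD (2.8 mm
between annotators on a ~14 mm radius shape) yields a DSC of 0.77 against
the consensus and a relative APL of 0.41 — an editor starting from this
annotator's contour would still need to draw 41% of the consensus path.
The estimated sensitivities (~0.65) say each annotator covers about
two-thirds of the probabilistic consensus volume; the deviation map
locates the disagreement, with a 10–90 percentile spread of up to 8.6 mm
at the most contested surface element.

A whole two-arm study (9 annotators × 10 cases × {manual, dl}) is one
call; it writes consensus masks, metric/time tables, deviation maps with
figures, statistics and a provenance-stamped report:

```r
report <- run_study(default_study_config(seed = 1), out_dir = "study_out")
report
#> <study_report> 10 cases x 9 annotators, methods: manual, dl
#>   manual consensus DSC 0.736 +/- 0.030, relative APL 0.474
#>   dl     consensus DSC 0.772 +/- 0.023, relative APL 0.415
#>   intra-observer DSC 0.813 +/- 0.019
#>   mean relative active-time change -0.226 (Wilcoxon p = 1.7e-15)
```

The same entry point analyses real data: set `simulate: false` and point
`manifest:` at a table of `(annotator_id, case_id, method, session,
mask_path, log_path)` records. A thin command-line wrapper is at
`scripts/run_study.R`; the bundled study config is
`inst/extdata/default_study.yaml`. See the methods vignette
(`vignettes/contour-evaluation-methods.Rmd`) for the model, every tunable
default, and what the synthetic cohort does and does not emulate.

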
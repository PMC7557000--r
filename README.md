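# islet3d

Whole-organ 3D quantification of pancreatic islets of Langerhans and their
innervation from cleared-tissue light-sheet volumes.

Tissue clearing (iDISCO+, ECi) plus light-sheet microscopy yields
multi-channel 3D images of the entire pancreas: insulin marks β cells,
NF200 (or TH / VAChT) marks nerve fibers and intrapancreatic ganglia.
Published analyses of such data lean on proprietary "surface" tools whose
operators are not reproducible outside the vendor software. `islet3d`
reimplements that quantification as explicit, tested operators for anyone
studying islet biology or diabetic neuropathy of the pancreas:

- **Segmentation** — the surface workflow made explicit: Gaussian
  pre-smoothing with FWHM equal to the *smoothing factor*, a local-contrast
  baseline estimated by Gaussian blur with `σ = threshold factor / 2`,
  subtraction, Otsu (or absolute) thresholding with a robust noise floor,
  and 3D connected components under 6- or 26-connectivity. Presets carry
  the published factors: islet smoothing 10 µm at 1.3× and 3.25 µm at 4×,
  islet background equal to the largest islet diameter (default 250 µm),
  nerve background 12.2 µm. TH⁺ β cells are excluded by the codified rule
  (volume < 120 µm³, residing in an insulin⁺ islet, overlapping insulin).
- **Distance geometry** — exact anisotropy-aware Euclidean distance
  transforms; per-islet minimum nerve distance with *innervated* defined as
  distance 0 (voxel contact) and a secondary <1.6 µm near-nerve bin;
  intra-islet nerve volume; ganglion detection (compact NF200⁺ objects,
  volume 20,000–400,000 µm³, sphericity ≥ 0.4) with density per mm³ and
  distance to the nearest islet; per-cell nerve contacts at confocal
  resolution with watershed cell splitting.
- **Quantification and statistics** — β-cell volume percent, islets/mm³,
  the 1,000 / 50,000 / 500,000 µm³ volume bins, endocrine vs exocrine nerve
  density, innervated vs non-innervated comparison, equivalent sphere
  diameter `d = 2(3V/4π)^{1/3}`, normalized insulin intensity; Shapiro-Wilk
  gated tests (t / ANOVA+Tukey vs Mann-Whitney / Kruskal-Wallis+Dunn,
  α = 0.05), exact order-statistic median CIs, normality-gated correlation.
- **Synthetic phantoms** — ground-truthed multi-channel volumes whose
  generative parameters are calibrated to published whole-pancreas values
  (β volume 1.31 % of tissue; 6.1 % of islets innervated carrying 43 % of
  islet volume; >6-fold endocrine:exocrine nerve density; ganglia at
  21.5 /mm³, 83,467 µm³, 47.3 µm from islets; 9.4 % of β cells contacting
  nerves), with presets for diabetic NOD, streptozotocin (STZ) day 5/15 and
  human donor conditions. Every pipeline stage is testable at desk scale
  with no data download.

## Worked example

```r
library(islet3d)

ph  <- generate_phantom("mouse_c57_default", seed = 42, noise = FALSE)
isl <- segment_islets(ph$grid)
nrv <- segment_nerves(ph$grid)
rec <- islet_nerve_distances(isl, object_mask(nrv))

tissue <- ph$grid$region_mask > 0
summ <- region_summary(rec, object_mask(nrv), tissue, ph$grid$voxel_size_um,
                       region_mask = ph$grid$region_mask,
                       tissue_mean_intensity = mean(ph$grid$channels$insulin[tissue]))
summ[summ$scope == "total",
     c("beta_volume_percent", "pct_innervated", "innervated_volume_share_pct")]
#>   beta_volume_percent pct_innervated innervated_volume_share_pct
#> 1             1.30855       4.918033                    42.18792
```

Read: β cells occupy 1.31 % of the phantom pancreas volume, 4.9 % of the
61 segmented islets touch an NF200⁺ fiber, and that handful of islets
carries 42 % of the total β-cell volume — the innervated islets are an
order of magnitude larger than the rest (`innervated_comparison(rec)`
reports the mean-volume ratio, 14.1 here).

Multi-sample studies run from a YAML config (`run_study()`, `report()`,
`write_results()`), or from the shell via
`Rscript inst/cli/islet3d.R <simulate|run|report> ...`.

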
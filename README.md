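# fdmap

Spatial inverted encoding models for neural feature dimension maps.

## What this package is for

Attention theory posits that visual cortex maintains spatial "feature
dimension maps" — one per feature dimension such as color or motion — whose
activation is reweighted by task goals. A central open question is whether
attending a feature dimension enhances only the map location containing the
stimulus (**local enhancement**) or lifts the whole map additively
(**global enhancement**, visible even at locations with no stimulus).
Distinguishing the two requires reconstructing *where* in the visual field
a region's multi-voxel activation pattern places its activity, which
univariate region averages cannot do.

`fdmap` is for researchers who want to run — or validate end-to-end — that
multivariate analysis. It provides:

* a spatial **inverted encoding model (IEM)**: k = 37 raised-cosine
  channels `f(r) = (0.5 + 0.5 cos(πr/s))^7` (r < s) on a hexagonal grid
  (2.83° spacing), trained on independent mapping-task data by OLS
  (`B₁ = C₁W`, `Ŵ = (C₁ᵀC₁)⁻¹C₁ᵀB₁`) and inverted on attention-task
  patterns (`Ĉ₂ = B₂Ŵᵀ(ŴŴᵀ)⁻¹`) to yield pixelized visual-field maps;
* **map quantification**: disk means at the stimulus and opposite
  locations, spatial selectivity (stimulus − opposite, immune to map-wide
  offsets), and the attention modulation index (AMI = motion − color);
* the **permutation statistical framework**: within-subject shuffling with
  a single seed, parametric statistics (repeated-measures ANOVA with
  partial η², paired t with d_z) with permutation p-values, BH-FDR,
  Cousineau–Morey within-subject SEM, and noncentral-t power analysis;
* a **synthetic BOLD generator**: compressive-spatial-summation Gaussian
  receptive fields, the full mapping/attention trial schedules, HRF
  convolution at TR = 0.75 s, Gaussian noise, and configurable local vs.
  global attentional gain regimes with ground truth for recovery testing.

## Worked example

Simulate a 8-subject experiment under the local-enhancement regime, run
the full pipeline (fit encoding models from mapping runs, invert and
quantify every attention trial, permutation tests), and inspect the
statistics:

```r
library(fdmap)
cfg <- sim_config(regime = "local", n_subjects = 8, n_voxels_per_roi = 120,
                  n_attention_runs = 4)
res <- run_pipeline(cfg, master_seed = 7, n_iter = 1000)
print(res$stats[, c("roi", "test", "t", "d_z", "p_perm", "p_fdr")], digits = 3)
#>      roi               test      t    d_z p_perm  p_fdr
#> 1  color        stim_C_vs_M  4.038  1.428  0.000 0.0000
#> 2  color    opposite_C_vs_M -1.081 -0.382  0.310 0.3543
#> 3  color selectivity_C_vs_M  3.267  1.155  0.005 0.0133
#> 4  color   ami_stim_vs_zero -4.038 -1.428  0.000 0.0000
#> 5 motion        stim_C_vs_M -3.685 -1.303  0.014 0.0224
#> 6 motion    opposite_C_vs_M -0.948 -0.335  0.357 0.3570
#> 7 motion selectivity_C_vs_M -2.172 -0.768  0.047 0.0627
#> 8 motion   ami_stim_vs_zero  3.685  1.303  0.012 0.0224
aggregate(ami ~ roi, res$ami, mean)
#>      roi         ami
#> 1  color -0.01840076
#> 2 motion  0.01934260
```

Reading the table: `stim_C_vs_M` compares disk-mean map activation at the
stimulus location between attend-color and attend-motion (positive t =
stronger under attend-color); `opposite_C_vs_M` does the same at the empty
location opposite fixation; `selectivity_C_vs_M` compares stimulus − 
opposite. Under this local regime each region represents the stimulus more
strongly when its preferred dimension is attended (significant selectivity
differences, opposite signs in the two regions), the opposite location is
unaffected (p ≈ 0.3), and the AMI is negative in the color map and positive
in the motion map — the signature that distinguishes local from global
enhancement (rerun with `regime = "global"` to see the reverse pattern:
opposite-location effects appear and selectivity differences vanish).

The power computation used to justify a sample size for a strong paired
effect:

```r
paired_t_min_n(d_z = 1.24, alpha = 0.05, power = 0.80, tail = "one.sided")
#> [1] 6
```

## Documentation

The methods vignette (`vignettes/feature-dimension-maps.Rmd`) describes
the model, the statistical framework, the synthetic generator and its
default study conditions, and the numerical design choices (per-voxel
scaling, alignment strategies, window conventions) in detail.
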
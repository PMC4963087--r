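# isozone

Mapping the zone of influence of a plant invader from multi-tracer foliar
isoscapes.

## What it does, and for whom

Ecologists studying plant–plant interactions — in the motivating system, the
invasion of Portuguese dune vegetation by the N₂-fixing shrub *Acacia
longifolia* — measure functional tracers in the foliage of a native indicator
species on a spatial lattice: nitrogen concentration (g N kg⁻¹), δ¹⁵N and
δ¹³C (‰). `isozone` turns such georeferenced point measurements into an
objective, unsupervised map of *regions of influence*:

1. **Isoscapes** — each tracer is interpolated by ordinary kriging. The
   semivariogram γ(h) is estimated with cutoff = ⅓ of the plot diagonal,
   fitted by weighted least squares (weights N_j/h_j²) for six model
   families, and the (model, lag-segmentation) pair is selected by
   leave-one-out cross-validation (smallest RMSE, ties to the higher R² of
   predicted-on-measured).
2. **Zoning** — the stacked cell × tracer matrix is clustered with Gaussian
   mixtures under the ten covariance parameterizations
   Σ_k = λ_k D_k A_k D_kᵀ (EII … VVV), fitted by EM; the number of zones is
   the *beginning of the plateau* of BIC = 2ℓ − m·log n.
3. **Harmonization** — zones from different plots are matched by UPGMA on
   the per-zone tracer medians (Euclidean distance, unscaled) cut at the
   silhouette-optimal number of final clusters.

Kruskal–Wallis tests with an α-corrected mean-rank post-hoc and compact
letter displays summarize between-zone contrasts. A synthetic-plot generator
with canopy-distance influence kernels (exponential decay for N and δ¹⁵N, a
hump-shaped kernel for δ¹³C) provides ground-truth zones for verification.

## Worked example

```r
library(isozone)

# simulate one invaded 20 x 50 m plot (2 x 5 m subplot lattice, 100 samples)
scen <- dune_study_scenarios(seed = 1)
plot1 <- generate_plot(scen[["1"]])
plot1$samples[1:3, ]
#>   x   y   n_conc      d15N      d13C
#> 1 1 2.5 6.540982 -10.88999 -26.53402
#> 2 3 2.5 6.722043 -10.44787 -26.44015
#> 3 5 2.5 7.064295 -10.55713 -26.07999

# full per-plot analysis: CV-selected kriging + mixture zoning
an <- analyze_plot(plot1$samples, plot1$canopies,
                   settings = pipeline_settings(
                     resolution = 0.5,
                     models = c("exponential", "spherical", "gaussian"),
                     k_range = 1:10))
an$zonemap
#> <zone_map> 7 zones (VVV, tau=0.01); sizes: 1143, 485, 491, 416, 138, 777, 550
subset(an$selection$d15N$report, chosen)
#>          model segmentation      rmse r_squared n_params converged chosen
#> 13 exponential  uniform 4 m 0.7964263 0.9618535        3      TRUE   TRUE
an$summary$table[, c("zone", "median_n_conc", "median_d15N", "median_dist")]
#>   zone median_n_conc  median_d15N median_dist
#> 1    1      6.349092 -10.57975427   10.000000
#> 2    2      6.727995  -9.66104757    7.000000
#> 3    3      7.346613  -8.69280439    5.147815
#> 4    4      8.315837  -6.99707417    3.500000
#> 5    5      9.478444  -5.43476212    2.500000
#> 6    6     10.592915  -3.15714519    1.000000
#> 7    7     12.589058   0.06633531    0.000000
```

The mixture settled on an ellipsoidal (VVV) model with seven zones; zones
are relabelled by ascending median N concentration, so zone 1 is the
low-nitrogen background. The median canopy distance — which was *not* a
clustering variable — decreases monotonically from zone 1 (10 m) to zone 7
(0 m, under the canopy, where median δ¹⁵N reaches 0.07‰, the atmospheric
signature of invader-fixed nitrogen). `harmonize()` then matches zones across plots and
`harmonized_raster()` paints the final clusters back onto each grid. The
file-based pipeline (`run_pipeline()` on a YAML config, or the
`inst/exec/isozone` command-line wrapper with subcommands
`simulate | run | interpolate | cluster | harmonize`) writes all isoscapes,
zone rasters, CV reports, BIC surfaces, the dendrogram (Newick) and a JSON
run manifest with checksums.

To attempt a replication of the original field analysis, place a
transcription of the published supplementary tracer tables under a directory
(`plot1.csv` … `plot3.csv` plus canopy polygons) and call
`replicate_field_study()`; it sweeps the plateau threshold τ over
0.005–0.05 and reports zone counts, the final harmonized k and the plot-1
N-isoscape maximum for each τ.

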
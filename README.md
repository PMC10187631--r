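# bordermap

Multi-scale quantification of repolarization and cardiomyocyte
heterogeneity in the myocardial-infarction border zone (BZ), for
cardiac electrophysiologists and computational biologists working with
post-infarct large-animal or clinical-style data.

After a reperfused infarct, the BZ — the rim of surviving myocardium
around the scar, mapped as bipolar voltage 0.5–1.5 mV or late
gadolinium enhancement (LGE) 20–70% of maximum — is the dominant
arrhythmia source. `bordermap` quantifies the hypothesis that
*cell-to-cell variability* of BZ cardiomyocyte remodeling underlies
this vulnerability, at four scales with matched estimators:

| scale | measurement | heterogeneity statistic |
|---|---|---|
| in vivo map | activation–recovery interval ARI = RT − AT per electrogram (Wyatt: AT at min dV/dt of the QRS, RT at max dV/dt of the T wave) | local SD of ARIs within a 1-cm radius of each endocardial point; per-animal regional summaries; OLS of VT-inducibility index on BZ heterogeneity |
| cell populations | APD25/50/90 from voltage-dye traces (10-beat average of a 15-s, 1-Hz record; APDx = upstroke → (1−x) crossing) | per-animal, per-region SD of APD90 (and of cell width/length) |
| single-nucleus RNA | PC-space embedding of gene × nucleus counts | mean Euclidean distance of each nucleus to its region's other nuclei (nested t test); HVGs = genes with ≥ 1.5-fold higher biological overdispersion in BZ at EFDR < 0.10; pseudobulk DEGs (P_adj < 0.05, \|log2FC\| > 0.25); NPPB+ fractions, subcluster composition |
| imaging | per-angle radial wall thickness from short-axis segmentations, LGE region labels, contour curvature | per-slice regional variance σ² of thickness; SD of σ² across slices |

A first-class synthetic-data generator (`synth_config()`, `gen_*()`)
produces all four data types with planted regional effects and complete
ground-truth tables, so the whole pipeline is testable without any
animal data.

## Worked example

```r
library(bordermap)

cfg <- synth_config(seed = 1)   # study-like defaults, see ?synth_config
report <- run_pipeline(cfg)
report
#> <bordermap_report>
#>   bz_ari_local_sd              4.472
#>   remote_ari_local_sd          2.434
#>   inducibility_slope           0.883
#>   inducibility_r_squared       0.7684
#>   bz_apd90_sd                  106.6
#>   remote_apd90_sd              71.95
#>   bz_distance_median           4.978
#>   remote_distance_median       4.056
#>   nested_test_p                0.0007088
#>   n_hvg                        12
#>   n_deg                        85
#>   n_hvg_and_deg                2
#>   nppb_fraction_bz             0.3558
#>   nppb_fraction_remote         0.05083
#>   bz_wall_variance             1.923
#>   remote_wall_variance         0.5101
```

Reading the output: BZ repolarization is more heterogeneous in vivo
(local ARI SD 4.5 vs 2.4 ms over five synthetic animals), arrhythmia
inducibility rises with BZ heterogeneity across eight animals (slope
0.88 index/ms, R² 0.77), BZ cardiomyocyte populations have wider APD90
distributions (SD 107 vs 72 ms), BZ nuclei are transcriptomically
farther apart (median PC-space distance 4.98 vs 4.06, nested t test
p < 0.001), 12 genes are called highly variable and 85 differentially
expressed (2 both), one third of BZ cardiomyocyte nuclei are NPPB+
(vs 5% remote), and BZ wall thickness is more variable (σ² 1.92 vs
0.51 mm²) — the joint cross-scale pattern the package quantifies.

Individual stages are plain functions: `gen_endocardial_map()` →
`map_ari()` → `local_heterogeneity()` → `regional_summary()`;
`gen_optical_population()` → `measure_apd()` →
`population_dispersion()`; `gen_counts()` → `normalize_and_embed()` →
`cell_cell_distance()` / `dispersion_analysis()` /
`differential_expression()`; `gen_lv_slices()` → `wall_thickness()` →
`wall_variance()`. Standard interchange formats are supported
(`write_counts_mtx()`/`read_counts_mtx()` for 10x-style Matrix Market
triplets, JSON maps, two-column trace CSVs).

The methods vignette
(`vignettes/border-zone-heterogeneity.Rmd`) documents the models,
the generator's planted conditions, every tunable threshold, and the
package's statistical design decisions.

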
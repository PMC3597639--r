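# cxplaque

Quantification of astrocyte connexin gap-junction plaques in retinal
wholemounts from six-marker spectral confocal imaging — with a fully
ground-truthed synthetic benchmark, so the entire analysis chain is
testable without any real images.

## What it does

Retinal astrocytes form gap junctions from four connexin isoforms (Cx26,
Cx30, Cx43, Cx45). Imaging all four together with GFAP (astrocytes) and GS
isolectin B4 (vessels) requires six overlapping fluorophores, acquired as a
**lambda stack** (32 spectral bins, 411–754 nm) and separated by **linear
unmixing**: each voxel spectrum *s* is decomposed against reference emission
fingerprints *B* by solving

```
min ‖s − B x‖₂   subject to  x ≥ 0      (per voxel)
```

The unmixed connexin channels are thresholded and labeled into 3D objects,
objects from different channels that overlap are merged into **plaques**,
each plaque gets a combination class (one of the 15 nonempty subsets of
{Cx26, Cx30, Cx43, Cx45}) and a compartment (**parenchymal** vs
**vascular**, by distance to the vessel mask). Counts per field are
converted to densities (mm⁻²), whole-retina totals, percent change between
age groups (truncated toward zero, the convention of the reference
quantification this package re-derives), and one-way ANOVA with Bonferroni
post-hoc comparisons across ages.

The package is organized as composable stages, each exposed as plain R
functions: `build_scene()` / `render_lambda_stack()` (synthetic fields with
planted ground truth), `extract_reference_spectra()` / `linear_unmix()`,
`segment_channel()` / `measure_objects()`, `merge_channels()` /
`assign_compartment()`, `aggregate_fields()` / `density_to_total()` /
`percent_change()`, `anova_bonferroni()`, and `run_pipeline()` for the
end-to-end cohort. A thin CLI (`inst/cli/cxplaque`) wraps the same
functions as `simulate / unmix / segment / classify / quantify / stats /
run-all` subcommands.

## Worked example

Simulate one nerve-fibre-layer field, image it through the six-dye forward
model, and recover the planted plaques:

```r
library(cxplaque)

sc    <- scene_config(field_shape = c(3L, 128L, 128L), seed = 42L)
truth <- build_scene(sc)              # planted plaques, vessels, astrocytes
refs  <- default_spectra()
refs
#> reference_spectra: 6 fluorophores x 32 bins (411-754 nm), condition 4.1
#>   AMCA      -> GS-lectin
#>   Alexa488  -> Cx43
#>   Alexa532  -> Cx26
#>   Cy3       -> Cx30
#>   Alexa594  -> Cx45
#>   Cy5       -> GFAP

field <- process_field(truth, refs, run_config(scene = sc))
head(field$plaques[, c("plaque_id", "class", "compartment", "n_voxels", "size_um3")])
#>   plaque_id          class compartment n_voxels size_um3
#> 1         1           Cx26 parenchymal        6  3.85728
#> 2         2 Cx26/Cx30/Cx43 parenchymal        2  1.28576
#> 3         3           Cx26 parenchymal        2  1.28576
#> 4         4           Cx45 parenchymal        7  4.50016
#> 5         5           Cx30    vascular        4  2.57152
#> 6         6           Cx26 parenchymal        4  2.57152
nrow(field$plaques)   # 36 of the 38 planted plaques recovered
```

Each row is one gap-junction plaque: its connexin combination class, its
compartment call from vessel proximity, and its size (voxels and µm³ at
0.28 × 0.28 × 8.2 µm voxels).

The percent-change arithmetic on the bundled printed totals table:

```r
tab <- percent_change_table(table2_totals())
head(tab[tab$compartment == "parenchymal",
         c("class", "total_3mo", "total_22mo", "percent", "printed_percent")], 5)
#>      class total_3mo total_22mo percent printed_percent
#>       Cx26  924662.2   437637.8     -52             -52
#>       Cx30  592002.0  4355278.7     635             636
#>       Cx43  428717.9  1185838.8     176             176
#>       Cx45  267653.5   758149.4     183             183
#>  Cx26/Cx30   11168.9     8912.0     -20             -20
```

All 25 internally consistent integer rows reproduce exactly under
truncation toward zero; the Cx30 row is a documented printing anomaly (its
own totals give +635.69, which truncates to 635 and rounds to the printed
636 — see the methods vignette).

A full simulated cohort (2 ages × 4 retinas × 24 fields, planted 6-fold
Cx30 increase, flat Cx43) runs in a few minutes:

```r
res <- run_pipeline(run_config(seed = 1L))
res$percent_change[res$percent_change$class %in% c("Cx30", "Cx43"), ]
#>    compartment class total_start   total_end percent percent_raw
#>  9 parenchymal  Cx30   253859.02 1593998.500     527  527.906977
#> 13 parenchymal  Cx43   193556.96  198617.273       2    2.614379
#> 24    vascular  Cx30    24326.90  149000.364     512  512.492207
#> 28    vascular  Cx43    15336.61   14952.783      -2   -2.502666
```

The planted +500% Cx30 change is recovered within ±15% relative in both
compartments and Cx43 stays flat; the output directory contains the
per-retina totals, group summaries, percent-change table, ANOVA report,
the serialized configuration, and a checksum manifest.

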
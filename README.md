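# ngmscreen

Untargeted LC-QTOF-MS metabolomics screening for inborn errors of
metabolism (IEM), as a self-contained R package.

In next-generation metabolic screening, a patient's plasma is profiled by
liquid chromatography / quadrupole time-of-flight mass spectrometry
alongside the other patients of the same batch, pooled QC injections and
spiked validation plasma. Instead of targeting a fixed metabolite list,
every aligned mass feature is tested for being an outlier in the target
patient relative to the co-acquired patients, and significant features
are annotated against a diagnostic panel (m/z + retention time) and a
compound library (m/z only).

## What the package computes

For a feature with patient mean intensity $x_p$ and reference
intensities $x_1,\dots,x_n$ from the other patients in the batch:

- **fold change** $\mathrm{FC} = x_p / \max(\mathrm{median}(x), \mathrm{floor})$
- **robust z-score**
  $z = (x_p - \mathrm{median}(x)) / \max(1.4826\,\mathrm{MAD}(x),\ 0.05\,\mathrm{median}(x),\ \mathrm{floor})$,
  with two-sided $p = 2\Phi(-|z|)$
- a feature is flagged **altered-up** when $z \ge 3$ and
  $\mathrm{FC} \ge 2$ (down: $z \le -3$, $\mathrm{FC} \le 0.5$)

Upstream of that: exact monoisotopic mass and adduct/isotopologue m/z
arithmetic ($m/z = (nM + \Delta_{\mathrm{adduct}} + k\,\delta_{13C})/z$,
electron-corrected), single-linkage feature alignment across injections
(5 ppm, 0.5 min), SHA-256–verified batch I/O (TSV and centroided mzML via
`mzR`), QC/validation gating, and an interpretation layer with immutable
result records, filter presets and an append-only audit log. A
deterministic, stream-keyed batch simulator (`synth`) stands in for the
instrument, so the entire pipeline is testable offline. See the methods
vignette (`vignettes/ngmscreen-methods.Rmd`) for the full model.

## Worked example

The bundled scenario simulates a 20-patient batch (2 injections each,
3 QC-pool and 2 validation-plasma injections per mode) in which patient
P01 carries a very-long-chain acyl-CoA dehydrogenase deficiency (VLCADD)
profile: nine long-chain acylcarnitines spiked at folds between 29 and
1227.

```r
library(ngmscreen)
cfg   <- session_config()           # 5 ppm, 0.5 min, z >= 3, FC >= 2
batch <- simulate_batch(vlcadd_scenario(seed = 17))
res   <- screen_sample(batch$peaklists, batch$worklist, "P01", cfg)

# gate the session on QC standards and validation plasma
defs <- builtin_standards("positive")
qc   <- qc_metrics(recover_standards(batch$peaklists, defs,
                                     cfg$mz_tolerance_ppm,
                                     cfg$rt_tolerance_min), defs)
val  <- screen_sample(batch$peaklists, batch$worklist, "VAL_PLASMA", cfg)
vr   <- validation_report(val$records, validation_spikes(), builtin_panel())
qc[, c("standard", "kind", "worst_abs_ppm", "rt_delta_pct",
       "response_cv_pct", "overall_pass")]
#>        standard     kind worst_abs_ppm rt_delta_pct response_cv_pct
#> 1 Tryptophan_IS internal      4.839100    2.2502462        17.18044
#> 2  Hippurate_IS internal      4.956594    2.0222648        19.19043
#> 3 CholicAcid_ES external      4.309886    0.8354309        17.55666
#>   overall_pass
#> 1         TRUE
#> 2         TRUE
#> 3         TRUE
session_gate(qc, vr$gate)
#> [1] TRUE

# diagnostic view: altered features with panel annotation
hits <- apply_filters(res$records, diagnostic_preset())
main <- hits[hits$adduct %in% "M+H" & hits$isotope %in% 0L, ]
main <- main[order(-main$fold_change), ]
print(main[, c("feature_id", "mz", "rt", "compound", "fold_change",
               "z", "p_value")], row.names = FALSE, digits = 4)
#>  feature_id    mz    rt                  compound fold_change       z p_value
#>      F00151 398.3 14.09     Hexadecenoylcarnitine     1385.12 7193.09       0
#>      F00133 370.3 13.37    Tetradecenoylcarnitine      398.41 3412.34       0
#>      F00138 372.3 13.81    Tetradecanoylcarnitine      371.65 1928.55       0
#>      F00129 368.3 12.81 Tetradecadienoylcarnitine      153.97  518.94       0
#>      F00166 424.3 14.32        Linoleoylcarnitine       74.53  373.35       0
#>      F00168 426.4 14.69           Oleoylcarnitine       68.97  321.28       0
#>      F00156 400.3 14.52        Palmitoylcarnitine       63.89  381.98       0
#>      F00124 344.3 12.24       Dodecanoylcarnitine       47.97  336.86       0
#>      F00170 428.4 15.08         Stearoylcarnitine       29.49   99.09       0
```

All nine spiked acylcarnitines are recovered as altered-up,
panel-annotated features, with fold-change estimates close to the
simulated folds (e.g. Stearoylcarnitine 29.49 vs a true fold of 29.269).
The theoretical ion table is exact; for example the protonated
tetradecenoylcarnitine ion:

```r
round(ion_mz(monoisotopic_mass("C21H39NO4"), "M+H"), 3)
#> [1] 370.295
```

## Command line

`exec/ngms` wraps the same functions for shell use:

```sh
exec/ngms simulate --seed 17 --out batch17            # write a batch to disk
exec/ngms ingest   --worklist batch17/worklist.tsv    # verify checksums
exec/ngms screen   --dir batch17 --patient P01 --out p01.tsv
exec/ngms qc       --dir batch17 --out qc.tsv         # QC standards report
exec/ngms validate --dir batch17 --out val.tsv        # validation gate
```

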
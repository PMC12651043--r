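# erythrospec

Quantitative analysis of drug-modified human erythrocytes, built around two
measurement surfaces used in red-blood-cell pharmacology studies:

1. **Cytoarchitectonics indices.** Scanning electron microscopy classifies
   erythrocytes into shape classes grouped as reversibly deformed (RD:
   discocytes, echinocytes, discocytes with a "ridge", mulberry forms) or
   irreversibly deformed (ID: dome-shaped cells, "deflated ball" cells,
   spherocytes, spiked spherocytes, stomatocytes, degenerative forms). With
   `D` the percent discocytes, the transformation index and its components
   are

   ```
   TI  = (RD + ID) / D        (ratio of all cells to normal discocytes)
   RTI = RD / D               IRTI = ID / D        so  TI = RTI + IRTI
   ```

   `TI = 1` when every cell is a biconcave discocyte; it grows as discocytes
   are lost to transformed forms.

2. **Hemoglobin ligand-form deconvolution.** Oxy-, deoxy- and
   methemoglobin concentrations (mol/L, 1 cm path) are recovered from
   absorbances at the three anchor wavelengths 577, 569 and 500 nm by the
   linear formulas

   ```
   [HbO2] = ( 1.7·A577 − 1.3·A569 − 0.15·A500) · 1e-4
   [Hb]   = (−1.6·A577 + 2.5·A569 − 0.33·A500) · 1e-4
   [MtHb] = ( 0.2·A577 − 0.4·A569 + 0.33·A500) · 1e-4
   ```

   i.e. `c = C a 1e-4`; the package also derives the forward (apparent
   extinction) matrix `E = 1e4 C⁻¹` so spectra can be simulated that are
   exactly consistent with a known speciation.

Around these sit: band metrics (Soret, Q-bands at 542/576 nm, aromatic
280 nm band) with percent-change comparisons, OD-0.8 normalization,
per-condition mean ± SEM summaries with pooled Student's t-tests, a
synthetic-data module (Dirichlet-multinomial donor count tables calibrated
to a published reference distribution for minocycline-treated cells;
anchor-consistent noisy spectra at the instrument's 0.001 Abs photometric
repeatability), and chemistry helpers (formula mass, dose-to-molarity).

Intended users: researchers quantifying erythrocyte shape redistribution
and intracellular hemoglobin state after exposure to a membrane-active
drug, from SEM counts and UV-Vis spectra.

## Worked example

```r
library(erythrospec)

# indices from a published-style summary column (D, RD, ID in percent)
compute_indices(profile_from_percent(D = 81.4, RD = 95.0, ID = 5.1))
#> TI = 1.2297 (reported 1.2)  RTI = 1.1671 (1.2)  IRTI = 0.0627 (0.06)

# hemoglobin speciation from an anchor absorbance triple (A577, A569, A500)
speciate(c(0.593, 0.502, 0.268))
#> Hemoglobin ligand forms (mol/L):
#>       HbO2         Hb       MtHb
#> 3.1530e-05 2.1776e-05 6.2400e-07
#> Fractions:
#>   HbO2     Hb   MtHb
#> 0.5846 0.4038 0.0116

# end-to-end: simulate a 30-donor panel for two conditions, summarize, test
rep <- run_pipeline(list(seed = 42, simulate_counts = list(
  conditions = c("control", "MC_24h"), n_donors = 30,
  cells_per_donor = 1000, overdispersion = 1500)), verbose = FALSE)
rep
#> Analysis report: 2 conditions, 30 donors
#>  metric control MC_24h
#>       D   91.10  81.70
#>      RD   97.70  95.10
#>      ID    2.30   4.90
#>      TI    1.10   1.20
#>     RTI    1.10   1.20
#>    IRTI    0.03   0.06
#> 6 of 6 t-tests significant at alpha = 0.05
```

The report's TI rises from 1.1 to 1.2 as discocytes fall from ~91% to
~81%, matching the reference table the simulation is calibrated to; the
t-test block confirms the shift is detectable across 30 donors.

A thin CLI over the same functions lives at `inst/cli/erythrospec-cli.R`
(subcommands `simulate-counts`, `simulate-spectra`, `indices`, `speciate`,
`bands`, `report`; flags `--config`, `--seed`, `--out`, `--verbose`).

## Documentation

The methods vignette (`vignettes/erythrocyte-analysis.Rmd`) describes the
model, the synthetic-data generator and its calibration, numerical
choices, and limitations.
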
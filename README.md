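# pepmem

Quantitative biophysics of antimicrobial peptide-membrane interactions,
as an R package plus a small analysis workflow. It serves researchers who
characterize membrane-active peptides with the classic trio of
ATR-FTIR spectroscopy, differential scanning calorimetry (DSC) and
sequence-level design descriptors, and who want those analyses as tested,
scriptable code rather than vendor-software button clicks.

The study system is alyteserin-1c (`GLKEIFKAGLGSLVKGIAAHVAS`, net charge
+2) and its cationic analogue (`GLKRIFKSGLGKLVKGISAHVAS`, +5) interacting
with model membranes (DMPC, DMPC/DMPG, POPC, POPC/POPG vesicles).

## What it computes

- **Amide I' decomposition** — the 1700-1600 cm^-1 band is modelled as a
  sum of Voigt profiles `V(nu; c_k, sigma_k, gamma_k)`; centers are seeded
  from Savitzky-Golay second-derivative minima, fitted in two stages
  (centers frozen, then free within +/-4 cm^-1), assigned to structure
  classes by wavenumber, and reported as integer percentages of amide I'
  area plus the lipid C=O area ratio (an inverse proxy for binding
  affinity).
- **DSC transition analysis** — baseline correction by iterative outlier
  rejection, peak detection with prominence thresholds, Tm as the refined
  peak maximum, and transition enthalpy
  `dH = integral(P/beta) dT / m` (J per gram of lipid).
- **Peptide descriptors** — net side-chain charge at pH 7, mean
  Fauchère-Pliška hydrophobicity, Eisenberg hydrophobic moment
  `mu_H = |sum H_n e^{i n 100°}|/N`, and 18-residue helical wheel
  projections.
- **Trajectory metrics** — unaligned RMSD
  `sqrt(sum |r_i(t1)-r_i(t2)|^2 / N)`, per-group RMSD series, minimum
  inter-group distances, mean energy; plain-text XYZ input.
- **Synthetic generators** — seeded spectra/thermograms with known ground
  truth, including one preset per tabulated experimental condition
  (6 FTIR compositions, 14 DSC rows), so every pipeline is validated by
  parameter recovery.

## Worked example

```r
library(pepmem)

net_charge("GLKRIFKSGLGKLVKGISAHVAS")
#> [1] 5

# peptide +5 bound to POPC vesicles: synthetic spectrum at SNR 100
ms <- make_spectrum("pep5_pc", seed = 1)
analyze_spectrum(ms$spectrum)
#> <structure_report>
#>   alpha_helix             71 %
#>   beta_sheet_or_turns     29 %
#>   C=O / total area       12.6 %
#>   reduced chi2           3.38e-08

# DSC control scan: DMPC multilamellar vesicles alone
mt <- make_thermogram("dmpc_control", seed = 1)
corr <- correct_baseline(mt$thermogram)
detect_transitions(corr)
#>     peak_T  prominence half_width role
#> 1 12.77424 0.004124469       1.96  pre
#> 2 22.90103 0.057956224       0.84 main
transition_enthalpy(corr, 22.9)
#> [1] 1.462492
```

The spectrum report reads: the helix fraction recovered from the
synthetic "+5 + POPC" condition is 71% against a generated truth of 72%,
with the remainder assigned to beta-sheet/turns, and the phospholipid
carbonyl band carrying ~13% of the fitted area. The DSC control recovers
the pre-transition near 12.9 °C, the main transition at 22.9 °C and a
transition enthalpy of 1.46 J/g against a generated truth of 1.47 J/g.

## Analysis workflow

Numbered drivers under `analysis/` rerun the full study on the synthetic
presets and write tables under `results/`:

```sh
Rscript analysis/01_peptide_descriptors.R   # charges, muH, wheels
Rscript analysis/02_dsc_titration.R         # Tm / dH vs peptide:lipid ratio
Rscript analysis/03_ftir_structure.R        # structure fractions vs truth
Rscript analysis/04_md_metrics.R            # RMSD / distance / energy demo
```

## Layout

- `R/` — implementation (I/O and containers, FTIR, DSC, descriptors,
  trajectory metrics, generators)
- `tests/testthat/` — unit, property and end-to-end recovery tests
- `analysis/` — the numbered workflow drivers
- `vignettes/peptide-membrane-biophysics.Rmd` — methods notes: model
  assumptions, parameter choices, numerical tolerances, limitations
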
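---
title: "Methods: amide I' decomposition, DSC transition analysis and peptide descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amide I' decomposition, DSC transition analysis and peptide descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmem)
```

`pepmem` implements the quantitative stages of a peptide-membrane
interaction study of the antimicrobial peptide alyteserin-1c (net charge
+2) and its more cationic, more hydrophilic analogue (+5): infrared
secondary-structure analysis, calorimetric phase-transition analysis,
sequence-level design descriptors, and trajectory metrics. Because raw
instrument traces for such studies are rarely deposited, every pipeline is
paired with a seeded synthetic generator carrying known ground truth, and
correctness is demonstrated by *parameter recovery* rather than by
re-reading published figures.

## ATR-FTIR amide I' decomposition

The amide I' band (1700-1600 cm^-1 in D2O) is a superposition of
backbone C=O stretching bands whose positions report secondary structure.
The pipeline follows standard resolution-enhanced curve fitting:

1. **Preprocessing** (`preprocess()`): a straight baseline through
   5-point mean anchors at 1800 and 1300 cm^-1 is subtracted, a 10-point
   centered adjacent-averaging smooth is applied (even windows use the
   standard half-weight 2xk filter so the output stays on the grid), and
   the spectrum is scaled so the trapezoidal area over 1700-1600 cm^-1
   equals 1. The normalization constant is arbitrary; unit area makes
   fitted component areas directly interpretable as fractions.
2. **Second-derivative band location** (`second_derivative()`,
   `locate_bands()`): a Savitzky-Golay filter (15-point window, cubic
   polynomial; the window corresponds to 15 cm^-1 at 1 cm^-1 sampling)
   yields d2A/dnu2, whose minima mark component centers. Minima with
   prominence below 5% of the strongest minimum are discarded; ties are
   broken toward higher wavenumber so output is deterministic.
3. **Two-stage Voigt fit** (`fit_amide_region()`): the 1775-1575 cm^-1
   window is modelled as a sum of Voigt profiles (Gaussian sd `sigma`,
   Lorentzian HWHM `gamma`). Stage 1 freezes the centers at the
   second-derivative positions and fits areas and widths; stage 2 releases
   the centers within +/-4 cm^-1 with widths bounded to [1, 25] cm^-1.
   The +/-4 cm^-1 freedom refines positions without letting neighbouring
   bands swap identities. When the metadata declares a lipid, one extra
   component models the phospholipid ester C=O band (initialized at
   1730 cm^-1 and allowed +/-15 cm^-1, since its position comes from
   chemistry rather than from a derivative minimum). Components whose
   areas collapse to the lower bound are removed and the fit repeated.
4. **Assignment** (`assign_band()`): contiguous windows interpolate the
   discrete catalogue — lipid C=O 1700-1775; high-frequency beta-sheet
   1685-1695; beta-sheet/turns 1670-1685; turns 1660-1670; alpha-helix
   1650-1660; unordered 1640-1650; low-frequency beta-sheet 1613-1640;
   His 1570-1580, amide II 1530-1550, Lys 1520-1530. A cohort rule
   handles intermolecular aggregation: simultaneous bands in 1613-1622
   *and* 1675-1685 cm^-1 in a lipid-free spectrum are both classed
   `aggregation`; in lipid-bound spectra the high band is read as
   beta-sheet/turns, because the diagnostic low-frequency partner is
   absent there.
5. **Summary** (`summarize_structure()`): class fractions are class area
   over total amide I' component area, times 100, rounded to integers
   with largest-remainder reconciliation so each report totals exactly
   100. Split classes (1691 + 1622 beta pair; 1680 + 1618 aggregation
   pair) are summed before rounding. The lipid C=O ratio is
   `CO / (CO + amide I') x 100`; amide II and side-chain bands are
   excluded from both totals. Whether an experimental "total area"
   should include amide II and side chains is ambiguous; excluding them
   is this package's documented choice, since those bands are not peptide
   backbone structure.

The Voigt profile is computed from the Faddeeva function via Weideman's
rational approximation (degree 36), which is overflow-free over the upper
half-plane and accurate to ~1e-12; the degenerate widths `gamma = 0` and
`sigma = 0` use the exact Gaussian and Lorentzian closed forms.

## DSC transition analysis

Multilamellar DMPC or DMPC/DMPG vesicles scanned from 8 to 40 °C at
1 °C/min show a small pre-transition (gel to ripple phase) and a sharp
main transition (gel to liquid-crystalline) near 23 °C. The pipeline:

- `correct_baseline()` fits a linear (optionally smoothing-spline)
  baseline to transition-free segments found by iterative outlier
  rejection (drop points > 2.5 robust sd above the current line, refit);
  at least 20% of the scan must remain as baseline, otherwise explicit
  exclusion zones are required.
- `detect_transitions()` finds local maxima of the lightly smoothed
  corrected trace. A peak must exceed both 2% of the largest prominence
  and an absolute floor of 4x the robust noise level; the floor is what
  lets a featureless scan return "no transitions" (the abolished-transition
  case) instead of ranking noise. The most prominent peak is the main
  transition (Tm is the peak maximum, not the onset, matching how such
  tables are reported); the most prominent smaller peak below it is the
  pre-transition. Peak temperatures are refined by local quadratic
  interpolation, so Tm is not quantized to the grid.
- `transition_enthalpy()` integrates the corrected excess heat flow
  between automatic limits (where the signal falls to 1% of peak height)
  and converts mW·°C to J/g by dividing by the heating rate in °C/s and
  the lipid mass. The 1%-height limits truncate ~0.25% of a Gaussian
  peak, far inside the 5% recovery tolerance. Enthalpies are per gram of
  *lipid*; the few weight-percent of peptide in the pan is ignored, the
  usual convention when the lipid mass is what is weighed.
- `titration_report()` assembles one row per scan ordered by
  peptide:lipid ratio, with `dTm` and `ddH` relative to the 0:1 control.

Shoulders from peptide-rich domains are deliberately *not* deconvolved by
default: the reported Tm is the envelope maximum, which is what a
single-Tm table records.

## Peptide descriptors

`net_charge()` uses the pH 7 side-chain model: +1 per Lys/Arg, -1 per
Asp/Glu, His neutral (pKa ~6), free termini cancelling. The two
sequences, `GLKEIFKAGLGSLVKGIAAHVAS` and `GLKRIFKSGLGKLVKGISAHVAS`, give
+2 and +5. Hydrophobicity uses the Fauchère-Pliška octanol scale (the
HeliQuest convention) and `hydrophobic_moment()` the Eisenberg mean
moment, mu_H = |sum H_n exp(i n delta)| / N with delta = 100° per
residue; normalization by N matches HeliQuest output, and an
unnormalized option is exposed. `wheel_projection()` places the first 18
residues (the N-terminal segment containing all four substitutions) at
100° increments and classes them hydrophobic / positive / negative /
polar / other; His is classed polar, consistent with its neutral state at
pH 7. The four substitution sites (0-based 3, 7, 11, 17) fall on the
polar face, which is why the analogue's mean hydrophobicity drops while
its hydrophobic moment rises.

## Trajectory metrics

`mean_energy()` is the arithmetic mean of an energy log. `frame_rmsd()`
and `rmsd_series()` implement the *unaligned* root-mean-square coordinate
deviation, sqrt(sum |r_i(t1) - r_i(t2)|^2 / N) — no superposition and no
mass weighting, so rigid drift contributes to the value; that is the
quantity printed by the study design this package serves, where drift of
lipid groups relative to a vesicle is part of the signal. A
Kabsch-superposed variant (`kabsch_rmsd()`) is provided separately and is
never used by the series functions. `min_distance_series()` is the
per-frame minimum Euclidean distance between two atom groups. Frames come
from plain-text XYZ files (`read_xyz()`) or in-memory matrices; binary
trajectory formats are out of scope.

## Synthetic data: what it does and does not emulate

`make_spectrum()` sums Voigt components plus a linear baseline and seeded
Gaussian noise; `make_thermogram()` sums Gaussian (optionally split-
Gaussian) endotherms whose per-gram excess-heat integrals equal their
nominal enthalpies, on a drifting baseline. Components are renormalized
on the finite grid so each band's on-grid integral equals its requested
area exactly. Presets encode every tabulated experimental condition:
6 amide I' compositions (e.g. `pep2_free` with beta-sheet 66% split
1691/1622 and turns 34%; `pep5_pcpg` with beta/turns 81% and unordered
19%) and 14 thermogram rows (e.g. `dmpc_control` with pre-transition
12.9 °C, Tm 22.9 °C, 1.47 J/g; `dmpc_pep5_1to25` with Tm 20.5 °C and
0.18 J/g). Preset choices the tables do not pin down, fixed once at
field-typical values: amide component widths sigma = 7, gamma = 3 cm^-1;
lipid C=O at 1730 cm^-1 (sigma 8, gamma 4); residual amide II (1540),
His (1575) and Lys (1527) bands at 8/1.5/2% of the amide area; spectral
noise 1% of the maximum signal (SNR 100); DSC sampling step 0.02 °C over
8-40 °C, 2 mg lipid, 1 °C/min; main-transition FWHM 0.8 °C for controls
broadening to 1.5 / 2 / 3 °C at 1:100 / 1:50 / 1:25, emulating the
near-disappearance of the transition at the highest load; pre-transition
FWHM 1.8 °C with 0.2 J/g.

The generators emulate band overlap, baseline drift and detector noise —
the features the algorithms must defeat — but not water-vapour lines,
ATR penetration-depth dispersion, H/D-exchange kinetics, scan-rate
hysteresis or asymmetric main transitions. Passing recovery tests
therefore demonstrates the correctness of the numerics on in-model data,
not robustness to every instrumental artefact.

## Problem sizes and numerical notes

Tests and the acceptance script run each FTIR preset on a 501-point
1300-1800 cm^-1 grid and each DSC preset on a 1601-point 8-40 °C grid;
full recovery across all 20 presets completes in well under a minute.
Known numerical behaviours worth stating:

- Second-derivative picking of closely spaced *pure Gaussian* bands can
  produce a shallow saddle minimum between real bands; the subsequent fit
  shrinks such phantom components to zero area and they are pruned.
- Side-chain/amide II absorption below 1600 cm^-1 overlaps the low edge
  of the 1775-1575 cm^-1 fit window without a dedicated component in the
  default model; on the lipid-free beta-rich preset this inflates the
  recovered beta-sheet fraction by ~2-3 points — inside the stated
  +/-5-point recovery tolerance, and the reason that tolerance is not
  tighter.
- The C=O band sits near the 1775 cm^-1 window edge; its recovered ratio
  runs ~1-2 points low for the same reason.
- Fraction rounding uses the largest-remainder method with deterministic
  tie-breaking (larger value first), so reported integers always total
  100.
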
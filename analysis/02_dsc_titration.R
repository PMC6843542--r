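#!/usr/bin/env Rscript
# DSC titrations of DMPC and DMPC/DMPG (3:1) multilamellar vesicles with
# each peptide: generate the seeded preset thermograms, run baseline
# correction / transition detection / enthalpy integration, and tabulate
# Tm and transition enthalpy against the peptide:lipid ratio.

library(pepmem)
dir.create("results", showWarnings = FALSE)
seed <- 1L

series <- list(
  dmpc_pep2 = c("dmpc_control", "dmpc_pep2_1to100", "dmpc_pep2_1to50",
                "dmpc_pep2_1to25"),
  dmpc_pep5 = c("dmpc_control", "dmpc_pep5_1to100", "dmpc_pep5_1to50",
                "dmpc_pep5_1to25"),
  dmpcg_pep2 = c("dmpcg_control", "dmpcg_pep2_1to100", "dmpcg_pep2_1to50",
                 "dmpcg_pep2_1to25"),
  dmpcg_pep5 = c("dmpcg_control", "dmpcg_pep5_1to100", "dmpcg_pep5_1to50",
                 "dmpcg_pep5_1to25"))

all_rows <- list()
for (nm in names(series)) {
  tgs <- lapply(series[[nm]], function(p) make_thermogram(p, seed = seed)$thermogram)
  tab <- titration_report(tgs)
  tab <- cbind(system = nm, tab)
  all_rows[[nm]] <- tab
  cat("\n==", nm, "\n")
  print(tab, digits = 4)
  if (all(diff(tab$dH) <= 0))
    cat("   transition enthalpy falls monotonically with peptide load\n")
}
out <- do.call(rbind, all_rows)
rownames(out) <- NULL
write.csv(out, "results/dsc_titration.csv", row.names = FALSE)
cat("\nWrote results/dsc_titration.csv\n")
cat("Controls: pre-transition near 12.9 C (DMPC) / 12 C (DMPC/DMPG),",
    "main transition near 22.9 C; peptide load depresses and broadens both.\n")
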
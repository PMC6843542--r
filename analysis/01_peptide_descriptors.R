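#!/usr/bin/env Rscript
# Sequence-level design comparison of alyteserin-1c (+2) and its cationic
# analogue (+5): net charge, mean hydrophobicity, hydrophobic moment and
# the 18-residue helical wheels of the N-terminal segment where the four
# substitutions sit.

library(pepmem)
dir.create("results", showWarnings = FALSE)

pep2 <- "GLKEIFKAGLGSLVKGIAAHVAS"
pep5 <- "GLKRIFKSGLGKLVKGISAHVAS"
w2 <- substr(pep2, 1, 18)
w5 <- substr(pep5, 1, 18)

desc <- data.frame(
  peptide = c("+2", "+5"),
  sequence = c(pep2, pep5),
  length = c(nchar(pep2), nchar(pep5)),
  net_charge = c(net_charge(pep2), net_charge(pep5)),
  mean_H_18 = c(mean_hydrophobicity(w2), mean_hydrophobicity(w5)),
  muH_18 = c(hydrophobic_moment(w2), hydrophobic_moment(w5)))
write.csv(desc, "results/peptide_descriptors.csv", row.names = FALSE)

write.csv(wheel_projection(pep2), "results/wheel_pep2.csv", row.names = FALSE)
write.csv(wheel_projection(pep5), "results/wheel_pep5.csv", row.names = FALSE)

diff_pos <- seq_diff_positions(pep2, pep5)

cat("Peptide descriptors\n")
print(desc, digits = 3)
cat("\nSubstitution positions (0-based):", diff_pos, "\n")
cat(sprintf("Design direction: hydrophobicity %s for +5, hydrophobic moment %s\n",
            if (desc$mean_H_18[2] < desc$mean_H_18[1]) "drops" else "rises",
            if (desc$muH_18[2] > desc$muH_18[1]) "rises" else "drops"))
cat("Wrote results/peptide_descriptors.csv and wheel tables.\n")
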
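#!/usr/bin/env Rscript
# Simulate the six input tables with planted ground truth.
#
# Generates the synthetic study at its default conditions — 97 compounds
# (56 drug-like, 3 of them targetless), 729 predicted target genes, 1893
# disease genes (272 shared), a 2000-gene tumor/normal expression matrix
# with the deciles planted (136 of the shared genes among them), a PPI
# edge table with two dense planted modules, and 100 annotation terms
# with one planted enriched pathway — and writes them under
# results/fixtures/ together with the ground-truth manifest.

suppressPackageStartupMessages(library(netpharm))

seed <- 17
data <- gen_all(seed = seed)
write_fixtures(data, "results/fixtures")

cat("seed:", seed, "\n")
cat("compounds:", nrow(data$descriptors), "\n")
cat("prediction rows:", nrow(data$predictions), "\n")
cat("disease-gene rows:", nrow(data$disease), "\n")
cat("expression:", nrow(data$expression$expr), "genes x",
    ncol(data$expression$expr), "samples\n")
cat("ppi edges:", nrow(data$ppi_edges), "\n")
cat("annotation terms:", nrow(data$annotations), "\n")
cat("planted: 56 drug-like, 729 targets, 272 candidates, 136 validated\n")
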
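#!/usr/bin/env Rscript
# Drug-likeness screen of the compound table.
#
# Applies the five rule systems (Lipinski, Ghose, Veber, Egan, Muegge)
# and the Abbott bioavailability score, then the candidate gate
# (>= 2 rules passed and bioavailability score >= 0.30). Writes the
# per-compound verdicts and the funnel summary.

suppressPackageStartupMessages(library(netpharm))

descriptors <- read_tsv("results/fixtures/compounds.tsv")
verdicts <- select_candidates(descriptors)

write_tsv(verdicts, "results/verdicts.tsv")
jsonlite::write_json(
  list(input_n = nrow(verdicts), selected_n = sum(verdicts$selected)),
  "results/chem_funnel.json", auto_unbox = TRUE
)

cat(nrow(verdicts), "compounds screened;", sum(verdicts$selected),
    "pass the candidate gate\n")
cat("rules passed, distribution:\n")
print(table(verdicts$rules_passed))
cat("bioavailability score, distribution:\n")
print(table(verdicts$bioavailability_score))
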
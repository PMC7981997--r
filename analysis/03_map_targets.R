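#!/usr/bin/env Rscript
# Target mapping and the two Venn intersections.
#
# Filters predicted compound-target interactions at probability >= 0.1,
# drops compounds left without targets, selects disease genes at
# relevance score >= 10, intersects the two sets, and validates the
# candidates against the top-decile over/under-expressed genes of the
# tumor/normal expression matrix.

suppressPackageStartupMessages(library(netpharm))

verdicts <- read_tsv("results/verdicts.tsv")
selected <- verdicts$compound_id[verdicts$selected]

preds <- read_tsv("results/fixtures/predictions.tsv")
fp <- filter_predictions(preds, p_min = 0.1)
retained <- drop_targetless_compounds(selected, fp$per_compound)
targets <- sort(unique(unlist(fp$per_compound[retained], use.names = FALSE)))

disease <- filter_disease_genes(
  read_tsv("results/fixtures/disease_genes.tsv"), score_min = 10
)
candidates <- intersect_gene_sets(targets, disease)

ex <- read_expression("results/fixtures/expression.tsv")
de <- select_top_decile_de(ex$expr, ex$labels, fraction = 0.10)
validated <- intersect_gene_sets(candidates, union(de$over, de$under))

write_gene_list(retained, "results/compounds_with_targets.txt")
write_gene_list(targets, "results/targets_predicted.txt")
write_gene_list(candidates, "results/targets_candidate.txt")
write_gene_list(validated, "results/targets_validated.txt")
jsonlite::write_json(
  list(
    compounds_selected = length(selected),
    compounds_with_targets = length(retained),
    predicted_targets = length(targets),
    disease_genes = length(disease),
    venn_first = as.list(attr(candidates, "venn")),
    de_over = length(de$over), de_under = length(de$under),
    venn_second = as.list(attr(validated, "venn"))
  ),
  "results/venn.json", auto_unbox = TRUE
)

cat(length(selected), "drug-like compounds ->", length(retained),
    "with targets\n")
cat(length(targets), "predicted target genes;", length(disease),
    "disease genes;", length(candidates), "candidates\n")
cat(length(validated), "candidates validated by top-decile expression\n")
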
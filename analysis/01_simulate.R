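#!/usr/bin/env Rscript
# Stage 1 — materialise the synthetic study system.
#
# Emulates the raw material of the analysis: a disease-gene catalog with risk
# scores, experimentally-style miRNA-gene and drug-gene interaction tables,
# and two paired mRNA/miRNA expression studies over the same catalog
# ("disease A" and "disease B", standing in for the two heart-disease
# profiles), each with 20 planted dysregulated triplets. Also writes a
# synthetic pathway GMT for the enrichment stage.

library(mgdtnet)

out <- "results/benchmark"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design_a <- synthetic_design(seed = 1L)   # the package's standard benchmark
bench_a <- make_benchmark(design_a, file.path(out, "disease_a"))

# disease B: same interaction catalog, independent expression study with its
# own planted triplet set
design_b <- synthetic_design(seed = 101L)
catalog <- bench_a$catalog
gen_b <- generate_study(design_b, catalog)
dir.create(file.path(out, "disease_b"), showWarnings = FALSE)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
write_tsv(data.frame(gene = rownames(gen_b$study$mrna),
                        gen_b$study$mrna, check.names = FALSE),
             file.path(out, "disease_b", "mrna.tsv"))
write_tsv(data.frame(mirna = rownames(gen_b$study$mirna),
                        gen_b$study$mirna, check.names = FALSE),
             file.path(out, "disease_b", "mirna.tsv"))
write_tsv(data.frame(sample = gen_b$study$samples,
                        group = gen_b$study$labels),
             file.path(out, "disease_b", "labels.tsv"))
write_tsv(gen_b$truth, file.path(out, "disease_b", "ground_truth.tsv"))

gs <- generate_gene_sets(catalog, n_sets = 15L, seed = 5L)
write_gene_sets(gs, file.path(out, "pathways.gmt"))

message(sprintf(
  "wrote benchmark: %d disease genes, %d miRNA-gene and %d drug-gene pairs;",
  length(catalog$disease_genes), nrow(catalog$mirna_targets),
  nrow(catalog$drug_targets)))
message(sprintf(
  "disease A: %d planted triplets over %d+%d samples; disease B: %d planted",
  nrow(bench_a$truth), design_a$n_disease, design_a$n_control,
  nrow(gen_b$truth)))
message(sprintf("pathway collection: %d gene sets", length(gs$sets)))
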
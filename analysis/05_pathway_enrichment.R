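#!/usr/bin/env Rscript
# Stage 5 — hypergeometric pathway enrichment of the miRNA target sets in
# the top drug's star subnetwork, common pathways across those miRNAs, and
# the miRNA-mediated drug-pathway network linking the repurposing candidate
# to its putative mechanism.

library(mgdtnet)

out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bench <- "results/benchmark/disease_a"
catalog <- read_interaction_catalog(file.path(bench, "disease_genes.tsv"),
                                    file.path(bench, "mirna_targets.tsv"),
                                    file.path(bench, "drug_targets.tsv"),
                                    quiet = TRUE)
gs <- read_gene_sets("results/benchmark/pathways.gmt")
sig <- subset(read.delim("results/scores/disease_a/mgdt_scores.tsv",
                         comment.char = "#"), significant)
rank_a <- drug_participation_ranking(sig)
# centre on the gene with the most significant regulating miRNAs and the
# top-participating drug bound to it
n_mirnas <- vapply(split(sig$mirna, sig$gene), function(x)
  length(unique(x)), integer(1L))
centre <- names(n_mirnas)[order(-n_mirnas, names(n_mirnas))][1L]
drugs_on_centre <- rank_a$drug[rank_a$drug %in% sig$drug[sig$gene == centre]]
top_drug <- drugs_on_centre[1L]
mirnas <- unique(sig$mirna[sig$gene == centre])

universe <- enrichment_universe(catalog, gs)
message(sprintf("universe: %d genes (catalog targets present in the GMT)",
                length(universe)))

# a permissive per-miRNA cutoff keeps the sparse synthetic profiles non-empty
profiles <- mirna_pathway_profiles(mirnas, catalog, gs, universe = universe,
                                   alpha = 0.25)
prof_tab <- data.frame(
  mirna = names(profiles),
  n_pathways = lengths(profiles),
  pathways = vapply(profiles, paste, character(1L), collapse = ","))
write.table(prof_tab, file.path(out, "mirna_pathway_profiles.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

common <- common_pathways(profiles, min_fraction = 0.5)
message(sprintf(
  "%d miRNAs around %s/%s; common pathways (>= half the profiles): %s",
  length(profiles), top_drug, centre,
  if (length(common)) paste(common, collapse = ", ") else "none"))

dpn <- build_drug_pathway_network(top_drug, centre, profiles, common)
write_network(dpn, file.path(out, "drug_pathway_network.sif"), "sif")
message(sprintf("drug-pathway network: %d nodes, %d edges",
                nrow(dpn$nodes), nrow(dpn$edges)))
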
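#!/usr/bin/env Rscript
# Stage 4 — disease-specific and common triplet sets, the networks they
# induce, drug participation rankings (repurposing candidates), a
# gene-centred star subnetwork around the top drug's target, and the score
# profile summaries.

library(mgdtnet)

out <- "results/disease_networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

read_scores <- function(disease) {
  read.delim(file.path("results/scores", disease, "mgdt_scores.tsv"),
             comment.char = "#")
}
sig_a <- subset(read_scores("disease_a"), significant)
sig_b <- subset(read_scores("disease_b"), significant)

cmp <- compare_triplet_sets(sig_a, sig_b)
for (nm in names(cmp)) {
  write.table(cmp[[nm]], file.path(out, paste0(nm, "_triplets.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
message(sprintf(
  "significant triplets: %d (A), %d (B); %d common, %d A-specific, %d B-specific",
  nrow(sig_a), nrow(sig_b), nrow(cmp$common), nrow(cmp$specific_a),
  nrow(cmp$specific_b)))

net_a <- significant_network(cmp$specific_a)
net_b <- significant_network(cmp$specific_b)
write_network(net_a, file.path(out, "specific_a.sif"), "sif")
write_network(net_b, file.path(out, "specific_b.sif"), "sif")
message(sprintf("A-specific network: %d nodes, %d edges; B-specific: %d nodes, %d edges",
                nrow(net_a$nodes), nrow(net_a$edges),
                nrow(net_b$nodes), nrow(net_b$edges)))

rank_a <- drug_participation_ranking(sig_a)
write.table(rank_a, file.path(out, "drug_ranking_a.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top_drug <- rank_a$drug[1L]
message(sprintf("top repurposing candidate in A: %s (%d triplets)",
                top_drug, rank_a$n_triplets[1L]))

# star subnetwork around the gene with the most regulating miRNAs in the
# significant set (the drug-target hub of the repurposing story)
n_mirnas <- vapply(split(sig_a$mirna, sig_a$gene), function(x)
  length(unique(x)), integer(1L))
centre <- names(n_mirnas)[order(-n_mirnas, names(n_mirnas))][1L]
star <- gene_centered_subnetwork(sig_a, centre)
write_network(star, file.path(out, "top_gene_star.sif"), "sif")
cls <- table(star$nodes$class)
message(sprintf("%s-centred star: %d miRNAs, %d drug(s)", centre,
                cls[["miRNA"]], cls[["drug"]]))

prof <- score_profile_summary(read_scores("disease_a"))
write.table(prof$summary, file.path(out, "score_profile_a.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("score profile (disease A):")
for (i in seq_len(nrow(prof$summary))) {
  message(sprintf("  %-11s mean %.3g, median %.3g, IQR [%.3g, %.3g]",
                  prof$summary$score_type[i], prof$summary$mean[i],
                  prof$summary$median[i], prof$summary$q25[i],
                  prof$summary$q75[i]))
}
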
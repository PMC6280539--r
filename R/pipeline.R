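# End-to-end driver: build -> enumerate -> score -> permute -> select ->
# networks -> (optional) enrichment. Every table written carries a
# provenance header (package version, seed, parameters) and the whole run is
# a deterministic function of its inputs and seed.

#' Run the full triplet-dysregulation pipeline
#'
#' Sequences the analysis stages: build the tripartite network from the
#' catalog, enumerate triplets, score them against the expression study,
#' attach permutation P values, select the significant set, derive the
#' significant network and drug participation ranking, and (when gene sets
#' are supplied) compute per-miRNA pathway profiles with their common
#' pathways.
#'
#' @param catalog an `interaction_catalog`.
#' @param study an `expression_study`.
#' @param gene_sets optional `gene_set_collection` for the enrichment stage.
#' @param n_perm permutations for the null (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed driving the permutation stream.
#' @param welch,allow_degenerate_groups,pooled_null,bh_adjust scoring and
#'   selection options, see [permutation_significance()] and
#'   [select_significant()].
#' @param min_fraction common-pathway fraction, see [common_pathways()].
#' @param out_dir optional directory; when given, all result tables and
#'   networks are written there.
#' @return list with `network`, `triplets`, `records` (scored, with
#'   `final_score`, `perm_p`, `significant`), `significant` (subset),
#'   `fraction`, `significant_network`, `drug_ranking`, `topology`
#'   (degree stats + power-law fit when estimable), `score_profile`, and —
#'   with gene sets — `profiles`, `common_pathways`.
#' @export
run_mgdt_pipeline <- function(catalog, study, gene_sets = NULL,
                              n_perm = 1000L, alpha = 0.05, seed = 1L,
                              welch = FALSE, allow_degenerate_groups = FALSE,
                              pooled_null = FALSE, bh_adjust = FALSE,
                              min_fraction = 1.0, out_dir = NULL) {
  net <- build_tripartite_network(catalog)
  triplets <- enumerate_mgdts(net)
  # restrict to triplets measurable in the study
  keep <- triplets$gene %in% rownames(study$mrna) &
    triplets$mirna %in% rownames(study$mirna)
  if (!all(keep)) {
    msg("dropping %d triplet(s) not covered by the expression matrices",
        sum(!keep))
    triplets <- triplets[keep, , drop = FALSE]
  }
  if (nrow(triplets) == 0L) stop2("no scoreable triplets")
  records <- permutation_significance(
    study, catalog, triplets, n_perm = n_perm, seed = seed,
    pooled = pooled_null, welch = welch,
    allow_degenerate_groups = allow_degenerate_groups)
  sel <- select_significant(records, alpha = alpha, bh_adjust = bh_adjust)
  records <- sel$records
  sig_net <- significant_network(sel$significant)
  ranking <- drug_participation_ranking(sel$significant)

  ds <- degree_stats(net)
  plaw <- tryCatch(fit_power_law(ds$distribution), error = function(e) NULL)
  profile <- score_profile_summary(records)

  result <- list(network = net, triplets = triplets, records = records,
                 significant = sel$significant, fraction = sel$fraction,
                 significant_network = sig_net, drug_ranking = ranking,
                 topology = list(degree = ds, power_law = plaw),
                 score_profile = profile)

  if (!is.null(gene_sets)) {
    universe <- enrichment_universe(catalog, gene_sets)
    mirnas <- unique(sel$significant$mirna)
    profiles <- if (length(mirnas) > 0L) {
      suppressWarnings(mirna_pathway_profiles(mirnas, catalog, gene_sets,
                                              universe = universe,
                                              alpha = alpha,
                                              bh_adjust = bh_adjust))
    } else list()
    result$profiles <- profiles
    result$common_pathways <- if (length(profiles) > 0L) {
      common_pathways(profiles, min_fraction = min_fraction)
    } else character(0)
  }

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir,
                           provenance = c(
                             package = "mgdtnet",
                             version = as.character(utils::packageVersion("mgdtnet")),
                             seed = as.character(seed),
                             n_perm = as.character(n_perm),
                             alpha = as.character(alpha),
                             welch = as.character(welch),
                             pooled_null = as.character(pooled_null),
                             bh_adjust = as.character(bh_adjust)))
  }
  result
}

write_pipeline_outputs <- function(result, out_dir, provenance) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_score_table(result$records, file.path(out_dir, "mgdt_scores.tsv"),
                    provenance = provenance)
  write_network(result$network, file.path(out_dir, "mgdt_network.sif"), "sif")
  write_network(result$significant_network,
                file.path(out_dir, "significant_network.sif"), "sif")
  prov_write <- function(df, file) {
    con <- file(file.path(out_dir, file), open = "wb")
    on.exit(close(con))
    writeLines(sprintf("# %s = %s", names(provenance), provenance), con)
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df) > 0L) {
      cols <- lapply(df, function(x)
        if (is.numeric(x)) sprintf("%.10g", x) else as.character(x))
      writeLines(do.call(paste, c(cols, sep = "\t")), con)
    }
  }
  prov_write(result$drug_ranking, "drug_ranking.tsv")
  prov_write(topology_table(result$network), "topology.tsv")
  prov_write(result$score_profile$summary, "score_profile_summary.tsv")
  invisible(out_dir)
}

#' Sensitivity of a run against planted ground truth
#'
#' Fraction of planted triplets recovered in the significant set (matching
#' on the full miRNA/gene/drug triple).
#'
#' @param significant data frame of selected triplets.
#' @param truth planted-triplet data frame from [generate_study()].
#' @return sensitivity in [0, 1].
#' @export
planted_sensitivity <- function(significant, truth) {
  if (nrow(truth) == 0L) stop2("no planted triplets in the ground truth")
  mean(triplet_key(truth) %in% triplet_key(as_triplet_df(significant)))
}
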
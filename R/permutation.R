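# Label-permutation null for the final ranking score. Each permutation
# redraws the disease/control assignment (group sizes preserved, identical
# for the mRNA and miRNA matrices since the samples are paired), recomputes
# the label-dependent scores (s_p, s_pcc; s_risk never changes), re-runs the
# rank aggregation over all triplets and records every triplet's permuted
# final score.

#' Permutation significance of the final ranking scores
#'
#' Assigns each triplet an empirical P value by comparing its observed final
#' score to final scores recomputed under `n_perm` random relabelings of the
#' samples. Assignments are drawn uniformly (with replacement across
#' permutations): one `sample()` call per permutation selects which samples
#' play the disease role, so results are bit-reproducible for a given seed.
#' The add-one estimator `perm_p = (1 + #{permuted >= observed}) /
#' (1 + n_perm)` keeps P values off zero.
#'
#' With `pooled = TRUE` the observed score is instead compared against the
#' pooled distribution of all triplets' permuted scores.
#'
#' @param study an `expression_study`.
#' @param catalog an `interaction_catalog`.
#' @param triplets data frame (mirna, gene, drug).
#' @param n_perm number of permutations (>= 1); 1000 by default.
#' @param seed integer seed; the permutation stream is a deterministic
#'   function of it.
#' @param pooled compare against the pooled null instead of each triplet's
#'   own permutation distribution.
#' @param welch,allow_degenerate_groups passed to the score computation.
#' @return the record data frame with `final_score` and `perm_p` columns.
#' @export
permutation_significance <- function(study, catalog, triplets,
                                     n_perm = 1000L, seed = 1L,
                                     pooled = FALSE, welch = FALSE,
                                     allow_degenerate_groups = FALSE) {
  stopifnot(n_perm >= 1L)
  obs <- aggregate_ranks(
    compute_triplet_scores(study, catalog, triplets, welch = welch,
                           allow_degenerate_groups = allow_degenerate_groups))
  n_samples <- length(study$labels)
  n_disease <- sum(study$labels == "disease")
  n_assign <- choose(n_samples, n_disease)
  if (n_assign < n_perm) {
    warn2("only %d distinct label assignments exist but %d permutations requested; sampling with replacement",
          n_assign, n_perm)
  }
  key <- paste(triplets$gene, triplets$mirna, sep = "\r")
  n_rec <- nrow(obs)
  ge_count <- integer(n_rec)
  pooled_ge <- 0
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  for (b in seq_len(n_perm)) {
    d_idx <- sample.int(n_samples, n_disease)
    fs <- score_features(study, triplets, welch, allow_degenerate_groups,
                         disease_idx = d_idx)
    s_p <- unname(fs$p_gene[obs$gene]) * unname(fs$p_mirna[obs$mirna])
    ix <- match(key, fs$pair_key)
    s_pcc <- abs(fs$d_pcc[ix] - fs$c_pcc[ix])
    perm_final <- final_scores(obs$s_risk, s_p, s_pcc)
    if (pooled) {
      # count, for each observed score, permuted scores from any triplet
      pooled_ge <- pooled_ge +
        (n_rec - findInterval(obs$final_score, sort(perm_final),
                              left.open = TRUE))
    } else {
      ge_count <- ge_count + (perm_final >= obs$final_score)
    }
  }
  obs$perm_p <- if (pooled) {
    (1 + pooled_ge) / (1 + n_perm * n_rec)
  } else {
    (1 + ge_count) / (1 + n_perm)
  }
  obs
}

#' Select significantly dysregulated triplets
#'
#' @param records data frame with a `perm_p` column.
#' @param alpha significance level; selection uses the strict inequality
#'   `perm_p < alpha`.
#' @param bh_adjust apply Benjamini-Hochberg correction to `perm_p` before
#'   thresholding (adds a `perm_p_adj` column); off by default.
#' @return list with `significant` (the selected rows, with a logical
#'   `significant` column also added to `records`), `records` (all rows) and
#'   `fraction` (selected / total).
#' @export
select_significant <- function(records, alpha = 0.05, bh_adjust = FALSE) {
  if (is.null(records$perm_p)) stop2("records carry no perm_p column")
  stopifnot(alpha > 0, alpha < 1)
  p <- records$perm_p
  if (bh_adjust) {
    records$perm_p_adj <- stats::p.adjust(p, method = "BH")
    p <- records$perm_p_adj
  }
  records$significant <- p < alpha
  list(significant = records[records$significant, , drop = FALSE],
       records = records,
       fraction = if (nrow(records) == 0L) 0 else mean(records$significant))
}

#' Write the triplet score table
#'
#' Tab-separated with the fixed column order (mirna, gene, drug, s_risk,
#' p_mrna, p_mirna, s_p, d_pcc, c_pcc, s_pcc, final_score, perm_p,
#' significant). Optional `#`-prefixed provenance header lines.
#'
#' @param records scored record data frame.
#' @param path output path.
#' @param provenance named character vector written as `# key = value` lines.
#' @return the path, invisibly.
#' @export
write_score_table <- function(records, path, provenance = NULL) {
  cols <- c("mirna", "gene", "drug", "s_risk", "p_mrna", "p_mirna", "s_p",
            "d_pcc", "c_pcc", "s_pcc", "final_score", "perm_p", "significant")
  cols <- intersect(cols, names(records))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s = %s", names(provenance), provenance), con)
  }
  out <- records[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  }
  invisible(path)
}
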
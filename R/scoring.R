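# The triplet dysregulation statistic. Each (miRNA, gene, drug) triplet gets
# three scores:
#   s_risk — the gene's disease-association risk score (label-invariant);
#   s_p    — product of the two-group t-test P values of the gene (mRNA) and
#            the miRNA; smaller = stronger differential expression;
#   s_pcc  — |D_pcc - C_pcc|, the absolute change of the miRNA-mRNA Pearson
#            correlation between disease and control samples.
# The three per-score rankings are combined with equal weight into a final
# score in (0,1]; significance comes from a sample-label permutation null.

#' Pooled-variance two-sample t test
#'
#' Classic Student t with pooled variance and df = n_a + n_b - 2 (Welch's
#' unequal-variance form available via `welch = TRUE`). Degenerate
#' zero-variance inputs follow a fixed convention: equal means give p = 1,
#' unequal means with zero pooled variance give p = 0 (the most extreme
#' evidence attainable).
#'
#' @param group_a,group_b numeric vectors, each of length >= `min_n`.
#' @param welch use the Welch unequal-variance statistic.
#' @param min_n minimum per-group size. The default 2 is the smallest size
#'   with a within-group variance; `min_n = 1` additionally admits a
#'   singleton group (pooled variance then comes from the other group
#'   alone), the degenerate-design escape hatch for unbalanced studies such
#'   as 4 disease vs 1 control. Welch's statistic has no singleton form and
#'   keeps the minimum of 2.
#' @param feature label used in error messages.
#' @return list with `statistic`, `df`, `p_value` (two-sided).
#' @export
student_t_test <- function(group_a, group_b, welch = FALSE, min_n = 2L,
                           feature = "feature") {
  if (min_n < 1L) stop2("min_n must be at least 1")
  if (welch) min_n <- max(min_n, 2L)
  if (length(group_a) < min_n || length(group_b) < min_n) {
    stop2("t test for '%s' needs >= %d samples per group (got %d and %d)",
          feature, min_n, length(group_a), length(group_b))
  }
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 + n2 < 4L) {
    stop2("t test for '%s' needs >= 4 samples in total", feature)
  }
  m1 <- mean(group_a); m2 <- mean(group_b)
  v1 <- if (n1 > 1L) stats::var(group_a) else 0
  v2 <- if (n2 > 1L) stats::var(group_b) else 0
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (!is.finite(se2) || se2 <= 0) {
    if (isTRUE(all.equal(m1, m2))) {
      return(list(statistic = 0, df = df, p_value = 1))
    }
    return(list(statistic = sign(m1 - m2) * Inf, df = df, p_value = 0))
  }
  t <- (m1 - m2) / sqrt(se2)
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlation with explicit degeneracy handling
#'
#' Requires at least 3 paired observations and two non-constant vectors; a
#' constant vector yields r = 0 flagged degenerate (attribute `degenerate`),
#' since the correlation is undefined there.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1]; attribute `degenerate` is `TRUE` when a
#'   constant input forced the 0 convention.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop2("x and y must have equal length")
  if (length(x) < 3L) {
    stop2("Pearson correlation needs >= 3 paired samples, got %d", length(x))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(x, y), degenerate = FALSE)
}

# ---- vectorized row engines (used per permutation) ----

# two-sample t-test p-values for every row of `mat` at once
row_t_pvalues <- function(mat, idx_a, idx_b, welch = FALSE) {
  n1 <- length(idx_a); n2 <- length(idx_b)
  a <- mat[, idx_a, drop = FALSE]; b <- mat[, idx_b, drop = FALSE]
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- if (n1 > 1L) rowSums((a - m1)^2) / (n1 - 1) else numeric(nrow(mat))
  v2 <- if (n2 > 1L) rowSums((b - m2)^2) / (n2 - 1) else numeric(nrow(mat))
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    se2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degen <- !is.finite(se2) | se2 <= 0
  if (any(degen)) {
    eq <- degen & abs(m1 - m2) < 1e-12
    p[degen] <- 0
    p[eq] <- 1
  }
  p
}

# Pearson correlation for row pairs: X[i,] of mat_x with Y[i,] of mat_y over
# columns idx; constant rows give NA (caller applies its degeneracy policy)
row_pair_cor <- function(mat_x, rows_x, mat_y, rows_y, idx) {
  X <- mat_x[rows_x, idx, drop = FALSE]
  Y <- mat_y[rows_y, idx, drop = FALSE]
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  denom <- sqrt(rowSums(Xc^2) * rowSums(Yc^2))
  r <- rowSums(Xc * Yc) / denom
  r[denom == 0] <- NA_real_
  unname(r)
}

# per-feature p's and per-pair correlations for one label assignment,
# returned on the unique-feature level; compute_triplet_scores maps them to
# triplets. `feat` is the precomputed index structure from score_features().
score_features <- function(study, triplets, welch, allow_degenerate_groups,
                           disease_idx = which(study$labels == "disease"),
                           quiet = TRUE) {
  control_idx <- setdiff(seq_along(study$labels), disease_idx)
  genes <- unique(triplets$gene)
  mirnas <- unique(triplets$mirna)
  pairs <- unique(triplets[, c("gene", "mirna")])

  miss_g <- setdiff(genes, rownames(study$mrna))
  miss_m <- setdiff(mirnas, rownames(study$mirna))
  if (length(miss_g) + length(miss_m) > 0L) {
    stop2("triplet feature(s) missing from the expression matrices: %s",
          paste(c(miss_g, miss_m), collapse = ", "))
  }
  min_cor <- 3L
  small <- c(disease = length(disease_idx), control = length(control_idx))
  small <- small[small < min_cor]
  if (length(small) > 0L && !allow_degenerate_groups) {
    stop2(paste0("group(s) too small for Pearson correlation (need >= 3): %s. ",
                 "Set allow_degenerate_groups = TRUE to substitute 0 for the ",
                 "undefined correlation."),
          paste(sprintf("%s (n = %d)", names(small), small), collapse = ", "))
  }
  min_t <- if (allow_degenerate_groups && !welch) 1L else 2L
  if (length(disease_idx) < min_t || length(control_idx) < min_t) {
    stop2("t test needs >= %d samples per group (got %d disease, %d control)",
          min_t, length(disease_idx), length(control_idx))
  }

  p_g <- row_t_pvalues(study$mrna[genes, , drop = FALSE], disease_idx,
                       control_idx, welch)
  p_m <- row_t_pvalues(study$mirna[mirnas, , drop = FALSE], disease_idx,
                       control_idx, welch)

  cor_group <- function(idx, group) {
    if (length(idx) < min_cor) {
      if (!quiet) warn2("%s group has %d sample(s); correlations set to 0",
                        group, length(idx))
      return(rep(0, nrow(pairs)))
    }
    r <- row_pair_cor(study$mrna, pairs$gene, study$mirna, pairs$mirna, idx)
    degen <- is.na(r)
    if (any(degen)) {
      if (!allow_degenerate_groups) {
        stop2("constant expression vector(s) make %d correlation(s) undefined in the %s group (first pair: %s/%s); set allow_degenerate_groups = TRUE to use 0",
              sum(degen), group, pairs$gene[which(degen)[1L]],
              pairs$mirna[which(degen)[1L]])
      }
      r[degen] <- 0
    }
    r
  }
  d_pcc <- cor_group(disease_idx, "disease")
  c_pcc <- cor_group(control_idx, "control")

  list(p_gene = stats::setNames(p_g, genes),
       p_mirna = stats::setNames(p_m, mirnas),
       pair_key = paste(pairs$gene, pairs$mirna, sep = "\r"),
       d_pcc = d_pcc, c_pcc = c_pcc)
}

#' Compute the three dysregulation scores for every triplet
#'
#' `s_risk` is copied from the catalog (a gene property, identical across
#' triplets sharing a gene); `p_mrna`/`p_mirna` come from the two-group
#' Student t test of the gene and miRNA expression rows; `d_pcc`/`c_pcc` are
#' the miRNA-mRNA Pearson correlations within the disease and control
#' samples; `s_p = p_mrna * p_mirna` and `s_pcc = |d_pcc - c_pcc|`.
#'
#' @param study an `expression_study`.
#' @param catalog an `interaction_catalog` providing the risk scores.
#' @param triplets data frame (mirna, gene, drug) from [enumerate_mgdts()].
#' @param welch use Welch's t instead of the pooled-variance Student t.
#' @param allow_degenerate_groups substitute 0 (with a warning) for
#'   correlations that are undefined because a group has < 3 samples or a
#'   constant vector; by default such inputs are an error. Needed to attempt
#'   heavily unbalanced designs such as 4 disease vs 1 control.
#' @return data frame of `MGDT` records: the triplet columns plus `s_risk`,
#'   `p_mrna`, `p_mirna`, `s_p`, `d_pcc`, `c_pcc`, `s_pcc` (ranks unset).
#' @export
compute_triplet_scores <- function(study, catalog, triplets, welch = FALSE,
                                   allow_degenerate_groups = FALSE) {
  stopifnot(inherits(study, "expression_study"),
            inherits(catalog, "interaction_catalog"))
  if (nrow(triplets) == 0L) {
    stop2("no triplets to score")
  }
  miss_risk <- setdiff(unique(triplets$gene), names(catalog$disease_genes))
  if (length(miss_risk) > 0L) {
    stop2("triplet gene(s) missing from the disease-gene catalog: %s",
          paste(miss_risk, collapse = ", "))
  }
  fs <- score_features(study, triplets, welch, allow_degenerate_groups,
                       quiet = FALSE)
  key <- paste(triplets$gene, triplets$mirna, sep = "\r")
  pair_ix <- match(key, fs$pair_key)
  rec <- data.frame(
    mirna = triplets$mirna, gene = triplets$gene, drug = triplets$drug,
    s_risk = unname(catalog$disease_genes[triplets$gene]),
    p_mrna = unname(fs$p_gene[triplets$gene]),
    p_mirna = unname(fs$p_mirna[triplets$mirna]),
    stringsAsFactors = FALSE)
  rec$s_p <- rec$p_mrna * rec$p_mirna
  rec$d_pcc <- fs$d_pcc[pair_ix]
  rec$c_pcc <- fs$c_pcc[pair_ix]
  rec$s_pcc <- abs(rec$d_pcc - rec$c_pcc)
  rec
}

#' Equally weighted rank aggregation of the three scores
#'
#' Triplets are ranked three times — by `s_risk` descending, `s_p` ascending
#' (a smaller P product is stronger evidence) and `s_pcc` descending — with
#' average ranks on ties. Each rank r over N records maps to
#' (N - r + 1)/N in (0, 1], and the final score is the mean of the three
#' mapped values; higher means more dysregulated.
#'
#' @param records data frame from [compute_triplet_scores()] (or any frame
#'   with `s_risk`, `s_p`, `s_pcc` columns).
#' @return `records` with a `final_score` column added.
#' @export
aggregate_ranks <- function(records) {
  if (nrow(records) == 0L) stop2("rank aggregation needs >= 1 record")
  records$final_score <- final_scores(records$s_risk, records$s_p,
                                      records$s_pcc)
  records
}

# rank aggregation core; shared with the permutation engine
final_scores <- function(s_risk, s_p, s_pcc) {
  n <- length(s_risk)
  to_score <- function(r) (n - r + 1) / n
  (to_score(rank(-s_risk, ties.method = "average")) +
   to_score(rank(s_p, ties.method = "average")) +
   to_score(rank(-s_pcc, ties.method = "average"))) / 3
}
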
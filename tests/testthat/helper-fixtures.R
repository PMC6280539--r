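# Fixture builders and independent brute-force oracles shared by the suite.
# Oracles are deliberately naive (loops, enumeration) so they stay
# independent of the vectorized implementation paths they check.

toy_catalog <- function() {
  mgdtnet:::new_interaction_catalog(
    disease_genes = c(g1 = 0.9, g2 = 0.5, g3 = 0.1),
    mirna_targets = data.frame(mirna = c("m1", "m1", "m2"),
                               gene = c("g1", "g2", "g1"),
                               stringsAsFactors = FALSE),
    drug_targets = data.frame(drug = c("d1", "d2"),
                              gene = c("g1", "g2"),
                              stringsAsFactors = FALSE))
}

# small two-group study with deterministic values
toy_study <- function(n_disease = 4L, n_control = 4L, seed = 42L,
                      genes = c("g1", "g2", "g3"),
                      mirnas = c("m1", "m2")) {
  set.seed(seed)
  n <- n_disease + n_control
  samples <- sprintf("s%02d", seq_len(n))
  mrna <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, samples))
  mirna <- matrix(rnorm(length(mirnas) * n), nrow = length(mirnas),
                  dimnames = list(mirnas, samples))
  labels <- stats::setNames(rep(c("disease", "control"),
                                c(n_disease, n_control)), samples)
  mgdtnet:::new_expression_study(mrna, mirna, labels)
}

write_catalog_files <- function(catalog, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  p <- c(dg = file.path(dir, "dg.tsv"), mt = file.path(dir, "mt.tsv"),
         dt = file.path(dir, "dt.tsv"))
  writeLines(c("gene\trisk_score",
               sprintf("%s\t%.10g", names(catalog$disease_genes),
                       catalog$disease_genes)), p[["dg"]])
  writeLines(c("mirna\tgene",
               sprintf("%s\t%s", catalog$mirna_targets$mirna,
                       catalog$mirna_targets$gene)), p[["mt"]])
  writeLines(c("drug\tgene",
               sprintf("%s\t%s", catalog$drug_targets$drug,
                       catalog$drug_targets$gene)), p[["dt"]])
  p
}

random_triplet_set <- function(n, seed) {
  set.seed(seed)
  unique(data.frame(
    mirna = sprintf("m%d", sample(1:8, n, replace = TRUE)),
    gene = sprintf("g%d", sample(1:6, n, replace = TRUE)),
    drug = sprintf("d%d", sample(1:8, n, replace = TRUE)),
    stringsAsFactors = FALSE))
}

random_catalog <- function(seed, n_genes = 6L, n_mirnas = 8L, n_drugs = 8L,
                           p_mg = 0.3, p_dg = 0.3) {
  set.seed(seed)
  genes <- sprintf("g%d", seq_len(n_genes))
  mg <- expand.grid(mirna = sprintf("m%d", seq_len(n_mirnas)), gene = genes,
                    stringsAsFactors = FALSE)
  dg <- expand.grid(drug = sprintf("d%d", seq_len(n_drugs)), gene = genes,
                    stringsAsFactors = FALSE)
  mgdtnet:::new_interaction_catalog(
    stats::setNames(runif(n_genes), genes),
    mg[runif(nrow(mg)) < p_mg, , drop = FALSE],
    dg[runif(nrow(dg)) < p_dg, , drop = FALSE])
}

# ---- independent oracles ----

# naive average-rank (count-based, no rank())
naive_rank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

naive_final_scores <- function(s_risk, s_p, s_pcc) {
  n <- length(s_risk)
  conv <- function(r) (n - r + 1) / n
  (conv(naive_rank(-s_risk)) + conv(naive_rank(s_p)) +
     conv(naive_rank(-s_pcc))) / 3
}

# brute-force triplet enumeration: triple loop over all combinations
naive_enumerate <- function(catalog) {
  genes <- names(catalog$disease_genes)
  mirnas <- unique(catalog$mirna_targets$mirna)
  drugs <- unique(catalog$drug_targets$drug)
  out <- list()
  mg <- paste(catalog$mirna_targets$mirna, catalog$mirna_targets$gene)
  dg <- paste(catalog$drug_targets$drug, catalog$drug_targets$gene)
  for (m in mirnas) for (g in genes) for (d in drugs) {
    if (paste(m, g) %in% mg && paste(d, g) %in% dg) {
      out[[length(out) + 1L]] <- c(m, g, d)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna = character(), gene = character(),
                      drug = character()))
  }
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("mirna", "gene", "drug")
  df[order(df$mirna, df$gene, df$drug), ]
}

# exhaustive pairwise topological coefficient
naive_tc <- function(edges) {
  ids <- sort(unique(c(edges[[1]], edges[[2]])))
  nbr <- lapply(ids, function(v) {
    unique(c(edges[[2]][edges[[1]] == v], edges[[1]][edges[[2]] == v]))
  })
  names(nbr) <- ids
  tc <- stats::setNames(numeric(length(ids)), ids)
  for (v in ids) {
    k <- length(nbr[[v]])
    if (k < 2) next
    vals <- c()
    for (w in setdiff(ids, v)) {
      shared <- length(intersect(nbr[[v]], nbr[[w]]))
      if (shared == 0) next
      vals <- c(vals, (shared + (w %in% nbr[[v]])) / k)
    }
    if (length(vals) > 0) tc[v] <- mean(vals)
  }
  tc
}

# hypergeometric upper tail by exhaustive subset enumeration
naive_enrichment_p <- function(universe, set, query) {
  k_obs <- length(intersect(query, set))
  combos <- utils::combn(length(universe), length(query))
  in_set <- universe %in% set
  hits <- colSums(matrix(in_set[combos], nrow = nrow(combos)))
  sum(hits >= k_obs) / ncol(combos)
}

random_graph_edges <- function(seed, n_nodes = 30L, p = 0.12) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(ids, 2L))
  keep <- runif(nrow(pairs)) < p
  data.frame(a = pairs[keep, 1L], b = pairs[keep, 2L],
             stringsAsFactors = FALSE)
}
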
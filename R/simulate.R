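# Synthetic benchmark generator: sparse bipartite interaction catalogs with
# Beta-distributed gene risk scores, and two-group expression studies with
# planted triplets carrying a mean shift and a group-dependent miRNA-mRNA
# correlation — the exact statistical structure the triplet scores target.

#' Describe a synthetic benchmark design
#'
#' Defaults describe the package's standard benchmark: 50 genes, 80 miRNAs,
#' 120 drugs, miRNA-gene/drug-gene edge densities 0.06/0.04, 10 disease vs
#' 10 control samples, 20 planted triplets with a 2-standard-deviation mean
#' shift and miRNA-mRNA correlations +0.8 (disease) / -0.5 (control) —
#' sized so a full scoring-plus-permutation run takes seconds to minutes.
#'
#' @param n_genes,n_mirnas,n_drugs node counts.
#' @param edge_density_mg,edge_density_dg per-pair inclusion probabilities
#'   for miRNA-gene and drug-gene edges.
#' @param n_disease,n_control per-group sample counts (>= 3 by default; the
#'   scoring stage enforces its own minima).
#' @param n_planted number of planted dysregulated triplets.
#' @param delta disease-group mean shift of planted genes and miRNAs, in
#'   units of `noise_sd`.
#' @param rho_disease,rho_control target Pearson correlation of each planted
#'   (gene, miRNA) pair within the two groups, in (-1, 1).
#' @param noise_sd expression standard deviation (log-scale units).
#' @param risk_alpha,risk_beta Beta shape parameters of the risk-score law
#'   on [0, 1]; the default Beta(2, 5) is right-skewed like curated
#'   gene-disease scores.
#' @param planted_high_risk draw planted genes' risk scores from the top
#'   quartile of the Beta law so all three score channels carry signal;
#'   disable to test partial-signal behaviour.
#' @param seed integer master seed; the catalog consumes `seed`, the study
#'   `seed + 1`.
#' @return a `synthetic_design` list.
#' @export
synthetic_design <- function(n_genes = 50L, n_mirnas = 80L, n_drugs = 120L,
                             edge_density_mg = 0.06, edge_density_dg = 0.04,
                             n_disease = 10L, n_control = 10L,
                             n_planted = 20L, delta = 2,
                             rho_disease = 0.8, rho_control = -0.5,
                             noise_sd = 1, risk_alpha = 2, risk_beta = 5,
                             planted_high_risk = TRUE, seed = 1L) {
  d <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
            n_drugs = as.integer(n_drugs),
            edge_density_mg = edge_density_mg,
            edge_density_dg = edge_density_dg,
            n_disease = as.integer(n_disease),
            n_control = as.integer(n_control),
            n_planted = as.integer(n_planted), delta = delta,
            rho_disease = rho_disease, rho_control = rho_control,
            noise_sd = noise_sd, risk_alpha = risk_alpha,
            risk_beta = risk_beta,
            planted_high_risk = isTRUE(planted_high_risk),
            seed = as.integer(seed))
  with(d, {
    stopifnot(n_genes >= 1, n_mirnas >= 1, n_drugs >= 1,
              edge_density_mg >= 0, edge_density_mg <= 1,
              edge_density_dg >= 0, edge_density_dg <= 1,
              n_disease >= 1, n_control >= 1, n_planted >= 0,
              abs(rho_disease) < 1, abs(rho_control) < 1,
              noise_sd > 0, risk_alpha > 0, risk_beta > 0)
  })
  structure(d, class = "synthetic_design")
}

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, nchar(n), seq_len(n))

#' Generate a synthetic interaction catalog
#'
#' Every miRNA-gene and drug-gene pair enters independently with its density;
#' risk scores are Beta(`risk_alpha`, `risk_beta`) draws. Deterministic per
#' design seed.
#'
#' @param design a `synthetic_design`.
#' @return an `interaction_catalog`.
#' @export
generate_catalog <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(design$seed, {
    genes <- pad_ids("g", design$n_genes)
    mirnas <- pad_ids("mir", design$n_mirnas)
    drugs <- pad_ids("drug", design$n_drugs)
    risk <- stats::setNames(stats::rbeta(design$n_genes, design$risk_alpha,
                                         design$risk_beta), genes)
    # pair grids in fixed (gene-major) order so the draw order is stable
    mg <- expand.grid(mirna = mirnas, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep_mg <- stats::runif(nrow(mg)) < design$edge_density_mg
    dg <- expand.grid(drug = drugs, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep_dg <- stats::runif(nrow(dg)) < design$edge_density_dg
    new_interaction_catalog(risk, mg[keep_mg, , drop = FALSE],
                            dg[keep_dg, , drop = FALSE])
  })
}

#' Generate a two-group expression study with planted triplets
#'
#' Background features are i.i.d. normal(0, `noise_sd`) in both groups. Each
#' planted triplet's (gene, miRNA) pair is drawn from a bivariate normal
#' (Cholesky construction) with correlation `rho_disease` in the disease
#' samples and `rho_control` in the controls, and both features' disease
#' means are shifted by `delta * noise_sd`. Planted triplets are chosen with
#' pairwise-distinct genes and miRNAs so each pair carries exactly its
#' requested signal; when `planted_high_risk` is set, planted genes' risk
#' scores are redrawn from the top quartile of the Beta law (the returned
#' catalog reflects this).
#'
#' @param design a `synthetic_design`.
#' @param catalog the catalog from [generate_catalog()] (or compatible).
#' @return list with `study` (an `expression_study`), `truth` (a data frame
#'   of planted triplets with the delta/rho actually used) and `catalog`
#'   (the possibly risk-adjusted catalog).
#' @export
generate_study <- function(design, catalog = generate_catalog(design)) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(catalog, "interaction_catalog"))
  net <- build_tripartite_network(catalog)
  all_triplets <- enumerate_mgdts(net)
  with_seed(design$seed + 1L, {
    planted <- pick_planted(all_triplets, design$n_planted)
    genes <- names(catalog$disease_genes)
    mirnas <- sort(unique(catalog$mirna_targets$mirna))
    n_d <- design$n_disease; n_c <- design$n_control; n <- n_d + n_c
    samples <- c(pad_ids("dis", n_d), pad_ids("ctl", n_c))
    labels <- stats::setNames(rep(c("disease", "control"), c(n_d, n_c)),
                              samples)
    sd0 <- design$noise_sd
    mrna <- matrix(stats::rnorm(length(genes) * n, 0, sd0),
                   nrow = length(genes), dimnames = list(genes, samples))
    mirna <- matrix(stats::rnorm(length(mirnas) * n, 0, sd0),
                    nrow = length(mirnas), dimnames = list(mirnas, samples))
    if (nrow(planted) > 0L) {
      shift <- design$delta * sd0
      for (i in seq_len(nrow(planted))) {
        g <- planted$gene[i]; m <- planted$mirna[i]
        pd <- rbinorm(n_d, design$rho_disease, sd0)
        pc <- rbinorm(n_c, design$rho_control, sd0)
        mrna[g, ] <- c(pd$x + shift, pc$x)
        mirna[m, ] <- c(pd$y + shift, pc$y)
      }
      if (design$planted_high_risk) {
        # top-quartile Beta draws via the inverse CDF
        u <- stats::runif(nrow(planted), 0.75, 1)
        catalog$disease_genes[planted$gene] <-
          stats::qbeta(u, design$risk_alpha, design$risk_beta)
      }
      planted$delta <- design$delta
      planted$rho_disease <- design$rho_disease
      planted$rho_control <- design$rho_control
    }
    list(study = new_expression_study(mrna, mirna, labels),
         truth = planted, catalog = catalog)
  })
}

# bivariate normal pair with the requested correlation
rbinorm <- function(n, rho, sd0) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  list(x = sd0 * z1, y = sd0 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

# greedy selection of triplets with pairwise-distinct genes and miRNAs
pick_planted <- function(triplets, n_planted) {
  empty <- data.frame(mirna = character(), gene = character(),
                      drug = character(), delta = numeric(),
                      rho_disease = numeric(), rho_control = numeric(),
                      stringsAsFactors = FALSE)
  if (n_planted == 0L) return(empty)
  if (nrow(triplets) < n_planted) {
    stop2("requested %d planted triplets but the catalog yields only %d",
          n_planted, nrow(triplets))
  }
  ord <- sample.int(nrow(triplets))
  used_g <- character(0); used_m <- character(0); take <- integer(0)
  for (i in ord) {
    if (triplets$gene[i] %in% used_g || triplets$mirna[i] %in% used_m) next
    take <- c(take, i)
    used_g <- c(used_g, triplets$gene[i])
    used_m <- c(used_m, triplets$mirna[i])
    if (length(take) == n_planted) break
  }
  if (length(take) < n_planted) {
    stop2("catalog supports only %d planted triplets with distinct genes and miRNAs (requested %d)",
          length(take), n_planted)
  }
  out <- triplets[sort(take), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate synthetic pathway gene sets
#'
#' Random gene sets over the catalog's target-gene universe, for exercising
#' the enrichment stage. Set sizes are uniform in `size_range`.
#'
#' @param catalog an `interaction_catalog`.
#' @param n_sets number of pathways.
#' @param size_range integer range of set sizes.
#' @param seed integer seed.
#' @return a `gene_set_collection`.
#' @export
generate_gene_sets <- function(catalog, n_sets = 15L, size_range = c(5L, 15L),
                               seed = 1L) {
  genes <- sort(unique(c(names(catalog$disease_genes),
                         catalog$mirna_targets$gene)))
  with_seed(seed, {
    ids <- pad_ids("PW", n_sets)
    sets <- lapply(seq_len(n_sets), function(i) {
      k <- min(sample(seq(size_range[1L], size_range[2L]), 1L), length(genes))
      sort(sample(genes, k))
    })
    names(sets) <- ids
    structure(list(sets = sets,
                   descriptions = stats::setNames(
                     sprintf("synthetic pathway %d", seq_len(n_sets)), ids)),
              class = "gene_set_collection")
  })
}

#' Write a complete benchmark to disk
#'
#' Materialises a design as the exact file dialects the readers consume
#' (catalog TSVs, expression matrices, label file) plus the ground-truth
#' triplet table and a `key = value` parameter manifest, so the whole
#' pipeline can be driven file-in/file-out.
#'
#' @param design a `synthetic_design`.
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the in-memory `catalog`, `study`, `truth`
#'   and the named file `paths`.
#' @export
make_benchmark <- function(design, dir) {
  stopifnot(inherits(design, "synthetic_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_study(design, generate_catalog(design))
  catalog <- gen$catalog
  paths <- c(disease_genes = file.path(dir, "disease_genes.tsv"),
             mirna_targets = file.path(dir, "mirna_targets.tsv"),
             drug_targets = file.path(dir, "drug_targets.tsv"),
             mrna = file.path(dir, "mrna.tsv"),
             mirna = file.path(dir, "mirna.tsv"),
             labels = file.path(dir, "labels.tsv"),
             ground_truth = file.path(dir, "ground_truth.tsv"),
             manifest = file.path(dir, "design.txt"))
  write_tsv0 <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv0(data.frame(gene = names(catalog$disease_genes),
                        risk_score = sprintf("%.10g", catalog$disease_genes)),
             paths[["disease_genes"]])
  write_tsv0(catalog$mirna_targets, paths[["mirna_targets"]])
  write_tsv0(catalog$drug_targets, paths[["drug_targets"]])
  write_matrix <- function(mat, id_col, path) {
    df <- data.frame(rownames(mat),
                     apply(mat, 2L, function(x) sprintf("%.10g", x)),
                     stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- c(id_col, colnames(mat))
    write_tsv0(df, path)
  }
  write_matrix(gen$study$mrna, "gene", paths[["mrna"]])
  write_matrix(gen$study$mirna, "mirna", paths[["mirna"]])
  write_tsv0(data.frame(sample = gen$study$samples, group = gen$study$labels),
             paths[["labels"]])
  write_tsv0(gen$truth, paths[["ground_truth"]])
  writeLines(sprintf("%s = %s", names(design),
                     vapply(design, format, character(1L))),
             paths[["manifest"]])
  invisible(list(catalog = catalog, study = gen$study, truth = gen$truth,
                 paths = paths))
}
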
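# Pathway enrichment by the hypergeometric upper-tail test (the statistic
# behind standard over-representation tools), per-miRNA pathway profiles
# from target-gene sets, common-pathway extraction, and the miRNA-mediated
# drug-pathway network.

#' Hypergeometric pathway enrichment
#'
#' For each pathway, restricts its gene set to the universe and computes the
#' upper-tail probability `P(X >= overlap)` of the hypergeometric law for
#' drawing `|query|` genes from the universe. Raw P values are gated at
#' `alpha` by default; Benjamini-Hochberg adjustment is optional.
#'
#' @param query character vector of gene ids (restricted to the universe;
#'   must be non-empty after restriction).
#' @param sets a `gene_set_collection`.
#' @param universe character vector of background gene ids.
#' @param alpha enrichment cutoff (strict `p < alpha`).
#' @param bh_adjust gate on BH-adjusted P values instead of raw ones.
#' @return data frame (pathway, overlap, query_size, set_size,
#'   universe_size, p, enriched), sorted by p then pathway id.
#' @export
hypergeometric_enrichment <- function(query, sets, universe, alpha = 0.05,
                                      bh_adjust = FALSE) {
  stopifnot(inherits(sets, "gene_set_collection"), alpha > 0, alpha < 1)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop2("empty gene universe")
  query <- intersect(unique(as.character(query)), universe)
  if (length(query) == 0L) {
    stop2("query is empty after restriction to the universe")
  }
  n_u <- length(universe)
  n_q <- length(query)
  res <- lapply(names(sets$sets), function(id) {
    set <- intersect(sets$sets[[id]], universe)
    k <- length(intersect(query, set))
    # P(X >= k), X ~ Hypergeometric(|set| successes, n_u - |set| failures,
    # n_q draws)
    p <- stats::phyper(k - 1L, length(set), n_u - length(set), n_q,
                       lower.tail = FALSE)
    data.frame(pathway = id, overlap = k, query_size = n_q,
               set_size = length(set), universe_size = n_u, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), overlap = integer(),
                      query_size = integer(), set_size = integer(),
                      universe_size = integer(), p = numeric())
  }
  p_gate <- if (bh_adjust) stats::p.adjust(out$p, method = "BH") else out$p
  out$enriched <- p_gate < alpha
  out <- out[order(out$p, out$pathway, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment universe from catalog and gene sets
#'
#' The default background for miRNA pathway profiles: genes present in both
#' the union of the pathway sets and the miRNA-target catalog. Alternatives:
#' the GMT union alone, or an explicit list.
#'
#' @param catalog an `interaction_catalog`.
#' @param sets a `gene_set_collection`.
#' @param policy one of "catalog_and_gmt", "gmt", "custom".
#' @param custom_genes background for `policy = "custom"`.
#' @return character vector of background gene ids.
#' @export
enrichment_universe <- function(catalog, sets,
                                policy = c("catalog_and_gmt", "gmt", "custom"),
                                custom_genes = NULL) {
  policy <- match.arg(policy)
  gmt_union <- unique(unlist(sets$sets, use.names = FALSE))
  switch(policy,
         catalog_and_gmt = intersect(gmt_union,
                                     unique(catalog$mirna_targets$gene)),
         gmt = gmt_union,
         custom = {
           if (is.null(custom_genes)) stop2("policy 'custom' needs custom_genes")
           unique(as.character(custom_genes))
         })
}

#' Per-miRNA enriched-pathway profiles
#'
#' For each miRNA, tests its catalog target genes for pathway enrichment and
#' records the enriched pathway ids. A miRNA's profile depends only on its
#' own target set; miRNAs with no target gene in the universe are skipped
#' with a warning.
#'
#' @param mirnas character vector of miRNA ids.
#' @param catalog an `interaction_catalog` supplying target sets.
#' @param sets a `gene_set_collection`.
#' @param universe background gene ids (see [enrichment_universe()]).
#' @param alpha enrichment cutoff per pathway.
#' @param bh_adjust gate on BH-adjusted P values.
#' @return named list: miRNA id -> character vector of enriched pathways.
#' @export
mirna_pathway_profiles <- function(mirnas, catalog, sets,
                                   universe = enrichment_universe(catalog, sets),
                                   alpha = 0.05, bh_adjust = FALSE) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  mt <- catalog$mirna_targets
  profiles <- list()
  skipped <- character(0)
  for (m in unique(mirnas)) {
    targets <- intersect(mt$gene[mt$mirna == m], universe)
    if (length(targets) == 0L) {
      skipped <- c(skipped, m)
      next
    }
    enr <- hypergeometric_enrichment(targets, sets, universe, alpha = alpha,
                                     bh_adjust = bh_adjust)
    profiles[[m]] <- enr$pathway[enr$enriched]
  }
  if (length(skipped) > 0L) {
    warn2("skipped %d miRNA(s) with no target gene in the universe: %s",
          length(skipped), paste(skipped, collapse = ", "))
  }
  profiles
}

#' Pathways common to a set of miRNA profiles
#'
#' Returns the pathways enriched in at least `ceil(min_fraction * n)` of the
#' `n` profiles; `min_fraction = 1` is the strict intersection.
#'
#' @param profiles named list of pathway-id vectors.
#' @param min_fraction required fraction of profiles, in (0, 1].
#' @return sorted character vector of pathway ids.
#' @export
common_pathways <- function(profiles, min_fraction = 1.0) {
  if (length(profiles) == 0L) stop2("need >= 1 profile")
  stopifnot(min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * length(profiles))
  tab <- table(unlist(lapply(profiles, unique), use.names = FALSE))
  sort(names(tab)[tab >= need])
}

#' Build the miRNA-mediated drug-pathway network
#'
#' One drug bound to one gene, the miRNAs regulating that gene, and the
#' common pathways; a miRNA is linked to each common pathway its profile
#' contains. This is the view that ties a repurposing candidate to its
#' putative pathway mechanism.
#'
#' @param drug drug id.
#' @param gene gene id (the drug's target).
#' @param profiles named list miRNA -> enriched pathway set (non-empty).
#' @param common character vector of pathway ids, a subset of the union of
#'   the profiles.
#' @return a `tripartite_network` with node classes drug/gene/miRNA/pathway.
#' @export
build_drug_pathway_network <- function(drug, gene, profiles,
                                       common = common_pathways(profiles)) {
  if (length(profiles) == 0L) stop2("empty miRNA profile list")
  extra <- setdiff(common, unique(unlist(profiles, use.names = FALSE)))
  if (length(extra) > 0L) {
    stop2("common pathway(s) not present in any profile: %s",
          paste(extra, collapse = ", "))
  }
  mirnas <- names(profiles)
  nodes <- data.frame(
    id = c(gene, drug, mirnas, common),
    class = rep(c("gene", "drug", "miRNA", "pathway"),
                c(1L, 1L, length(mirnas), length(common))))
  mp <- do.call(rbind, lapply(mirnas, function(m) {
    hit <- intersect(profiles[[m]], common)
    if (length(hit) == 0L) return(NULL)
    data.frame(from = m, to = hit, stringsAsFactors = FALSE)
  }))
  edges <- rbind(data.frame(from = drug, to = gene),
                 data.frame(from = mirnas, to = gene),
                 mp)
  tripartite_network(nodes, edges)
}
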
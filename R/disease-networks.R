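# From significant triplet sets to disease-specific/common networks, drug
# participation rankings and gene-centred star subnetworks.

triplet_key <- function(triplets) {
  paste(triplets$mirna, triplets$gene, triplets$drug, sep = "\r")
}

as_triplet_df <- function(x) {
  out <- data.frame(mirna = as.character(x$mirna), gene = as.character(x$gene),
                    drug = as.character(x$drug), stringsAsFactors = FALSE)
  out <- out[!duplicated(triplet_key(out)), , drop = FALSE]
  out <- out[order_chr(out$mirna, out$gene, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Network induced by a triplet set
#'
#' Nodes are the ids appearing in the triplets; edges are the union of each
#' triplet's (miRNA, gene) and (drug, gene) pairs (shared edges collapse).
#'
#' @param triplets data frame (mirna, gene, drug).
#' @return a `tripartite_network`.
#' @export
significant_network <- function(triplets) {
  triplets <- as_triplet_df(triplets)
  if (nrow(triplets) == 0L) return(tripartite_network())
  nodes <- data.frame(
    id = c(unique(triplets$gene), unique(triplets$mirna), unique(triplets$drug)),
    class = rep(c("gene", "miRNA", "drug"),
                c(length(unique(triplets$gene)), length(unique(triplets$mirna)),
                  length(unique(triplets$drug)))))
  edges <- data.frame(from = c(triplets$mirna, triplets$drug),
                      to = c(triplets$gene, triplets$gene))
  tripartite_network(nodes, edges)
}

#' Compare two triplet sets
#'
#' Intersection and differences on whole (miRNA, gene, drug) triples —
#' a "common" triplet must match in all three components.
#'
#' @param a,b triplet data frames.
#' @return list with `common`, `specific_a` (= a minus common), `specific_b`
#'   (= b minus common); the three are pairwise disjoint.
#' @export
compare_triplet_sets <- function(a, b) {
  a <- as_triplet_df(a); b <- as_triplet_df(b)
  ka <- triplet_key(a); kb <- triplet_key(b)
  list(common = a[ka %in% kb, , drop = FALSE],
       specific_a = a[!(ka %in% kb), , drop = FALSE],
       specific_b = b[!(kb %in% ka), , drop = FALSE])
}

#' Rank drugs by triplet participation
#'
#' Counts, for each drug, the triplets it appears in — the basis for
#' nominating repurposing candidates (the drug in most dysregulated triplets
#' first). Ties are broken lexicographically by drug id.
#'
#' @param triplets triplet data frame.
#' @return data frame (drug, n_triplets), descending by count.
#' @export
drug_participation_ranking <- function(triplets) {
  triplets <- as_triplet_df(triplets)
  if (nrow(triplets) == 0L) {
    return(data.frame(drug = character(), n_triplets = integer()))
  }
  tab <- table(triplets$drug)
  out <- data.frame(drug = names(tab), n_triplets = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_triplets, out$drug, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-centred star subnetwork
#'
#' The subgraph of edges incident to one gene within a triplet set: the gene
#' with every miRNA and drug it is paired with — the drug-target-centred
#' view used to read a repurposing candidate's regulatory context.
#'
#' @param triplets triplet data frame.
#' @param gene a gene id occurring in at least one triplet.
#' @return a `tripartite_network` star.
#' @export
gene_centered_subnetwork <- function(triplets, gene) {
  triplets <- as_triplet_df(triplets)
  sel <- triplets[triplets$gene == gene, , drop = FALSE]
  if (nrow(sel) == 0L) {
    stop2("gene '%s' does not occur in any triplet", gene)
  }
  significant_network(sel)
}

#' Summary statistics of the four score profiles
#'
#' Mean, median, quartiles and a fixed-bin histogram for each of
#' `final_score`, `s_risk`, `s_p` and `s_pcc` — the tabular counterpart of
#' score density curves.
#'
#' @param records scored record data frame.
#' @param bins number of equal-width histogram bins over the observed
#'   min..max range (30 by default).
#' @return list with `summary` (data frame score_type/mean/q25/median/q75)
#'   and `histograms` (named list of data frames bin_lo/bin_hi/count; counts
#'   sum to `nrow(records)`).
#' @export
score_profile_summary <- function(records, bins = 30L) {
  if (nrow(records) == 0L) stop2("score profile needs >= 1 record")
  stopifnot(bins >= 1L)
  types <- intersect(c("final_score", "s_risk", "s_p", "s_pcc"),
                     names(records))
  summarise_one <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(x), q25 = q[1L], median = q[2L], q75 = q[3L])
  }
  summary_df <- data.frame(
    score_type = types,
    t(vapply(records[types], summarise_one, numeric(4L))),
    stringsAsFactors = FALSE)
  names(summary_df) <- c("score_type", "mean", "q25", "median", "q75")
  rownames(summary_df) <- NULL
  histograms <- lapply(records[types], function(x) {
    lo <- min(x); hi <- max(x)
    if (lo == hi) { # all values equal: one occupied bin
      return(data.frame(bin_lo = lo, bin_hi = hi, count = length(x)))
    }
    edges <- seq(lo, hi, length.out = bins + 1L)
    cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = bins)
    data.frame(bin_lo = edges[-(bins + 1L)], bin_hi = edges[-1L], count = cnt)
  })
  list(summary = summary_df, histograms = histograms)
}
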
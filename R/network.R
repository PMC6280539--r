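# The tripartite network container. Nodes carry a class (gene, miRNA, drug,
# and "pathway" for the drug-pathway views); edges are unordered pairs stored
# with a canonical orientation (non-gene endpoint first for gene edges,
# miRNA first for miRNA-pathway edges) so set semantics and writers are
# deterministic.

NODE_CLASSES <- c("gene", "miRNA", "drug", "pathway")

# which unordered class pairs may be joined
ALLOWED_EDGE_CLASSES <- list(
  c("miRNA", "gene"),
  c("drug", "gene"),
  c("miRNA", "pathway"))

edge_relation <- function(class_from, class_to) {
  ifelse(class_from == "miRNA" & class_to == "gene", "targets",
  ifelse(class_from == "drug" & class_to == "gene", "binds",
  ifelse(class_from == "miRNA" & class_to == "pathway", "enriched_in",
         NA_character_)))
}

#' Construct a typed tripartite network
#'
#' Nodes are genes, miRNAs, drugs (plus pathways in drug-pathway views);
#' edges are allowed only between a gene and a miRNA, a gene and a drug, or a
#' miRNA and a pathway. Self-loops and any other class pairing are rejected.
#'
#' @param nodes data frame with columns `id`, `class`.
#' @param edges data frame with columns `from`, `to` (ids present in
#'   `nodes`); orientation is normalised internally.
#' @return a `tripartite_network` with components `nodes` (id, class) and
#'   `edges` (from, to, relation), both sorted lexicographically.
#' @export
tripartite_network <- function(nodes = data.frame(id = character(),
                                                  class = character()),
                               edges = data.frame(from = character(),
                                                  to = character())) {
  nodes <- data.frame(id = as.character(nodes$id),
                      class = as.character(nodes$class),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id)) {
    stop2("duplicate node id '%s'", nodes$id[duplicated(nodes$id)][1L])
  }
  bad_cls <- setdiff(unique(nodes$class), NODE_CLASSES)
  if (length(bad_cls) > 0L) {
    stop2("unknown node class '%s'", bad_cls[1L])
  }
  cls <- stats::setNames(nodes$class, nodes$id)

  from <- as.character(edges$from); to <- as.character(edges$to)
  missing <- setdiff(c(from, to), nodes$id)
  if (length(missing) > 0L) {
    stop2("edge endpoint(s) not in node table: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (any(from == to)) stop2("self-loops are not allowed")
  cf <- cls[from]; ct <- cls[to]
  # canonical orientation: relation-defining endpoint first
  flip <- (ct %in% c("miRNA", "drug") & cf == "gene") |
    (ct == "miRNA" & cf == "pathway")
  tmp <- from[flip]; from[flip] <- to[flip]; to[flip] <- tmp
  cf <- cls[from]; ct <- cls[to]
  rel <- edge_relation(cf, ct)
  if (anyNA(rel)) {
    i <- which(is.na(rel))[1L]
    stop2("edge %s--%s joins classes %s and %s, which is not allowed",
          from[i], to[i], cf[i], ct[i])
  }
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  edges <- data.frame(from = from[keep], to = to[keep],
                      relation = rel[keep], stringsAsFactors = FALSE)
  nodes <- nodes[order_chr(nodes$class, nodes$id), , drop = FALSE]
  edges <- edges[order_chr(edges$relation, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  counts <- table(factor(x$nodes$class, levels = NODE_CLASSES))
  cat(sprintf("tripartite_network: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", counts, names(counts))[counts > 0],
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

node_classes <- function(net) stats::setNames(net$nodes$class, net$nodes$id)

#' Build the miRNA-gene-drug network from an interaction catalog
#'
#' Keeps only target pairs whose gene is a disease-associated gene, and only
#' disease genes with at least one miRNA or drug partner (no isolated
#' nodes): the triplet analyses downstream are entirely edge-driven.
#'
#' @param catalog an `interaction_catalog`.
#' @return a `tripartite_network` of gene, miRNA and drug nodes.
#' @export
build_tripartite_network <- function(catalog) {
  stopifnot(inherits(catalog, "interaction_catalog"))
  genes <- names(catalog$disease_genes)
  mt <- catalog$mirna_targets[catalog$mirna_targets$gene %in% genes, , drop = FALSE]
  dt <- catalog$drug_targets[catalog$drug_targets$gene %in% genes, , drop = FALSE]
  used_genes <- sort(unique(c(mt$gene, dt$gene)))
  nodes <- data.frame(
    id = c(used_genes, sort(unique(mt$mirna)), sort(unique(dt$drug))),
    class = rep(c("gene", "miRNA", "drug"),
                c(length(used_genes), length(unique(mt$mirna)),
                  length(unique(dt$drug)))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = c(mt$mirna, dt$drug), to = c(mt$gene, dt$gene),
                      stringsAsFactors = FALSE)
  tripartite_network(nodes, edges)
}

#' Enumerate all miRNA-gene-drug triplets
#'
#' A triplet is a miRNA and a drug that both target the same gene; the
#' number of triplets equals the sum over genes of
#' (miRNA degree x drug degree). Output is in lexicographic
#' (miRNA, gene, drug) order.
#'
#' @param net a `tripartite_network`.
#' @return data frame with columns `mirna`, `gene`, `drug`.
#' @export
enumerate_mgdts <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  e <- net$edges
  mg <- e[e$relation == "targets", c("from", "to")]
  dg <- e[e$relation == "binds", c("from", "to")]
  if (nrow(mg) == 0L || nrow(dg) == 0L) {
    return(data.frame(mirna = character(), gene = character(),
                      drug = character(), stringsAsFactors = FALSE))
  }
  merged <- merge(mg, dg, by = "to", suffixes = c(".m", ".d"))
  out <- data.frame(mirna = merged$from.m, gene = merged$to,
                    drug = merged$from.d, stringsAsFactors = FALSE)
  out <- out[order_chr(out$mirna, out$gene, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree distribution, per-class mean degrees and hub list
#'
#' @param net a `tripartite_network`.
#' @param k size of the top-degree node list (ties broken by id).
#' @return list with `distribution` (data frame degree/count over nodes with
#'   degree >= 1 plus a 0 row if isolated nodes exist), `class_means` (named
#'   numeric; `NA` for classes absent from the network) and `top` (data frame
#'   node/class/degree of the `k` highest-degree nodes).
#' @export
degree_stats <- function(net, k = 10L) {
  stopifnot(inherits(net, "tripartite_network"), k >= 1L)
  deg <- node_degrees(net)
  if (length(deg) == 0L) {
    return(list(distribution = data.frame(degree = integer(), count = integer()),
                class_means = stats::setNames(numeric(0), character(0)),
                top = data.frame(node = character(), class = character(),
                                 degree = integer())))
  }
  tab <- table(deg)
  distribution <- data.frame(degree = as.integer(names(tab)),
                             count = as.integer(tab))
  cls <- net$nodes$class
  class_means <- vapply(split(deg, cls), mean, numeric(1L))
  ord <- order(-deg, net$nodes$id, method = "radix")
  top <- utils::head(data.frame(node = net$nodes$id[ord], class = cls[ord],
                                degree = deg[ord], stringsAsFactors = FALSE),
                     k)
  rownames(top) <- NULL
  list(distribution = distribution, class_means = class_means, top = top)
}

node_degrees <- function(net) {
  deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes$id))
  stats::setNames(as.integer(deg), net$nodes$id)
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of log10(count) on log10(degree) over the raw
#' (unbinned) integer degree frequencies, the log-log regression commonly
#' used to report scale-free topology. Optional logarithmic binning averages
#' counts within degree octaves before fitting.
#'
#' @param dist data frame with columns `degree`, `count` (as produced by
#'   [degree_stats()]), or a named vector degree -> count.
#' @param binned if `TRUE`, counts are pooled into log2-spaced degree bins
#'   before the fit. Off by default.
#' @return list with `slope`, `intercept`, `r_squared`.
#' @export
fit_power_law <- function(dist, binned = FALSE) {
  if (!is.data.frame(dist)) {
    dist <- data.frame(degree = as.numeric(names(dist)),
                       count = as.numeric(dist))
  }
  dist <- dist[dist$degree > 0 & dist$count > 0, , drop = FALSE]
  if (binned && nrow(dist) > 0L) {
    bin <- floor(log2(dist$degree))
    deg <- vapply(split(dist$degree, bin), mean, numeric(1L))
    cnt <- vapply(split(dist$count, bin), mean, numeric(1L))
    dist <- data.frame(degree = deg, count = cnt)
  }
  if (length(unique(dist$degree)) < 3L) {
    stop2("underdetermined fit: need >= 3 distinct degrees with nonzero counts, got %d",
          length(unique(dist$degree)))
  }
  fit <- stats::lm(log10(count) ~ log10(degree), data = dist)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Topological coefficients
#'
#' For a node n with degree k_n >= 2, the topological coefficient is the
#' mean over all other nodes m sharing at least one neighbour with n of
#' J(n,m)/k_n, where J(n,m) is the number of shared neighbours plus one if n
#' and m are directly linked. Nodes with degree < 2 or no shared-neighbour
#' partner get 0. In hierarchical networks the coefficient decays with
#' degree.
#'
#' Accepts either a `tripartite_network` or a plain two-column edge table
#' (any undirected simple graph), so the metric can be validated on
#' unconstrained graphs.
#'
#' @param x a `tripartite_network` or a two-column data frame / matrix of
#'   edges.
#' @return named numeric vector of coefficients, one per node.
#' @export
topological_coefficients <- function(x) {
  if (inherits(x, "tripartite_network")) {
    edges <- cbind(x$edges$from, x$edges$to)
    ids <- x$nodes$id
  } else {
    edges <- cbind(as.character(x[[1L]]), as.character(x[[2L]]))
    ids <- sort(unique(as.vector(edges)))
  }
  n <- length(ids)
  tc <- stats::setNames(numeric(n), ids)
  if (nrow(edges) == 0L || n == 0L) return(tc)
  # sparse adjacency as a logical incidence matrix: fine at analysis scale
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  A[edges] <- TRUE
  A[edges[, 2:1, drop = FALSE]] <- TRUE
  deg <- rowSums(A)
  shared <- (A %*% A) # shared-neighbour counts, integer-valued
  J <- shared + A     # +1 when directly linked
  diag(J) <- 0
  has_partner <- shared > 0
  diag(has_partner) <- FALSE
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    part <- which(has_partner[i, ])
    if (length(part) == 0L) next
    tc[i] <- mean(J[i, part]) / deg[i]
  }
  tc
}

#' Node-level topology table
#'
#' Convenience wrapper joining degree and topological coefficient per node.
#' @param net a `tripartite_network`.
#' @return data frame (node, class, degree, topological_coefficient).
#' @export
topology_table <- function(net) {
  deg <- node_degrees(net)
  tc <- topological_coefficients(net)
  data.frame(node = net$nodes$id, class = net$nodes$class,
             degree = unname(deg[net$nodes$id]),
             topological_coefficient = unname(tc[net$nodes$id]),
             stringsAsFactors = FALSE)
}
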
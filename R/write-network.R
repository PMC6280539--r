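# Network export/import: SIF (node TAB relation TAB node), a minimal GraphML
# dialect carrying the node_class attribute, and a flat edge TSV. Line order
# is deterministic (lexicographic) and every writer ends with a newline.

#' Write a network to SIF, GraphML or edge-TSV
#'
#' SIF lines are `from<TAB>relation<TAB>to` with relations `targets`
#' (miRNA-gene), `binds` (drug-gene) and `enriched_in` (miRNA-pathway).
#' GraphML carries a `node_class` node attribute; edge-TSV has the columns
#' `from`, `relation`, `to`, `from_class`, `to_class`. Isolated nodes survive
#' GraphML and edge-TSV round-trips; SIF, by format, only carries nodes with
#' edges plus a single-column line per isolated node.
#'
#' @param net a `tripartite_network`.
#' @param path output path.
#' @param format one of "sif", "graphml", "tsv".
#' @return the path, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "tripartite_network"))
  format <- match.arg(tolower(format), c("sif", "graphml", "tsv"))
  e <- net$edges
  switch(format,
    sif = {
      lines <- sprintf("%s\t%s\t%s", e$from, e$relation, e$to)
      isolated <- setdiff(net$nodes$id, c(e$from, e$to))
      lines <- c(sort(lines), sort(isolated))
      writeLines(lines, path, useBytes = TRUE)
    },
    tsv = {
      cls <- node_classes(net)
      header <- "from\trelation\tto\tfrom_class\tto_class"
      lines <- sprintf("%s\t%s\t%s\t%s\t%s", e$from, e$relation, e$to,
                       cls[e$from], cls[e$to])
      isolated <- setdiff(net$nodes$id, c(e$from, e$to))
      iso_lines <- sprintf("%s\t\t\t%s\t", isolated, cls[isolated])
      writeLines(c(header, sort(lines), sort(iso_lines)), path, useBytes = TRUE)
    },
    graphml = write_graphml(net, path))
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

write_graphml <- function(net, path) {
  n <- net$nodes[order_chr(net$nodes$id), , drop = FALSE]
  e <- net$edges
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"d0\" for=\"node\" attr.name=\"node_class\" attr.type=\"string\"/>",
    "  <key id=\"d1\" for=\"edge\" attr.name=\"relation\" attr.type=\"string\"/>",
    "  <graph id=\"G\" edgedefault=\"undirected\">",
    sprintf("    <node id=\"%s\"><data key=\"d0\">%s</data></node>",
            xml_escape(n$id), n$class),
    sort(sprintf("    <edge source=\"%s\" target=\"%s\"><data key=\"d1\">%s</data></edge>",
                 xml_escape(e$from), xml_escape(e$to), e$relation)),
    "  </graph>",
    "</graphml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' SIF input infers node classes from the relation labels; GraphML and
#' edge-TSV carry classes explicitly.
#'
#' @param path input path.
#' @param format one of "sif", "graphml", "tsv".
#' @return a `tripartite_network`.
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(tolower(format), c("sif", "graphml", "tsv"))
  assert_file_exists(path)
  switch(format,
    sif = read_network_sif(path),
    tsv = read_network_tsv(path),
    graphml = read_network_graphml(path))
}

read_network_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- lengths(parts) >= 3L
  e <- do.call(rbind, parts[is_edge])
  iso <- unlist(parts[!is_edge])
  if (is.null(e)) {
    if (length(iso) > 0L) {
      stop2("SIF '%s' has isolated nodes but no relations to infer classes from", path)
    }
    return(tripartite_network())
  }
  cls_from <- c(targets = "miRNA", binds = "drug", enriched_in = "miRNA")
  cls_to <- c(targets = "gene", binds = "gene", enriched_in = "pathway")
  unknown <- setdiff(unique(e[, 2L]), names(cls_from))
  if (length(unknown) > 0L) {
    stop2("unknown SIF relation '%s' in '%s'", unknown[1L], path)
  }
  ids <- c(e[, 1L], e[, 3L], iso)
  classes <- c(cls_from[e[, 2L]], cls_to[e[, 2L]],
               rep(NA_character_, length(iso)))
  keep <- !duplicated(ids)
  if (anyNA(classes[keep])) {
    stop2("cannot infer a class for isolated node(s) in SIF '%s'", path)
  }
  tripartite_network(
    nodes = data.frame(id = ids[keep], class = classes[keep]),
    edges = data.frame(from = e[, 1L], to = e[, 3L]))
}

read_network_tsv <- function(path) {
  tab <- read_tsv_table(path, n_cols_min = 1L)
  if (nrow(tab) == 0L) return(tripartite_network())
  is_edge <- nzchar(tab$relation) & !is.na(tab$relation)
  ids <- c(tab$from[is_edge], tab$to[is_edge], tab$from[!is_edge])
  classes <- c(tab$from_class[is_edge], tab$to_class[is_edge],
               tab$from_class[!is_edge])
  keep <- !duplicated(ids)
  tripartite_network(
    nodes = data.frame(id = ids[keep], class = classes[keep]),
    edges = data.frame(from = tab$from[is_edge], to = tab$to[is_edge]))
}

read_network_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(node_els, "id"),
    class = xml2::xml_text(xml2::xml_find_first(node_els, "./g:data", ns)),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    stringsAsFactors = FALSE)
  tripartite_network(nodes, edges)
}
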
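# Readers for the three interaction catalogs, paired expression matrices and
# GMT gene sets. All inputs are tab-separated with one header line; lines
# starting with '#' are ignored. Identifier case is preserved verbatim and no
# symbol normalisation is attempted.

new_interaction_catalog <- function(disease_genes, mirna_targets, drug_targets) {
  stopifnot(is.numeric(disease_genes))
  structure(
    list(disease_genes = disease_genes,
         mirna_targets = mirna_targets,
         drug_targets = drug_targets),
    class = "interaction_catalog")
}

#' Read an interaction catalog
#'
#' Loads the three tables a triplet network is built from: disease-associated
#' genes with a per-gene risk score (a DisGeNET-style gene-disease confidence
#' value), experimentally supported miRNA-to-gene target pairs, and
#' drug-to-gene target pairs. Duplicate pairs are collapsed to a set and the
#' number of duplicates is reported.
#'
#' Each file is tab-separated with a single header line; `#` comment lines are
#' skipped. Column positions define the roles: the disease-gene file is
#' `gene<TAB>risk_score`, the miRNA file `mirna<TAB>gene`, the drug file
#' `drug<TAB>gene`.
#'
#' @param disease_gene_path path to the gene/risk-score table.
#' @param mirna_target_path path to the miRNA-target pair table.
#' @param drug_target_path path to the drug-target pair table.
#' @param quiet suppress the per-file row-count messages.
#' @return an `interaction_catalog`: a list with `disease_genes` (named
#'   numeric vector of risk scores), `mirna_targets` and `drug_targets`
#'   (two-column character data frames, one row per unique pair).
#' @export
read_interaction_catalog <- function(disease_gene_path, mirna_target_path,
                                     drug_target_path, quiet = FALSE) {
  dg <- read_tsv_table(disease_gene_path, n_cols_min = 2L)
  ln <- attr(dg, "line_numbers")
  gene <- trimws(dg[[1L]])
  if (any(!nzchar(gene))) {
    stop2("empty gene identifier in '%s' at line %d",
          disease_gene_path, ln[which(!nzchar(gene))[1L]])
  }
  score <- suppressWarnings(as.numeric(dg[[2L]]))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad) > 0L) {
    stop2("non-numeric or non-finite risk score '%s' in '%s' at line %d",
          dg[[2L]][bad[1L]], disease_gene_path, ln[bad[1L]])
  }
  dup_g <- duplicated(gene)
  disease_genes <- stats::setNames(score[!dup_g], gene[!dup_g])
  if (any(disease_genes < 0 | disease_genes > 1)) {
    warn2("%d risk score(s) fall outside [0,1]; kept as-is",
          sum(disease_genes < 0 | disease_genes > 1))
  }

  read_pairs <- function(path, col_names) {
    tab <- read_tsv_table(path, n_cols_min = 2L)
    ln <- attr(tab, "line_numbers")
    a <- trimws(tab[[1L]]); b <- trimws(tab[[2L]])
    empty <- which(!nzchar(a) | !nzchar(b))
    if (length(empty) > 0L) {
      stop2("empty identifier in '%s' at line %d", path, ln[empty[1L]])
    }
    dup <- duplicated(paste(a, b, sep = "\r"))
    out <- data.frame(a = a[!dup], b = b[!dup], stringsAsFactors = FALSE)
    names(out) <- col_names
    attr(out, "n_dropped") <- sum(dup)
    out
  }
  mt <- read_pairs(mirna_target_path, c("mirna", "gene"))
  dt <- read_pairs(drug_target_path, c("drug", "gene"))
  if (!quiet) {
    msg("disease genes: %d read, %d kept (%d duplicate)",
        length(gene), length(disease_genes), sum(dup_g))
    msg("miRNA-gene pairs: %d read, %d kept (%d duplicate)",
        nrow(mt) + attr(mt, "n_dropped"), nrow(mt), attr(mt, "n_dropped"))
    msg("drug-gene pairs: %d read, %d kept (%d duplicate)",
        nrow(dt) + attr(dt, "n_dropped"), nrow(dt), attr(dt, "n_dropped"))
  }
  new_interaction_catalog(disease_genes, mt, dt)
}

read_expression_matrix <- function(path) {
  tab <- read_tsv_table(path, n_cols_min = 2L)
  ln <- attr(tab, "line_numbers")
  ids <- trimws(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop2("non-numeric expression value '%s' in '%s' at line %d, column '%s'",
          vals[bad[1L, , drop = FALSE]], path, ln[bad[1L, 1L]],
          colnames(vals)[bad[1L, 2L]])
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Read a paired two-group expression study
#'
#' Loads an mRNA matrix (genes x samples), a miRNA matrix (miRNAs x samples)
#' and a per-sample label file assigning each sample to the `disease` or
#' `control` group. The two matrices must cover the same samples; the miRNA
#' matrix is reordered to the mRNA sample order. Feature rows containing
#' missing values are dropped (the scoring stage requires complete vectors)
#' and the dropped count is reported.
#'
#' @param mrna_path tab-separated matrix, first column gene id, remaining
#'   columns samples.
#' @param mirna_path tab-separated matrix, first column miRNA id.
#' @param labels_path two-column table `sample<TAB>group`, group in
#'   \{disease, control\}.
#' @param quiet suppress row-drop messages.
#' @return an `expression_study`: list with matrices `mrna`, `mirna` and the
#'   character vector `labels` aligned with the shared sample order.
#' @export
read_expression_study <- function(mrna_path, mirna_path, labels_path,
                                  quiet = FALSE) {
  mrna <- read_expression_matrix(mrna_path)
  mirna <- read_expression_matrix(mirna_path)
  if (!setequal(colnames(mrna), colnames(mirna))) {
    only_a <- setdiff(colnames(mrna), colnames(mirna))
    only_b <- setdiff(colnames(mirna), colnames(mrna))
    stop2("sample sets differ between '%s' and '%s' (only in mRNA: %s; only in miRNA: %s)",
          mrna_path, mirna_path,
          if (length(only_a)) paste(only_a, collapse = ",") else "-",
          if (length(only_b)) paste(only_b, collapse = ",") else "-")
  }
  mirna <- mirna[, colnames(mrna), drop = FALSE]

  lab_tab <- read_tsv_table(labels_path, n_cols_min = 2L)
  samp <- trimws(lab_tab[[1L]])
  grp <- trimws(lab_tab[[2L]])
  unknown <- setdiff(samp, colnames(mrna))
  if (length(unknown) > 0L) {
    stop2("label file '%s' references sample(s) absent from the matrices: %s",
          labels_path, paste(unknown, collapse = ", "))
  }
  missing_lab <- setdiff(colnames(mrna), samp)
  if (length(missing_lab) > 0L) {
    stop2("sample(s) without a label in '%s': %s", labels_path,
          paste(missing_lab, collapse = ", "))
  }
  bad_grp <- setdiff(unique(grp), c("disease", "control"))
  if (length(bad_grp) > 0L) {
    stop2("unknown group label(s) in '%s': %s (expected 'disease'/'control')",
          labels_path, paste(bad_grp, collapse = ", "))
  }
  labels <- stats::setNames(grp, samp)[colnames(mrna)]

  drop_incomplete <- function(mat, what) {
    keep <- stats::complete.cases(mat)
    if (!all(keep) && !quiet) {
      msg("%s: dropped %d row(s) with missing values", what, sum(!keep))
    }
    mat[keep, , drop = FALSE]
  }
  mrna <- drop_incomplete(mrna, "mRNA matrix")
  mirna <- drop_incomplete(mirna, "miRNA matrix")
  new_expression_study(mrna, mirna, labels)
}

new_expression_study <- function(mrna, mirna, labels) {
  stopifnot(identical(colnames(mrna), colnames(mirna)),
            identical(colnames(mrna), names(labels)),
            all(labels %in% c("disease", "control")))
  if (!any(labels == "disease") || !any(labels == "control")) {
    stop2("each group needs at least one sample (got %d disease, %d control)",
          sum(labels == "disease"), sum(labels == "control"))
  }
  structure(list(mrna = mrna, mirna = mirna, labels = unname(labels),
                 samples = colnames(mrna)),
            class = "expression_study")
}

#' Read pathway gene sets in GMT format
#'
#' One pathway per line: `name<TAB>description<TAB>gene<TAB>gene...`. Genes
#' are deduplicated per set; sets left empty are dropped with a warning;
#' duplicate pathway ids are an error.
#'
#' @param gmt_path path to the GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character vector).
#' @export
read_gene_sets <- function(gmt_path) {
  assert_file_exists(gmt_path)
  lines <- readLines(gmt_path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short) > 0L) {
    stop2("GMT line %d in '%s' has fewer than 3 fields", line_no[short[1L]],
          gmt_path)
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop2("duplicate pathway id '%s' in '%s'", ids[duplicated(ids)][1L],
          gmt_path)
  }
  descriptions <- stats::setNames(vapply(parts, `[[`, character(1L), 2L), ids)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn2("dropped %d empty gene set(s): %s", sum(empty),
          paste(ids[empty], collapse = ", "))
    sets <- sets[!empty]
    descriptions <- descriptions[!empty]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' Write pathway gene sets in GMT format
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  ids <- names(sets$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, sets$descriptions[[id]], sets$sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.interaction_catalog <- function(x, ...) {
  cat(sprintf("interaction_catalog: %d disease genes, %d miRNA-gene pairs, %d drug-gene pairs\n",
              length(x$disease_genes), nrow(x$mirna_targets), nrow(x$drug_targets)))
  invisible(x)
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes, %d miRNAs, %d samples (%d disease / %d control)\n",
              nrow(x$mrna), nrow(x$mirna), length(x$labels),
              sum(x$labels == "disease"), sum(x$labels == "control")))
  invisible(x)
}
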
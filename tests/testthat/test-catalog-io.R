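test_that("interaction catalogs load with deduplication and validation", {
  dir <- withr::local_tempdir()
  dg <- file.path(dir, "dg.tsv"); mt <- file.path(dir, "mt.tsv")
  dt <- file.path(dir, "dt.tsv")
  writeLines(c("gene\trisk", "g1\t0.9", "g2\t0.5", "g3\t0.1"), dg)
  # 4 miRNA rows, one duplicate -> 3 kept
  writeLines(c("mirna\tgene", "m1\tg1", "m1\tg2", "m1\tg1", "m2\tg3"), mt)
  writeLines(c("drug\tgene", "d1\tg1", "d2\tg2"), dt)
  cat <- read_interaction_catalog(dg, mt, dt, quiet = TRUE)
  expect_equal(length(cat$disease_genes), 3L)
  expect_equal(nrow(cat$mirna_targets), 3L)
  expect_equal(nrow(cat$drug_targets), 2L)
  expect_equal(cat$disease_genes[["g1"]], 0.9)

  # header-only files -> empty catalog
  writeLines("gene\trisk", dg); writeLines("mirna\tgene", mt)
  writeLines("drug\tgene", dt)
  empty <- read_interaction_catalog(dg, mt, dt, quiet = TRUE)
  expect_equal(length(empty$disease_genes), 0L)
  expect_equal(nrow(empty$mirna_targets), 0L)
  expect_equal(nrow(empty$drug_targets), 0L)

  # malformed rows are named with file and line
  writeLines(c("gene\trisk", "g1\t0.9", "g2\tnot_a_number"), dg)
  expect_error(read_interaction_catalog(dg, mt, dt, quiet = TRUE),
               "line 3")
  writeLines(c("gene\trisk", "g1"), dg)
  expect_error(read_interaction_catalog(dg, mt, dt, quiet = TRUE),
               "malformed row")

  # out-of-range risk scores warn but are kept verbatim
  writeLines(c("gene\trisk", "g1\t1.7"), dg)
  writeLines(c("mirna\tgene", "m1\tg1"), mt)
  expect_warning(cat2 <- read_interaction_catalog(dg, mt, dt, quiet = TRUE),
                 "outside")
  expect_equal(cat2$disease_genes[["g1"]], 1.7)
})

test_that("catalog loading is idempotent", {
  p <- write_catalog_files(random_catalog(3))
  a <- read_interaction_catalog(p[["dg"]], p[["mt"]], p[["dt"]], quiet = TRUE)
  b <- read_interaction_catalog(p[["dg"]], p[["mt"]], p[["dt"]], quiet = TRUE)
  expect_identical(a, b)
})

test_that("expression studies load with aligned samples and labels", {
  dir <- withr::local_tempdir()
  mr <- file.path(dir, "mrna.tsv"); mi <- file.path(dir, "mirna.tsv")
  lb <- file.path(dir, "labels.tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4\ts5\ts6",
               "g1\t1\t2\t3\t4\t5\t6", "g2\t6\t5\t4\t3\t2\t1"), mr)
  # miRNA columns deliberately in another order
  writeLines(c("mirna\ts6\ts5\ts4\ts3\ts2\ts1",
               "m1\t1\t1\t1\t2\t2\t2", "m2\t0\t0\t1\t1\t0\t0"), mi)
  writeLines(c("sample\tgroup", "s1\tdisease", "s2\tdisease", "s3\tdisease",
               "s4\tcontrol", "s5\tcontrol", "s6\tcontrol"), lb)
  st <- read_expression_study(mr, mi, lb, quiet = TRUE)
  expect_equal(dim(st$mrna), c(2L, 6L))
  expect_equal(dim(st$mirna), c(2L, 6L))
  expect_identical(colnames(st$mrna), colnames(st$mirna))
  expect_equal(sum(st$labels == "disease"), 3L)
  expect_equal(sum(st$labels == "control"), 3L)
  # reindexing put the right values in place
  expect_equal(unname(st$mirna["m1", "s1"]), 2)

  # unknown sample in the label file is named
  writeLines(c("sample\tgroup", "s1\tdisease", "sX\tcontrol"), lb)
  expect_error(read_expression_study(mr, mi, lb, quiet = TRUE), "sX")

  # non-numeric cell reports row and column
  writeLines(c("sample\tgroup", "s1\tdisease", "s2\tdisease", "s3\tdisease",
               "s4\tcontrol", "s5\tcontrol", "s6\tcontrol"), lb)
  writeLines(c("gene\ts1\ts2\ts3\ts4\ts5\ts6",
               "g1\t1\t2\toops\t4\t5\t6"), mr)
  expect_error(read_expression_study(mr, mi, lb, quiet = TRUE),
               "line 2.*s3")

  # sample mismatch between matrices lists the difference
  writeLines(c("gene\ts1\ts2\ts3\ts4\ts5\ts7",
               "g1\t1\t2\t3\t4\t5\t6"), mr)
  expect_error(read_expression_study(mr, mi, lb, quiet = TRUE), "s7")
})

test_that("rows with missing values are dropped with a logged count", {
  dir <- withr::local_tempdir()
  mr <- file.path(dir, "mrna.tsv"); mi <- file.path(dir, "mirna.tsv")
  lb <- file.path(dir, "labels.tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4", "g2\tNA\t5\t4\t3"), mr)
  writeLines(c("mirna\ts1\ts2\ts3\ts4", "m1\t1\t1\t2\t2"), mi)
  writeLines(c("sample\tgroup", "s1\tdisease", "s2\tdisease",
               "s3\tcontrol", "s4\tcontrol"), lb)
  expect_message(st <- read_expression_study(mr, mi, lb), "dropped 1")
  expect_equal(rownames(st$mrna), "g1")
})

test_that("GMT gene sets parse, deduplicate and validate", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("P1\tdesc\tg1\tg2", "P2\tdesc\tg1\tg1"), gmt)
  gs <- read_gene_sets(gmt)
  expect_equal(gs$sets$P1, c("g1", "g2"))
  expect_equal(gs$sets$P2, "g1") # within-set duplicates collapse

  writeLines(c("P1\tdesc\tg1", "P1\tdesc\tg2"), gmt)
  expect_error(read_gene_sets(gmt), "duplicate pathway id")

  writeLines(c("P1\tdesc"), gmt)
  expect_error(read_gene_sets(gmt), "fewer than 3")

  # empty sets are dropped with a warning; round trip preserves content
  writeLines(c("P1\tdesc\tg1\tg2\tg3", "P2\tdesc\t\t"), gmt)
  expect_warning(gs2 <- read_gene_sets(gmt), "empty")
  expect_named(gs2$sets, "P1")
  out <- file.path(dir, "out.gmt")
  write_gene_sets(gs2, out)
  expect_identical(read_gene_sets(out), gs2)
})

test_that("network writers round-trip node classes and edge sets", {
  # single-edge SIF line matches the format definition
  net1 <- tripartite_network(
    nodes = data.frame(id = c("m1", "g1"), class = c("miRNA", "gene")),
    edges = data.frame(from = "m1", to = "g1"))
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "one.sif")
  write_network(net1, sif, "sif")
  expect_identical(readLines(sif), "m1\ttargets\tg1")

  # empty network -> zero-line SIF
  write_network(tripartite_network(), sif, "sif")
  expect_length(readLines(sif), 0L)

  # random networks round-trip exactly through all three formats
  for (seed in 1:5) {
    net <- build_tripartite_network(random_catalog(seed))
    for (fmt in c("sif", "graphml", "tsv")) {
      path <- file.path(dir, paste0("net.", fmt))
      write_network(net, path, fmt)
      back <- read_network(path, fmt)
      expect_identical(back$nodes, net$nodes)
      expect_identical(back$edges, net$edges)
    }
  }
})

test_that("GraphML output parses in an independent graph library", {
  skip_if_not_installed("igraph")
  net <- build_tripartite_network(random_catalog(7))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, path, "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$node_class, net$nodes$class)
})
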
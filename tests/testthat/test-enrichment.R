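make_sets <- function(sets) {
  structure(list(sets = sets,
                 descriptions = stats::setNames(rep("", length(sets)),
                                                names(sets))),
            class = "gene_set_collection")
}

test_that("hypergeometric enrichment reproduces exact tail probabilities", {
  universe <- sprintf("g%02d", 1:10)
  sets <- make_sets(list(P1 = universe[1:5]))
  # query of 5 overlapping all 5 set genes: p = 1/C(10,5) = 1/252
  res <- hypergeometric_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-15)
  expect_equal(res$overlap, 5L)
  expect_true(res$enriched)

  # query = universe -> certain overlap, p = 1
  res2 <- hypergeometric_enrichment(universe, sets, universe)
  expect_equal(res2$p, 1)
  # zero overlap -> upper tail from zero is 1
  sets0 <- make_sets(list(P1 = universe[1:5]))
  res3 <- hypergeometric_enrichment(universe[6:7], sets0, universe)
  expect_equal(res3$overlap, 0L)
  expect_equal(res3$p, 1)

  expect_error(hypergeometric_enrichment("absent", sets, universe),
               "empty after restriction")
})

test_that("enrichment p matches exhaustive subset enumeration", {
  for (seed in 1:50) {
    set.seed(seed)
    n_u <- sample(6:12, 1)
    universe <- sprintf("u%02d", seq_len(n_u))
    set_genes <- sample(universe, sample(2:(n_u - 1), 1))
    query <- sample(universe, sample(2:min(6, n_u - 1), 1))
    res <- hypergeometric_enrichment(query, make_sets(list(S = set_genes)),
                                     universe)
    expect_equal(res$p, naive_enrichment_p(universe, set_genes, query),
                 tolerance = 1e-12)
  }
})

test_that("enrichment p decreases as overlap grows", {
  universe <- sprintf("u%02d", 1:20)
  set_genes <- universe[1:8]
  sets <- make_sets(list(S = set_genes))
  p_at <- vapply(1:8, function(k) {
    query <- c(set_genes[seq_len(k)], universe[9:(16 - k + 1)])[1:8]
    hypergeometric_enrichment(query, sets, universe)$p
  }, numeric(1))
  expect_true(all(diff(p_at) < 0))
})

test_that("miRNA pathway profiles are per-miRNA and independent", {
  cat <- mgdtnet:::new_interaction_catalog(
    c(g1 = .5, g2 = .5, g3 = .5, g4 = .5, g5 = .5, g6 = .5),
    data.frame(mirna = c("mA", "mA", "mA", "mB", "mB", "mC"),
               gene = c("g1", "g2", "g3", "g4", "g5", "gZ")),
    data.frame(drug = "d1", gene = "g1"))
  sets <- make_sets(list(P1 = c("g1", "g2", "g3"),
                         P2 = c("g4", "g5", "g6")))
  universe <- enrichment_universe(cat, sets)
  expect_setequal(universe, c("g1", "g2", "g3", "g4", "g5"))

  expect_warning(
    prof <- mirna_pathway_profiles(c("mA", "mB", "mC"), cat, sets,
                                   universe = universe),
    "mC")
  expect_named(prof, c("mA", "mB"))
  # compositional oracle: each profile equals a direct enrichment call
  for (m in names(prof)) {
    targets <- intersect(
      cat$mirna_targets$gene[cat$mirna_targets$mirna == m], universe)
    direct <- hypergeometric_enrichment(targets, sets, universe)
    expect_setequal(prof[[m]], direct$pathway[direct$enriched])
  }
  # adding an unrelated miRNA leaves existing profiles unchanged
  cat2 <- cat
  cat2$mirna_targets <- rbind(cat2$mirna_targets,
                              data.frame(mirna = "mD", gene = "g2"))
  prof2 <- mirna_pathway_profiles(c("mA", "mB", "mD"), cat2, sets,
                                  universe = universe)
  expect_identical(prof2[c("mA", "mB")], prof[c("mA", "mB")])
})

test_that("common pathways respect the membership fraction", {
  prof <- list(m1 = c("A", "B"), m2 = c("B", "C"), m3 = c("B", "D"))
  expect_equal(common_pathways(prof), "B")
  expect_equal(common_pathways(prof["m1"]), c("A", "B"))
  expect_length(common_pathways(list(m1 = "A", m2 = "C")), 0L)
  # brute-force membership counting at min_fraction = 2/3
  got <- common_pathways(prof, min_fraction = 2 / 3)
  counts <- table(unlist(prof))
  expect_setequal(got, names(counts)[counts >= 2])
  # strict intersection equals Reduce(intersect, .)
  for (seed in 1:10) {
    set.seed(seed)
    p <- replicate(4, sample(LETTERS[1:8], sample(2:6, 1)),
                   simplify = FALSE)
    names(p) <- paste0("m", 1:4)
    expect_setequal(common_pathways(p, 1), Reduce(intersect, p))
  }
})

test_that("drug-pathway networks wire drug, gene, miRNAs and pathways", {
  prof <- list(mA = c("P1", "P2"), mB = "P1")
  net <- build_drug_pathway_network("d1", "g1", prof, common = "P1")
  expect_equal(nrow(net$nodes), 5L) # drug + gene + 2 miRNAs + 1 pathway
  expect_equal(nrow(net$edges), 5L) # 1 drug-gene + 2 miRNA-gene + 2 miRNA-P1
  expect_setequal(net$nodes$class,
                  c("drug", "gene", "miRNA", "pathway"))

  # no common pathways -> no pathway nodes, 1 + |profiles| edges
  net0 <- build_drug_pathway_network("d1", "g1", prof, common = character(0))
  expect_equal(nrow(net0$edges), 3L)
  expect_false("pathway" %in% net0$nodes$class)

  expect_error(build_drug_pathway_network("d1", "g1", list()), "empty")
  expect_error(
    build_drug_pathway_network("d1", "g1", prof, common = "P99"), "P99")

  # seeded instance: edge list matches hand enumeration from the profiles
  set.seed(6)
  prof2 <- lapply(stats::setNames(nm = paste0("m", 1:5)), function(i)
    sample(paste0("P", 1:4), sample(1:3, 1)))
  common <- common_pathways(prof2, min_fraction = 0.4)
  net2 <- build_drug_pathway_network("dX", "gX", prof2, common)
  want_edges <- 1L + length(prof2) +
    sum(vapply(common, function(p)
      sum(vapply(prof2, function(pr) p %in% pr, logical(1))), integer(1)))
  expect_equal(nrow(net2$edges), want_edges)
  # every pathway node connects to >= 1 miRNA
  pw <- net2$nodes$id[net2$nodes$class == "pathway"]
  expect_true(all(pw %in% net2$edges$to[net2$edges$relation == "enriched_in"]))
})
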
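test_that("pooled-variance t test matches the reference implementation", {
  # equal means -> t = 0, p = 1
  r <- student_t_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # zero pooled variance with equal means -> p = 1 by convention
  r <- student_t_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$p_value, 1)
  # ... and with unequal means -> p = 0 (most extreme evidence)
  r <- student_t_test(c(5, 5, 5), c(7, 7, 7))
  expect_equal(r$p_value, 0)

  # reference computation (stats::t.test) across random draws
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(4 + i %% 3); b <- rnorm(3 + i %% 4, mean = 0.5)
    got <- student_t_test(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    gw <- student_t_test(a, b, welch = TRUE)
    rw <- t.test(a, b)
    expect_equal(gw$p_value, rw$p.value, tolerance = 1e-12)
  }
  expect_error(student_t_test(1, c(1, 2)), "feature")
})

test_that("Pearson correlation handles identity, reflection and degeneracy", {
  x <- c(1, 5, 2, 9)
  expect_equal(as.numeric(pearson_correlation(x, x)), 1)
  expect_equal(as.numeric(pearson_correlation(x, -x)), -1)
  expect_equal(as.numeric(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))),
               0.8)
  expect_error(pearson_correlation(c(1, 2), c(3, 4)), ">= 3")
  d <- pearson_correlation(c(1, 1, 1), c(1, 2, 3))
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("vectorized row statistics agree with the scalar paths", {
  set.seed(9)
  mat <- matrix(rnorm(200), nrow = 10,
                dimnames = list(sprintf("f%02d", 1:10), sprintf("s%02d", 1:20)))
  ia <- 1:8; ib <- 9:20
  p_vec <- mgdtnet:::row_t_pvalues(mat, ia, ib)
  p_scalar <- apply(mat, 1L, function(x)
    student_t_test(x[ia], x[ib])$p_value)
  expect_equal(unname(p_vec), unname(p_scalar), tolerance = 1e-12)

  r_vec <- mgdtnet:::row_pair_cor(mat, c("f01", "f02"), mat,
                                  c("f03", "f04"), ia)
  expect_equal(r_vec[1], cor(mat["f01", ia], mat["f03", ia]),
               tolerance = 1e-12)
  expect_equal(r_vec[2], cor(mat["f02", ia], mat["f04", ia]),
               tolerance = 1e-12)
})

test_that("triplet scores assemble the three channels correctly", {
  study <- toy_study()
  cat <- toy_catalog()
  tr <- enumerate_mgdts(build_tripartite_network(cat))
  rec <- compute_triplet_scores(study, cat, tr)

  # s_p is the product of the printed-style per-feature P values
  expect_equal(rec$s_p, rec$p_mrna * rec$p_mirna, tolerance = 1e-15)
  expect_equal(0.001 * 0.039, 3.9e-05) # the product rule on its own
  expect_equal(rec$s_pcc, abs(rec$d_pcc - rec$c_pcc), tolerance = 1e-15)
  expect_true(all(rec$s_p > 0 & rec$s_p <= 1))
  expect_true(all(rec$s_pcc >= 0 & rec$s_pcc <= 2))

  # triplets sharing a gene share s_risk
  shared <- split(rec$s_risk, rec$gene)
  for (v in shared) expect_equal(length(unique(v)), 1L)
  expect_equal(unique(rec$s_risk[rec$gene == "g1"]),
               cat$disease_genes[["g1"]])

  # identical group submatrices -> s_pcc = 0 everywhere
  st2 <- study
  st2$mrna[, 5:8] <- st2$mrna[, 1:4]
  st2$mirna[, 5:8] <- st2$mirna[, 1:4]
  rec2 <- compute_triplet_scores(st2, cat, tr)
  expect_equal(rec2$s_pcc, rep(0, nrow(rec2)), tolerance = 1e-12)

  # per-feature checks against the scalar statistics
  d <- 1:4; c0 <- 5:8
  expect_equal(rec$p_mrna[rec$gene == "g1"][1],
               student_t_test(study$mrna["g1", d], study$mrna["g1", c0])$p_value,
               tolerance = 1e-12)
  pair <- rec[rec$gene == "g1" & rec$mirna == "m1", ][1, ]
  expect_equal(pair$d_pcc,
               as.numeric(pearson_correlation(study$mrna["g1", d],
                                              study$mirna["m1", d])),
               tolerance = 1e-12)

  # missing features are reported
  bad <- tr; bad$gene[1] <- "ghost"
  expect_error(compute_triplet_scores(study, cat, bad), "ghost")
})

test_that("degenerate correlation groups error by default and zero out with the override", {
  cat <- toy_catalog()
  study <- toy_study(n_disease = 4L, n_control = 1L)
  tr <- enumerate_mgdts(build_tripartite_network(cat))
  expect_error(compute_triplet_scores(study, cat, tr), "allow_degenerate")
  expect_warning(
    rec <- compute_triplet_scores(study, cat, tr,
                                  allow_degenerate_groups = TRUE),
    "correlations set to 0")
  expect_equal(unique(rec$c_pcc), 0)
  expect_equal(rec$s_pcc, abs(rec$d_pcc))
})

test_that("rank aggregation matches hand-enumerated and naive oracles", {
  # hand-worked three-record case
  rec <- data.frame(s_risk = c(0.9, 0.5, 0.1), s_p = c(0.001, 0.2, 0.9),
                    s_pcc = c(1.2, 0.3, 0.05))
  out <- aggregate_ranks(rec)
  expect_equal(out$final_score, c(1, 2/3, 1/3))

  # single record -> 1.0; full ties -> all equal
  expect_equal(aggregate_ranks(rec[1, ])$final_score, 1)
  tied <- data.frame(s_risk = rep(0.4, 4), s_p = rep(0.1, 4),
                     s_pcc = rep(0.7, 4))
  expect_equal(length(unique(aggregate_ranks(tied)$final_score)), 1L)

  # naive-oracle equivalence on 100 random tables of <= 8 records, with ties
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(1:8, 1)
    tab <- data.frame(
      s_risk = sample(seq(0, 1, 0.25), n, replace = TRUE),
      s_p = sample(c(1e-4, 0.01, 0.2, 0.8), n, replace = TRUE),
      s_pcc = sample(seq(0, 2, 0.5), n, replace = TRUE))
    expect_equal(aggregate_ranks(tab)$final_score,
                 naive_final_scores(tab$s_risk, tab$s_p, tab$s_pcc),
                 tolerance = 1e-12)
  }
})

test_that("final score is weakly monotone in each channel", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    tab <- data.frame(s_risk = runif(n), s_p = runif(n), s_pcc = runif(n) * 2)
    base <- aggregate_ranks(tab)$final_score
    i <- sample(n, 1)
    up <- tab; up$s_pcc[i] <- up$s_pcc[i] + runif(1)
    expect_gte(aggregate_ranks(up)$final_score[i], base[i])
    dn <- tab; dn$s_p[i] <- dn$s_p[i] * runif(1)
    expect_gte(aggregate_ranks(dn)$final_score[i], base[i])
    rk <- tab; rk$s_risk[i] <- rk$s_risk[i] + runif(1)
    expect_gte(aggregate_ranks(rk)$final_score[i], base[i])
  }
})

test_that("scores are invariant under a consistent sample reordering", {
  study <- toy_study(n_disease = 5L, n_control = 5L, seed = 8L)
  cat <- toy_catalog()
  tr <- enumerate_mgdts(build_tripartite_network(cat))
  rec <- compute_triplet_scores(study, cat, tr)
  perm <- c(3, 1, 2, 5, 4, 8, 10, 9, 7, 6) # within-group shuffle
  st2 <- mgdtnet:::new_expression_study(
    study$mrna[, perm], study$mirna[, perm],
    stats::setNames(study$labels[perm], colnames(study$mrna)[perm]))
  rec2 <- compute_triplet_scores(st2, cat, tr)
  expect_equal(rec2, rec, tolerance = 1e-12)
})
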
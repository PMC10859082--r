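test_that("age distance matrix holds absolute age differences", {
  m <- age_distance_matrix(c(1, 2, 4), c("a", "b", "c"))
  expect_equal(m[upper.tri(m)], c(1, 3, 2))
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))

  expect_equal(sort(unique(as.vector(
    age_distance_matrix(c(1, 1, 2, 2))))), c(0, 1))

  z <- age_distance_matrix(c(5, 5, 5))
  expect_true(all(z == 0))

  expect_error(age_distance_matrix(c(1, 2)), "3 samples")
})

test_that("upper-triangle Spearman matches rank-based first principles", {
  mk <- function(ut) {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- ut
    m + t(m)
  }
  d1 <- mk(c(1, 2, 3, 4, 5, 6))

  # monotone transform of the entries leaves the score at 1
  expect_equal(upper_triangle_spearman(d1, mk(exp(c(1, 2, 3, 4, 5, 6)))), 1)
  # order reversal gives -1
  expect_equal(upper_triangle_spearman(d1, mk(7 - c(1, 2, 3, 4, 5, 6))), -1)

  # value frozen from the independent rank-arithmetic oracle
  d2 <- mk(c(2, 1, 3, 4, 6, 5))
  expect_equal(spearman_brute(c(1, 2, 3, 4, 5, 6), c(2, 1, 3, 4, 6, 5)),
               0.8857142857, tolerance = 1e-9)
  expect_equal(upper_triangle_spearman(d1, d2), 0.8857142857,
               tolerance = 1e-9)

  # constant triangle is flagged undefined, not NaN-propagated
  expect_true(is.na(upper_triangle_spearman(d1, mk(rep(2, 6)))))
})

test_that("mantel test honours its permutation-p contract", {
  set.seed(81)
  n <- 5
  ages <- c(1, 2, 3, 4, 5)
  d_age <- age_distance_matrix(ages)
  d_assoc <- d_age + matrix(runif(n * n, 0, 0.3), n, n)
  d_assoc <- (d_assoc + t(d_assoc)) / 2
  diag(d_assoc) <- 0

  mt <- mantel_test(d_assoc, d_age, n_perm = 99, seed = 1)
  # observed statistic is exactly the upper-triangle Spearman score
  expect_equal(mt$statistic, upper_triangle_spearman(d_assoc, d_age))
  # permutation p floor
  expect_gte(mt$p_value, 1 / 100)
  expect_lte(mt$p_value, 1)

  # same seed, same p
  mt2 <- mantel_test(d_assoc, d_age, n_perm = 99, seed = 1)
  expect_identical(mt$p_value, mt2$p_value)

  # constant matrix: undefined statistic, p = 1 by convention
  mt3 <- mantel_test(matrix(0, 4, 4), age_distance_matrix(1:4),
                     n_perm = 49)
  expect_true(is.na(mt3$statistic))
  expect_equal(mt3$p_value, 1)

  expect_equal(formals(run_workflow)$n_perm, 1000)
})

test_that("mantel p matches exhaustive enumeration for small n", {
  set.seed(91)
  d_age <- age_distance_matrix(c(1, 2, 3, 6))
  noise <- matrix(runif(16), 4, 4)
  d_gene <- (noise + t(noise)) / 2 + d_age * 0.4
  diag(d_gene) <- 0

  exact <- mantel_exact_p(d_gene, d_age)
  n_perm <- 2000
  mt <- mantel_test(d_gene, d_age, n_perm = n_perm, seed = 7)
  se <- sqrt(exact * (1 - exact) / n_perm)
  expect_lt(abs(mt$p_value - exact), 3 * se + 2 / n_perm)
})

test_that("mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(101)
  d_age <- age_distance_matrix(c(1, 1, 2, 3, 3, 6, 9, 12))
  noise <- matrix(runif(64), 8, 8)
  d_gene <- (noise + t(noise)) / 2 + d_age * 0.2
  diag(d_gene) <- 0

  ref <- vegan::mantel(d_gene, d_age, method = "spearman",
                       permutations = 999)
  mt <- mantel_test(d_gene, d_age, n_perm = 999, seed = 5)
  expect_equal(mt$statistic, as.numeric(ref$statistic), tolerance = 1e-12)
  # both p-values estimate the same exceedance probability
  expect_lt(abs(mt$p_value - ref$signif), 0.05)
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(111)
  for (i in 1:10) {
    p <- runif(25)^2
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("gene distance matrices are symmetric with a zero diagonal", {
  ds <- toy_dataset()
  for (metric in c("hellinger", "js", "ks")) {
    m <- gene_distance_matrix(ds, "g2", metric = metric, k = 200)
    expect_true(isSymmetric(unname(m)))
    expect_equal(unname(diag(m)), rep(0, 3))
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_error(gene_distance_matrix(ds, "nope"), "unknown gene")
})

test_that("distance structure follows the data: identical near, shifted far", {
  # two identical samples and one shifted far away
  expr <- cbind(g = c(rnorm(50, 0, 0.1), rnorm(50, 0, 0.1) + 1e-9,
                      rnorm(50, 50, 0.1)))
  ds <- cell_dataset(matrix(expr, ncol = 1,
                            dimnames = list(NULL, "g")),
                     rep(c("a", "b", "far"), each = 50),
                     data.frame(sample_id = c("a", "b", "far"),
                                age = c(1, 2, 3)))
  m <- gene_distance_matrix(ds, "g", k = 500)
  expect_lt(m["a", "b"], 0.2)
  expect_gt(m["a", "far"], 0.95)
  expect_gt(m["b", "far"], 0.95)
})

test_that("monotonic dispersion makes distance grow with age difference", {
  sim <- simulate_dataset(sim_config(n_genes = 1, fraction_monotonic = 1,
                                     fraction_nonmonotonic = 0,
                                     samples_per_age = 2,
                                     cells_per_sample = 300, seed = 13))
  m <- gene_distance_matrix(sim$dataset, "gene00001", k = 500)
  age_d <- age_distance_matrix(sim$dataset$sample_metadata$age)
  ut <- upper.tri(m)
  # average distance increases with age separation
  means <- tapply(m[ut], age_d[ut], mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})

test_that("cached and pairwise KDE paths agree", {
  ds <- toy_dataset()
  for (gene in ds$gene_ids) {
    a <- gene_distance_matrix(ds, gene, kde = "cached")
    b <- gene_distance_matrix(ds, gene, kde = "pairwise")
    expect_lt(max(abs(a - b)), 0.01)
  }
})

test_that("run_workflow classifies, adjusts and is seed-deterministic", {
  sim <- simulate_dataset(sim_config(n_genes = 6, fraction_monotonic = 0.5,
                                     fraction_nonmonotonic = 0,
                                     samples_per_age = 3,
                                     cells_per_sample = 150, seed = 3))
  res <- run_workflow(sim$dataset, n_perm = 99, seed = 42, k = 300)
  expect_s3_class(res, "association_table")
  expect_equal(nrow(res), 6)
  expect_equal(res$adjusted_p, bh_adjust(res$mantel_p))
  expect_true(all(res$mantel_p >= 1 / 100))
  expect_identical(res$passed_cutoff, !is.na(res$rho) & res$rho > 0.85)
  expect_equal(formals(run_workflow)$cutoff, 0.85)

  res2 <- run_workflow(sim$dataset, n_perm = 99, seed = 42, k = 300)
  expect_identical(res, res2)

  # per-gene permutation streams: a gene's p must not depend on whether
  # other metrics were run alongside
  res3 <- run_workflow(sim$dataset, metric = c("hellinger", "ks"),
                       n_perm = 99, seed = 42, k = 300)
  expect_equal(res3$mantel_p[res3$metric == "hellinger"], res$mantel_p)
})

test_that("a perfectly monotone dispersion gene scores near 1", {
  # per-sample sigma a strict monotone function of age, negligible noise
  set.seed(17)
  ages <- rep(1:4, each = 2)
  sigmas <- 0.2 + 0.5 * ages
  cells <- unlist(lapply(seq_along(ages),
                         function(i) rnorm(400, 0, sigmas[i])))
  ds <- cell_dataset(matrix(cells, ncol = 1, dimnames = list(NULL, "g")),
                     rep(paste0("s", seq_along(ages)), each = 400),
                     data.frame(sample_id = paste0("s", seq_along(ages)),
                                age = ages))
  res <- run_workflow(ds, n_perm = 99, seed = 1, k = 500)
  expect_gt(res$rho, 0.8)
  expect_true(res$passed_cutoff)
})

test_that("pseudo-bulk correlation tracks per-sample means only", {
  # means strictly increasing with age
  expr <- matrix(rep(c(1, 2, 3), each = 2), ncol = 1,
                 dimnames = list(NULL, "up"))
  ds <- cell_dataset(expr, rep(c("a", "b", "c"), each = 2),
                     data.frame(sample_id = c("a", "b", "c"),
                                age = c(1, 5, 9)))
  expect_equal(pseudobulk_correlation(ds)$rho, 1)

  # hand-ranked example: means (10.0, 10.1, 9.9) vs ages (1, 2, 3)
  expr2 <- matrix(rep(c(10.0, 10.1, 9.9), each = 2), ncol = 1,
                  dimnames = list(NULL, "g"))
  ds2 <- cell_dataset(expr2, rep(c("a", "b", "c"), each = 2),
                      data.frame(sample_id = c("a", "b", "c"),
                                 age = c(1, 2, 3)))
  expect_equal(pseudobulk_correlation(ds2)$rho, -0.5)

  # constant means are flagged undefined
  expr3 <- matrix(rep(5, 6), ncol = 1, dimnames = list(NULL, "flat"))
  ds3 <- cell_dataset(expr3, rep(c("a", "b", "c"), each = 2),
                      data.frame(sample_id = c("a", "b", "c"),
                                 age = c(1, 2, 3)))
  expect_true(is.na(pseudobulk_correlation(ds3)$rho))
})
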
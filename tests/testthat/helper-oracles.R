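# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Closed-form Hellinger distance between two normal densities.
normal_hellinger <- function(m1, s1, m2, s2) {
  sqrt(1 - sqrt(2 * s1 * s2 / (s1^2 + s2^2)) *
         exp(-(m1 - m2)^2 / (4 * (s1^2 + s2^2))))
}

# All permutations of 1..n (n <= 7), for exhaustive Mantel enumeration.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Exact one-sided Mantel p: fraction of all n! simultaneous row/column
# permutations of d2 whose upper-triangle correlation with d1 meets or
# exceeds the observed one.
mantel_exact_p <- function(d1, d2, method = "spearman") {
  ut <- upper.tri(d1)
  obs <- cor(d1[ut], d2[ut], method = method)
  stats <- vapply(all_perms(nrow(d1)), function(p) {
    cor(d1[ut], d2[p, p][ut], method = method)
  }, numeric(1))
  mean(stats >= obs - 1e-12)
}

# Brute-force Benjamini-Hochberg step-up adjustment.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  pmin(1, adj_sorted)[order(o)]
}

# Spearman correlation built from first principles (average ranks + the
# Pearson product-moment formula), independent of cor(method = "spearman").
spearman_brute <- function(u, v) {
  r <- function(x) {
    sx <- sort(x)
    vapply(x, function(xi) mean(which(sx == xi)), numeric(1))
  }
  a <- r(u)
  b <- r(v)
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Random PMF on a shared grid, for metric property tests.
random_pmf <- function(k = 20, grid = seq_len(k)) {
  w <- stats::rexp(k)
  pmf(grid, w / sum(w))
}

# Small deterministic dataset: 2 genes, 3 samples x 4 cells.
toy_dataset <- function() {
  set.seed(11)
  expr <- cbind(g1 = rnorm(12, rep(c(5, 6, 7), each = 4), 0.2),
                g2 = rnorm(12, 5, rep(c(0.2, 0.6, 1.2), each = 4)))
  rownames(expr) <- paste0("c", 1:12)
  cell_dataset(expr, rep(c("s1", "s2", "s3"), each = 4),
               data.frame(sample_id = c("s1", "s2", "s3"),
                          age = c(3, 12, 24)))
}

# Annotated dataset for subset/filter tests: 2 samples, sex + cell_type.
annotated_dataset <- function() {
  expr <- matrix(c(1, 2, 3, 4, 5,
                   5, 5, 5, 5, 5,
                   2, 1, 2, 1, 2), nrow = 5,
                 dimnames = list(paste0("c", 1:5), c("gA", "gB", "gC")))
  cell_dataset(expr, c("m1", "m1", "m1", "f1", "f1"),
               data.frame(sample_id = c("m1", "f1"), age = c(3, 18),
                          sex = c("male", "female")),
               cell_metadata = data.frame(
                 cell_type = c("granulocyte", "granulocyte", "b_cell",
                               "granulocyte", "b_cell")))
}
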
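#' Donor-age distance matrix
#'
#' Entry (i, j) is the absolute donor-age difference between samples i and
#' j — the "response" matrix every gene's distance matrix is scored against.
#'
#' @param ages Numeric donor ages, one per sample, in sample order.
#' @param sample_ids Optional sample identifiers (default `names(ages)` or
#'   generated labels).
#' @return Symmetric matrix with zero diagonal and `sample_ids` dimnames.
#' @export
age_distance_matrix <- function(ages, sample_ids = names(ages)) {
  if (length(ages) < 3) {
    stop("at least 3 samples are required (fewer give too few ",
         "upper-triangle entries for a rank correlation)", call. = FALSE)
  }
  if (!is.numeric(ages) || any(!is.finite(ages))) {
    stop("ages must be finite numbers", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_along(ages))
  m <- abs(outer(ages, ages, "-"))
  dimnames(m) <- list(sample_ids, sample_ids)
  m
}

.check_matrix_pair <- function(d1, d2) {
  if (!is.matrix(d1) || !is.matrix(d2) || !all(dim(d1) == dim(d2)) ||
      nrow(d1) != ncol(d1)) {
    stop("d1 and d2 must be square matrices of identical dimension",
         call. = FALSE)
  }
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("d1 and d2 must index the same samples in the same order",
         call. = FALSE)
  }
  if (nrow(d1) < 3) stop("need at least 3 samples", call. = FALSE)
}

#' Spearman correlation of two distance matrices' upper triangles
#'
#' Unfolds the strictly-above-diagonal entries of both matrices and returns
#' their Spearman rank correlation (average ranks for ties). This is the
#' per-gene age-association score of the workflow. If either unfolded
#' vector is constant the correlation is undefined and `NA` is returned
#' (flagged, not propagated as an error).
#'
#' @param d1,d2 Symmetric matrices over the same samples in the same order.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
upper_triangle_spearman <- function(d1, d2) {
  .check_matrix_pair(d1, d2)
  ut <- upper.tri(d1)
  .spearman_safe(d1[ut], d2[ut])
}

.spearman_safe <- function(u1, u2, method = "spearman") {
  if (stats::sd(u1) == 0 || stats::sd(u2) == 0) return(NA_real_)
  stats::cor(u1, u2, method = method)
}

#' Mantel permutation test between two distance matrices
#'
#' Tests whether inter-sample distances in `d1` are positively associated
#' with those in `d2`. The observed statistic is the correlation of the two
#' upper triangles (Spearman by default, matching the association score;
#' Pearson available). The null distribution is built by simultaneously
#' permuting the rows and columns of `d2` by a random sample permutation
#' and recomputing the statistic; the one-sided p-value is
#' `(1 + #{permuted statistic >= observed}) / (1 + n_perm)`, so `p >= 1 /
#' (n_perm + 1)` always. A constant upper triangle makes the statistic
#' undefined; then `statistic = NA` and `p = 1` by convention.
#'
#' @param d1,d2 Symmetric matrices over the same samples in the same order
#'   (`d2` is the matrix that is permuted; which one is permuted does not
#'   change the null).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed for the permutation stream.
#' @param stat `"spearman"` (default) or `"pearson"`.
#' @return List with `statistic`, `p_value`, `n_perm` and `stat`.
#' @export
mantel_test <- function(d1, d2, n_perm = 1000, seed = NULL,
                        stat = c("spearman", "pearson")) {
  stat <- match.arg(stat)
  .check_matrix_pair(d1, d2)
  stopifnot(is.numeric(n_perm), length(n_perm) == 1, n_perm >= 1)
  n_perm <- as.integer(n_perm)
  ut <- upper.tri(d1)
  u1 <- d1[ut]
  observed <- .spearman_safe(u1, d2[ut], method = stat)
  if (is.na(observed)) {
    return(list(statistic = NA_real_, p_value = 1, n_perm = n_perm,
                stat = stat))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d1)
  # permuting rows and columns together only permutes the multiset of
  # upper-triangle entries, so ranks can be assigned once and carried
  # through each permutation instead of being recomputed
  if (stat == "spearman") {
    v1 <- rank(u1)
    m2 <- matrix(0, n, n)
    m2[ut] <- rank(d2[ut])
    m2 <- m2 + t(m2)
    obs_cmp <- stats::cor(v1, m2[ut])
  } else {
    v1 <- u1
    m2 <- d2
    obs_cmp <- observed
  }
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    s <- stats::cor(v1, m2[perm, perm][ut])
    if (!is.na(s) && s >= obs_cmp - 1e-12) exceed <- exceed + 1L
  }
  list(statistic = observed, p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, stat = stat)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false-discovery-rate adjustment applied across the per-gene
#' Mantel p-values.
#'
#' @param pvalues Numeric vector with entries in `(0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(is.na(pvalues)) ||
      any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# --- per-gene distance matrices -------------------------------------------

# values_by_sample: list of numeric vectors (one per sample, in sample
# order). Computes the distance matrices for the requested metrics in a
# single pass over sample pairs, sharing the pair PMFs between hellinger
# and js.
.distance_matrices <- function(values_by_sample, metrics, k = 1000,
                               bandwidth_rule = "nrd0",
                               kde = c("cached", "pairwise")) {
  kde <- match.arg(kde)
  n <- length(values_by_sample)
  needs_pmf <- any(metrics %in% c("hellinger", "js"))
  out <- lapply(metrics, function(m) matrix(0, n, n))
  names(out) <- metrics

  caches <- NULL
  sorted <- NULL
  if (needs_pmf && kde == "cached") {
    caches <- lapply(values_by_sample, .sample_kde_cache, bandwidth_rule)
  }
  if ("ks" %in% metrics) sorted <- lapply(values_by_sample, sort)

  for (i in seq_len(n - 1L)) {
    xi <- values_by_sample[[i]]
    for (j in seq.int(i + 1L, n)) {
      yj <- values_by_sample[[j]]
      if (needs_pmf) {
        g <- pooled_grid(xi, yj, k)
        if (length(g) == 1L) {
          pm <- qm <- 1
        } else if (kde == "cached") {
          pm <- .cached_masses(caches[[i]], g, k, bandwidth_rule)
          qm <- .cached_masses(caches[[j]], g, k, bandwidth_rule)
        } else {
          pp <- estimate_pair_pmfs(xi, yj, k, bandwidth_rule)
          pm <- pp[[1]]$masses
          qm <- pp[[2]]$masses
        }
        if ("hellinger" %in% metrics) {
          h2 <- sum((sqrt(pm) - sqrt(qm))^2) / 2
          out$hellinger[i, j] <- out$hellinger[j, i] <-
            sqrt(max(0, min(1, h2)))
        }
        if ("js" %in% metrics) {
          out$js[i, j] <- out$js[j, i] <- .js_from_masses(pm, qm)
        }
      }
      if ("ks" %in% metrics) {
        out$ks[i, j] <- out$ks[j, i] <- .ks_sorted(sorted[[i]], sorted[[j]])
      }
    }
  }
  out
}

.values_by_sample <- function(ds, gene_id) {
  j <- match(gene_id, ds$gene_ids)
  if (is.na(j)) stop("unknown gene: ", gene_id, call. = FALSE)
  v <- ds$expression[, j]
  split(v, factor(ds$cell_sample_ids,
                  levels = ds$sample_metadata$sample_id))
}

#' Sample-by-sample distance matrix for one gene
#'
#' For every unordered pair of samples, extracts the gene's per-cell
#' expression vectors, estimates the pair of PMFs on the shared pooled-range
#' grid ([estimate_pair_pmfs()]) and applies the chosen distance
#' ([hellinger()] or [js_distance()]); the Kolmogorov-Smirnov metric skips
#' density estimation and works on the raw samples. The result is symmetric
#' with a zero diagonal by construction (each pair computed once).
#'
#' @param ds A validated [cell_dataset()].
#' @param gene_id Gene to analyse.
#' @param metric `"hellinger"` (default), `"js"` or `"ks"`.
#' @param k Grid size for the PMF metrics (default 1000).
#' @param bandwidth_rule Passed to [estimate_pair_pmfs()].
#' @param kde `"cached"` (default; one KDE per sample on a fine grid,
#'   interpolated onto each pair grid) or `"pairwise"` (exact per-pair
#'   evaluation). The two agree to well within the sampling noise of the
#'   KDE; `"pairwise"` is the reference procedure.
#' @return Distance matrix with sample dimnames.
#' @export
gene_distance_matrix <- function(ds, gene_id,
                                 metric = c("hellinger", "js", "ks"),
                                 k = 1000, bandwidth_rule = "nrd0",
                                 kde = c("cached", "pairwise")) {
  metric <- match.arg(metric)
  kde <- match.arg(kde)
  validate_dataset(ds)
  vbs <- .values_by_sample(ds, gene_id)
  m <- .distance_matrices(vbs, metric, k, bandwidth_rule, kde)[[metric]]
  dimnames(m) <- list(names(vbs), names(vbs))
  m
}

# --- the full screen -------------------------------------------------------

#' Screen every gene for age-associated distribution change
#'
#' Runs the complete workflow over all genes of a dataset: per-gene
#' sample-by-sample distance matrix, Spearman correlation of its upper
#' triangle against the donor-age distance matrix, Mantel permutation test
#' of that association, Benjamini-Hochberg adjustment across genes, and a
#' cutoff classification on the correlation score.
#'
#' Genes whose distance upper triangle is constant (e.g. a gene identical
#' in every sample) get an undefined score: `rho = NA`, `mantel_p = 1`,
#' `passed_cutoff = FALSE`. They are retained so gene counts are stable.
#'
#' The run is deterministic given `seed`: one permutation stream is derived
#' per gene from the master seed, so results do not depend on gene order or
#' on which metrics are requested together.
#'
#' @param ds A validated [cell_dataset()] with at least 3 samples.
#' @param metric Character vector of metrics to score
#'   (`"hellinger"`, `"js"`, `"ks"`); the density estimation work is shared
#'   when several PMF metrics are requested. Default `"hellinger"`.
#' @param n_perm Mantel permutations per gene (default 1000).
#' @param seed Master seed (default 1).
#' @param cutoff Genes with `rho > cutoff` are classified as age-associated
#'   (default 0.85). Classification uses the raw correlation score; the
#'   adjusted Mantel p is reported alongside.
#' @param k,bandwidth_rule,kde Density settings, see
#'   [gene_distance_matrix()].
#' @param mantel_stat Statistic for the Mantel test, `"spearman"` (default)
#'   or `"pearson"`.
#' @param verbose Print a progress line every 50 genes.
#' @return A data frame (class `association_table`) with one row per gene
#'   and metric: `gene_id`, `rho`, `mantel_p`, `adjusted_p`, `n_samples`,
#'   `n_permutations`, `metric`, `passed_cutoff`. Adjustment is performed
#'   within each metric.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 4, samples_per_age = 2,
#'                                    cells_per_sample = 50, seed = 1))
#' run_workflow(sim$dataset, n_perm = 49, seed = 1)
#' @export
run_workflow <- function(ds, metric = "hellinger", n_perm = 1000, seed = 1,
                         cutoff = 0.85, k = 1000, bandwidth_rule = "nrd0",
                         kde = c("cached", "pairwise"),
                         mantel_stat = c("spearman", "pearson"),
                         verbose = FALSE) {
  kde <- match.arg(kde)
  mantel_stat <- match.arg(mantel_stat)
  metrics <- match.arg(metric, c("hellinger", "js", "ks"),
                       several.ok = TRUE)
  validate_dataset(ds)
  sm <- ds$sample_metadata
  if (nrow(sm) < 3) stop("need at least 3 samples", call. = FALSE)
  age_dm <- age_distance_matrix(sm$age, sm$sample_id)

  gene_ids <- ds$gene_ids
  n_genes <- length(gene_ids)
  set.seed(seed)
  gene_seeds <- sample.int(2147483646L, n_genes, replace = TRUE)

  sample_f <- factor(ds$cell_sample_ids, levels = sm$sample_id)
  cell_idx <- split(seq_along(sample_f), sample_f)

  rows <- vector("list", n_genes)
  for (gi in seq_len(n_genes)) {
    vbs <- lapply(cell_idx, function(ix) ds$expression[ix, gi])
    mats <- .distance_matrices(vbs, metrics, k, bandwidth_rule, kde)
    res <- lapply(metrics, function(m) {
      mt <- mantel_test(mats[[m]], age_dm, n_perm = n_perm,
                        seed = gene_seeds[gi], stat = mantel_stat)
      # the reported age-association score is always the Spearman one
      rho <- if (mantel_stat == "spearman") mt$statistic else
        upper_triangle_spearman(mats[[m]], age_dm)
      data.frame(gene_id = gene_ids[gi], rho = rho,
                 mantel_p = mt$p_value, n_samples = nrow(sm),
                 n_permutations = n_perm, metric = m,
                 stringsAsFactors = FALSE)
    })
    rows[[gi]] <- do.call(rbind, res)
    if (verbose && gi %% 50 == 0) {
      message("scored ", gi, " / ", n_genes, " genes")
    }
  }
  tbl <- do.call(rbind, rows)
  tbl$adjusted_p <- NA_real_
  for (m in metrics) {
    i <- tbl$metric == m
    tbl$adjusted_p[i] <- bh_adjust(tbl$mantel_p[i])
  }
  tbl$passed_cutoff <- !is.na(tbl$rho) & tbl$rho > cutoff
  tbl <- tbl[, c("gene_id", "rho", "mantel_p", "adjusted_p", "n_samples",
                 "n_permutations", "metric", "passed_cutoff")]
  rownames(tbl) <- NULL
  class(tbl) <- c("association_table", "data.frame")
  tbl
}

#' Pseudo-bulk age correlation per gene
#'
#' The mean-based comparator: collapses each sample to its average
#' expression per gene (what a bulk assay would measure) and correlates
#' those means with donor age by Spearman rank correlation. Changes that
#' affect only the *shape* of the single-cell distribution — e.g. a
#' variance increase at fixed mean — are invisible to this statistic.
#'
#' @param ds A validated [cell_dataset()] with at least 3 samples.
#' @return Data frame with `gene_id` and `rho` (`NA` when the per-sample
#'   means are constant).
#' @export
pseudobulk_correlation <- function(ds) {
  validate_dataset(ds)
  sm <- ds$sample_metadata
  if (nrow(sm) < 3) stop("need at least 3 samples", call. = FALSE)
  f <- factor(ds$cell_sample_ids, levels = sm$sample_id)
  sums <- rowsum(ds$expression, f)            # samples x genes
  means <- sums / as.vector(table(f))
  rho <- apply(means, 2, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, sm$age, method = "spearman")
  })
  data.frame(gene_id = ds$gene_ids, rho = as.numeric(rho),
             stringsAsFactors = FALSE)
}
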
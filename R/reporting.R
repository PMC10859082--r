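# pooled per-age expression values for one gene, as a long data frame
.pooled_by_age <- function(ds, gene_id) {
  j <- match(gene_id, ds$gene_ids)
  if (is.na(j)) stop("unknown gene: ", gene_id, call. = FALSE)
  age <- ds$sample_metadata$age[
    match(ds$cell_sample_ids, ds$sample_metadata$sample_id)]
  data.frame(expression = ds$expression[, j], age = age)
}

.save_or_return <- function(p, file, width = 8, height = 5) {
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(file))
  }
  p
}

#' Pooled expression histograms by age category
#'
#' One panel per age category, cells pooled across all of that age's
#' samples, with a shared x-range across panels — the standard way to
#' inspect *how* a high-scoring gene's distribution changes with age
#' (variance inflation, emerging positive population, peak shift, ...).
#'
#' @param ds A validated [cell_dataset()].
#' @param gene_id Gene to plot.
#' @param bins Number of bins over the pooled range (default 50).
#' @param file Optional output path (png/pdf); when `NULL` the ggplot
#'   object is returned.
#' @return The ggplot object, or `file` invisibly.
#' @export
gene_histogram <- function(ds, gene_id, bins = 50, file = NULL) {
  validate_dataset(ds)
  d <- .pooled_by_age(ds, gene_id)
  d$age <- factor(d$age, levels = sort(unique(d$age)),
                  labels = paste("Age", sort(unique(d$age))))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$expression)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::facet_wrap(~age, ncol = 1) +
    ggplot2::labs(x = "expression", y = "cells", title = gene_id) +
    ggplot2::theme_bw()
  .save_or_return(p, file, width = 6, height = 2 * nlevels(d$age))
}

#' Quantile-quantile plot against the youngest age
#'
#' Quantiles of each older age category's pooled expression distribution
#' plotted against the matching quantiles of the youngest age's pooled
#' distribution, with the identity line for reference. Points on the line
#' mean no change; fanning away from it at the tails indicates variance
#' inflation, a vertical offset a location shift.
#'
#' Quantiles are taken at matched probability points `(1..m)/(m+1)` with
#' `m` the smaller pooled size, capped at `max_points`.
#'
#' @inheritParams gene_histogram
#' @param max_points Cap on the number of quantile points (default 1000).
#' @return The ggplot object, or `file` invisibly.
#' @export
gene_qq <- function(ds, gene_id, max_points = 1000, file = NULL) {
  validate_dataset(ds)
  d <- .pooled_by_age(ds, gene_id)
  ages <- sort(unique(d$age))
  if (length(ages) < 2) {
    stop("QQ plot needs at least two age categories", call. = FALSE)
  }
  youngest <- d$expression[d$age == ages[1]]
  qq <- do.call(rbind, lapply(ages[-1], function(a) {
    older <- d$expression[d$age == a]
    m <- min(length(youngest), length(older), max_points)
    probs <- seq_len(m) / (m + 1)
    data.frame(young = as.numeric(quantile(youngest, probs)),
               old = as.numeric(quantile(older, probs)),
               age = paste("Age", a))
  }))
  p <- ggplot2::ggplot(qq, ggplot2::aes(x = .data$young, y = .data$old)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~age) +
    ggplot2::labs(x = paste0("quantiles, Age ", ages[1], " (youngest)"),
                  y = "quantiles, older age", title = gene_id) +
    ggplot2::theme_bw()
  .save_or_return(p, file)
}

#' Histograms of association scores and adjusted Mantel p-values
#'
#' Side-by-side histograms of the per-gene Spearman correlation score and
#' the BH-adjusted Mantel p-value — the genome-wide picture an aging scan
#' produces (one facet pair per metric when several were run).
#'
#' @param results An association table from [run_workflow()].
#' @param bins Bins per histogram (default 50).
#' @param file Optional output path.
#' @return The ggplot object, or `file` invisibly.
#' @export
score_histogram <- function(results, bins = 50, file = NULL) {
  results <- as.data.frame(results)
  if (!nrow(results)) stop("empty result table", call. = FALSE)
  long <- rbind(
    data.frame(value = results$rho, which = "Spearman rho",
               metric = results$metric),
    data.frame(value = results$adjusted_p, which = "adjusted Mantel p",
               metric = results$metric))
  long <- long[!is.na(long$value), , drop = FALSE]
  multi <- length(unique(long$metric)) > 1
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    (if (multi) ggplot2::facet_grid(metric ~ which, scales = "free")
     else ggplot2::facet_wrap(~which, scales = "free")) +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_bw()
  .save_or_return(p, file)
}

#' Boxplots of scores by true simulation pattern
#'
#' For a simulated dataset with known pattern labels: boxplots of the
#' per-gene correlation score and the Mantel p-value, grouped by true
#' pattern — the visual check that monotonic dispersion changes score
#' highest, non-monotonic ones intermediate, and stable genes near zero.
#'
#' @param sim A [simulate_dataset()] result.
#' @param results An association table from [run_workflow()] on
#'   `sim$dataset`.
#' @param file Optional output path.
#' @return The ggplot object, or `file` invisibly.
#' @export
pattern_boxplot <- function(sim, results, file = NULL) {
  stopifnot(inherits(sim, "simulated_dataset"))
  results <- as.data.frame(results)
  truth <- data.frame(gene_id = names(sim$true_pattern),
                      pattern = unname(sim$true_pattern))
  d <- merge(results, truth, by = "gene_id")
  if (!nrow(d)) {
    stop("no overlap between result gene_ids and simulated genes",
         call. = FALSE)
  }
  d$pattern <- factor(d$pattern,
                      levels = c("monotonic", "nonmonotonic", "stable"))
  long <- rbind(
    data.frame(value = d$rho, which = "Spearman rho", pattern = d$pattern,
               metric = d$metric),
    data.frame(value = d$mantel_p, which = "Mantel p", pattern = d$pattern,
               metric = d$metric))
  long <- long[!is.na(long$value), , drop = FALSE]
  multi <- length(unique(long$metric)) > 1
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$pattern, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    (if (multi) ggplot2::facet_grid(metric ~ which, scales = "free_y")
     else ggplot2::facet_wrap(~which, scales = "free_y")) +
    ggplot2::labs(x = "true age pattern", y = NULL) +
    ggplot2::theme_bw()
  .save_or_return(p, file)
}
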
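#' F1 score from confusion counts
#'
#' `F1 = 2 tp / (2 tp + fp + fn)`; defined as 0 when all counts are 0.
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) ml_stop_value("counts must be non-negative")
  den <- 2 * tp + fp + fn
  if (den == 0) return(0)
  2 * tp / den
}

#' Precision-recall curve and AUPRC from a significance ranking
#'
#' Ranks items by ascending score (smaller = more significant); tied scores
#' are ordered positives-last so tied blocks are scored pessimistically.
#' Precision and recall are evaluated after each prefix and the area is the
#' step integral `sum((R_k - R_{k-1}) * P_k)` (average precision).
#'
#' @param scores Numeric scores, e.g. p-values.
#' @param labels Logical truth labels; at least one must be `TRUE`.
#' @return List with `curve` (data.frame `recall`, `precision`) and `auprc`.
#' @export
pr_curve_auprc <- function(scores, labels) {
  if (length(scores) != length(labels))
    ml_stop_consistency("scores and labels lengths differ")
  labels <- as.logical(labels)
  if (!any(labels)) ml_stop_value("no positive labels")
  o <- order(scores, labels)          # FALSE before TRUE within ties
  lab <- labels[o]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / sum(lab)
  auprc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(recall = recall, precision = precision),
       auprc = auprc)
}

## Precision at each point of a fixed recall grid (vertical averaging
## convention: precision of the smallest prefix reaching that recall).
precision_on_grid <- function(curve, grid) {
  vapply(grid, function(r) {
    i <- which(curve$recall >= r - 1e-12)
    if (!length(i)) return(NA_real_)
    curve$precision[i[1L]]
  }, 0)
}

fdr_levels_default <- c(0.01, 0.05, 0.1, 0.2)

## Per-rep empirical FDR of the padj<level rule (the adjustment-level
## FDR-control check; the rho cut is deliberately not applied here).
empirical_fdr <- function(padj, truth, levels = fdr_levels_default) {
  vapply(levels, function(l) {
    calls <- padj < l
    sum(calls & !truth) / max(1L, sum(calls))
  }, 0)
}

summarize_bench <- function(per_rep, pr_store, methods, params, reps, seed,
                            recall_grid) {
  summary <- do.call(rbind, lapply(methods, function(m) {
    d <- per_rep[per_rep$method == m & !is.na(per_rep$f1), , drop = FALSE]
    data.frame(method = m, reps_used = nrow(d),
               mean_f1 = mean(d$f1), sd_f1 = stats::sd(d$f1),
               mean_auprc = mean(d$auprc), sd_auprc = stats::sd(d$auprc),
               stringsAsFactors = FALSE)
  }))
  fdr_cols <- grep("^fdr_", names(per_rep), value = TRUE)
  fdr <- do.call(rbind, lapply(methods, function(m) {
    d <- per_rep[per_rep$method == m & !is.na(per_rep$f1), fdr_cols,
                 drop = FALSE]
    data.frame(method = m, nominal = fdr_levels_default,
               empirical = colMeans(d),
               mc_se = apply(d, 2L, stats::sd) / sqrt(nrow(d)),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  mean_pr <- do.call(rbind, lapply(methods, function(m) {
    P <- pr_store[[m]]
    data.frame(method = m, recall = recall_grid,
               precision = colMeans(P, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, per_rep = per_rep, fdr = fdr,
                 mean_pr = mean_pr, reps = reps, seed = seed,
                 params = params),
            class = "BenchmarkSummary")
}

#' @export
print.BenchmarkSummary <- function(x, ...) {
  cat(sprintf("BenchmarkSummary: %d reps, seed %d\n", x$reps, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Benchmark correlation-based paired integration on simulated studies
#'
#' Per replicate: simulate a paired study, run the Welch DE step on both
#' matrices, integrate each correlation method over the candidate pairs
#' (DE-miRNA x target DEG), and score calls (`padj < alpha & rho < rho_cut`)
#' against the truly affected pairs restricted to the tested candidates.
#' AUPRC ranks candidates by raw p-value, so it is threshold-free.
#'
#' @param params A [sim_params()] object; `params$seed` is overridden per
#'   replicate by `seed + rep`.
#' @param methods Correlation methods to compare.
#' @param reps Number of simulation replicates (>= 2).
#' @param alpha,rho_cut Call rule (defaults 0.1 and -0.5).
#' @param de_alpha Adjusted-p threshold selecting DE features from the
#'   internal Welch step (default 0.05).
#' @param adjust Multiplicity procedure for the integration p-values.
#' @param seed Base seed.
#' @return A `BenchmarkSummary`: list with `summary` (mean/sd F1 and AUPRC
#'   per method), `per_rep` metrics, `fdr` (empirical FDR at nominal
#'   levels), `mean_pr` (vertically averaged PR curve on a 101-point recall
#'   grid), `reps`, `seed`, `params`.
#' @export
run_paired_benchmark <- function(params,
                                 methods = c("pearson", "spearman",
                                             "partial_pearson",
                                             "partial_spearman"),
                                 reps = 100L, alpha = 0.1, rho_cut = -0.5,
                                 de_alpha = 0.05, adjust = "BH", seed = 1L) {
  stopifnot(inherits(params, "SimParams"))
  if (reps < 2L) ml_stop_value("reps must be >= 2")
  recall_grid <- seq(0, 1, length.out = 101L)
  pr_store <- lapply(methods, function(m) matrix(NA_real_, reps, 101L))
  names(pr_store) <- methods
  rows <- vector("list", reps * length(methods))
  dropped <- 0L
  for (r in seq_len(reps)) {
    p_r <- params; p_r$seed <- seed + r
    study <- simulate_study(p_r)
    de_m <- welch_de(study$mirna_expr)
    de_g <- welch_de(study$gene_expr)
    de_m <- de_m[de_m$padj < de_alpha, , drop = FALSE]
    de_g <- de_g[de_g$padj < de_alpha, , drop = FALSE]
    truth_key <- paste(study$truth_pairs$mirna_id, study$truth_pairs$gene_id)
    for (k in seq_along(methods)) {
      m <- methods[k]
      res <- integrate_paired(study$mirna_expr, study$gene_expr,
                              study$target_map, de_m, de_g, method = m,
                              rho_cut = rho_cut, alpha = alpha,
                              adjust = adjust)
      row <- data.frame(rep = r, method = m, n_candidates = nrow(res),
                        f1 = NA_real_, auprc = NA_real_,
                        stringsAsFactors = FALSE)
      for (l in fdr_levels_default)
        row[[sprintf("fdr_%g", l)]] <- NA_real_
      truth <- paste(res$mirna_id, res$gene_id) %in% truth_key
      if (nrow(res) > 0L && any(truth)) {
        tp <- sum(res$call & truth)
        row$f1 <- f1_score(tp, sum(res$call & !truth), sum(!res$call & truth))
        pr <- pr_curve_auprc(res$pvalue, truth)
        row$auprc <- pr$auprc
        pr_store[[m]][r, ] <- precision_on_grid(pr$curve, recall_grid)
        row[paste0("fdr_", fdr_levels_default)] <-
          as.list(empirical_fdr(res$padj, truth))
      } else if (k == 1L) dropped <- dropped + 1L
      rows[[(r - 1L) * length(methods) + k]] <- row
    }
  }
  if (dropped > 0L)
    message(sprintf("run_paired_benchmark: %d rep(s) had no scorable candidates",
                    dropped))
  per_rep <- do.call(rbind, rows)
  summarize_bench(per_rep, pr_store, methods, params, reps, seed, recall_grid)
}

#' Benchmark per-miRNA categorical integration on simulated studies
#'
#' Per replicate: simulate a paired study, split it into disjoint miRNA and
#' mRNA cohorts, run Welch DE per cohort, then test each DE-miRNA with the
#' selected categorical methods — exact association tests on the
#' (target x anti-directional DEG) table, or expression-level rotation /
#' CAMERA set tests on the mRNA cohort. A miRNA is a true positive iff it
#' is a simulated DE-miRNA with at least one truly affected target.
#'
#' @inheritParams run_paired_benchmark
#' @param methods Subset of `c("fisher", "fisher_midp", "boschloo",
#'   "rotation", "camera")`.
#' @param deg_alpha DEG definition threshold for the association tests.
#' @param B Rotations per miRNA for the rotation test (default 999 to keep
#'   benchmark runs tractable; single analyses default to 9999).
#' @return A `BenchmarkSummary` (see [run_paired_benchmark()]).
#' @export
run_categorical_benchmark <- function(params,
                                      methods = c("fisher", "fisher_midp",
                                                  "boschloo", "rotation",
                                                  "camera"),
                                      reps = 100L, alpha = 0.1,
                                      deg_alpha = 0.05, de_alpha = 0.05,
                                      adjust = "BH", B = 999L, seed = 1L) {
  stopifnot(inherits(params, "SimParams"))
  if (reps < 2L) ml_stop_value("reps must be >= 2")
  recall_grid <- seq(0, 1, length.out = 101L)
  pr_store <- lapply(methods, function(m) matrix(NA_real_, reps, 101L))
  names(pr_store) <- methods
  rows <- vector("list", reps * length(methods))
  dropped <- 0L
  for (r in seq_len(reps)) {
    p_r <- params; p_r$seed <- seed + r
    study <- simulate_study(p_r)
    cohorts <- split_unpaired(study, seed = seed + r)
    de_m <- welch_de(cohorts$mirna_expr)
    de_m <- de_m[de_m$padj < de_alpha & de_m$direction != 0, , drop = FALSE]
    de_g <- welch_de(cohorts$gene_expr)
    universe <- feature_ids(cohorts$gene_expr)
    for (k in seq_along(methods)) {
      m <- methods[k]
      res <- if (m %in% c("fisher", "fisher_midp", "boschloo")) {
        integrate_unpaired(de_m, de_g, study$target_map, universe,
                           method = m, deg_alpha = deg_alpha, alpha = alpha,
                           adjust = adjust)
      } else {
        integrate_unpaired_sets(de_m, cohorts$gene_expr, study$target_map,
                                method = m, B = B, alpha = alpha,
                                adjust = adjust, seed = seed + r)
      }
      res <- res[res$testable, , drop = FALSE]
      row <- data.frame(rep = r, method = m, n_candidates = nrow(res),
                        f1 = NA_real_, auprc = NA_real_,
                        stringsAsFactors = FALSE)
      for (l in fdr_levels_default)
        row[[sprintf("fdr_%g", l)]] <- NA_real_
      truth <- res$mirna_id %in% study$truth_mirnas
      if (nrow(res) > 0L && any(truth)) {
        tp <- sum(res$call & truth)
        row$f1 <- f1_score(tp, sum(res$call & !truth), sum(!res$call & truth))
        pr <- pr_curve_auprc(res$pvalue, truth)
        row$auprc <- pr$auprc
        pr_store[[m]][r, ] <- precision_on_grid(pr$curve, recall_grid)
        row[paste0("fdr_", fdr_levels_default)] <-
          as.list(empirical_fdr(res$padj, truth))
      } else if (k == 1L) dropped <- dropped + 1L
      rows[[(r - 1L) * length(methods) + k]] <- row
    }
  }
  if (dropped > 0L)
    message(sprintf("run_categorical_benchmark: %d rep(s) had no scorable DE-miRNAs",
                    dropped))
  per_rep <- do.call(rbind, rows)
  summarize_bench(per_rep, pr_store, methods, params, reps, seed, recall_grid)
}

#' Mean F1 of the paired methods across a sample-size grid
#'
#' Re-runs the paired benchmark at each `n_per_group` in `n_grid` with
#' shared per-replicate seeds across cells, and returns mean F1 per method
#' per n in long format.
#'
#' @inheritParams run_paired_benchmark
#' @param n_grid Sample sizes per group to evaluate.
#' @return `data.frame` with columns `n_per_group`, `method`, `mean_f1`,
#'   `sd_f1`, `reps_used`.
#' @export
sample_size_sweep <- function(params, n_grid = c(5, 10, 15, 20, 25, 30, 40, 50),
                              reps = 20L,
                              methods = c("pearson", "spearman",
                                          "partial_pearson",
                                          "partial_spearman"),
                              alpha = 0.1, rho_cut = -0.5, de_alpha = 0.05,
                              seed = 1L) {
  out <- lapply(n_grid, function(n) {
    p_n <- params; p_n$n_per_group <- as.integer(n)
    b <- run_paired_benchmark(p_n, methods = methods, reps = reps,
                              alpha = alpha, rho_cut = rho_cut,
                              de_alpha = de_alpha, seed = seed)
    cbind(n_per_group = n, b$summary[, c("method", "mean_f1", "sd_f1",
                                         "reps_used")])
  })
  do.call(rbind, out)
}
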
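#' Mid-rank (fractional) ranks
#'
#' Ranks 1..n with ties receiving the mean of the ranks they span; the
#' building block for Spearman correlation throughout the package.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector of mid-tie ranks; `sum(rank_midtie(x)) == n*(n+1)/2`.
#' @export
rank_midtie <- function(x) {
  if (length(x) == 0L) ml_stop_value("cannot rank an empty vector")
  if (!all(is.finite(x))) ml_stop_value("non-finite values in 'x'")
  rank(x, ties.method = "average")
}

#' Least-squares residuals on a covariate matrix
#'
#' Projects `y` onto the orthogonal complement of the column space of
#' `covariates`; the residuals are orthogonal to every covariate column.
#' Used to remove the group effect before partial correlation, guarding
#' against Simpson's-paradox artifacts where a shared group shift fakes a
#' pairwise anti-correlation.
#'
#' @param y Numeric response vector.
#' @param covariates Numeric matrix including an intercept column; must have
#'   full column rank.
#' @return Numeric vector of residuals.
#' @export
residualize <- function(y, covariates) {
  covariates <- as.matrix(covariates)
  if (!is.numeric(y) || !all(is.finite(y)))
    ml_stop_value("'y' must be finite numeric")
  if (nrow(covariates) != length(y))
    ml_stop_consistency("nrow(covariates) != length(y)")
  qr_c <- qr(covariates)
  if (qr_c$rank < ncol(covariates))
    ml_stop_value("covariate matrix is rank-deficient (rank %d < %d columns)",
                  qr_c$rank, ncol(covariates))
  as.numeric(qr.resid(qr_c, y))
}

## Design used by all partial methods: intercept + group indicator(s).
group_design <- function(groups, n) {
  g <- factor(groups)
  if (nlevels(g) <= 1L) return(matrix(1, n, 1L))
  cbind(1, stats::model.matrix(~g)[, -1L, drop = FALSE])
}

#' Correlate two vectors with an anti-correlation-oriented test
#'
#' Computes simple or partial (group-adjusted) Pearson or Spearman
#' correlation. Spearman is Pearson on mid-tie ranks; the partial variants
#' correlate the residuals after regressing out the intercept + group design
#' (for Spearman, the ranks are residualized: rank first, then adjust).
#' The p-value comes from the t transform `t = rho * sqrt(df / (1 - rho^2))`
#' with `df = n - 2` (simple) or `n - 2 - k` (partial, `k` non-intercept
#' covariate columns), lower tail for the default alternative `"less"`
#' (negative association, the miRNA-repression signature).
#'
#' @param x,y Numeric vectors of equal length.
#' @param method One of `"pearson"`, `"spearman"`, `"partial_pearson"`,
#'   `"partial_spearman"`.
#' @param groups Group labels (required for partial methods; a single level
#'   reduces them to the simple estimators).
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @return List with `rho`, `pvalue`, `n`, `df`, `method`. A vector that is
#'   constant (after any residualization) yields `rho = NA`, `pvalue = 1`
#'   and a warning rather than an error.
#' @export
correlate <- function(x, y,
                      method = c("pearson", "spearman",
                                 "partial_pearson", "partial_spearman"),
                      groups = NULL,
                      alternative = c("less", "greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) ml_stop_consistency("length(x) != length(y)")
  n <- length(x)
  partial <- startsWith(method, "partial_")
  spearman <- grepl("spearman", method)
  if (partial && is.null(groups))
    ml_stop_value("partial methods require 'groups'")
  X <- if (partial) group_design(groups, n) else matrix(1, n, 1L)
  k <- ncol(X) - 1L
  df <- n - 2L - k
  if (df < 1L) ml_stop_value("too few samples (n = %d) for method '%s'", n, method)
  if (spearman) { x <- rank_midtie(x); y <- rank_midtie(y) }
  rx <- residualize(x, X)
  ry <- residualize(y, X)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  eps <- 1e-12
  if (sx < eps * max(1, abs(mean(x))) || sy < eps * max(1, abs(mean(y)))) {
    warning("constant vector after residualization; rho set to NA, p = 1")
    return(list(rho = NA_real_, pvalue = 1, n = n, df = df, method = method))
  }
  rho <- sum(rx * ry) / (sx * sy)
  rho <- max(-1, min(1, rho))
  list(rho = rho, pvalue = cor_pvalue(rho, df, alternative),
       n = n, df = df, method = method)
}

cor_pvalue <- function(rho, df, alternative) {
  p <- if (abs(rho) >= 1) {
    ifelse(rho >= 1, 1, 0)      # lower-tail p at the boundary
  } else {
    stats::pt(rho * sqrt(df / (1 - rho^2)), df = df)
  }
  switch(alternative,
         less = p,
         greater = 1 - p,
         two.sided = 2 * pmin(p, 1 - p))
}

## Vectorized engine shared by integrate_paired and the benchmark: given the
## two matrices and an index pair list, returns rho + one-sided p per pair.
## Identical, by construction and by test, to scalar correlate() per pair.
pair_correlations <- function(Xm, Xg, mi, gi, method, groups,
                              alternative = "less") {
  n <- ncol(Xm)
  partial <- startsWith(method, "partial_")
  spearman <- grepl("spearman", method)
  D <- if (partial) group_design(groups, n) else matrix(1, n, 1L)
  k <- ncol(D) - 1L
  df <- n - 2L - k
  if (df < 1L) ml_stop_value("too few samples (n = %d) for method '%s'", n, method)
  prep <- function(M) {
    if (spearman) M <- t(apply(M, 1L, rank, ties.method = "average"))
    qr_d <- qr(D)
    R <- t(qr.resid(qr_d, t(M)))
    nrm <- sqrt(rowSums(R^2))
    list(R = R, nrm = nrm)
  }
  pm <- prep(Xm); pg <- prep(Xg)
  num <- unname(rowSums(pm$R[mi, , drop = FALSE] * pg$R[gi, , drop = FALSE]))
  den <- unname(pm$nrm[mi] * pg$nrm[gi])
  bad <- den < 1e-10
  rho <- ifelse(bad, NA_real_, pmin(1, pmax(-1, num / pmax(den, 1e-300))))
  if (any(bad))
    warning(sprintf("%d pair(s) with a constant vector; rho = NA, p = 1",
                    sum(bad)))
  pv <- rep(1, length(rho))
  ok <- !bad
  pv[ok] <- vapply(rho[ok], cor_pvalue, 0, df = df, alternative = alternative)
  list(rho = rho, pvalue = pv, n = n, df = df)
}

#' Paired-mode integration of miRNA and mRNA differential expression
#'
#' For every candidate pair — a target-map pair whose miRNA is in
#' `de_mirnas` and whose gene is in `de_genes`, both measured — tests
#' one-sided anti-correlation across the shared samples, adjusts p-values
#' over exactly the tested pairs, and calls pairs with
#' `rho < rho_cut & padj < alpha` (defaults: rho below -0.5 at adjusted
#' p below 0.1).
#'
#' @param mirna_expr,gene_expr [ExpressionMatrix] objects sharing an
#'   identical sample set and groups (paired design). Columns of
#'   `gene_expr` are aligned to `mirna_expr` by sample id.
#' @param targets A [TargetMap] of candidate interactions.
#' @param de_mirnas,de_genes [DETable]s already filtered to significant
#'   features.
#' @param method Correlation variant, see [correlate()].
#' @param rho_cut Correlation threshold for a call (default -0.5).
#' @param alpha Adjusted-p threshold for a call (default 0.1).
#' @param adjust `"BH"` or `"qvalue"` (Storey).
#' @param alternative Test sidedness, default `"less"`.
#' @return A `data.frame` of class `PairedIntegration`, one row per tested
#'   pair in lexicographic (mirna_id, gene_id) order, with columns
#'   `mirna_id`, `gene_id`, `rho`, `pvalue`, `padj`, `n`, `method`, `call`;
#'   attributes `rho_cut` and `alpha` record the decision rule.
#' @export
integrate_paired <- function(mirna_expr, gene_expr, targets,
                             de_mirnas, de_genes,
                             method = c("partial_spearman", "spearman",
                                        "pearson", "partial_pearson"),
                             rho_cut = -0.5, alpha = 0.1,
                             adjust = c("BH", "qvalue"),
                             alternative = "less") {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(inherits(mirna_expr, "ExpressionMatrix"),
            inherits(gene_expr, "ExpressionMatrix"))
  if (!setequal(sample_ids(mirna_expr), sample_ids(gene_expr)))
    ml_stop_consistency("miRNA and gene matrices have different sample sets")
  ord <- sample_ids(mirna_expr)
  Xg <- gene_expr$values[, ord, drop = FALSE]
  grp_g <- as.character(gene_expr$groups[match(ord, sample_ids(gene_expr))])
  if (!identical(grp_g, as.character(mirna_expr$groups)))
    ml_stop_consistency("group labels differ between matrices")
  groups <- mirna_expr$groups

  cand <- targets[targets$mirna_id %in% de_mirnas$feature_id &
                  targets$gene_id %in% de_genes$feature_id &
                  targets$mirna_id %in% feature_ids(mirna_expr) &
                  targets$gene_id %in% rownames(Xg), , drop = FALSE]
  cand <- cand[order(cand$mirna_id, cand$gene_id), , drop = FALSE]
  if (nrow(cand) == 0L) {
    res <- data.frame(mirna_id = character(), gene_id = character(),
                      rho = numeric(), pvalue = numeric(), padj = numeric(),
                      n = integer(), method = character(), call = logical(),
                      stringsAsFactors = FALSE)
    return(structure(res, rho_cut = rho_cut, alpha = alpha,
                     class = c("PairedIntegration", "data.frame")))
  }
  mi <- match(cand$mirna_id, feature_ids(mirna_expr))
  gi <- match(cand$gene_id, rownames(Xg))
  cc <- pair_correlations(mirna_expr$values, Xg, mi, gi, method, groups,
                          alternative)
  padj <- if (adjust == "BH") bh_adjust(cc$pvalue)
          else storey_qvalue(cc$pvalue)$qvalues
  res <- data.frame(mirna_id = cand$mirna_id, gene_id = cand$gene_id,
                    rho = cc$rho, pvalue = cc$pvalue, padj = padj,
                    n = cc$n, method = method,
                    call = !is.na(cc$rho) & cc$rho < rho_cut & padj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, rho_cut = rho_cut, alpha = alpha,
            class = c("PairedIntegration", "data.frame"))
}
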
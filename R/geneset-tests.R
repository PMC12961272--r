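#' Per-gene two-group contrast statistics
#'
#' Ordinary pooled-variance two-sample t statistics for the contrast
#' (second group level minus first), `df = n - 2`, plus the normal-quantile
#' transform `z = qnorm(pt(t, df))` clamped to `|z| <= 8`. Genes with zero
#' residual variance get `t = 0`, `z = 0` with a warning.
#'
#' @param Y An [ExpressionMatrix] with two groups.
#' @param groups Optional group labels overriding `Y$groups`.
#' @return `data.frame` with columns `gene_id`, `t`, `df`, `z`.
#' @export
gene_contrast_stats <- function(Y, groups = NULL) {
  stopifnot(inherits(Y, "ExpressionMatrix"))
  g <- factor(if (is.null(groups)) Y$groups else groups)
  if (nlevels(g) != 2L) ml_stop_value("exactly two groups required")
  M <- Y$values
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) ml_stop_value("each group needs >= 2 samples")
  m1 <- rowMeans(M[, i1, drop = FALSE]); m2 <- rowMeans(M[, i2, drop = FALSE])
  ss1 <- rowSums((M[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((M[, i2, drop = FALSE] - m2)^2)
  df <- n - 2L
  s2 <- (ss1 + ss2) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  tt <- (m2 - m1) / se
  zero <- se < 1e-12
  if (any(zero)) {
    warning(sprintf("%d gene(s) with zero residual variance; z set to 0",
                    sum(zero)))
    tt[zero] <- 0
  }
  z <- stats::qnorm(stats::pt(tt, df))
  z <- pmin(pmax(z, -8), 8)
  data.frame(gene_id = rownames(M), t = tt, df = df, z = z,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Directional rotation gene-set test
#'
#' Self-contained set test in the spirit of ROAST/fry: the observed
#' statistic is the mean of `direction * z` over the set genes, and the
#' null is generated by random rotations in the sample space. Each gene's
#' data are projected onto the (n-1)-dimensional complement of the
#' intercept, whose first coordinate spans the group contrast; a rotation
#' replaces that effect coordinate with the projection onto a random unit
#' vector (uniform on the sphere, *shared across genes within a rotation*,
#' which preserves inter-gene correlation), the t and z statistics are
#' recomputed, and `p = (1 + #{S_b >= S}) / (B + 1)`.
#'
#' @param Y An [ExpressionMatrix] with two groups.
#' @param groups Optional group labels overriding `Y$groups`.
#' @param set Character vector of gene ids (intersected with measured genes).
#' @param direction +1 or -1: the expected sign of the set's group effect
#'   (for miRNA targets, the opposite of the miRNA's log2 fold change sign).
#' @param B Number of rotations (>= 99; default 9999).
#' @param seed Integer seed for the rotation draws; `NULL` uses the current
#'   RNG state.
#' @return List of class `SetTestResult`: `set_size`, `statistic`, `pvalue`,
#'   `method = "rotation"`, `n_rotations`, `testable`.
#' @export
rotation_set_test <- function(Y, set, direction, B = 9999L, seed = NULL,
                              groups = NULL) {
  stopifnot(inherits(Y, "ExpressionMatrix"))
  if (B < 99L) ml_stop_value("B must be >= 99 (got %d)", B)
  if (!direction %in% c(-1, 1)) ml_stop_value("direction must be +1 or -1")
  g <- factor(if (is.null(groups)) Y$groups else groups)
  if (nlevels(g) != 2L) ml_stop_value("exactly two groups required")
  idx <- which(rownames(Y$values) %in% set)
  if (!length(idx))
    return(structure(list(set_size = 0L, statistic = NA_real_,
                          pvalue = NA_real_, method = "rotation",
                          n_rotations = B, testable = FALSE),
                     class = "SetTestResult"))
  n <- ncol(Y$values)
  d <- n - 1L                      # dim of intercept-complement space
  df <- d - 1L                     # residual df, = n - 2
  x <- as.numeric(g) - 1
  Qc <- qr.Q(qr(cbind(1, x)), complete = TRUE)
  ## U: set genes in the basis where row 1 is the contrast direction
  U <- t(Qc[, -1L, drop = FALSE]) %*% t(Y$values[idx, , drop = FALSE])
  norm2 <- colSums(U^2)
  z_of <- function(e) {            # effect coordinate -> z, vectorized
    s2 <- pmax(norm2 - e^2, 0) / df
    tt <- ifelse(s2 < 1e-24, 0, e / sqrt(s2))
    pmin(pmax(stats::qnorm(stats::pt(tt, df)), -8), 8)
  }
  s_obs <- mean(direction * z_of(U[1L, ]))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  W <- matrix(stats::rnorm(B * d), B, d)
  W <- W / sqrt(rowSums(W^2))
  E <- W %*% U                     # B x m rotated effect coordinates
  s_rot <- numeric(B)
  for (b in seq_len(B)) s_rot[b] <- mean(direction * z_of(E[b, ]))
  p <- (1 + sum(s_rot >= s_obs)) / (B + 1)
  structure(list(set_size = length(idx), statistic = s_obs, pvalue = p,
                 method = "rotation", n_rotations = B, testable = TRUE),
            class = "SetTestResult")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' CAMERA-style competitive gene-set test
#'
#' Compares the mean directional z of set genes against all other genes,
#' inflating the variance for inter-gene correlation:
#' `delta = mean(dir * z, set) - mean(dir * z, out)`,
#' `VIF = 1 + (m - 1) * rho_bar`,
#' `var = s2 * (VIF / m + 1 / (M - m))` with `s2` the pooled z variance,
#' and a one-sided normal upper-tail p for `delta / sqrt(var)`.
#'
#' @param stats Output of [gene_contrast_stats()].
#' @param set Character vector of gene ids (set size >= 2 after
#'   intersection; must not contain every measured gene).
#' @param direction +1 or -1.
#' @param residual_corr Mean inter-gene residual correlation `rho_bar` of
#'   the set, e.g. from [estimate_setcorr()]; default 0 (independence).
#' @return List of class `SetTestResult`: `set_size`, `statistic` (delta),
#'   `pvalue`, `method = "camera"`, `vif`, `testable`.
#' @export
camera_test <- function(stats, set, direction, residual_corr = 0) {
  if (!direction %in% c(-1, 1)) ml_stop_value("direction must be +1 or -1")
  in_set <- stats$gene_id %in% set
  m <- sum(in_set); M <- nrow(stats)
  if (m == M) ml_stop_value("set contains every measured gene; no competitive comparison")
  if (m < 2L)
    return(structure(list(set_size = m, statistic = NA_real_,
                          pvalue = NA_real_, method = "camera",
                          vif = NA_real_, testable = FALSE),
                     class = "SetTestResult"))
  dz <- direction * stats$z
  delta <- mean(dz[in_set]) - mean(dz[!in_set])
  vif <- max(1 + (m - 1) * residual_corr, 1e-6)
  s2 <- stats::var(dz)
  v <- s2 * (vif / m + 1 / (M - m))
  p <- stats::pnorm(delta / sqrt(v), lower.tail = FALSE)
  structure(list(set_size = m, statistic = delta, pvalue = p,
                 method = "camera", vif = vif, testable = TRUE),
            class = "SetTestResult")
}

#' Unpaired-mode integration with expression-level set tests
#'
#' Applies [rotation_set_test()] or [camera_test()] per DE-miRNA to its
#' measured target set on the gene expression matrix, with the tested
#' direction opposite to the miRNA's log2 fold change (the anti-correlation
#' hypothesis). Untestable miRNAs (direction 0, or too few measured
#' targets) are flagged and excluded from the multiplicity correction.
#'
#' @param de_mirnas [DETable] of significant DE-miRNAs.
#' @param gene_expr [ExpressionMatrix] of the mRNA cohort (two groups).
#' @param targets A [TargetMap].
#' @param method `"rotation"` or `"camera"`.
#' @param B Rotations per miRNA (rotation only).
#' @param alpha Adjusted-p call threshold.
#' @param adjust `"BH"` or `"qvalue"`.
#' @param seed Base seed; miRNA i uses `seed + i` (rotation only).
#' @return `data.frame` of class `SetIntegrationResult` with columns
#'   `mirna_id`, `set_size`, `direction_tested`, `statistic`, `pvalue`,
#'   `padj`, `method`, `testable`, `call`.
#' @export
integrate_unpaired_sets <- function(de_mirnas, gene_expr, targets,
                                    method = c("rotation", "camera"),
                                    B = 999L, alpha = 0.1,
                                    adjust = c("BH", "qvalue"),
                                    seed = NULL) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  gs <- if (method == "camera") gene_contrast_stats(gene_expr) else NULL
  rows <- lapply(seq_len(nrow(de_mirnas)), function(i) {
    dir_m <- sign(de_mirnas$log2fc[i])
    if (dir_m == 0) {
      warning(sprintf("miRNA '%s' has direction 0; skipping",
                      de_mirnas$feature_id[i]))
      return(NULL)
    }
    set <- targets_of(targets, de_mirnas$feature_id[i])
    r <- if (method == "rotation") {
      rotation_set_test(gene_expr, set, direction = -dir_m, B = B,
                        seed = if (is.null(seed)) NULL else seed + i)
    } else {
      measured <- intersect(set, gs$gene_id)
      rho <- if (length(measured) >= 2L) estimate_setcorr(gene_expr, measured)
             else 0
      camera_test(gs, set, direction = -dir_m, residual_corr = rho)
    }
    data.frame(mirna_id = de_mirnas$feature_id[i], set_size = r$set_size,
               direction_tested = -dir_m, statistic = r$statistic,
               pvalue = r$pvalue, method = method, testable = r$testable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(mirna_id = character(), set_size = integer(),
                      direction_tested = numeric(), statistic = numeric(),
                      pvalue = numeric(), method = character(),
                      testable = logical(), stringsAsFactors = FALSE)
  res$padj <- NA_real_
  ok <- res$testable
  if (any(ok)) {
    res$padj[ok] <- if (adjust == "BH") bh_adjust(res$pvalue[ok])
                    else storey_qvalue(res$pvalue[ok])$qvalues
  }
  res$call <- !is.na(res$padj) & res$padj < alpha
  rownames(res) <- NULL
  structure(res, alpha = alpha,
            class = c("SetIntegrationResult", "data.frame"))
}

#' Mean inter-gene residual correlation of a gene set
#'
#' Mean pairwise Pearson correlation of the group-centered residuals of the
#' set genes, truncated to \[0, 1): negative estimates are floored at 0 (a
#' VIF below 1 is not used) and perfect correlation is kept strictly below
#' 1 for numerical safety.
#'
#' @param Y An [ExpressionMatrix] with two groups.
#' @param set Character vector of gene ids, >= 2 measured.
#' @param groups Optional group labels overriding `Y$groups`.
#' @return Scalar `rho_bar` in \[0, 1).
#' @export
estimate_setcorr <- function(Y, set, groups = NULL) {
  stopifnot(inherits(Y, "ExpressionMatrix"))
  g <- factor(if (is.null(groups)) Y$groups else groups)
  idx <- which(rownames(Y$values) %in% set)
  if (length(idx) < 2L) ml_stop_value("set must have >= 2 measured genes")
  M <- Y$values[idx, , drop = FALSE]
  for (lev in levels(g)) {
    j <- g == lev
    M[, j] <- M[, j, drop = FALSE] - rowMeans(M[, j, drop = FALSE])
  }
  cm <- suppressWarnings(stats::cor(t(M)))
  rho <- mean(cm[upper.tri(cm)], na.rm = TRUE)
  if (!is.finite(rho)) rho <- 0
  min(max(rho, 0), 1 - 1e-6)
}
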
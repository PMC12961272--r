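## Hypergeometric upper-tail kernel shared by Fisher, mid-P and ORA:
## P(X >= q) with X ~ Hypergeometric(N total, K "successes", n drawn),
## accumulated from the point masses for numerical transparency.
hyper_upper_tail <- function(q, N, K, n, strict = FALSE, half_point = FALSE) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  if (q > hi) return(0)
  xs <- max(q, lo):hi
  dens <- stats::dhyper(xs, K, N - K, n)
  p <- sum(dens)
  if (strict) p <- p - dens[1L] * if (half_point) 0.5 else 1
  min(max(p, 0), 1)
}

as_table2x2 <- function(t) {
  v <- if (is.list(t)) c(t$a, t$b, t$c, t$d) else as.numeric(t)
  if (length(v) != 4L || anyNA(v)) ml_stop_value("need a 2x2 table (a, b, c, d)")
  if (any(v < 0) || any(v != round(v)))
    ml_stop_value("table entries must be non-negative integers")
  as.integer(round(v))
}

#' 2x2 contingency table for miRNA-target directional association
#'
#' @param a Targets of the miRNA that are anti-directional DEGs.
#' @param b Targets that are not.
#' @param c Non-target universe genes that are anti-directional DEGs.
#' @param d Remaining universe genes.
#' @return List of class `ContingencyTable2x2`.
#' @export
contingency_table <- function(a, b, c, d) {
  v <- as_table2x2(c(a, b, c, d))
  structure(list(a = v[1L], b = v[2L], c = v[3L], d = v[4L]),
            class = "ContingencyTable2x2")
}

#' One-sided Fisher exact test (enrichment)
#'
#' `p = P(X >= a)` with `X ~ Hypergeometric(N = a+b+c+d, K = a+c, n = a+b)`:
#' the probability, conditional on both margins, of an overlap at least as
#' large as observed. Degenerate margins give `p = 1`.
#'
#' @param t A 2x2 table: [contingency_table()], a list with `a,b,c,d`, or a
#'   numeric vector `c(a, b, c, d)`.
#' @return One-sided p-value.
#' @export
fisher_one_sided <- function(t) {
  v <- as_table2x2(t)
  hyper_upper_tail(v[1L], N = sum(v), K = v[1L] + v[3L], n = v[1L] + v[2L])
}

#' Lancaster mid-P variant of the one-sided Fisher test
#'
#' `p_mid = P(X > a) + 0.5 * P(X = a)`: half the observed table's
#' probability is counted, reducing the conservativeness of the discrete
#' tail. Always `<= fisher_one_sided(t)`.
#'
#' @inheritParams fisher_one_sided
#' @return One-sided mid-P value.
#' @export
fisher_midp <- function(t) {
  v <- as_table2x2(t)
  hyper_upper_tail(v[1L], N = sum(v), K = v[1L] + v[3L], n = v[1L] + v[2L],
                   strict = TRUE, half_point = TRUE)
}

#' Boschloo's unconditional exact test (one-sided)
#'
#' Uses the one-sided Fisher p as the test statistic T and removes the
#' conditioning on the column margin: with row totals `n1 = a+b` (targets)
#' and `n2 = c+d` (non-targets) fixed and a common success probability `pi`
#' under the null,
#' `p_B = max over pi of P(T(X1, X2) <= T(a, c))` with independent
#' `X1 ~ Binom(n1, pi)`, `X2 ~ Binom(n2, pi)`. The maximum is taken over a
#' uniform grid on \[0, 1\] including the endpoints; T-ties are resolved
#' with a 1e-12 absolute tolerance. Uniformly at least as powerful as
#' Fisher's test: `boschloo(t) <= fisher_one_sided(t)` for every table.
#'
#' The outcome-space sum exploits that T is increasing in `x2` for fixed
#' `x1` (larger column margin makes the observed row-1 count less extreme),
#' so the rejection region is `{x2 <= cut(x1)}` with each cut found by
#' binary search; the grid scan then uses binomial tail sums instead of an
#' explicit double loop, keeping large universes (n2 in the thousands)
#' tractable.
#'
#' @inheritParams fisher_one_sided
#' @param grid_size Number of equally spaced nuisance values (default 1001).
#' @return One-sided p-value.
#' @export
boschloo <- function(t, grid_size = 1001L) {
  v <- as_table2x2(t)
  n1 <- v[1L] + v[2L]; n2 <- v[3L] + v[4L]
  if (n1 == 0L || n2 == 0L) return(1)
  tol <- 1e-12
  t_obs <- fisher_one_sided(v)
  stat <- function(x1, x2) fisher_one_sided(c(x1, n1 - x1, x2, n2 - x2))
  ## cut[x1 + 1] = largest x2 with T(x1, x2) <= t_obs + tol, or -1
  cut <- integer(n1 + 1L)
  for (x1 in 0:n1) {
    if (stat(x1, 0L) > t_obs + tol) { cut[x1 + 1L] <- -1L; next }
    lo <- 0L; hi <- n2
    while (lo < hi) {                       # invariant: T(x1, lo) <= t_obs
      mid <- lo + (hi - lo + 1L) %/% 2L
      if (stat(x1, mid) <= t_obs + tol) lo <- mid else hi <- mid - 1L
    }
    cut[x1 + 1L] <- lo
  }
  if (all(cut == n2)) return(1)             # region is the whole space
  grid <- seq(0, 1, length.out = grid_size)
  active <- which(cut >= 0L)
  p_max <- 0
  for (pi0 in grid) {
    d1 <- stats::dbinom(active - 1L, n1, pi0)
    tails <- stats::pbinom(cut[active], n2, pi0)
    p_max <- max(p_max, sum(d1 * tails))
  }
  min(p_max, 1)
}

#' Build the association contingency table for one DE-miRNA
#'
#' Defines the anti-directional DEG set
#' `D = {g : padj(g) < deg_alpha and sign(log2fc(g)) == -sign(miRNA log2fc)}`
#' within the measured-gene universe and counts the 2x2 overlap with the
#' miRNA's measured targets: `a = |targets  D|`, `b = |targets \ D|`,
#' `c = |D \ targets|`, `d` the rest of the universe.
#'
#' @param mirna One row of a [DETable] (the DE-miRNA).
#' @param targets A [TargetMap].
#' @param de_genes Full gene [DETable] (all measured genes with their padj).
#' @param universe Character vector of all measured gene ids.
#' @param deg_alpha Adjusted-p threshold defining DEGs (default 0.05).
#' @return A `ContingencyTable2x2` with extra fields `mirna_id`,
#'   `direction_tested` and `testable` (`FALSE` when the miRNA has no
#'   measured targets).
#' @export
build_contingency <- function(mirna, targets, de_genes, universe,
                              deg_alpha = 0.05) {
  if (!length(universe)) ml_stop_value("empty gene universe")
  universe <- unique(as.character(universe))
  dir_m <- sign(mirna$log2fc)
  if (dir_m == 0) {
    warning(sprintf("miRNA '%s' has direction 0; skipping", mirna$feature_id))
    return(NULL)
  }
  tg <- intersect(targets_of(targets, mirna$feature_id), universe)
  keep <- de_genes$feature_id %in% universe
  D <- de_genes$feature_id[keep & de_genes$padj < deg_alpha &
                           sign(de_genes$log2fc) == -dir_m]
  a <- length(intersect(tg, D))
  b <- length(tg) - a
  cc <- length(setdiff(D, tg))
  d <- length(universe) - length(tg) - cc
  out <- contingency_table(a, b, cc, d)
  out$mirna_id <- mirna$feature_id
  out$direction_tested <- -dir_m
  out$testable <- length(tg) > 0L
  out
}

#' Unpaired-mode integration: per-miRNA directional association
#'
#' For each DE-miRNA, tests whether its measured targets are
#' over-represented among genes differentially expressed in the opposite
#' direction, using the selected exact test. miRNAs with direction 0 or no
#' measured targets are reported but flagged untestable and excluded from
#' the multiplicity correction.
#'
#' @param de_mirnas [DETable] of significant DE-miRNAs (filtered upstream).
#' @param de_genes Full gene [DETable] for the measured universe.
#' @param targets A [TargetMap].
#' @param universe Character vector of measured gene ids.
#' @param method `"boschloo"` (default), `"fisher"` or `"fisher_midp"`.
#' @param deg_alpha DEG definition threshold on `padj` (default 0.05).
#' @param alpha Adjusted-p call threshold (default 0.1).
#' @param adjust `"BH"` or `"qvalue"`.
#' @param grid_size Nuisance grid for [boschloo()].
#' @return `data.frame` of class `AssociationResult`: one row per DE-miRNA
#'   with columns `mirna_id`, `a`, `b`, `c`, `d`, `direction_tested`,
#'   `pvalue`, `padj`, `method`, `testable`, `call`.
#' @export
integrate_unpaired <- function(de_mirnas, de_genes, targets, universe,
                               method = c("boschloo", "fisher", "fisher_midp"),
                               deg_alpha = 0.05, alpha = 0.1,
                               adjust = c("BH", "qvalue"),
                               grid_size = 1001L) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  rows <- lapply(seq_len(nrow(de_mirnas)), function(i) {
    tab <- build_contingency(de_mirnas[i, ], targets, de_genes, universe,
                             deg_alpha)
    if (is.null(tab)) return(NULL)
    p <- if (!tab$testable) NA_real_
         else switch(method,
                     fisher = fisher_one_sided(tab),
                     fisher_midp = fisher_midp(tab),
                     boschloo = boschloo(tab, grid_size))
    data.frame(mirna_id = tab$mirna_id, a = tab$a, b = tab$b, c = tab$c,
               d = tab$d, direction_tested = tab$direction_tested,
               pvalue = p, method = method, testable = tab$testable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(mirna_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(),
                      direction_tested = numeric(), pvalue = numeric(),
                      method = character(), testable = logical(),
                      padj = numeric(), call = logical(),
                      stringsAsFactors = FALSE)
    return(structure(res, alpha = alpha,
                     class = c("AssociationResult", "data.frame")))
  }
  res$padj <- NA_real_
  ok <- res$testable
  if (any(ok)) {
    res$padj[ok] <- if (adjust == "BH") bh_adjust(res$pvalue[ok])
                    else storey_qvalue(res$pvalue[ok])$qvalues
  }
  res$call <- !is.na(res$padj) & res$padj < alpha
  rownames(res) <- NULL
  structure(res, alpha = alpha, class = c("AssociationResult", "data.frame"))
}
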
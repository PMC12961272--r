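#' Over-representation analysis of a hit list against gene sets
#'
#' For each gene set, tests whether the hit list overlaps the set more than
#' expected by chance within the measured universe:
#' `p = P(X >= overlap)` with
#' `X ~ Hypergeometric(universe_size, set_size_in_universe, hits_size)` —
#' the same upper-tail kernel as [fisher_one_sided()] on the corresponding
#' 2x2 table. P-values are BH-adjusted across tested sets.
#'
#' The universe should be the genes actually measured in the mRNA
#' experiment, not the genome, to avoid detection-bias inflation.
#'
#' @param hits Character vector of hit gene ids, a subset of `universe`.
#' @param sets A [read_gmt()] collection or named list of gene-id vectors.
#' @param universe Character vector of measured gene ids.
#' @param alpha Adjusted-p threshold recorded in the `call` column.
#' @param min_size Minimum set size after intersection with the universe
#'   (default 2); smaller sets are skipped.
#' @return `data.frame` of class `OraResult`, sorted by p-value, with
#'   columns `set_name`, `overlap`, `set_size_in_universe`, `hits_size`,
#'   `universe_size`, `pvalue`, `padj`, `call`.
#' @export
ora <- function(hits, sets, universe, alpha = 0.1, min_size = 2L) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  bad <- setdiff(hits, universe)
  if (length(bad))
    ml_stop_consistency("hits not in universe: %s", paste(bad, collapse = ", "))
  N <- length(universe)
  n_hits <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    if (length(s) < min_size) return(NULL)
    ov <- length(intersect(s, hits))
    p <- hyper_upper_tail(ov, N = N, K = length(s), n = n_hits)
    data.frame(set_name = nm, overlap = ov,
               set_size_in_universe = length(s), hits_size = n_hits,
               universe_size = N, pvalue = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(set_name = character(), overlap = integer(),
                      set_size_in_universe = integer(), hits_size = integer(),
                      universe_size = integer(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  res$padj <- bh_adjust(res$pvalue)
  res <- res[order(res$pvalue, res$set_name), , drop = FALSE]
  res$call <- res$padj < alpha
  rownames(res) <- NULL
  structure(res, alpha = alpha, class = c("OraResult", "data.frame"))
}
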
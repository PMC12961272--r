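## Independent oracles: every routine here is deliberately written from the
## definition (explicit enumeration / normal equations / choose()), not by
## calling the package's own kernels.

## Exact hypergeometric upper tail by explicit enumeration with choose().
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  lo <- max(0L, n - (N - K)); hi <- min(n, K)
  if (a > hi) return(0)
  xs <- max(a, lo):hi
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

midp_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  lo <- max(0L, n - (N - K)); hi <- min(n, K)
  if (a > hi) return(0)
  xs <- max(a, lo):hi
  dens <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  sum(dens) - 0.5 * dens[1L]
}

## Brute-force Boschloo: full (n1+1) x (n2+1) outcome grid, T from
## fisher_oracle, nuisance maximized on the same uniform grid.
boschloo_oracle <- function(a, b, c, d, grid_size = 1001L) {
  n1 <- a + b; n2 <- c + d
  if (n1 == 0L || n2 == 0L) return(1)
  Tm <- outer(0:n1, 0:n2,
              Vectorize(function(x1, x2)
                fisher_oracle(x1, n1 - x1, x2, n2 - x2)))
  mask <- (Tm <= Tm[a + 1L, c + 1L] + 1e-12) * 1
  best <- 0
  for (p in seq(0, 1, length.out = grid_size)) {
    d1 <- dbinom(0:n1, n1, p); d2 <- dbinom(0:n2, n2, p)
    best <- max(best, as.numeric(t(d1) %*% mask %*% d2))
  }
  min(best, 1)
}

## Least squares by explicit normal equations (matrix inversion).
residual_oracle <- function(y, X) {
  as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
}

## Pearson correlation + one-sided lower p by explicit sums.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n; sy <- y - sum(y) / n
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  list(rho = r, pvalue = pt(r * sqrt((n - 2) / (1 - r^2)), n - 2))
}

## Tiny two-group expression fixture with named features/samples.
make_expr <- function(values, n_per_group, feature_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(feature_ids))
    sprintf("f%02d", seq_len(nrow(m))) else feature_ids
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  ExpressionMatrix(m, rep(c("g1", "g2"), each = n_per_group))
}

write_tsv_tmp <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  path
}

## Frozen expected output of the unpaired-integration regression fixture
## (tiny_params below with mirna_effect_range=c(2,3), coupling_range=c(2,3),
## program_frac=0.2, confound_frac=0, gene_noise_sd=0.4, seed=101).
FROZEN_UNPAIRED_CALLS <- c("miR-003", "miR-014", "miR-017")

## Small fast simulator settings for integration-level tests.
tiny_params <- function(...) {
  sim_params(n_mirnas = 20L, n_genes = 300L, targets_per_mirna = 10L, ...)
}
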
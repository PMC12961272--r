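#' Simulation parameters for paired miRNA-mRNA studies
#'
#' The generator's stated world: a paired two-group design in which a
#' fraction of miRNAs are differentially expressed, a fraction of each
#' DE-miRNA's targets are truly repressed (expression coupled negatively to
#' the miRNA on the log2 scale), and a further fraction of unaffected
#' targets receive an *independent* group effect whose sign mimics
#' anti-correlation at the group level — the Simpson's-paradox confounder
#' that separates partial from simple correlation.
#'
#' @param n_per_group Samples per group (default 10, >= 3).
#' @param n_mirnas,n_genes Feature counts (default 100 and 2000).
#' @param targets_per_mirna Targets sampled per miRNA without replacement
#'   (default 50).
#' @param frac_de_mirnas Fraction of miRNAs given a group effect
#'   (default 0.2).
#' @param mirna_effect_range Absolute miRNA group effect, log2 units,
#'   uniform in this range with random sign (default c(1, 2)).
#' @param frac_influential_mirnas Fraction of DE-miRNAs that truly affect
#'   their targets (default 0.4). The remainder are differentially
#'   expressed without downstream influence — their targets move only
#'   through the independent confounding channel, providing the true
#'   negatives against which per-miRNA association tests are scored.
#' @param frac_affected_targets Fraction of each influential DE-miRNA's
#'   targets truly repressed (default 0.5;
#'   count = `round(frac * targets_per_mirna)`).
#' @param coupling_range Repression strength `beta`, uniform in this range,
#'   applied with negative sign (default c(0.7, 1.7)).
#' @param gene_noise_sd Gene-level noise sd, log2 units (default 0.85).
#' @param gene_noise_df Degrees of freedom of the gene noise: `Inf`
#'   (Gaussian) or a finite value for scaled Student-t noise (default 3,
#'   mimicking the occasional outlying sample seen in real expression
#'   data; the t draw is rescaled so its sd stays `gene_noise_sd`).
#' @param mirna_noise_sd miRNA-level noise sd (default 0.5).
#' @param mirna_noise_df Degrees of freedom of the miRNA noise (`Inf` =
#'   Gaussian, default 3 for sd-matched Student-t as for genes).
#' @param confound_frac Fraction of the unaffected targets of each
#'   DE-miRNA receiving a *mild* independent group effect whose sign
#'   mimics anti-correlation with that miRNA (default 0.4). These genes
#'   are marginally anti-correlated with the miRNA at the group level with
#'   no within-group dependence — the Simpson's-paradox false positives
#'   that separate partial from simple correlation in paired analyses.
#' @param confound_effect_range Magnitude range of the targeted
#'   confounding effect (default c(1.05, 1.55)): large enough to reach
#'   differential-expression significance in a full-size paired cohort,
#'   mostly below it in a half-size unpaired cohort.
#' @param confound_within_rho Within-group anti-correlation of targeted
#'   confounders with their miRNA (default 0.18): genes sharing upstream
#'   regulators with the miRNA co-fluctuate sample-to-sample even inside a
#'   group, but well below the partial-correlation call threshold. 0
#'   disables the channel.
#' @param program_frac Fraction of all remaining genes carrying a strong
#'   group effect with random sign (default 0.6): the disease's
#'   miRNA-independent transcriptional program. It supplies additional
#'   anti-correlated coincidences for paired analyses and, because it hits
#'   targets and non-targets uniformly, raises the differential-expression
#'   baseline against which the per-miRNA association tests compare —
#'   competitive tests stay calibrated while self-contained set tests do
#'   not.
#' @param program_effect_range Magnitude range of the disease-program
#'   effect (default c(2.5, 4.5)).
#' @param baseline_mean_range Baseline log2 abundance, uniform
#'   (default c(4, 12)).
#' @param coupling Shape of the miRNA-to-target dose-response applied to
#'   the centered miRNA signal `u` before scaling by `-beta`:
#'   `"rank"` (default) couples the target to the *rank* of the miRNA
#'   signal across samples, rescaled to the signal's spread
#'   (`sqrt(12) * sd(u) * (rank(u)/(m+1) - 1/2)` per pair): a monotone
#'   dose-response that saturates in the extremes by construction, so the
#'   miRNA-target relation is monotone but not linear on the log2 scale;
#'   `"exponential"` uses `(2^u - 1) / log(2)`, repression proportional to
#'   raw-scale miRNA abundance (convex on the log2 analysis scale);
#'   `"saturating"` uses `sat_scale * tanh(u / sat_scale)`, a plateauing
#'   dose-response; `"linear"` uses `u` unchanged. All are monotone; only
#'   `"linear"` makes Pearson correlation the correctly specified
#'   estimator.
#' @param sat_scale Half-saturation scale of the tanh coupling, log2 units
#'   (default 1).
#' @param seed Integer seed; identical seeds give bit-identical studies.
#' @return List of class `SimParams`.
#' @export
sim_params <- function(n_per_group = 10L, n_mirnas = 100L, n_genes = 2000L,
                       targets_per_mirna = 50L, frac_de_mirnas = 0.2,
                       mirna_effect_range = c(1, 2),
                       frac_influential_mirnas = 0.4,
                       frac_affected_targets = 0.5,
                       coupling_range = c(0.7, 1.7),
                       gene_noise_sd = 0.85, gene_noise_df = 3,
                       mirna_noise_sd = 0.5, mirna_noise_df = 3,
                       confound_frac = 0.4,
                       confound_effect_range = c(1.05, 1.55),
                       confound_within_rho = 0.18,
                       program_frac = 0.6,
                       program_effect_range = c(2.5, 4.5),
                       baseline_mean_range = c(4, 12),
                       coupling = c("rank", "exponential", "saturating",
                                    "linear"),
                       sat_scale = 1, seed = 1L) {
  coupling <- match.arg(coupling)
  p <- list(n_per_group = as.integer(n_per_group),
            n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
            targets_per_mirna = as.integer(targets_per_mirna),
            frac_de_mirnas = frac_de_mirnas,
            mirna_effect_range = mirna_effect_range,
            frac_influential_mirnas = frac_influential_mirnas,
            frac_affected_targets = frac_affected_targets,
            coupling_range = coupling_range,
            gene_noise_sd = gene_noise_sd, gene_noise_df = gene_noise_df,
            mirna_noise_sd = mirna_noise_sd, mirna_noise_df = mirna_noise_df,
            confound_frac = confound_frac,
            confound_effect_range = confound_effect_range,
            confound_within_rho = confound_within_rho,
            program_frac = program_frac,
            program_effect_range = program_effect_range,
            baseline_mean_range = baseline_mean_range,
            coupling = coupling, sat_scale = sat_scale,
            seed = as.integer(seed))
  for (f in c("frac_de_mirnas", "frac_influential_mirnas",
              "frac_affected_targets", "confound_frac", "program_frac"))
    if (p[[f]] < 0 || p[[f]] > 1) ml_stop_value("'%s' must be in [0, 1]", f)
  for (r in c("mirna_effect_range", "coupling_range", "baseline_mean_range",
              "confound_effect_range", "program_effect_range"))
    if (length(p[[r]]) != 2L || p[[r]][1L] > p[[r]][2L])
      ml_stop_value("'%s' must be an ordered length-2 range", r)
  if (p$n_per_group < 3L) ml_stop_value("n_per_group must be >= 3")
  if (p$targets_per_mirna > p$n_genes)
    ml_stop_value("targets_per_mirna exceeds n_genes")
  if (p$gene_noise_sd < 0 || p$mirna_noise_sd < 0)
    ml_stop_value("noise sd must be >= 0")
  if (p$gene_noise_df <= 2 || p$mirna_noise_df <= 2)
    ml_stop_value("noise df must exceed 2 (finite variance)")
  if (p$confound_within_rho < 0 || p$confound_within_rho >= 1)
    ml_stop_value("confound_within_rho must be in [0, 1)")
  structure(p, class = "SimParams")
}

runif_range <- function(n, range) stats::runif(n, range[1L], range[2L])

## Measurement noise: Gaussian (df = Inf) or sd-matched scaled Student-t.
scaled_noise <- function(n, sd, df) {
  if (is.infinite(df)) return(stats::rnorm(n, sd = sd))
  stats::rt(n, df) * sd / sqrt(df / (df - 2))
}
gene_noise <- function(n, params)
  scaled_noise(n, params$gene_noise_sd, params$gene_noise_df)

#' Simulate a paired two-group miRNA-mRNA study with known truth
#'
#' Generative model (all on the log2 scale, group indicator `I = 1` in the
#' second group):
#' \itemize{
#'   \item miRNA i: `x = mu_i + delta_i * I + N(0, mirna_noise_sd^2)`,
#'     `delta_i != 0` only for DE-miRNAs;
#'   \item unaffected gene g: `y = mu_g + gamma_g * I + N(0, gene_noise_sd^2)`,
#'     `gamma_g != 0` only for disease-program (confounded) genes, with
#'     random sign;
#'   \item truly affected pair (i, g):
#'     `y = mu_g - beta_ig * h(x_i - mu_i) + N(0, gene_noise_sd^2)` with
#'     `h` the coupling shape (exponential, saturating or linear).
#' }
#' All draws come from one seeded generator; the caller's RNG state is
#' untouched.
#'
#' @param params A [sim_params()] object.
#' @return List of class `SimulatedStudy` with elements `mirna_expr`,
#'   `gene_expr` ([ExpressionMatrix]s sharing samples/groups), `target_map`
#'   ([TargetMap]), `truth_pairs` (data.frame `mirna_id`, `gene_id`,
#'   `beta`), `truth_mirnas` (character), `de_truth` (data.frame `feature_id`,
#'   `type`, `true_effect`), `params`.
#' @export
simulate_study <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(params$seed)

  n <- params$n_per_group
  samples <- sprintf("S%02d", seq_len(2L * n))
  groups <- rep(c("group1", "group2"), each = n)
  names(groups) <- samples
  I2 <- rep(c(0, 1), each = n)
  mirnas <- sprintf("miR-%03d", seq_len(params$n_mirnas))
  genes <- sprintf("gene-%04d", seq_len(params$n_genes))

  ## miRNA layer
  n_de <- round(params$frac_de_mirnas * params$n_mirnas)
  de_idx <- sort(sample.int(params$n_mirnas, n_de))
  delta <- numeric(params$n_mirnas)
  delta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
    runif_range(n_de, params$mirna_effect_range)
  mu_m <- runif_range(params$n_mirnas, params$baseline_mean_range)
  X <- mu_m + outer(delta, I2) +
    matrix(scaled_noise(params$n_mirnas * 2L * n, params$mirna_noise_sd,
                        params$mirna_noise_df), params$n_mirnas)
  dimnames(X) <- list(mirnas, samples)

  ## target map
  tgt <- lapply(seq_len(params$n_mirnas), function(i)
    sample(genes, params$targets_per_mirna))
  target_map <- TargetMap(rep(mirnas, each = params$targets_per_mirna),
                          unlist(tgt))

  ## ground-truth assignment: affected targets of influential DE-miRNAs;
  ## a gene is claimed by at most one miRNA so each affected gene has a
  ## single coupling partner
  n_aff <- round(params$frac_affected_targets * params$targets_per_mirna)
  n_infl <- round(params$frac_influential_mirnas * n_de)
  infl_idx <- if (n_infl > 0L) sort(sample(de_idx, n_infl)) else integer()
  claimed <- character()
  truth <- list()
  for (i in infl_idx) {
    free <- setdiff(tgt[[i]], claimed)
    aff <- sample(free, min(n_aff, length(free)))
    claimed <- c(claimed, aff)
    if (length(aff))
      truth[[length(truth) + 1L]] <- data.frame(
        mirna_id = mirnas[i], gene_id = aff,
        beta = runif_range(length(aff), params$coupling_range),
        stringsAsFactors = FALSE)
  }
  truth_pairs <- if (length(truth)) do.call(rbind, truth)
    else data.frame(mirna_id = character(), gene_id = character(),
                    beta = numeric(), stringsAsFactors = FALSE)
  ## targeted confounders: mild anti-mimicking group effects on unaffected
  ## targets of each DE-miRNA
  conf <- list()
  for (i in de_idx) {
    free <- setdiff(tgt[[i]], claimed)
    n_conf <- round(params$confound_frac * length(free))
    cf <- sample(free, min(n_conf, length(free)))
    claimed <- c(claimed, cf)
    if (length(cf))
      conf[[length(conf) + 1L]] <- data.frame(
        gene_id = cf,
        gamma = -sign(delta[i]) * runif_range(length(cf),
                                              params$confound_effect_range),
        mirna_idx = i, stringsAsFactors = FALSE)
  }
  ## miRNA-independent disease program: strong random-signed group effects
  ## on a fraction of all remaining genes, targets and non-targets alike
  pool <- setdiff(genes, claimed)
  n_prog <- round(params$program_frac * params$n_genes)
  pg <- sample(pool, min(n_prog, length(pool)))
  conf_targeted <- if (length(conf)) do.call(rbind, conf)
    else data.frame(gene_id = character(), gamma = numeric(),
                    mirna_idx = integer(), stringsAsFactors = FALSE)
  confounded <- rbind(
    conf_targeted[, c("gene_id", "gamma")],
    data.frame(gene_id = pg,
               gamma = sample(c(-1, 1), length(pg), replace = TRUE) *
                 runif_range(length(pg), params$program_effect_range),
               stringsAsFactors = FALSE))

  ## gene layer
  mu_g <- runif_range(params$n_genes, params$baseline_mean_range)
  names(mu_g) <- genes
  gamma <- numeric(params$n_genes)
  names(gamma) <- genes
  gamma[confounded$gene_id] <- confounded$gamma
  Y <- mu_g + outer(gamma, I2) +
    matrix(gene_noise(params$n_genes * 2L * n, params), params$n_genes)
  dimnames(Y) <- list(genes, samples)
  h <- switch(params$coupling,
              linear = identity,
              exponential = function(u) (2^u - 1) / log(2),
              saturating = function(u)
                params$sat_scale * tanh(u / params$sat_scale),
              rank = function(u)
                sqrt(12) * stats::sd(u) *
                  (rank(u, ties.method = "average") / (length(u) + 1) - 0.5))
  if (nrow(truth_pairs)) {
    mi <- match(truth_pairs$mirna_id, mirnas)
    gi <- match(truth_pairs$gene_id, genes)
    centered <- X[mi, , drop = FALSE] - mu_m[mi]
    dose <- t(apply(centered, 1L, h))
    Y[gi, ] <- mu_g[gi] - truth_pairs$beta * dose +
      matrix(gene_noise(length(gi) * 2L * n, params), length(gi))
  }

  ## within-group co-fluctuation of targeted confounders with their miRNA:
  ## shared upstream regulation, not miRNA-mediated repression
  w_rho <- params$confound_within_rho
  if (w_rho > 0 && nrow(conf_targeted)) {
    gi <- match(conf_targeted$gene_id, genes)
    mi <- conf_targeted$mirna_idx
    Xw <- X[mi, , drop = FALSE]
    for (lev in unique(groups)) {
      j <- which(groups == lev)
      Xw[, j] <- Xw[, j, drop = FALSE] - rowMeans(Xw[, j, drop = FALSE])
    }
    sx <- sqrt(rowSums(Xw^2) / (ncol(Xw) - 2L))
    w <- w_rho * params$gene_noise_sd / (pmax(sx, 1e-8) * sqrt(1 - w_rho^2))
    Y[gi, ] <- Y[gi, ] - w * Xw
  }

  de_truth <- rbind(
    data.frame(feature_id = mirnas, type = "mirna", true_effect = delta,
               stringsAsFactors = FALSE),
    data.frame(feature_id = genes, type = "gene",
               true_effect = ifelse(
                 genes %in% truth_pairs$gene_id,
                 -truth_pairs$beta[match(genes, truth_pairs$gene_id)] *
                   delta[match(truth_pairs$mirna_id[
                     match(genes, truth_pairs$gene_id)], mirnas)],
                 gamma),
               stringsAsFactors = FALSE))

  structure(list(
    mirna_expr = ExpressionMatrix(X, groups),
    gene_expr = ExpressionMatrix(Y, groups),
    groups = groups,
    target_map = target_map,
    truth_pairs = truth_pairs,
    truth_mirnas = unique(truth_pairs$mirna_id),
    de_truth = de_truth,
    params = params), class = "SimulatedStudy")
}

#' @export
print.SimulatedStudy <- function(x, ...) {
  cat(sprintf(
    "SimulatedStudy: %d miRNAs x %d genes, %d+%d samples; %d DE-miRNAs, %d affected pairs\n",
    nrow(x$mirna_expr$values), nrow(x$gene_expr$values),
    x$params$n_per_group, x$params$n_per_group,
    length(x$truth_mirnas), nrow(x$truth_pairs)))
  invisible(x)
}

#' Welch t-test differential expression per feature
#'
#' Two-sided Welch (unequal-variance) t-test per feature between the two
#' groups, with `log2fc = mean(group2) - mean(group1)` and BH-adjusted
#' p-values. This is the benchmark's internal DE step; real analyses would
#' normally supply limma/DESeq2 results via [read_de_table()].
#'
#' @param expr An [ExpressionMatrix] with two groups.
#' @return A [DETable] in feature order.
#' @export
welch_de <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  g <- expr$groups
  if (nlevels(g) != 2L) ml_stop_value("exactly two groups required")
  M <- expr$values
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(M[, i1, drop = FALSE]); m2 <- rowMeans(M[, i2, drop = FALSE])
  v1 <- rowSums((M[, i1, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((M[, i2, drop = FALSE] - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  degenerate <- se2 < 1e-24
  tt[degenerate] <- 0; df[degenerate] <- n1 + n2 - 2L
  p <- 2 * stats::pt(-abs(tt), df)
  DETable(rownames(M), log2fc = m2 - m1, pvalue = p, padj = bh_adjust(p))
}

#' Split a paired study into disjoint miRNA and mRNA cohorts
#'
#' Emulates an unpaired design: samples are partitioned into two disjoint
#' halves preserving group balance; the miRNA matrix is restricted to one
#' half and the gene matrix to the other.
#'
#' @param study A [simulate_study()] result with even `n_per_group`.
#' @param seed Integer seed for the split.
#' @return List with `mirna_expr` and `gene_expr` ([ExpressionMatrix]s on
#'   disjoint samples).
#' @export
split_unpaired <- function(study, seed = 1L) {
  stopifnot(inherits(study, "SimulatedStudy"))
  n <- study$params$n_per_group
  if (n %% 2L != 0L)
    ml_stop_value("n_per_group must be even for an unpaired split (got %d)", n)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  g <- study$groups
  half1 <- unlist(lapply(unique(g), function(lev) {
    s <- names(g)[g == lev]
    sort(sample(s, length(s) %/% 2L))
  }))
  half2 <- setdiff(names(g), half1)
  list(
    mirna_expr = ExpressionMatrix(
      study$mirna_expr$values[, half1, drop = FALSE], g[half1]),
    gene_expr = ExpressionMatrix(
      study$gene_expr$values[, half2, drop = FALSE], g[half2]))
}

#' Write a simulated study to TSV files
#'
#' Emits `mirna_expr.tsv`, `gene_expr.tsv`, `groups.tsv`, `targets.tsv`,
#' `truth_pairs.tsv` and `truth_mirnas.tsv` in the package's TSV formats.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "SimulatedStudy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    d <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wm(study$mirna_expr$values, "mirna_expr.tsv")
  wm(study$gene_expr$values, "gene_expr.tsv")
  utils::write.table(
    data.frame(sample_id = names(study$groups), group = study$groups),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$target_map, file.path(dir, "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth_pairs, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(mirna_id = study$truth_mirnas),
    file.path(dir, "truth_mirnas.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
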
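test_that("rank_midtie assigns mid-ranks and conserves the rank sum", {
  expect_identical(rank_midtie(c(3, 1, 2)), c(3, 1, 2))
  expect_identical(rank_midtie(c(5, 5, 1)), c(2.5, 2.5, 1))
  set.seed(1)
  for (i in 1:20) {
    x <- sample(round(rnorm(6), 1), 6, replace = TRUE)
    expect_equal(sum(rank_midtie(x)), 21)
  }
  expect_error(rank_midtie(numeric()), class = "mirlink_value_error")
})

test_that("residualize matches the normal-equations oracle and centers", {
  set.seed(7)
  y <- rnorm(12)
  expect_equal(residualize(y, matrix(1, 12, 1)), y - mean(y))
  g <- rep(0:1, each = 6)
  X <- cbind(1, g)
  expect_equal(residualize(3 - 2 * g, X), rep(0, 12), tolerance = 1e-12)
  r <- residualize(y, X)
  expect_equal(r, residual_oracle(y, X), tolerance = 1e-10)
  expect_lt(max(abs(t(X) %*% r)), 1e-8 * sqrt(sum(y^2)))
  expect_error(residualize(y, cbind(1, g, g)), class = "mirlink_value_error")
})

test_that("correlate matches direct-formula oracle and handles boundaries", {
  r <- correlate(c(1, 2, 3, 4), c(4, 3, 2, 1), method = "spearman")
  expect_equal(r$rho, -1)
  expect_lt(r$pvalue, 1e-6)

  set.seed(11)
  x <- rnorm(10); y <- rnorm(10)
  got <- correlate(x, y, "pearson")
  ora <- pearson_oracle(x, y)
  expect_equal(got$rho, ora$rho, tolerance = 1e-12)
  expect_equal(got$pvalue, ora$pvalue, tolerance = 1e-12)

  same <- correlate(x, y, "partial_pearson", groups = rep("A", 10))
  expect_equal(same$rho, got$rho, tolerance = 1e-14)

  expect_warning(cc <- correlate(rep(1, 8), rnorm(8), "pearson"), "constant")
  expect_true(is.na(cc$rho))
  expect_equal(cc$pvalue, 1)
})

test_that("spearman = pearson on mid-tie ranks; anti-symmetry holds", {
  set.seed(3)
  for (i in 1:25) {
    x <- sample(round(rnorm(15), 1)); y <- round(rnorm(15), 1)
    a <- correlate(x, y, "spearman")
    b <- correlate(rank_midtie(x), rank_midtie(y), "pearson")
    expect_equal(a$rho, b$rho, tolerance = 1e-12)
    neg <- correlate(x, -y, "spearman")
    expect_equal(neg$rho, -a$rho, tolerance = 1e-12)
  }
  g <- rep(c("a", "b"), c(7, 8))
  x <- rnorm(15); y <- rnorm(15)
  ps <- correlate(x, y, "partial_spearman", groups = g)
  man <- correlate(residualize(rank_midtie(x), cbind(1, g == "b")),
                   residualize(rank_midtie(y), cbind(1, g == "b")),
                   "pearson")
  expect_equal(ps$rho, man$rho, tolerance = 1e-12)
  expect_identical(ps$df, 15L - 3L)
})

test_that("vectorized pair engine equals scalar correlate", {
  set.seed(5)
  Xm <- matrix(rnorm(5 * 12), 5, 12,
               dimnames = list(sprintf("m%d", 1:5), sprintf("s%d", 1:12)))
  Xg <- matrix(rnorm(7 * 12), 7, 12,
               dimnames = list(sprintf("g%d", 1:7), sprintf("s%d", 1:12)))
  groups <- factor(rep(c("A", "B"), each = 6))
  mi <- c(1L, 3L, 5L); gi <- c(2L, 7L, 4L)
  for (m in c("pearson", "spearman", "partial_pearson", "partial_spearman")) {
    vec <- mirlink:::pair_correlations(Xm, Xg, mi, gi, m, groups)
    for (k in seq_along(mi)) {
      sc <- correlate(Xm[mi[k], ], Xg[gi[k], ], m, groups = groups)
      expect_equal(vec$rho[k], sc$rho, tolerance = 1e-12)
      expect_equal(vec$pvalue[k], sc$pvalue, tolerance = 1e-12)
    }
  }
})

test_that("integrate_paired applies the call rule over candidate pairs", {
  em <- make_expr(rbind(c(1, 2, 3, 4, 5, 6)), 3, "m1")
  gex <- make_expr(rbind(6:1, c(2, 1, 4, 3, 6, 5)), 3, c("g1", "g2"))
  tm <- TargetMap(c("m1", "m1"), c("g1", "g2"))
  de_m <- DETable("m1", 1, 0.001, 0.01)
  de_g <- DETable(c("g1", "g2"), c(-1, 1), c(0.001, 0.2), c(0.01, 0.3))

  res <- integrate_paired(em, gex, tm, de_m, de_g, method = "pearson",
                          alpha = 0.1)
  expect_identical(nrow(res), 2L)                # both genes in de_g
  expect_identical(res$gene_id, c("g1", "g2"))   # lexicographic order
  expect_equal(res$rho[1], -1)
  expect_true(res$call[1])

  empty <- integrate_paired(em, gex, TargetMap(character(), character()),
                            de_m, de_g)
  expect_identical(nrow(empty), 0L)

  g2 <- make_expr(rbind(6:1), 3, "g1")
  colnames(g2$values) <- sprintf("t%02d", 1:6)
  expect_error(integrate_paired(em, g2, tm, de_m, de_g),
               class = "mirlink_consistency_error")
})

test_that("saturated simulated effects are fully recovered in paired mode", {
  params <- tiny_params(coupling = "linear", coupling_range = c(1.5, 1.5),
                        gene_noise_sd = 0.3, gene_noise_df = Inf,
                        mirna_noise_df = Inf, n_per_group = 20L,
                        frac_influential_mirnas = 1, confound_frac = 0,
                        program_frac = 0, seed = 42L)
  st <- simulate_study(params)
  de_m <- welch_de(st$mirna_expr); de_g <- welch_de(st$gene_expr)
  res <- integrate_paired(st$mirna_expr, st$gene_expr, st$target_map,
                          de_m[de_m$padj < 0.05, ], de_g[de_g$padj < 0.05, ],
                          method = "partial_spearman")
  key <- paste(st$truth_pairs$mirna_id, st$truth_pairs$gene_id)
  truth <- paste(res$mirna_id, res$gene_id) %in% key
  expect_true(all(res$call[truth]))
  expect_false(any(res$call[!truth]))
})
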
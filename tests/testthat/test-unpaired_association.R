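test_that("build_contingency counts the anti-directional overlap", {
  de_g <- DETable(sprintf("G%d", 1:5),
                  log2fc = c(-2, 1, -1, 0.5, -0.2),
                  pvalue = c(0.001, 0.2, 0.3, 0.6, 0.01),
                  padj = c(0.01, 0.4, 0.5, 0.8, 0.04))
  tm <- TargetMap(c("m1", "m1"), c("G1", "G2"))
  mir <- DETable("m1", 2, 0.001, 0.01)
  tab <- build_contingency(mir[1, ], tm, de_g, sprintf("G%d", 1:5))
  ## D = down DEGs = {G1, G5}; targets {G1, G2} -> a=1 b=1 c=1 d=2
  expect_identical(c(tab$a, tab$b, tab$c, tab$d), c(1L, 1L, 1L, 2L))
  expect_identical(tab$direction_tested, -1)
  expect_true(tab$testable)

  none <- build_contingency(mir[1, ], TargetMap("m2", "G1"), de_g,
                            sprintf("G%d", 1:5))
  expect_identical(none$a + none$b, 0L)
  expect_false(none$testable)

  flat <- DETable("m1", 0, 0.5, 0.5)
  expect_warning(out <- build_contingency(flat[1, ], tm, de_g,
                                          sprintf("G%d", 1:5)), "direction 0")
  expect_null(out)
  expect_error(build_contingency(mir[1, ], tm, de_g, character()),
               class = "mirlink_value_error")
})

test_that("randomized contingency tables match a set-operation oracle", {
  set.seed(19)
  for (i in 1:10) {
    genes <- sprintf("g%02d", 1:20)
    tm <- TargetMap(rep("m", 6), sample(genes, 6))
    lfc <- rnorm(20); padj <- runif(20)
    de_g <- DETable(genes, lfc, padj, padj)
    mir <- DETable("m", sample(c(-1, 1), 1) * runif(1, 0.5, 2), 0.01, 0.01)
    tab <- build_contingency(mir[1, ], tm, de_g, genes, deg_alpha = 0.3)
    D <- genes[padj < 0.3 & sign(lfc) == -sign(mir$log2fc)]
    tg <- tm$gene_id
    expect_identical(tab$a, length(intersect(tg, D)))
    expect_identical(tab$b, length(setdiff(tg, D)))
    expect_identical(tab$c, length(setdiff(D, tg)))
    expect_identical(tab$d, 20L - tab$a - tab$b - tab$c)
  }
})

test_that("fisher and mid-P match hypergeometric enumeration on hand cases", {
  expect_equal(fisher_one_sided(c(3, 1, 1, 5)), 25 / 210, tolerance = 1e-12)
  expect_equal(fisher_midp(c(3, 1, 1, 5)), 13 / 210, tolerance = 1e-12)
  expect_equal(fisher_one_sided(c(0, 4, 3, 5)), 1)
  ## maximal a: tail is the single most extreme term
  expect_equal(fisher_one_sided(c(4, 0, 0, 6)), fisher_oracle(4, 0, 0, 6),
               tolerance = 1e-12)
  ## degenerate margin: the observed table is a point mass
  expect_equal(fisher_midp(c(0, 0, 3, 4)), 0.5)
})

test_that("boschloo matches the brute-force oracle and known edge cases", {
  expect_equal(boschloo(c(3, 1, 1, 5)), boschloo_oracle(3, 1, 1, 5),
               tolerance = 1e-10)
  expect_equal(boschloo(c(0, 3, 2, 4)), 1)
  expect_equal(boschloo(c(0, 0, 2, 4)), 1)
  set.seed(23)
  for (i in 1:25) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    a <- sample(0:n1, 1); cc <- sample(0:n2, 1)
    t <- c(a, n1 - a, cc, n2 - cc)
    p <- boschloo(t, grid_size = 201L)
    expect_equal(p, boschloo_oracle(t[1], t[2], t[3], t[4], grid_size = 201L),
                 tolerance = 1e-10)
    expect_lte(p, fisher_one_sided(t) + 1e-12)
  }
})

test_that("p-values are monotone in the table's enrichment", {
  set.seed(29)
  for (i in 1:10) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    a <- sample(0:(n1 - 1), 1); cc <- sample(1:n2, 1)
    worse <- c(a, n1 - a, cc, n2 - cc)
    better <- c(a + 1, n1 - a - 1, cc - 1, n2 - cc + 1)  # margins fixed
    for (f in list(fisher_one_sided, fisher_midp, boschloo))
      expect_lte(f(better), f(worse) + 1e-12)
  }
})

test_that("integrate_unpaired flags untestable miRNAs and applies the rule", {
  genes <- sprintf("g%02d", 1:40)
  empty <- integrate_unpaired(DETable(character(), numeric(), numeric(),
                                      numeric()),
                              DETable(genes, rnorm(40), runif(40), runif(40)),
                              TargetMap("m", "g01"), genes)
  expect_identical(nrow(empty), 0L)

  ## one miRNA whose targets are exactly the down-regulated DEGs
  lfc <- c(rep(-2, 8), rep(0.1, 32))
  padj <- c(rep(0.001, 8), rep(0.9, 32))
  de_g <- DETable(genes, lfc, padj, padj)
  tm <- TargetMap(rep(c("mUp", "mNoTargets"), c(8, 1)),
                  c(genes[1:8], "not_measured"))
  de_m <- DETable(c("mUp", "mNoTargets"), c(1.5, 2), c(0.01, 0.01),
                  c(0.02, 0.02))
  res <- integrate_unpaired(de_m, de_g, tm, genes, method = "fisher")
  expect_identical(res$testable, c(TRUE, FALSE))
  expect_true(res$call[1])
  expect_true(is.na(res$padj[2]))          # excluded from multiplicity
  expect_lt(res$pvalue[1], 1e-6)

  expect_error(integrate_unpaired(de_m, de_g, tm, genes, method = "nope"))
})

test_that("simulated unpaired integration reproduces a frozen call set", {
  params <- tiny_params(n_per_group = 10L, frac_influential_mirnas = 1,
                        mirna_effect_range = c(2, 3),
                        coupling_range = c(2, 3), program_frac = 0.2,
                        confound_frac = 0, gene_noise_sd = 0.4, seed = 101L)
  st <- simulate_study(params)
  ch <- split_unpaired(st, seed = 101L)
  de_m <- welch_de(ch$mirna_expr)
  de_m <- de_m[de_m$padj < 0.05 & de_m$direction != 0, ]
  res <- integrate_unpaired(de_m, welch_de(ch$gene_expr), st$target_map,
                            feature_ids(ch$gene_expr), method = "boschloo")
  ## frozen from the reference run of this exact configuration
  expect_identical(sort(res$mirna_id[res$call]), FROZEN_UNPAIRED_CALLS)
})
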
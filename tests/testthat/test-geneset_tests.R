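test_that("gene_contrast_stats matches the pooled-t oracle", {
  set.seed(31)
  M <- rbind(flat = rep(1, 20),
             shift = c(rnorm(10, 0, 0.1), rnorm(10, 1, 0.1)),
             noise = rnorm(20))
  Y <- make_expr(M, 10, rownames(M))
  expect_warning(gs <- gene_contrast_stats(Y), "zero residual variance")
  expect_equal(gs$t[1], 0)
  expect_equal(gs$z[1], 0)
  expect_identical(unique(gs$df), 18L)

  ## textbook pooled t by explicit sums for the shifted gene
  x1 <- M["shift", 1:10]; x2 <- M["shift", 11:20]
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 18
  t_ora <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  expect_equal(gs$t[2], t_ora, tolerance = 1e-12)

  perm <- sample(20)
  Yp <- ExpressionMatrix(Y$values[, perm], Y$groups[perm])
  expect_warning(gsp <- gene_contrast_stats(Yp), "zero residual")
  expect_equal(gsp$t, gs$t, tolerance = 1e-12)
})

test_that("rotation test is deterministic, powered, and validates inputs", {
  set.seed(37)
  M <- matrix(rnorm(40 * 20), 40, 20)
  M[1:10, 11:20] <- M[1:10, 11:20] - 2       # set genes shifted down in g2
  Y <- make_expr(M, 10)
  set_ids <- sprintf("f%02d", 1:10)
  r1 <- rotation_set_test(Y, set_ids, direction = -1, B = 999, seed = 5)
  r2 <- rotation_set_test(Y, set_ids, direction = -1, B = 999, seed = 5)
  expect_identical(r1$pvalue, r2$pvalue)
  expect_lte(r1$pvalue, 0.001)
  r3 <- rotation_set_test(Y, set_ids, direction = -1, B = 999, seed = 6)
  expect_lt(abs(r3$pvalue - r1$pvalue), 0.01)

  expect_error(rotation_set_test(Y, set_ids, direction = -1, B = 50),
               class = "mirlink_value_error")
  miss <- rotation_set_test(Y, "absent_gene", direction = 1, B = 999)
  expect_false(miss$testable)
})

test_that("rotation null p-values are uniform, also under correlation", {
  set.seed(41)
  ps <- replicate(400, {
    M <- matrix(rnorm(25 * 10), 25, 10)
    Y <- make_expr(M, 5)
    rotation_set_test(Y, sprintf("f%02d", 1:8), direction = 1, B = 199)$pvalue
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif")$statistic), 0.08)

  ## shared rotations preserve inter-gene correlation: injected rho = 0.3
  ## must not inflate type-I error beyond nominal + 3 * MC error
  set.seed(43)
  ps_corr <- replicate(400, {
    shared <- rnorm(10)
    M <- matrix(rnorm(25 * 10), 25, 10)
    M[1:8, ] <- sqrt(0.7) * M[1:8, ] + sqrt(0.3) * rep(shared, each = 8)
    Y <- make_expr(M, 5)
    rotation_set_test(Y, sprintf("f%02d", 1:8), direction = 1, B = 199)$pvalue
  })
  mc <- sqrt(0.05 * 0.95 / 400)
  expect_lte(mean(ps_corr < 0.05), 0.05 + 3 * mc)
})

test_that("camera test centers under the null and responds to VIF", {
  set.seed(47)
  mean_p <- mean(replicate(400, {
    z <- rnorm(60)
    st <- data.frame(gene_id = sprintf("g%02d", 1:60), t = z, df = 18, z = z)
    camera_test(st, sprintf("g%02d", 1:12), direction = 1)$pvalue
  }))
  expect_lt(abs(mean_p - 0.5), 0.05)

  st <- data.frame(gene_id = sprintf("g%02d", 1:50),
                   t = c(rep(3, 10), rep(0, 40)), df = 18,
                   z = c(rep(3, 10), rep(0, 40)))
  strong <- camera_test(st, sprintf("g%02d", 1:10), direction = 1)
  expect_lt(strong$pvalue, 1e-4)
  infl <- camera_test(st, sprintf("g%02d", 1:10), direction = 1,
                      residual_corr = 0.2)
  expect_gt(infl$pvalue, strong$pvalue)
  expect_error(camera_test(st, st$gene_id, direction = 1),
               class = "mirlink_value_error")
})

test_that("estimate_setcorr truncates to [0, 1) and detects independence", {
  set.seed(53)
  M <- matrix(rnorm(20 * 40), 20, 40)
  Y <- make_expr(M, 20)
  expect_lt(abs(estimate_setcorr(Y, sprintf("f%02d", 1:20))), 0.05)

  dup <- make_expr(rbind(M[1, ], M[1, ]), 20, c("a", "b"))
  expect_gt(estimate_setcorr(dup, c("a", "b")), 0.99)
  expect_lt(estimate_setcorr(dup, c("a", "b")), 1)

  anti <- make_expr(rbind(M[1, ], -M[1, ]), 20, c("a", "b"))
  expect_identical(estimate_setcorr(anti, c("a", "b")), 0)
})
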
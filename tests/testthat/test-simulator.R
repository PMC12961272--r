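test_that("study construction follows the deterministic count arithmetic", {
  p <- sim_params(seed = 7L)
  st <- simulate_study(p)
  n_de <- round(p$frac_de_mirnas * p$n_mirnas)
  n_infl <- round(p$frac_influential_mirnas * n_de)
  n_aff <- round(p$frac_affected_targets * p$targets_per_mirna)
  expect_equal(length(st$truth_mirnas), n_infl)
  expect_equal(nrow(st$truth_pairs), n_infl * n_aff)
  ## invariants: truth pairs live in the target map; matrices share samples
  key <- paste(st$target_map$mirna_id, st$target_map$gene_id)
  expect_true(all(paste(st$truth_pairs$mirna_id, st$truth_pairs$gene_id)
                  %in% key))
  expect_identical(sample_ids(st$mirna_expr), sample_ids(st$gene_expr))
  ## bit-identical under the same seed, different under another
  st2 <- simulate_study(p)
  expect_identical(st$gene_expr$values, st2$gene_expr$values)
  p2 <- p; p2$seed <- 8L
  expect_false(identical(simulate_study(p2)$gene_expr$values,
                         st$gene_expr$values))
})

test_that("no-signal and noiseless limits behave as stated", {
  null <- simulate_study(sim_params(frac_de_mirnas = 0, n_mirnas = 30L,
                                    n_genes = 200L, targets_per_mirna = 5L,
                                    seed = 1L))
  expect_identical(nrow(null$truth_pairs), 0L)
  expect_identical(length(null$truth_mirnas), 0L)

  clean <- simulate_study(sim_params(
    n_mirnas = 10L, n_genes = 100L, targets_per_mirna = 5L,
    coupling = "linear", coupling_range = c(1, 1), gene_noise_sd = 0,
    frac_influential_mirnas = 1, confound_frac = 0, program_frac = 0,
    seed = 3L))
  pr <- clean$truth_pairs[1, ]
  x <- clean$mirna_expr$values[pr$mirna_id, ]
  y <- clean$gene_expr$values[pr$gene_id, ]
  expect_lt(abs(cor(x, y) - (-1)), 1e-6)

  expect_error(sim_params(targets_per_mirna = 50, n_genes = 40),
               class = "mirlink_value_error")
})

test_that("welch_de is calibrated, powered, and sign-consistent", {
  set.seed(79)
  ## 2000 null features in one matrix stand in for repeated simulations
  Y0 <- make_expr(matrix(rnorm(2000 * 20), 2000, 20), 10,
                  sprintf("n%04d", 1:2000))
  de0 <- welch_de(Y0)
  expect_lt(suppressWarnings(ks.test(de0$pvalue, "punif")$statistic), 0.05)

  Yd <- make_expr(cbind(matrix(rnorm(500 * 10, 0, 0.5), 500, 10),
                        matrix(rnorm(500 * 10, 2, 0.5), 500, 10)), 10,
                  sprintf("d%03d", 1:500))
  ded <- welch_de(Yd)
  expect_gte(mean(ded$pvalue < 0.01), 0.99)
  expect_gte(mean(ded$direction == 1), 0.99)
  expect_equal(mean(ded$log2fc), 2, tolerance = 0.1)
})

test_that("DE-miRNA group-mean difference recovers the injected effect", {
  p <- sim_params(n_per_group = 50L, n_mirnas = 40L, n_genes = 100L,
                  targets_per_mirna = 5L, seed = 13L)
  st <- simulate_study(p)
  de <- welch_de(st$mirna_expr)
  truth <- st$de_truth[st$de_truth$type == "mirna", ]
  idx <- which(truth$true_effect != 0)
  err <- de$log2fc[idx] - truth$true_effect[idx]
  se <- p$mirna_noise_sd * sqrt(2 / p$n_per_group)
  expect_lt(abs(mean(err)), 3 * se / sqrt(length(idx)))
})

test_that("split_unpaired partitions samples with balance and determinism", {
  st <- simulate_study(tiny_params(seed = 17L))
  ch <- split_unpaired(st, seed = 2L)
  s1 <- sample_ids(ch$mirna_expr); s2 <- sample_ids(ch$gene_expr)
  expect_length(s1, 10); expect_length(s2, 10)
  expect_length(intersect(s1, s2), 0)
  expect_setequal(c(s1, s2), sample_ids(st$mirna_expr))
  expect_identical(as.integer(table(ch$mirna_expr$groups)), c(5L, 5L))
  ch2 <- split_unpaired(st, seed = 2L)
  expect_identical(sample_ids(ch2$mirna_expr), s1)

  odd <- simulate_study(tiny_params(n_per_group = 5L, seed = 17L))
  expect_error(split_unpaired(odd), class = "mirlink_value_error")
})

test_that("write_study emits readable TSVs that round-trip", {
  st <- simulate_study(tiny_params(seed = 19L))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  em <- read_expression_matrix(file.path(dir, "mirna_expr.tsv"),
                               file.path(dir, "groups.tsv"))
  expect_equal(dim(em$values), dim(st$mirna_expr$values))
  tm <- read_target_map(file.path(dir, "targets.tsv"))
  expect_identical(nrow(tm), nrow(st$target_map))
})
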
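test_that("ground-truth networks honor density, hubs and determinism", {
  tru <- generate_ground_truth_network(50, density = 0.04, n_hubs = 2, seed = 7)
  m <- round(0.04 * 50 * 49)
  expect_lte(abs(sum(tru$W_true != 0) - m), 1)
  tru2 <- generate_ground_truth_network(50, density = 0.04, n_hubs = 2, seed = 7)
  expect_identical(tru$W_true, tru2$W_true)

  outdeg <- colSums(tru$W_true != 0)
  expect_true(all(outdeg[tru$hub_ids] > median(outdeg)))

  # nonzero magnitudes within +-[0.5, 1] * weight_scale
  w <- tru$W_true[tru$W_true != 0]
  expect_true(all(abs(w) >= 0.5 * 2 & abs(w) <= 2))

  empty <- generate_ground_truth_network(10, density = 0, n_hubs = 0, seed = 1)
  expect_true(all(empty$W_true == 0))

  expect_error(generate_ground_truth_network(10, density = 0.01, n_hubs = 3,
                                             seed = 1),
               "hub")
})

test_that("simulated datasets are deterministic with noise applied per replicate", {
  tru <- generate_ground_truth_network(10, density = 0.15, n_hubs = 1, seed = 3)

  ds0 <- simulate_dataset(tru, replicates = 3, noise_sd = 0,
                          n_null_genes = 5, seed = 5)
  v <- ds0$expression$values
  tp <- ds0$expression$design$time_hours
  for (t in unique(tp))   # zero noise: replicate columns identical
    expect_true(all(v[, tp == t] == v[, which(tp == t)[1]]))

  ds1 <- simulate_dataset(tru, replicates = 3, noise_sd = 0.1,
                          n_null_genes = 5, seed = 5)
  ds1b <- simulate_dataset(tru, replicates = 3, noise_sd = 0.1,
                           n_null_genes = 5, seed = 5)
  expect_identical(ds1$expression$values, ds1b$expression$values)
  expect_setequal(c(ds1$de_gene_ids, ds1$null_gene_ids),
                  gene_ids(ds1$expression))

  expect_error(simulate_dataset(tru, noise_sd = -1, seed = 1), "noise_sd")
})

test_that("replicate means concentrate on the noise-free trajectory (CLT bound)", {
  tru <- generate_ground_truth_network(10, density = 0.15, n_hubs = 1, seed = 3)
  ds <- simulate_dataset(tru, replicates = 50, noise_sd = 0.1,
                         n_null_genes = 0, seed = 11)
  tp <- ds$expression$design$time_hours
  times <- sort(unique(tp))
  devs <- vapply(times, function(t)
    abs(rowMeans(ds$expression$values[, tp == t, drop = FALSE]) -
          ds$trajectories[, as.character(t)]),
    numeric(10))
  expect_gte(mean(devs <= 3 * 0.1 / sqrt(50)), 0.99)
})

test_that("null genes have calibrated classical F-test p-values", {
  tru <- generate_ground_truth_network(5, density = 0.2, n_hubs = 0, seed = 2)
  ds <- simulate_dataset(tru, replicates = 3, noise_sd = 0.1,
                         n_null_genes = 1000, seed = 8)
  x <- ds$expression
  groups <- factor(x$design$time_hours)
  nulls <- ds$null_gene_ids
  p <- vapply(nulls, function(g) {
    summary(aov(x$values[g, ] ~ groups))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("annotation catalogs implement dropout exactly and reproducibly", {
  tru <- generate_ground_truth_network(20, density = 0.25, n_hubs = 2, seed = 4)
  ds <- simulate_dataset(tru, n_null_genes = 10, seed = 4)
  n_true <- sum(tru$W_true != 0)

  ann0 <- generate_annotations(ds, 10, 2, dropout = 0, seed = 6)
  expect_equal(nrow(ann0$catalog), n_true)

  ann1 <- generate_annotations(ds, 10, 2, dropout = 1, seed = 6)
  expect_equal(nrow(ann1$catalog), 0L)

  ann3 <- generate_annotations(ds, 10, 2, dropout = 0.3, seed = 6)
  ann3b <- generate_annotations(ds, 10, 2, dropout = 0.3, seed = 6)
  expect_identical(ann3$catalog, ann3b$catalog)
  # binomial(n_true, 0.7): within 4 sd of the mean
  expect_lt(abs(nrow(ann3$catalog) - 0.7 * n_true),
            4 * sqrt(n_true * 0.3 * 0.7) + 1)

  # catalog types reflect true weight signs
  W <- tru$W_true
  w <- W[cbind(match(ann3$catalog$target, tru$gene_ids),
               match(ann3$catalog$source, tru$gene_ids))]
  expect_true(all(ifelse(w > 0, "activation", "inhibition") ==
                    ann3$catalog$type))

  # planted categories are >= 80% network-driven genes
  for (id in ann3$enriched_ids) {
    members <- ann3$gene_sets$sets[[id]]
    expect_gte(mean(members %in% ds$de_gene_ids), 0.8)
  }
})

test_that("with vanishing noise the dataset converges to the integrator reference", {
  tru <- generate_ground_truth_network(8, density = 0.2, n_hubs = 1, seed = 9)
  ds <- simulate_dataset(tru, timepoints = seq(0, 4, by = 0.5), replicates = 2,
                         noise_sd = 0, n_null_genes = 0, seed = 10)
  tp <- ds$expression$design$time_hours
  means <- vapply(sort(unique(tp)), function(t)
    rowMeans(ds$expression$values[, tp == t, drop = FALSE]), numeric(8))
  expect_lt(max(abs(means - ds$trajectories)), 1e-8)
})
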
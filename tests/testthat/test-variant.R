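test_that("heteroplasmy is the wild-type share of all copies", {
  expect_equal(heteroplasmy(cbind(c(10, 10), c(1, 1))), 100 * 20 / 22)
  expect_equal(heteroplasmy(cbind(c(3, 7), c(0, 0))), 100)
  expect_error(heteroplasmy(cbind(c(0, 0), c(0, 0))), "no ecDNA")
  expect_error(heteroplasmy(matrix(1, 2, 1)), "two copy types")
})

test_that("no variant can appear without founder copies or a mutation size", {
  vc <- variant_config(kwt = 10, kvar = 0, vvar = 0, s_wt = 1, s_var = 2)
  st <- run_variant_sim(vc, sim_config(k = 0, s = 0, q = 5, n_final = 400,
                                       seed = 1), check = TRUE)
  expect_true(all(st$copies[, "variant"] == 0))
  wm <- run_variant_sim(vc, sim_config(k = 0, s = 0, n_final = 400,
                                       seed = 2), engine = "well_mixed")
  expect_true(all(wm$copies[, "variant"] == 0))
})

test_that("a vvar-triggered mutation converts exactly one wild-type copy", {
  vc <- variant_config(kwt = 20, kvar = 0, vvar = 300, s_wt = 1, s_var = 1)
  # stop the run at the mutation size: exactly one variant copy must exist
  st <- run_variant_sim(vc, sim_config(k = 0, s = 0, q = 5, n_final = 300,
                                       seed = 3), check = TRUE)
  expect_equal(sum(st$copies[, "variant"]), 1)
  expect_equal(st$variant_arrival_n, 300)
  # conversion, not creation: totals are what wt-only growth would carry
  expect_equal(sum(st$copies), sum(st$copies[, "wt"]) + 1)
  expect_error(
    run_variant_sim(variant_config(kwt = 5, vvar = 500),
                    sim_config(k = 0, s = 0, n_final = 100)),
    "never reached"
  )
})

test_that("pre-expansion variants reproduce the founder mixture", {
  vc <- variant_config(kwt = 20, kvar = 1, vvar = 0, s_wt = 1, s_var = 1)
  st <- run_variant_sim(vc, sim_config(k = 0, s = 0, q = 5, n_final = 500,
                                       seed = 4), check = TRUE)
  expect_equal(ncol(st$copies), 2L)
  expect_gt(sum(st$copies[, "variant"]), 0)
})

test_that("equal-selection heteroplasmy is a martingale", {
  vc <- variant_config(kwt = 20, kvar = 1, s_wt = 1, s_var = 1)
  cfg <- sim_config(k = 0, s = 0, n_final = 400)
  set.seed(5)
  het <- replicate(80, heteroplasmy(
    run_variant_sim(vc, cfg, engine = "well_mixed")))
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 100 * 20 / 21), 3 * se)
})

test_that("covariegation probability has the right degenerate limits", {
  cfg <- sim_config(k = 0, s = 0, q = 5, n_final = 400)
  # variant clonal at initiation with strong selection: always detected
  res <- covariegation_probability(
    variant_config(kwt = 10, kvar = 10, s_wt = 2, s_var = 2), cfg,
    n_sample = 150, replicates = 8, seed = 6)
  expect_equal(res$probability, 1)
  # no variant source at all: never detected
  res0 <- covariegation_probability(
    variant_config(kwt = 5, kvar = 0, s_wt = 1, s_var = 1), cfg,
    n_sample = 150, replicates = 5, seed = 7)
  expect_equal(res0$probability, 0)
})

test_that("mutation-origin runs respect the founder convention and enumeration", {
  # mu = 1: the founder always mutates, wild-type abundance is k - 1
  res <- mutation_origin_distribution(k = 7, s = 1, mu = 1, n_final = 50,
                                      replicates = 50, seed = 8)
  expect_true(all(res$values == 6))
  expect_equal(res$n_no_mutation, 0)
  # mu = 0: no mutation ever
  res0 <- mutation_origin_distribution(k = 7, s = 1, mu = 0, n_final = 50,
                                       replicates = 20, seed = 9)
  expect_length(res0$values, 0)
  expect_equal(res0$n_no_mutation, 20)
  # exact enumeration oracle: k = 1 stopped after the first division.
  # Mutation at initiation (prob mu) records 0; at the first division the
  # single new copy mutates with prob mu and the variant-receiving
  # daughter holds 0 or 1 wt copies with equal probability. Hence
  # P(record 0 | mutation) = (mu + (1 - mu) * mu / 2) / (mu + (1 - mu) * mu).
  mu <- 0.2
  p0 <- (mu + (1 - mu) * mu / 2) / (mu + (1 - mu) * mu)
  res1 <- mutation_origin_distribution(k = 1, s = 0, mu = mu, n_final = 2,
                                       replicates = 4000, seed = 10)
  expect_true(all(res1$values %in% 0:1))
  phat <- mean(res1$values == 0)
  se <- sqrt(p0 * (1 - p0) / length(res1$values))
  expect_lt(abs(phat - p0), 3 * se)
})

test_that("mean wild-type abundance at first mutation grows with k", {
  set.seed(11)
  m5 <- mean(mutation_origin_distribution(k = 5, s = 1, mu = 0.001,
                                          n_final = 300,
                                          replicates = 150)$values)
  m40 <- mean(mutation_origin_distribution(k = 40, s = 1, mu = 0.001,
                                           n_final = 300,
                                           replicates = 150)$values)
  expect_gt(m40, m5)
})
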
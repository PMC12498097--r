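test_that("a simulation matching the observation is accepted with sigma 0", {
  # homogeneous tumor: every sample has the same degenerate distribution,
  # so the simulated regions reproduce the observation exactly
  st <- disk_state(18)
  obs <- observed_patient_data(core = rep(5, 50), margins = rep(5, 50))
  sim_fixed <- function(k, s, q, settings) st
  post <- abc_rejection(
    obs, prior_grid(k = 5, s = 1, q = 5),
    abc_settings(budget = 2, margins_per_sim = 3, n_final = 100, seed = 1),
    simulator = sim_fixed
  )
  expect_equal(nrow(post), 2 * 3)
  expect_true(all(post$sigma == 0))
})

test_that("degenerate thresholds accept everything and return the prior", {
  sp <- generate_synthetic_patient(truth = list(k = 5, s = 1, q = 5),
                                   sizes = list(core = 60, margins = 60),
                                   n_final = 400, seed = 2)
  pri <- prior_grid(k = c(2, 5, 20), s = c(0, 1), q = c(5, 1000))
  st <- abc_settings(budget = 30, eps_region = 1e9, delta_fraction = 1,
                     margins_per_sim = 4, n_final = 400, seed = 3)
  post <- abc_rejection(sp$observed, pri, st)
  expect_equal(nrow(post), 30 * 4)
  expect_equal(attr(post, "acceptance_rate"), 1)
  # the accepted parameter marginals are exactly the prior draws
  per_sim <- unique(post[, c("sim", "k", "s", "q")])
  expect_equal(nrow(per_sim), 30)
  expect_true(all(per_sim$k %in% pri$k))
})

test_that("loosening the thresholds never removes an accepted pair", {
  sp <- generate_synthetic_patient(truth = list(k = 10, s = 1, q = 5),
                                   sizes = list(core = 80, margins = 80),
                                   n_final = 500, seed = 4)
  st_tight <- abc_settings(budget = 60, eps_region = 2, delta_fraction = 0.05,
                           margins_per_sim = 5, n_final = 500, seed = 5)
  st_loose <- abc_settings(budget = 60, eps_region = 6, delta_fraction = 0.2,
                           margins_per_sim = 5, n_final = 500, seed = 5)
  tight <- abc_rejection(sp$observed, prior_grid(k = c(5, 10, 20)), st_tight)
  loose <- abc_rejection(sp$observed, prior_grid(k = c(5, 10, 20)), st_loose)
  key <- function(p) paste(p$sim, p$pair)
  expect_true(all(key(tight) %in% key(loose)))
  expect_gte(nrow(loose), nrow(tight))
})

test_that("posterior summaries report mode and central 68% interval", {
  post <- structure(
    data.frame(k = 20L, s = 1, q = 5, sigma = 0.5, pair = 1L, sim = 1L,
               sim_seed = 1L),
    class = c("posterior_table", "data.frame")
  )
  ps <- posterior_summary(post)
  expect_equal(ps$mode, c(20, 1, 5))
  expect_equal(ps$lower, ps$mode)
  expect_equal(ps$upper, ps$mode)
  empty <- structure(data.frame(k = integer(0), s = numeric(0),
                                q = numeric(0)),
                     class = c("posterior_table", "data.frame"))
  expect_error(posterior_summary(empty), "no accepted")
})

test_that("an empty posterior still carries distance diagnostics", {
  obs <- observed_patient_data(core = rep(50, 40), margins = rep(50, 40))
  post <- abc_rejection(
    obs, prior_grid(k = 1, s = 0, q = 1000),
    abc_settings(budget = 4, eps_region = 0.01, delta_fraction = 0.01,
                 margins_per_sim = 2, n_final = 200, seed = 6)
  )
  expect_equal(nrow(post), 0)
  diag <- attr(post, "diagnostics")
  expect_length(diag$core_wasserstein, 5)
  # every candidate was far beyond the threshold (Inf marks simulations
  # with nothing left above the copy filter)
  expect_true(all(diag$core_wasserstein > 0.01))
})

test_that("quantile-based acceptance adapts to the copy-number scale", {
  # a high-copy patient: Wasserstein distances sit far above any threshold
  # tuned for low-copy data, so a tight fixed epsilon accepts nothing
  sp <- generate_synthetic_patient(truth = list(k = 100, s = 1, q = 5),
                                   sizes = list(core = 60, margins = 60),
                                   n_final = 400, seed = 9)
  fixed_eps <- abc_rejection(
    sp$observed, prior_grid(k = c(50, 100, 150)),
    abc_settings(budget = 20, eps_region = 0.1, margins_per_sim = 5,
                 n_final = 400, seed = 10))
  expect_equal(nrow(fixed_eps), 0)
  frac <- abc_rejection(
    sp$observed, prior_grid(k = c(50, 100, 150)),
    abc_settings(budget = 20, accept_fraction = 0.1, margins_per_sim = 5,
                 n_final = 400, seed = 10))
  expect_equal(nrow(frac), ceiling(0.1 * 20 * 5))
  expect_true(is.finite(attr(frac, "eps_used")))
  # the accepted pairs are exactly the closest ones
  expect_lte(max(frac$sigma), 2 * attr(frac, "eps_used"))
})

test_that("two-species observations run through the joint acceptance gates", {
  sp <- generate_synthetic_patient(
    truth = list(k1 = 10, k2 = 5, s_p = 1, s_m = 1, rho = 0.5, q = 5),
    sizes = list(core = 60, margins = 60), n_final = 400, seed = 7
  )
  expect_equal(sp$observed$n_species, 2L)
  post <- abc_rejection(
    sp$observed, prior_grid(k = c(5, 10, 20), s = 1, q = 5),
    abc_settings(budget = 20, eps_region = 1e9, delta_fraction = 1,
                 margins_per_sim = 3, n_final = 400, seed = 8),
    fixed = list(k2 = 5, s_p = 1, rho = 0.5)
  )
  expect_equal(nrow(post), 20 * 3)
  expect_true(all(post$sigma >= 0))
})
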
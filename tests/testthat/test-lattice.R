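test_that("division rate depends on ecDNA presence, not copy number", {
  expect_equal(division_rate(0, s = 1.5), 1)
  expect_equal(division_rate(7, s = 1.5), 2.5)
  expect_equal(division_rate(1, s = 1.5), division_rate(700, s = 1.5))
  expect_equal(division_rate(c(0, 3), s = 2), 3) # any species counts
  expect_error(division_rate(5, s = -1), "greater than -1")
  expect_error(division_rate(-2, s = 1), "non-negative")
})

test_that("segregation duplicates then splits copies binomially", {
  expect_equal(segregate_ecdna(0, n = 50), cbind(daughter_a = rep(0L, 50),
                                                 daughter_b = rep(0L, 50)))
  set.seed(1)
  draws <- segregate_ecdna(5, n = 3000)
  expect_true(all(rowSums(draws) == 10))
  binned <- table(factor(pmin(pmax(draws[, 1], 2), 8), levels = 2:8))
  p <- dbinom(0:10, 10, 0.5)
  p_binned <- c(sum(p[1:3]), p[4:8], sum(p[9:11]))
  gof <- chisq.test(binned, p = p_binned)
  expect_gt(gof$p.value, 0.01)
  expect_error(segregate_ecdna(-1), "non-negative")
})

test_that("event selection follows the rate proportions and exponential clock", {
  # one ecDNA-free cell (rate 1) and one positive cell (rate 3 at s = 2):
  # the positive cell should be picked 75% of the time
  st <- make_state(c(0, 1), c(0, 0), c(0L, 5L))
  cfg <- sim_config(k = 5, s = 2, q = 1, n_final = 10)
  set.seed(42)
  ev <- select_event(st, cfg, n = 20000)
  expect_true(all(ev$kind == "division")) # d = 0
  p_hat <- mean(ev$cell == 2)
  se <- sqrt(0.75 * 0.25 / 20000)
  expect_lt(abs(p_hat - 0.75), 3 * se)
  # waiting times are exponential with mean 1 / total rate = 1/4
  ks <- ks.test(ev$dt, "pexp", rate = 4)
  expect_gt(ks$p.value, 0.01)
})

test_that("death events enter selection in proportion to d", {
  st <- make_state(c(0, 1), c(0, 0), c(0L, 0L))
  cfg <- sim_config(k = 0, s = 0, d = 0.5, q = 1, n_final = 10)
  set.seed(7)
  ev <- select_event(st, cfg, n = 10000)
  # total rate 2 * 1 + 2 * 0.5 = 3, death share 1/3
  p_death <- mean(ev$kind == "death")
  expect_lt(abs(p_death - 1 / 3), 3 * sqrt(2 / 9 / 10000))
})

test_that("division placement respects the pushing range", {
  # lone pair: mother has empty neighbors, q = 1 suffices, nothing displaced
  st <- make_state(c(0, 1), c(0, 0), c(5L, 5L))
  set.seed(1)
  site <- find_division_site(st, mother = 1, q = 1)
  expect_false(is.null(site))
  expect_equal(site$steps, 1)
  expect_equal(nrow(site$displaced), 0)

  # mother enclosed by a full ring of width 2: nearest empty at ray
  # distance 3 in every direction
  ring <- expand.grid(x = -2:2, y = -2:2)
  st <- make_state(ring$x, ring$y, rep(1L, nrow(ring)))
  mother <- which(st$x == 0 & st$y == 0)
  expect_null(find_division_site(st, mother, q = 2))
  set.seed(2)
  site <- find_division_site(st, mother, q = 5)
  expect_equal(site$steps, 3)
  expect_equal(nrow(site$displaced), 2) # the two ring cells on the ray
  site_inf <- find_division_site(st, mother, q = Inf)
  expect_equal(site_inf$steps, 3)
})

test_that("q = 1 confines divisions to cells with an empty neighbor", {
  st <- run_tumor(sim_config(k = 5, s = 1, q = 1, n_final = 400, seed = 3),
                  check = TRUE)
  occupied <- paste(st$x, st$y)
  for (i in sample.int(st$n_cells, 50)) {
    nbrs <- paste(st$x[i] + c(1, 1, 0, -1, -1, -1, 0, 1),
                  st$y[i] + c(0, 1, 1, 1, 0, -1, -1, -1))
    if (all(nbrs %in% occupied)) {
      expect_null(find_division_site(st, i, q = 1))
    }
  }
})

test_that("runs conserve copies and occupancy under per-event checking", {
  # the engine's check mode asserts copy conservation, class bookkeeping
  # and the occupancy bijection after every event
  for (cfg in list(sim_config(k = 10, s = 1, q = 2, n_final = 500, seed = 5),
                   sim_config(k = 3, s = 0.5, q = Inf, d = 0.3,
                              n_final = 500, seed = 6))) {
    st <- run_tumor(cfg, check = TRUE)
    expect_equal(anyDuplicated(paste(st$x, st$y)), 0)
    expect_equal(length(st$x), st$n_cells)
    expect_equal(nrow(st$copies), st$n_cells)
  }
})

test_that("initialization places one founder with exactly k copies", {
  st <- run_tumor(sim_config(k = 10, s = 1, q = 5, n_final = 1, seed = 1))
  expect_equal(st$n_cells, 1)
  expect_equal(unname(st$copies[1, 1]), 10)
  expect_equal(st$time, 0)
  expect_equal(st$founder_site, c(0L, 0L))
  expect_equal(c(st$x, st$y), c(0L, 0L))
  # variant founder carries the wild-type and variant mixture
  vst <- run_variant_sim(variant_config(kwt = 20, kvar = 1),
                         sim_config(k = 0, s = 0, q = 5, n_final = 1,
                                    seed = 2))
  expect_equal(unname(vst$copies[1, ]), c(20, 1))
})

test_that("zero-copy founders give ecDNA-free tumors", {
  st <- run_tumor(sim_config(k = 0, s = 2, q = Inf, n_final = 1000, seed = 9))
  expect_true(all(st$copies == 0))
  expect_equal(st$n_cells, 1000)
})

test_that("extinction is reported as an outcome, not an error", {
  extinct_seen <- FALSE
  for (seed in 1:20) {
    st <- run_tumor(sim_config(k = 0, s = 0, d = 0.9, n_final = 500,
                               seed = seed))
    if (st$extinct) {
      extinct_seen <- TRUE
      expect_equal(st$n_cells, 0)
      break
    }
  }
  expect_true(extinct_seen)
})

test_that("stronger selection raises the ecDNA-positive fraction (paired seeds)", {
  set.seed(11)
  seeds <- sample.int(1e6, 40)
  frac <- function(s, seed) {
    st <- run_tumor(sim_config(k = 1, s = s, q = 5, n_final = 300,
                               seed = seed))
    mean(st$copies[, 1] > 0)
  }
  wins <- mean(vapply(seeds, function(sd) frac(2, sd) > frac(0, sd), TRUE))
  expect_gte(wins, 0.8)
})
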
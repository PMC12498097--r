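test_that("tumor radius equals the brute-force maximum distance", {
  expect_equal(tumor_radius(make_state(0, 0, 5L)), 0)
  block <- expand.grid(x = -1:1, y = -1:1)
  expect_equal(tumor_radius(make_state(block$x, block$y, rep(1L, 9))),
               sqrt(2))
  st <- run_tumor(sim_config(k = 5, s = 1, q = 5, n_final = 1000, seed = 1))
  brute <- 0
  for (i in seq_len(st$n_cells)) {
    brute <- max(brute, sqrt(st$x[i]^2 + st$y[i]^2))
  }
  expect_equal(tumor_radius(st), brute)
})

test_that("circular sampling grows to n cells and subsamples uniformly", {
  st <- run_tumor(sim_config(k = 5, s = 1, q = 5, n_final = 800, seed = 2))
  s1 <- sample_circular(st, c(0, 0), n = 1)
  expect_equal(s1$counts, st$copies[which(st$x == 0 & st$y == 0), 1])
  all_cells <- sample_circular(st, c(3, -2), n = st$n_cells)
  expect_equal(sort(all_cells$counts), sort(st$copies[, 1]))
  expect_false(all_cells$shortfall)
  # deterministic under a fixed seed
  a <- sample_circular(st, c(0, 0), n = 100, seed = 99)
  b <- sample_circular(st, c(0, 0), n = 100, seed = 99)
  expect_identical(a$counts, b$counts)
  # requesting more cells than exist flags a shortfall instead of failing
  small <- make_state(0:2, c(0, 0, 0), c(1L, 2L, 3L))
  s <- sample_circular(small, c(0, 0), n = 10)
  expect_true(s$shortfall)
  expect_equal(length(s$counts), 3)
})

test_that("core samples are founder-centered subsets of the tumor", {
  st <- run_tumor(sim_config(k = 5, s = 1, q = 5, n_final = 800, seed = 3))
  core <- core_sample(st, 200, seed = 1)
  expect_equal(core$center, c(0, 0))
  expect_equal(core$label, "core")
  # counts multiset is contained in the tumor multiset
  expect_true(all(table(core$counts) <=
                    table(factor(st$copies[, 1],
                                 levels = names(table(core$counts))))))
  # sampled cells are the nearest-to-center ones (up to ties)
  d <- sqrt(st$x^2 + st$y^2)
  expect_lte(max(d[core$cell_index]), sort(d)[201] + 1e-9)
})

test_that("margin centers sit at the requested radial fraction", {
  st <- run_tumor(sim_config(k = 5, s = 1, q = 5, n_final = 2000, seed = 4))
  R <- tumor_radius(st)
  ms <- margin_samples(st, n = 100, count = 10, seed = 5)
  expect_length(ms, 10)
  for (m in ms) {
    expect_equal(m$label, "margin")
    expect_lt(abs(sqrt(sum(m$center^2)) - 0.75 * R), 3 + 1e-9)
    expect_false(is.na(m$angle))
  }
  edge <- leading_edge_sample(st, 100, seed = 6)
  expect_equal(edge$label, "leading_edge")
  expect_gt(sqrt(sum(edge$center^2)), max(vapply(ms, function(m)
    sqrt(sum(m$center^2)), 0)) - 3)
})

test_that("radially symmetric tumors give matching core and margin samples", {
  st <- disk_state(25) # every cell carries 5 copies
  core <- core_sample(st, 150, seed = 7)
  m <- margin_samples(st, 150, count = 3, seed = 8)
  expect_equal(mean(core$counts), 5)
  for (mm in m) expect_equal(mean(mm$counts), 5)
})

test_that("the copy filter removes low-copy cells and is idempotent", {
  st <- make_state(0:4, rep(0, 5), c(0L, 1L, 2L, 3L, 4L))
  s <- sample_circular(st, c(2, 0), n = 5)
  f <- filter_min_copies(s)
  expect_equal(sort(f$counts), c(3, 4))
  expect_true(f$filtered)
  f2 <- filter_min_copies(f)
  expect_equal(f2$counts, f$counts)
  # all counts above threshold: unchanged
  st2 <- run_tumor(sim_config(k = 40, s = 0, q = Inf, n_final = 300,
                              seed = 9))
  s2 <- core_sample(st2, 100, seed = 1)
  f3 <- filter_min_copies(s2)
  expect_equal(length(f3$counts), sum(s2$counts >= 3)) # brute-force tally
  f4 <- filter_min_copies(s2, threshold = 0)
  expect_equal(sort(f4$counts), sort(s2$counts))
})
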
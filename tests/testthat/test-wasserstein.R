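test_that("simple distances match closed forms", {
  expect_equal(wasserstein1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein1d(0, 4), 4)
  expect_equal(wasserstein1d(c(0, 0), c(4, 4)), 4)
  expect_equal(wasserstein1d(c(0, 4), c(2, 2)), 2)
  expect_equal(wasserstein1d(c(1, 2), c(1, 2, 3)), 0.5)
  expect_error(wasserstein1d(numeric(0), 1), "empty")
})

test_that("distance equals exhaustive minimum-cost transport", {
  set.seed(1)
  sets <- list()
  for (m in 1:3) sets <- c(sets, all_multisets(m, 3))
  # exhaustive over all pairs of multisets of size <= 3, values <= 3
  for (a in sets) {
    for (b in sets) {
      if (lcm2(length(a), length(b)) > 6) next
      expect_equal(wasserstein1d(a, b), w1_transport_oracle(a, b))
    }
  }
  # randomized coverage of the larger sizes (<= 5) and values (<= 4)
  for (i in 1:150) {
    na <- sample(1:5, 1)
    nb <- sample(1:5, 1)
    if (lcm2(na, nb) > 6) next
    a <- sample(0:4, na, replace = TRUE)
    b <- sample(0:4, nb, replace = TRUE)
    expect_equal(wasserstein1d(a, b), w1_transport_oracle(a, b))
  }
})

test_that("the distance is a metric with the translation property", {
  set.seed(2)
  rmset <- function() sample(0:4, sample(1:5, 1), replace = TRUE)
  for (i in 1:200) {
    a <- rmset()
    b <- rmset()
    cc <- rmset()
    wab <- wasserstein1d(a, b)
    expect_gte(wab, 0)
    expect_equal(wab, wasserstein1d(b, a))                       # symmetry
    expect_equal(wasserstein1d(a, a), 0)                         # identity
    expect_lte(wab, wasserstein1d(a, cc) + wasserstein1d(cc, b) + 1e-12)
    shift <- runif(1, -5, 5)
    expect_equal(wasserstein1d(a, a + shift), abs(shift))        # translation
  }
  # zero iff identical multisets
  expect_gt(wasserstein1d(c(1, 1, 2), c(1, 2, 2)), 0)
})

test_that("region distance combines the filtered metric and the raw fraction gap", {
  obs <- c(0, 1, 3, 5, 8, 10)
  d <- region_distance(obs, obs)
  expect_equal(d$wasserstein, 0)
  expect_equal(d$fraction_gap, 0)
  # identical above the filter, one extra zero below it
  a <- c(0, 3, 4, 5)
  b <- c(3, 3, 4, 5)
  d <- region_distance(a, b)
  expect_equal(d$fraction_gap, 1 / 4)
  expect_equal(d$wasserstein, wasserstein1d(c(3, 4, 5), c(3, 3, 4, 5)))
  # compositional: equals wasserstein1d on the filtered lists
  set.seed(3)
  for (i in 1:20) {
    a <- sample(0:20, 30, replace = TRUE)
    b <- sample(0:20, 30, replace = TRUE)
    d <- region_distance(a, b)
    expect_equal(d$wasserstein, wasserstein1d(a[a >= 3], b[b >= 3]))
    expect_equal(d$fraction_gap, abs(mean(a > 0) - mean(b > 0)))
  }
  expect_error(region_distance(1:5, 1:6), "size-matched")
  # nothing left after filtering: infinite distance, never accepted
  expect_equal(region_distance(c(0, 1), c(5, 9))$wasserstein, Inf)
})
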
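# Construct a tumor_state by hand from coordinates and copy counts, for
# geometry and sampling tests that need exact control over occupancy.
make_state <- function(x, y, copies,
                       config = sim_config(k = 1, s = 0, q = 1,
                                           n_final = length(x))) {
  copies <- cbind(copies)
  colnames(copies) <- if (ncol(copies) == 2) c("species1", "species2") else "ecDNA"
  structure(
    list(x = as.integer(x), y = as.integer(y), copies = copies,
         founder_site = c(0L, 0L), time = 0, n_cells = length(x),
         extinct = FALSE, events = 0, blocked = 0, config = config,
         seed = NA_integer_),
    class = "tumor_state"
  )
}

# Fully occupied disk of given radius centered on the founder.
disk_state <- function(radius, copies_fun = function(n) rep(5L, n)) {
  g <- expand.grid(x = -radius:radius, y = -radius:radius)
  g <- g[g$x^2 + g$y^2 <= radius^2, ]
  make_state(g$x, g$y, copies_fun(nrow(g)))
}

# All multisets of size n over values 0..vmax, as a list of integer vectors.
all_multisets <- function(n, vmax) {
  if (n == 0) return(list(integer(0)))
  combs <- utils::combn(n + vmax, vmax)
  # stars-and-bars bijection: column -> multiset
  apply(combs, 2, function(bars) {
    counts <- diff(c(0, bars, n + vmax + 1)) - 1
    rep(0:vmax, counts)
  }, simplify = FALSE)
}

# Exhaustive minimum-cost transport between two multisets with uniform
# marginals, by expanding both to a common size (lcm of the lengths) and
# enumerating all assignments.  Only feasible for small expanded sizes.
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

w1_transport_oracle <- function(a, b) {
  l <- lcm2(length(a), length(b))
  ra <- rep(a, each = l / length(a))
  rb <- rep(b, each = l / length(b))
  min(vapply(perms(seq_len(l)), function(p) mean(abs(ra - rb[p])), 0))
}

lcm2 <- function(m, n) {
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  m * n / gcd(m, n)
}

# 95th percentile of Wasserstein distances between pooled random halves of
# one condition's replicate samples: the Monte-Carlo noise floor used when
# asking whether two conditions are statistically indistinguishable.
pooled_noise_floor <- function(replicate_samples, n_splits = 40) {
  r <- length(replicate_samples)
  stats::quantile(vapply(seq_len(n_splits), function(i) {
    half <- sample.int(r, r %/% 2)
    wasserstein1d(unlist(replicate_samples[half]),
                  unlist(replicate_samples[-half]))
  }, 0), 0.95)
}
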
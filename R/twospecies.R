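#' Configuration for two cosegregating, coselected ecDNA species
#'
#' Two distinct ecDNA species (e.g. an EGFR- and a PDGFRA-amplifying
#' circle) evolve in the same tumor. `rho` tunes cosegregation, the
#' correlated co-inheritance of the two species at division (see
#' [cosegregate()]); coselection enters through the fitness rule: cells
#' carrying exactly one species divide at `1 + s_p` ("pure") and cells
#' carrying both at `1 + s_m` ("mixed"), so `s_m > s_p` rewards
#' maintaining the mixture.
#'
#' @param k1,k2 Founder copies of species 1 and 2.
#' @param s_p Selection coefficient for pure cells.
#' @param s_m Selection coefficient for mixed cells.
#' @param rho Cosegregation strength in `[0, 1]`: 0 = fully independent
#'   binomial segregation, 1 = maximally correlated.
#' @return A `two_species_config` object.
#' @export
two_species_config <- function(k1, k2, s_p = 0, s_m = s_p, rho = 0) {
  k1 <- check_count(k1, "k1")
  k2 <- check_count(k2, "k2")
  stopifnot(s_p > -1, s_m > -1, rho >= 0, rho <= 1)
  structure(list(k1 = k1, k2 = k2, s_p = s_p, s_m = s_m, rho = rho),
            class = "two_species_config")
}

#' Correlated segregation of two ecDNA species
#'
#' Both species duplicate (`2 * c1` and `2 * c2` copies);
#' `round(rho * min(2 c1, 2 c2))` cross-species pairs are formed
#' (round-half-to-even), each pair assigned to one daughter by a single
#' fair coin, and all unpaired copies segregate independently by fair
#' coins. Per-species conservation holds for every `rho`: daughter counts
#' sum to `2 * c1` and `2 * c2`. At `rho = 0` the two species segregate
#' independently; at `rho = 1` with `c1 = c2` the daughters receive equal
#' numbers of both species in every draw.
#'
#' @param c1,c2 Mother's copies of species 1 and 2.
#' @param rho Cosegregation strength in `[0, 1]`.
#' @param n Number of independent draws.
#' @return An `n x 4` integer matrix with columns `a1`, `a2`, `b1`, `b2`:
#'   daughter A's and daughter B's counts of each species.
#' @examples
#' cosegregate(5, 5, rho = 1, n = 3) # a1 == a2 in every row
#' @export
cosegregate <- function(c1, c2, rho, n = 1) {
  c1 <- check_count(c1, "c1")
  c2 <- check_count(c2, "c2")
  stopifnot(rho >= 0, rho <= 1)
  out <- cpp_cosegregate(c1, c2, rho, as.integer(n))
  colnames(out) <- c("a1", "a2", "b1", "b2")
  out
}

#' Division rate with two ecDNA species
#'
#' Constant selection extended to two species: rate 1 for ecDNA-free
#' cells, `1 + s_p` when exactly one species is present, `1 + s_m` when
#' both are.
#'
#' @param copies1,copies2 The cell's copies of each species.
#' @param s_p,s_m Pure- and mixed-cell selection coefficients.
#' @return The division rate.
#' @examples
#' two_species_rate(3, 0, s_p = 1, s_m = 2) # 2
#' two_species_rate(2, 5, s_p = 1, s_m = 2) # 3
#' @export
two_species_rate <- function(copies1, copies2, s_p, s_m) {
  stopifnot(copies1 >= 0, copies2 >= 0, s_p > -1, s_m > -1)
  has1 <- copies1 > 0
  has2 <- copies2 > 0
  if (has1 && has2) 1 + s_m else if (has1 || has2) 1 + s_p else 1
}

#' Simulate a tumor carrying two ecDNA species
#'
#' The spatial engine with [cosegregate()] inheritance and the
#' [two_species_rate()] fitness rule. With `k2 = 0` this reduces exactly
#' to the single-species engine at `s = s_p`.
#'
#' @param tsc A [two_species_config()].
#' @param config A [sim_config()] supplying `q`, `d`, `n_final`, `seed`,
#'   and `lattice_span` (its `k` and `s` are ignored).
#' @param check Verify per-event invariants (slow).
#' @return A `tumor_state` whose `copies` matrix has columns `species1`
#'   and `species2`.
#' @export
run_two_species <- function(tsc, config, check = FALSE) {
  stopifnot(inherits(tsc, "two_species_config"),
            inherits(config, "sim_config"))
  seed_used <- seed_rng(config$seed)
  res <- cpp_run_lattice(
    k1 = tsc$k1, k2 = tsc$k2, model = 2L, s_a = tsc$s_p, s_b = tsc$s_m,
    rho = tsc$rho, d = config$d, q_inf = is.infinite(config$q),
    q = if (is.infinite(config$q)) 0L else as.integer(config$q),
    n_final = config$n_final, span = config$lattice_span, vvar = 0L,
    check = check
  )
  new_tumor_state(res, config, species = c("species1", "species2"),
                  seed_used = seed_used,
                  extra = list(two_species_config = tsc))
}

#' Fraction of mixed cells
#'
#' The fraction of cells carrying at least one copy of each of the two
#' ecDNA species.
#'
#' @param sample A `region_sample`, `tumor_state`, or a two-column count
#'   matrix.
#' @return A fraction in `[0, 1]`.
#' @export
mixed_fraction <- function(sample) {
  counts <- if (inherits(sample, "region_sample")) sample$counts
            else if (inherits(sample, c("tumor_state", "well_mixed_pop"))) sample$copies
            else sample
  if (!is.matrix(counts) || ncol(counts) != 2L) {
    stop("mixed_fraction needs two-species counts", call. = FALSE)
  }
  if (nrow(counts) == 0L) stop("empty sample", call. = FALSE)
  mean(counts[, 1] > 0 & counts[, 2] > 0)
}
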
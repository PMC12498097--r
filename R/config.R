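#' Simulation configuration for a single tumor run
#'
#' Bundles the parameters of one spatial tumor simulation: the founder
#' cell's ecDNA copy number `k`, the selection coefficient `s` of
#' ecDNA-positive cells, the pushing range `q` (in lattice units), the
#' per-cell death rate `d`, and the target population size `n_final`.
#' Rates are relative to a base division rate of 1 for ecDNA-free cells,
#' so time is measured in expected ecDNA-free cell generations.
#'
#' @param k Non-negative integer; ecDNA copies in the founder cell.
#' @param s Selection coefficient (> -1). Cells carrying at least one ecDNA
#'   copy divide at rate `1 + s`, independent of how many copies they carry
#'   (constant selection).
#' @param q Pushing range: a dividing cell may displace a contiguous run of
#'   up to `q - 1` neighbors along one of the 8 lattice directions to open
#'   space. `q = 1` restricts divisions to cells with an empty neighbor
#'   (boundary growth); `Inf` makes every direction eligible.
#' @param d Death rate per cell (events per unit time), `0 <= d < 1` so net
#'   growth stays positive.
#' @param n_final Target number of cells at which the run stops.
#' @param seed Optional integer seed; when given, [run_tumor()] seeds the
#'   R session RNG before simulating.
#' @param lattice_span Half-width of the square lattice. Defaults to
#'   `ceiling(2 * sqrt(n_final / pi)) + 10`, twice the radius of a fully
#'   compact tumor of `n_final` cells; the engine stops with an error if a
#'   cell would ever reach the boundary.
#'
#' @return An object of class `sim_config`.
#' @seealso [run_tumor()], [variant_config()], [two_species_config()]
#' @examples
#' cfg <- sim_config(k = 10, s = 1, q = 5, n_final = 1000, seed = 1)
#' cfg
#' @export
sim_config <- function(k, s, q = Inf, d = 0, n_final = 10000, seed = NULL,
                       lattice_span = NULL) {
  k <- check_count(k, "k")
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= -1) {
    stop("`s` must be a single number greater than -1", call. = FALSE)
  }
  if (!(is.numeric(q) && length(q) == 1L &&
        (is.infinite(q) || (q >= 1 && q == floor(q))))) {
    stop("`q` must be a positive integer or Inf", call. = FALSE)
  }
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d >= 1) {
    stop("`d` must satisfy 0 <= d < 1", call. = FALSE)
  }
  n_final <- check_count(n_final, "n_final")
  if (n_final < 1L) stop("`n_final` must be at least 1", call. = FALSE)
  if (is.null(lattice_span)) {
    lattice_span <- as.integer(ceiling(2 * sqrt(n_final / pi)) + 10)
  }
  lattice_span <- check_count(lattice_span, "lattice_span")
  if (!is.null(seed)) seed <- check_count(seed, "seed", allow_zero = TRUE)
  structure(
    list(k = k, s = s, q = q, d = d, n_final = n_final, seed = seed,
         lattice_span = lattice_span),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  k = %d, s = %g, q = %s, d = %g\n", x$k, x$s,
              if (is.infinite(x$q)) "Inf" else format(x$q), x$d))
  cat(sprintf("  n_final = %d, lattice_span = %d, seed = %s\n",
              x$n_final, x$lattice_span,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

check_count <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < if (allow_zero) 0 else 1) {
    stop(sprintf("`%s` must be a single non-negative integer", name),
         call. = FALSE)
  }
  as.integer(x)
}

# Seed the session RNG if a seed is supplied; invisibly returns the seed in
# effect (NA when inheriting the ambient RNG state).
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    set.seed(seed)
    return(invisible(seed))
  }
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  invisible(NA_integer_)
}
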
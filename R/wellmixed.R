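#' Grow a well-mixed (non-spatial) population
#'
#' Gillespie birth(-death) dynamics with the same constant-selection
#' division rates and binomial ecDNA segregation as the spatial engine, but
#' with no lattice: every division succeeds. This is the limit the spatial
#' model approaches as the pushing range grows (weak spatial constraint),
#' and serves as its reference implementation in tests. Growth is
#' exponential with no carrying capacity; an optional fixed-passage mode
#' emulates cell-culture dynamics by subsampling the population back to
#' `passage$n0` cells after every `passage$doublings` doublings.
#'
#' @param k Founder ecDNA copy number (non-negative integer).
#' @param s Selection coefficient (> -1) of ecDNA-positive cells.
#' @param n_final Target population size (ignored in passage mode).
#' @param seed Optional integer seed.
#' @param d Death rate per cell, `0 <= d < 1`.
#' @param record_history Record the trajectory after every event?
#' @param passage `NULL` (default: pure expansion) or
#'   `list(n0 = , doublings = , rounds = )` for serial passaging.
#' @return A `well_mixed_pop`: list with `copies` (per-cell counts),
#'   `time`, `n_cells`, `extinct`, and `history`, a data frame with
#'   columns `time`, `n_cells`, `positive_fraction`, `mean_copies`.
#' @examples
#' pop <- run_well_mixed(k = 10, s = 0, n_final = 200, seed = 1)
#' tail(pop$history, 3)
#' @export
run_well_mixed <- function(k, s, n_final, seed = NULL, d = 0,
                           record_history = TRUE, passage = NULL) {
  k <- check_count(k, "k")
  stopifnot(is.numeric(s), length(s) == 1L, s > -1, d >= 0, d < 1)
  n_final <- check_count(n_final, "n_final")
  seed_used <- seed_rng(seed)
  p <- passage %||% list(n0 = 0L, doublings = 0L, rounds = 0L)
  res <- cpp_run_wellmixed(
    k1 = k, k2 = 0L, model = 0L, s_a = s, s_b = s, rho = 0, d = d,
    n_final = n_final, vvar = 0L, record_history = record_history,
    passage_n0 = as.integer(p$n0), passage_g = as.integer(p$doublings),
    passage_rounds = as.integer(p$rounds), check = FALSE
  )
  new_well_mixed(res, species = "ecDNA", seed_used = seed_used,
                 params = list(k = k, s = s, d = d, n_final = n_final,
                               passage = passage))
}

new_well_mixed <- function(res, species, seed_used, params) {
  copies <- cbind(res$copies1)
  if (length(species) == 2L) copies <- cbind(res$copies1, res$copies2)
  colnames(copies) <- species
  h <- res$history
  history <- data.frame(
    time = h$time, n_cells = h$n_cells,
    positive_fraction = ifelse(h$n_cells > 0, h$n_positive / h$n_cells, NA),
    mean_copies = ifelse(h$n_cells > 0,
                         (h$total_copies1 + h$total_copies2) / h$n_cells, NA)
  )
  structure(
    list(copies = copies, time = res$time, n_cells = res$n_cells,
         extinct = res$extinct, history = history,
         variant_arrival_n = res$variant_arrival_n,
         params = params, seed = seed_used),
    class = "well_mixed_pop"
  )
}

#' @export
print.well_mixed_pop <- function(x, ...) {
  cat(sprintf("<well_mixed_pop> %d cells, time %.3f%s\n", x$n_cells, x$time,
              if (x$extinct) " (EXTINCT)" else ""))
  for (sp in colnames(x$copies)) {
    cc <- x$copies[, sp]
    cat(sprintf("  %s: positive fraction %.3f, mean copies %.2f\n",
                sp, if (x$n_cells) mean(cc > 0) else NA, mean(cc)))
  }
  invisible(x)
}

#' Trajectory of the ecDNA-positive cell fraction
#'
#' The fraction of cells carrying at least one ecDNA copy, over the
#' recorded history of a well-mixed run. Under neutrality this fraction
#' can only erode (zero-copy cells are an absorbing state); under positive
#' selection it is maintained.
#'
#' @param pop A `well_mixed_pop` with a recorded history.
#' @return Data frame with columns `time` and `positive_fraction`.
#' @export
positive_fraction_trajectory <- function(pop) {
  stopifnot(inherits(pop, "well_mixed_pop"))
  if (nrow(pop$history) == 0L) {
    stop("no history was recorded for this run; rerun with record_history = TRUE",
         call. = FALSE)
  }
  pop$history[, c("time", "positive_fraction")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
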
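#' First Wasserstein distance between empirical distributions
#'
#' The 1-Wasserstein (earth mover's) distance between the empirical
#' distributions of two samples: the integral of the absolute difference
#' of their ECDFs, equivalently the minimum-cost transport between the two
#' point masses. It is symmetric, zero exactly when the two multisets are
#' identical, satisfies the triangle inequality, and shifts by `|c|` under
#' a constant translation of one sample.
#'
#' @param a,b Non-empty numeric vectors (need not be the same length).
#' @return A single non-negative number.
#' @examples
#' wasserstein1d(c(1, 2, 3), c(1, 2, 3)) # 0
#' wasserstein1d(0, 4)                   # 4
#' @export
wasserstein1d <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("cannot compute a Wasserstein distance from an empty sample",
         call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("inputs must be finite numbers", call. = FALSE)
  }
  if (length(a) == length(b)) {
    return(mean(abs(sort(a) - sort(b))))
  }
  x <- sort(unique(c(a, b)))
  if (length(x) == 1L) return(0)
  xl <- x[-length(x)]
  sum(abs(ecdf(a)(xl) - ecdf(b)(xl)) * diff(x))
}

#' Distance components between a simulated and an observed region
#'
#' Two complementary summaries are compared per region: the Wasserstein
#' distance between the copy-number distributions after removing cells
#' below the minimum-copy filter (see [filter_min_copies()]), and the
#' absolute difference of the ecDNA-positive cell fractions computed on
#' the unfiltered counts. The simulated sample must be size-matched to the
#' observed region before filtering.
#'
#' @param sim A `region_sample` (unfiltered) or numeric vector of
#'   simulated per-cell counts.
#' @param obs Numeric vector of observed per-cell counts.
#' @param min_copy_filter Copy-number threshold applied to both sides
#'   before the Wasserstein term (default 3).
#' @return List with elements `wasserstein` and `fraction_gap`. When
#'   either side has no cells left after filtering the Wasserstein term is
#'   `Inf` (the pair can never be accepted).
#' @export
region_distance <- function(sim, obs, min_copy_filter = 3) {
  sim_counts <- region_total_copies(sim)
  obs_counts <- region_total_copies(obs)
  if (length(sim_counts) != length(obs_counts)) {
    stop(sprintf(
      "simulated region (%d cells) is not size-matched to the observed region (%d cells)",
      length(sim_counts), length(obs_counts)), call. = FALSE)
  }
  fraction_gap <- abs(mean(sim_counts > 0) - mean(obs_counts > 0))
  sim_f <- sim_counts[sim_counts >= min_copy_filter]
  obs_f <- obs_counts[obs_counts >= min_copy_filter]
  w <- if (length(sim_f) == 0L || length(obs_f) == 0L) {
    Inf
  } else {
    wasserstein1d(sim_f, obs_f)
  }
  list(wasserstein = w, fraction_gap = fraction_gap)
}
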
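#' Tumor radius
#'
#' Maximum Euclidean distance from the founder site over all occupied
#' lattice sites, in lattice units.
#'
#' @param state A `tumor_state`.
#' @return A single non-negative number.
#' @export
tumor_radius <- function(state) {
  stopifnot(inherits(state, "tumor_state"), state$n_cells >= 1)
  max(sqrt((state$x - state$founder_site[1])^2 +
             (state$y - state$founder_site[2])^2))
}

#' Circular spatial sample of cells
#'
#' Emulates taking a tissue punch: the sampling radius around `center`
#' grows from zero until at least `n` cells are enclosed, then exactly `n`
#' of the enclosed cells are subsampled uniformly without replacement.
#' If the tumor holds fewer than `n` cells, all cells are returned and the
#' shortfall is flagged rather than raised as an error, so downstream
#' inference can down-weight the region.
#'
#' @param state A `tumor_state`.
#' @param center Numeric length-2 coordinate pair.
#' @param n Requested number of cells (>= 1).
#' @param seed Optional integer seed for the subsampling.
#' @param label Region label, one of `"core"`, `"margin"`,
#'   `"leading_edge"`, or a custom string.
#' @return A `region_sample`: list with `label`, `center`, `angle`,
#'   `n_requested`, `counts` (per-cell copy numbers; a matrix with one
#'   column per species when the tumor carries two), `cell_index`,
#'   `shortfall`, and filter state (`filtered`, `threshold`).
#' @seealso [core_sample()], [margin_samples()], [leading_edge_sample()],
#'   [filter_min_copies()]
#' @export
sample_circular <- function(state, center, n, seed = NULL, label = "custom") {
  stopifnot(inherits(state, "tumor_state"), length(center) == 2L)
  n <- check_count(n, "n", allow_zero = FALSE)
  seed_rng(seed)
  d <- sqrt((state$x - center[1])^2 + (state$y - center[2])^2)
  if (n >= state$n_cells) {
    idx <- seq_len(state$n_cells)
    shortfall <- n > state$n_cells
  } else {
    r_star <- sort(d, partial = n)[n]
    enclosed <- which(d <= r_star)
    idx <- if (length(enclosed) > n) sample(enclosed, n) else enclosed
    shortfall <- FALSE
  }
  new_region_sample(state, idx, label = label, center = center,
                    n_requested = n, shortfall = shortfall)
}

new_region_sample <- function(state, idx, label, center, n_requested,
                              shortfall = FALSE, angle = NA_real_) {
  counts <- state$copies[idx, , drop = FALSE]
  if (ncol(counts) == 1L) counts <- counts[, 1L]
  structure(
    list(label = label, center = as.numeric(center), angle = angle,
         n_requested = n_requested, counts = counts, cell_index = idx,
         shortfall = shortfall, filtered = FALSE, threshold = NA_real_),
    class = "region_sample"
  )
}

#' @export
print.region_sample <- function(x, ...) {
  tot <- region_total_copies(x)
  cat(sprintf(
    "<region_sample> %s: %d cells (requested %d)%s%s\n  center (%.1f, %.1f), positive fraction %.3f, mean copies %.2f\n",
    x$label, length(tot), x$n_requested,
    if (x$shortfall) " [SHORTFALL]" else "",
    if (x$filtered) sprintf(" [filtered >= %g]", x$threshold) else "",
    x$center[1], x$center[2], mean(tot > 0), mean(tot)))
  invisible(x)
}

# per-cell total copies across species, for filtering and positivity
region_total_copies <- function(sample) {
  counts <- if (inherits(sample, "region_sample")) sample$counts else sample
  if (is.matrix(counts)) rowSums(counts) else as.numeric(counts)
}

#' Core sample centered on the founder cell
#'
#' The tumor core is the circular region centered on the coordinates of
#' the first tumor cell.
#'
#' @inheritParams sample_circular
#' @return A `region_sample` labeled `"core"`.
#' @export
core_sample <- function(state, n, seed = NULL) {
  sample_circular(state, state$founder_site, n, seed = seed, label = "core")
}

#' Infiltrating-margin samples
#'
#' Each margin sample is a circular region centered on the occupied cell
#' nearest to a point at `fraction` (default 0.75) of the tumor radius
#' from the founder, at a uniformly random angle. Ten samples per tumor is
#' the default, capturing the margin-to-margin variability of the
#' copy-number distribution. An angle whose target point has no occupied
#' cell within `tol` lattice units is redrawn (bounded retries).
#'
#' @inheritParams sample_circular
#' @param n Cells per sample; a vector is recycled across samples so each
#'   margin can be size-matched to its observed counterpart.
#' @param count Number of margin samples (default 10).
#' @param fraction Radial fraction of the tumor radius at which margin
#'   centers are placed.
#' @param tol Maximum accepted distance (lattice units) between the target
#'   point and the nearest occupied cell. [leading_edge_sample()] defaults
#'   to `Inf`: targets near the maximal radius overshoot the irregular
#'   boundary at most angles, so its center is clamped to the most
#'   peripheral occupied cell toward the drawn direction.
#' @param max_retries Attempts per sample before failing.
#' @return A list of `region_sample`s labeled `"margin"`, each recording
#'   the angle used.
#' @export
margin_samples <- function(state, n, count = 10, seed = NULL,
                           fraction = 0.75, tol = 3, max_retries = 20) {
  stopifnot(inherits(state, "tumor_state"), count >= 1)
  seed_rng(seed)
  n <- rep_len(as.integer(n), count)
  lapply(seq_len(count), function(j) {
    radial_sample(state, n[j], fraction = fraction, label = "margin",
                  tol = tol, max_retries = max_retries)
  })
}

#' Leading-edge sample
#'
#' Like a margin sample but centered farther out, at `fraction` (default
#' 0.95) of the tumor radius: the most peripheral, "most normal" region of
#' the specimen.
#'
#' @inheritParams margin_samples
#' @return A single `region_sample` labeled `"leading_edge"`.
#' @export
leading_edge_sample <- function(state, n, seed = NULL, fraction = 0.95,
                                tol = Inf, max_retries = 20) {
  seed_rng(seed)
  radial_sample(state, as.integer(n), fraction = fraction,
                label = "leading_edge", tol = tol, max_retries = max_retries)
}

radial_sample <- function(state, n, fraction, label, tol, max_retries) {
  r_target <- fraction * tumor_radius(state)
  fx <- state$founder_site[1]
  fy <- state$founder_site[2]
  for (try in seq_len(max_retries)) {
    angle <- runif(1, 0, 2 * pi)
    tx <- fx + r_target * cos(angle)
    ty <- fy + r_target * sin(angle)
    d2 <- (state$x - tx)^2 + (state$y - ty)^2
    nearest <- which.min(d2)
    if (sqrt(d2[nearest]) <= tol) {
      center <- c(state$x[nearest], state$y[nearest])
      out <- sample_circular(state, center, n, label = label)
      out$angle <- angle
      return(out)
    }
  }
  stop(sprintf(
    "no occupied cell within %g lattice units of the %s target after %d angle draws",
    tol, label, max_retries), call. = FALSE)
}

#' Remove low-copy cells from a region sample
#'
#' DNA FISH regions are contaminated by non-tumor cells; cells whose total
#' ecDNA copy number falls below `threshold` (default 3) are therefore
#' removed from both simulated and observed samples before computing
#' distribution distances. Filtering an already-filtered sample is
#' idempotent.
#'
#' @param sample A `region_sample`.
#' @param threshold Minimum total copy number retained.
#' @return The filtered `region_sample` with its `filtered` flag set.
#' @examples
#' # counts {0,1,2,3,4} -> {3,4}
#' @export
filter_min_copies <- function(sample, threshold = 3) {
  stopifnot(inherits(sample, "region_sample"))
  keep <- region_total_copies(sample) >= threshold
  sample$counts <- if (is.matrix(sample$counts)) {
    sample$counts[keep, , drop = FALSE]
  } else {
    sample$counts[keep]
  }
  sample$cell_index <- sample$cell_index[keep]
  sample$filtered <- TRUE
  sample$threshold <- threshold
  sample
}
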
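#' Grow a spatial tumor to its target size
#'
#' Runs the on-lattice cellular automaton: starting from a single founder
#' cell at the origin carrying `k` ecDNA copies, cells divide and die by
#' rejection-free kinetic Monte Carlo (Bortz-Kalos-Lebowitz event
#' selection). At division a mother may push the contiguous run of
#' neighbors along one of the 8 lattice directions one step outward,
#' provided the nearest empty site on that ray lies within `q` steps; the
#' run's ecDNA copies are duplicated and split between the daughters by
#' binomial partitioning. A division with no eligible direction is consumed
#' without a birth (time still advances). The run stops when the population
#' reaches `n_final` cells, or earlier if it goes extinct (possible only
#' when `d > 0`); extinction is reported in the returned state, not as an
#' error.
#'
#' @param config A [sim_config()].
#' @param check Logical; when `TRUE` the engine verifies occupancy
#'   integrity, fitness-class bookkeeping, and ecDNA copy conservation
#'   after every event (slow; intended for testing).
#' @return A `tumor_state`: a list with integer coordinate vectors `x`,
#'   `y`, an `n_cells x n_species` integer matrix `copies`, `founder_site`
#'   (always the origin), elapsed `time`, `n_cells`, logical `extinct`,
#'   event diagnostics (`events`, `blocked`), and the generating `config`.
#' @examples
#' st <- run_tumor(sim_config(k = 10, s = 1, q = 5, n_final = 500, seed = 1))
#' st
#' mean(st$copies[, 1] > 0) # ecDNA-positive fraction
#' @export
run_tumor <- function(config, check = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  seed_used <- seed_rng(config$seed)
  res <- cpp_run_lattice(
    k1 = config$k, k2 = 0L, model = 0L, s_a = config$s, s_b = config$s,
    rho = 0, d = config$d, q_inf = is.infinite(config$q),
    q = if (is.infinite(config$q)) 0L else as.integer(config$q),
    n_final = config$n_final, span = config$lattice_span, vvar = 0L,
    check = check
  )
  new_tumor_state(res, config, species = "ecDNA", seed_used = seed_used)
}

new_tumor_state <- function(res, config, species, seed_used = NA_integer_,
                            extra = list()) {
  copies <- cbind(res$copies1)
  if (length(species) == 2L) copies <- cbind(res$copies1, res$copies2)
  colnames(copies) <- species
  structure(
    c(list(
      x = res$x, y = res$y, copies = copies,
      founder_site = c(0L, 0L), time = res$time, n_cells = res$n_cells,
      extinct = res$extinct, events = res$events, blocked = res$blocked,
      config = config, seed = seed_used
    ), extra),
    class = "tumor_state"
  )
}

#' @export
print.tumor_state <- function(x, ...) {
  cat(sprintf("<tumor_state> %d cells, %d ecDNA species, time %.3f\n",
              x$n_cells, ncol(x$copies), x$time))
  if (x$extinct) cat("  population went EXTINCT before reaching n_final\n")
  for (sp in colnames(x$copies)) {
    cc <- x$copies[, sp]
    cat(sprintf("  %s: positive fraction %.3f, mean copies %.2f\n",
                sp, mean(cc > 0), mean(cc)))
  }
  invisible(x)
}

#' Division rate under the constant-selection model
#'
#' A cell carrying at least one ecDNA copy (of any species) divides at rate
#' `1 + s`; an ecDNA-free cell divides at the base rate 1. The rate does
#' not depend on how many copies the cell carries.
#'
#' @param copies Non-negative integer vector: the cell's per-species copy
#'   counts (a single number for one species).
#' @param s Selection coefficient, must exceed -1.
#' @return The division rate (a single number).
#' @examples
#' division_rate(0, s = 1.5) # 1
#' division_rate(7, s = 1.5) # 2.5, independent of the 7
#' @export
division_rate <- function(copies, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= -1) {
    stop("`s` must be a single number greater than -1", call. = FALSE)
  }
  if (any(copies < 0)) stop("copy counts must be non-negative", call. = FALSE)
  if (sum(copies) == 0) 1 else 1 + s
}

#' Binomial segregation of ecDNA at cell division
#'
#' ecDNA lacks centromeres and is not partitioned mitotically: the mother's
#' `copies` are duplicated to `2 * copies` and each copy independently goes
#' to either daughter with probability 1/2. A cell with zero copies stays
#' at zero forever (absorbing state).
#'
#' @param copies Non-negative integer; the mother's pre-division count.
#' @param n Number of independent draws.
#' @return An `n x 2` integer matrix of daughter counts; each row sums to
#'   `2 * copies`.
#' @examples
#' segregate_ecdna(5, n = 3)
#' @export
segregate_ecdna <- function(copies, n = 1) {
  copies <- check_count(copies, "copies")
  out <- cpp_segregate(copies, as.integer(n))
  colnames(out) <- c("daughter_a", "daughter_b")
  out
}

#' Draw the next event(s) by rejection-free kinetic Monte Carlo
#'
#' Events are chosen with probability proportional to their rates: each
#' cell contributes its division rate (see [division_rate()]) and a death
#' rate `d`; the waiting time is exponential with mean one over the total
#' rate. Every drawn event is executed (a division may still place no
#' daughter when all directions are blocked). This function exposes the
#' engine's selection kernel on a standing population for inspection and
#' testing; [run_tumor()] performs the same draw internally at every step.
#'
#' @param state A `tumor_state`.
#' @param config The [sim_config()] supplying `s` and `d`.
#' @param n Number of events to draw (all from the same standing state).
#' @return A data frame with columns `kind` ("division" or "death"),
#'   `cell` (index into the state's cell arrays), and `dt`.
#' @export
select_event <- function(state, config, n = 1) {
  stopifnot(inherits(state, "tumor_state"), state$n_cells >= 1)
  total <- rowSums(state$copies)
  pos <- total > 0
  draws <- cpp_pick_events(sum(!pos), sum(pos), 0, config$s, config$s,
                           config$d, as.integer(n))
  cell <- integer(n)
  idx_free <- which(!pos)
  idx_pos <- which(pos)
  for (i in seq_len(n)) {
    cell[i] <- if (draws[i, "kind"] == 1) {
      sample.int(state$n_cells, 1L)
    } else if (draws[i, "class"] == 0) {
      idx_free[sample.int(length(idx_free), 1L)]
    } else {
      idx_pos[sample.int(length(idx_pos), 1L)]
    }
  }
  data.frame(kind = ifelse(draws[, "kind"] == 1, "death", "division"),
             cell = cell, dt = draws[, "dt"])
}

#' Find where a dividing cell can place its daughter
#'
#' Scans the 8 lattice directions from the mother: a direction is eligible
#' if the nearest empty site along that ray lies within `q` steps. One
#' eligible direction is chosen uniformly at random; the cells between the
#' mother and that empty site form the contiguous run to be pushed one step
#' outward. Returns `NULL` when no direction is eligible, in which case the
#' division is aborted and the state unchanged (a legal outcome, not an
#' error). With `q = 1` only cells with an empty Moore neighbor can divide;
#' with `q = Inf` every direction is eligible.
#'
#' @param state A `tumor_state`.
#' @param mother Index of the dividing cell.
#' @param q Pushing range (positive integer or `Inf`); defaults to the
#'   state's configuration.
#' @return `NULL`, or a list with `direction` (1-8), the unit step
#'   (`dx`, `dy`), `steps` (ray distance to the empty site),
#'   `daughter_site`, and `displaced` (matrix of sites shifted outward,
#'   possibly zero rows).
#' @export
find_division_site <- function(state, mother, q = state$config$q) {
  stopifnot(inherits(state, "tumor_state"))
  mother <- check_count(mother, "mother", allow_zero = FALSE)
  res <- cpp_eligible_directions(
    state$x, state$y, mother,
    q_inf = is.infinite(q), q = if (is.infinite(q)) 0L else as.integer(q),
    span = lattice_span_for(state)
  )
  if (length(res$direction) == 0L) return(NULL)
  pick <- sample.int(length(res$direction), 1L)
  dir <- res$direction[pick]
  steps <- res$steps[pick]
  dx <- res$dx[dir]
  dy <- res$dy[dir]
  mx <- state$x[mother]
  my <- state$y[mother]
  displaced <- if (steps > 1) {
    cbind(x = mx + dx * seq_len(steps - 1), y = my + dy * seq_len(steps - 1))
  } else {
    cbind(x = integer(0), y = integer(0))
  }
  list(direction = dir, dx = dx, dy = dy, steps = steps,
       daughter_site = c(mx + dx, my + dy), displaced = displaced)
}

# span large enough to hold the state's coordinates with headroom for ray
# scans; used when re-gridding a state snapshot.
lattice_span_for <- function(state) {
  as.integer(max(abs(c(state$x, state$y, 1L))) + 3L +
               ceiling(sqrt(state$n_cells)))
}
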
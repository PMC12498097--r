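#' Observed per-region ecDNA copy-number data
#'
#' Per-cell ecDNA copy numbers (DNA FISH foci counts per nucleus) for the
#' spatial regions of one tumor: the core is required, at least one
#' infiltrating margin, and optionally a leading edge. For two-species
#' tumors supply two-column matrices (one column per ecDNA species)
#' instead of vectors.
#'
#' @param core Numeric vector (or two-column matrix) of per-cell counts.
#' @param margins A vector/matrix or a list of them, one per measured
#'   margin region.
#' @param leading_edge Optional vector/matrix.
#' @param tumor_id Identifier carried through to results.
#' @return An `observed_patient_data` object.
#' @export
observed_patient_data <- function(core, margins, leading_edge = NULL,
                                  tumor_id = "tumor") {
  if (!is.list(margins)) margins <- list(margins)
  regions <- c(list(core = core), margins, list(leading_edge = leading_edge))
  for (r in regions) {
    if (is.null(r)) next
    cc <- if (is.matrix(r)) as.vector(r) else r
    if (length(cc) == 0L || any(cc < 0) || any(cc != floor(cc))) {
      stop("copy counts must be non-negative integers and non-empty",
           call. = FALSE)
    }
  }
  structure(
    list(core = core, margins = margins, leading_edge = leading_edge,
         tumor_id = tumor_id,
         n_species = if (is.matrix(core)) ncol(core) else 1L),
    class = "observed_patient_data"
  )
}

#' @export
print.observed_patient_data <- function(x, ...) {
  cat(sprintf("<observed_patient_data> %s (%d ecDNA species)\n", x$tumor_id,
              x$n_species))
  cat(sprintf("  core: %d cells; margins: %s cells%s\n",
              NROW(x$core),
              paste(vapply(x$margins, NROW, 1L), collapse = ", "),
              if (is.null(x$leading_edge)) "" else
                sprintf("; leading edge: %d cells", NROW(x$leading_edge))))
  invisible(x)
}

#' Prior grid over the simulator parameters
#'
#' Uniform (or weighted) discrete prior over the initial copy number `k`,
#' the selection coefficient `s`, and the pushing range `q`. The default
#' `q` candidates span the regimes from strict boundary growth (`q = 1`)
#' through strong (`q = 2, 5`) and weak (`q = 10, 50, 1000`) spatial
#' constraint.
#'
#' @param k Integer candidates for the founder copy number.
#' @param s Numeric candidates for the selection coefficient.
#' @param q Candidates for the pushing range (may include `Inf`).
#' @param weights Optional list with elements `k`, `s`, `q` of sampling
#'   weights (defaults to uniform).
#' @return A `prior_grid` object.
#' @export
prior_grid <- function(k = 1:150, s = seq(0, 4, by = 0.25),
                       q = c(1, 2, 5, 10, 50, 1000), weights = NULL) {
  stopifnot(length(k) >= 1, length(s) >= 1, length(q) >= 1,
            all(k >= 0), all(s > -1), all(is.infinite(q) | q >= 1))
  w <- list(
    k = weights$k %||% rep(1, length(k)),
    s = weights$s %||% rep(1, length(s)),
    q = weights$q %||% rep(1, length(q))
  )
  structure(list(k = as.integer(k), s = s, q = q, weights = w),
            class = "prior_grid")
}

#' Settings for ABC rejection sampling
#'
#' @param budget Number of simulated tumors.
#' @param eps_region Per-region Wasserstein acceptance threshold. A
#'   core-margin pair is accepted only if every region is individually
#'   within `eps_region`, so an accepted pair has total distance
#'   `sigma < 2 * eps_region`.
#' @param accept_fraction `NULL` (default; use the fixed `eps_region`), or
#'   a fraction in (0, 1]: ignore `eps_region` and instead accept the
#'   closest `accept_fraction` of all candidate pairs, ranked by their
#'   worst per-region Wasserstein distance among pairs passing the
#'   positive-fraction gate. Because the Wasserstein distance scales with
#'   the magnitude of the copy numbers, a fixed threshold that suits a
#'   20-copy tumor rejects everything for a 140-copy tumor; quantile-based
#'   acceptance adapts automatically and is standard practice in rejection
#'   ABC. The realized threshold is reported in `attr(, "eps_used")`.
#' @param delta_fraction Tolerance on the absolute difference in
#'   ecDNA-positive cell fraction per region (computed unfiltered).
#' @param margins_per_sim Margin samples per simulated tumor; the core is
#'   paired with each, giving that many core-margin candidate pairs.
#' @param margin_fraction Radial fraction for margin centers.
#' @param edge_fraction Radial fraction for the leading-edge center.
#' @param min_copy_filter Copy filter applied before Wasserstein terms.
#' @param n_final Simulated tumor size.
#' @param d Death rate used in the simulations.
#' @param seed Seed for the whole inference run.
#' @return An `abc_settings` object.
#' @export
abc_settings <- function(budget = 1000, eps_region = 5,
                         accept_fraction = NULL, delta_fraction = 0.1,
                         margins_per_sim = 10, margin_fraction = 0.75,
                         edge_fraction = 0.95, min_copy_filter = 3,
                         n_final = 10000, d = 0, seed = NULL) {
  stopifnot(budget >= 1, eps_region > 0, delta_fraction >= 0,
            delta_fraction <= 1, margins_per_sim >= 1,
            is.null(accept_fraction) ||
              (accept_fraction > 0 && accept_fraction <= 1))
  structure(
    list(budget = as.integer(budget), eps_region = eps_region,
         accept_fraction = accept_fraction,
         delta_fraction = delta_fraction,
         margins_per_sim = as.integer(margins_per_sim),
         margin_fraction = margin_fraction, edge_fraction = edge_fraction,
         min_copy_filter = min_copy_filter,
         n_final = as.integer(n_final), d = d, seed = seed),
    class = "abc_settings"
  )
}

#' Fit the spatial simulator to observed copy-number data by ABC rejection
#'
#' For each of `settings$budget` draws, parameters `(k, s, q)` are sampled
#' from the prior, one tumor is simulated to `n_final` cells, a core
#' sample and `margins_per_sim` margin samples are taken size-matched to
#' the observed regions, and the core is paired with each margin to give
#' independent core-margin candidate pairs. A pair is accepted when every
#' region individually satisfies both gates: Wasserstein distance (on
#' copy-filtered counts) at most `eps_region`, and ecDNA-positive-fraction
#' gap (unfiltered) at most `delta_fraction`. Each accepted pair is
#' recorded with its total distance `sigma`, the sum of the per-region
#' Wasserstein distances.
#'
#' For two-species observations the Wasserstein gate applies to each
#' species' marginal distribution, and the gap in mixed-cell fraction
#' (cells carrying both species) enters as an additional gate at
#' `delta_fraction`; `sigma` sums the marginal Wasserstein terms.
#'
#' @param observed An [observed_patient_data()].
#' @param prior A [prior_grid()]. For two-species data the prior `k` is
#'   the founder copy number of species 1 and `s` is the mixed-cell
#'   selection coefficient; the remaining two-species parameters come from
#'   `fixed`.
#' @param settings An [abc_settings()].
#' @param simulator Optional function `(k, s, q, settings)` returning a
#'   `tumor_state`, replacing the built-in engines.
#' @param fixed Named list of fixed two-species parameters
#'   (`k2`, `s_p`, `rho`), ignored for single-species data.
#' @return A `posterior_table`: data frame of accepted rows with columns
#'   `k`, `s`, `q`, `sigma`, `pair`, `sim`, `sim_seed`, plus attributes
#'   `settings`, `n_sims`, `acceptance_rate`, and `diagnostics`
#'   (per-region distance quantiles over all candidate pairs; useful when
#'   nothing is accepted).
#' @seealso [posterior_summary()]
#' @export
abc_rejection <- function(observed, prior, settings, simulator = NULL,
                          fixed = list()) {
  stopifnot(inherits(observed, "observed_patient_data"),
            inherits(prior, "prior_grid"),
            inherits(settings, "abc_settings"))
  two_species <- observed$n_species == 2L
  seed_rng(settings$seed)
  budget <- settings$budget

  draw_from <- function(v, w) v[sample.int(length(v), budget, replace = TRUE,
                                           prob = w)]
  draw_k <- draw_from(prior$k, prior$weights$k)
  draw_s <- draw_from(prior$s, prior$weights$s)
  draw_q <- draw_from(prior$q, prior$weights$q)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, budget)

  if (is.null(simulator)) {
    simulator <- if (two_species) {
      function(k, s, q, settings) {
        run_two_species(
          two_species_config(k1 = k, k2 = fixed$k2 %||% 0L,
                             s_p = fixed$s_p %||% s, s_m = s,
                             rho = fixed$rho %||% 0),
          sim_config(k = k, s = s, q = q, d = settings$d,
                     n_final = settings$n_final)
        )
      }
    } else {
      function(k, s, q, settings) {
        run_tumor(sim_config(k = k, s = s, q = q, d = settings$d,
                             n_final = settings$n_final))
      }
    }
  }

  n_core <- NROW(observed$core)
  n_margins_obs <- vapply(observed$margins, NROW, 1L)
  has_edge <- !is.null(observed$leading_edge)

  # every candidate core-margin pair, accepted or not (preallocated)
  n_cand_max <- budget * settings$margins_per_sim
  cv <- list(sigma = numeric(n_cand_max), max_w = numeric(n_cand_max),
             w_core = numeric(n_cand_max), w_margin = numeric(n_cand_max),
             delta_ok = logical(n_cand_max), gap_core = numeric(n_cand_max),
             pair = integer(n_cand_max), sim = integer(n_cand_max))
  n_cand <- 0L
  n_failed <- 0L

  for (b in seq_len(budget)) {
    set.seed(sim_seeds[b])
    state <- tryCatch(
      simulator(draw_k[b], draw_s[b], draw_q[b], settings),
      error = function(e) NULL
    )
    if (is.null(state) || state$extinct || state$n_cells < n_core) {
      n_failed <- n_failed + 1L
      next
    }
    core <- core_sample(state, n_core)
    obs_margin_of <- function(j) ((j - 1L) %% length(n_margins_obs)) + 1L
    margin_sizes <- n_margins_obs[vapply(seq_len(settings$margins_per_sim),
                                         obs_margin_of, 1L)]
    margins <- tryCatch(
      margin_samples(state, n = margin_sizes,
                     count = settings$margins_per_sim,
                     fraction = settings$margin_fraction),
      error = function(e) NULL
    )
    if (is.null(margins)) {
      n_failed <- n_failed + 1L
      next
    }
    edge <- if (has_edge) {
      leading_edge_sample(state, NROW(observed$leading_edge),
                          fraction = settings$edge_fraction)
    }

    dc <- abc_region_distance(core, observed$core, settings, two_species)
    de <- if (has_edge) {
      abc_region_distance(edge, observed$leading_edge, settings, two_species)
    }

    for (j in seq_len(settings$margins_per_sim)) {
      dm <- abc_region_distance(margins[[j]],
                                observed$margins[[obs_margin_of(j)]],
                                settings, two_species)
      parts <- list(dc, dm)
      if (has_edge) parts <- c(parts, list(de))
      n_cand <- n_cand + 1L
      cv$sigma[n_cand] <- sum(vapply(parts, function(p) sum(p$w), 0))
      cv$max_w[n_cand] <- max(vapply(parts, function(p) max(p$w), 0))
      cv$w_core[n_cand] <- max(dc$w)
      cv$w_margin[n_cand] <- max(dm$w)
      cv$delta_ok[n_cand] <- all(vapply(parts, function(p)
        all(p$gaps <= settings$delta_fraction), TRUE))
      cv$gap_core[n_cand] <- dc$gap
      cv$pair[n_cand] <- j
      cv$sim[n_cand] <- b
    }
  }

  idx <- seq_len(n_cand)
  cand <- data.frame(
    k = draw_k[cv$sim[idx]], s = draw_s[cv$sim[idx]], q = draw_q[cv$sim[idx]],
    sigma = cv$sigma[idx], max_w = cv$max_w[idx], w_core = cv$w_core[idx],
    w_margin = cv$w_margin[idx], delta_ok = cv$delta_ok[idx],
    gap_core = cv$gap_core[idx], pair = cv$pair[idx], sim = cv$sim[idx],
    sim_seed = sim_seeds[cv$sim[idx]]
  )
  if (is.null(settings$accept_fraction)) {
    keep <- cand$delta_ok & cand$max_w <= settings$eps_region
    eps_used <- settings$eps_region
  } else {
    n_keep <- ceiling(settings$accept_fraction *
                        budget * settings$margins_per_sim)
    eligible <- which(cand$delta_ok & is.finite(cand$max_w))
    ranked <- eligible[order(cand$max_w[eligible])]
    keep <- rep(FALSE, nrow(cand))
    keep[head(ranked, n_keep)] <- TRUE
    eps_used <- if (any(keep)) max(cand$max_w[keep]) else NA_real_
  }
  out <- cand[keep, c("k", "s", "q", "sigma", "pair", "sim", "sim_seed")]
  rownames(out) <- NULL
  qs <- function(x) if (length(x)) quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95)) else NULL
  structure(out, class = c("posterior_table", "data.frame"),
            settings = settings, n_sims = budget, n_failed = n_failed,
            eps_used = eps_used,
            acceptance_rate = nrow(out) /
              (budget * settings$margins_per_sim),
            diagnostics = list(
              core_wasserstein = qs(cand$w_core[cand$pair == 1]),
              margin_wasserstein = qs(cand$w_margin),
              core_fraction_gap = qs(cand$gap_core[cand$pair == 1])))
}

# per-region gates: vector of Wasserstein terms (one per species) and
# vector of fraction gaps (positive fraction; plus mixed fraction for two
# species), as used by the acceptance rule.
abc_region_distance <- function(sim, obs, settings, two_species) {
  if (!two_species) {
    d <- region_distance(sim, obs, settings$min_copy_filter)
    return(list(w = d$wasserstein, gaps = d$fraction_gap, gap = d$fraction_gap))
  }
  sim_counts <- sim$counts # matrix
  obs_counts <- obs
  if (nrow(sim_counts) != nrow(obs_counts)) {
    stop("simulated region is not size-matched to the observed region",
         call. = FALSE)
  }
  keep_s <- rowSums(sim_counts) >= settings$min_copy_filter
  keep_o <- rowSums(obs_counts) >= settings$min_copy_filter
  w <- vapply(1:2, function(sp) {
    a <- sim_counts[keep_s, sp]
    b <- obs_counts[keep_o, sp]
    if (length(a) == 0L || length(b) == 0L) Inf else wasserstein1d(a, b)
  }, 0)
  pos_gap <- abs(mean(rowSums(sim_counts) > 0) - mean(rowSums(obs_counts) > 0))
  mix_gap <- abs(mixed_fraction(sim_counts) - mixed_fraction(obs_counts))
  list(w = w, gaps = c(pos_gap, mix_gap), gap = pos_gap)
}

#' Summarize an ABC posterior
#'
#' Marginal point estimate and uncertainty interval per parameter: the
#' mode of the accepted values (the most frequent grid value) with an
#' asymmetric interval spanning the central 68% of accepted values,
#' reported as `mode - lo + hi`.
#'
#' @param post A `posterior_table` with at least one accepted row.
#' @return A `posterior_summary` data frame with columns `parameter`,
#'   `mode`, `lower`, `upper`, `n_accepted`.
#' @export
posterior_summary <- function(post) {
  stopifnot(inherits(post, "posterior_table"))
  if (nrow(post) == 0L) {
    stop("no accepted simulations: loosen the thresholds or raise the budget; see attr(post, 'diagnostics')",
         call. = FALSE)
  }
  one <- function(v, name) {
    tab <- table(v)
    mode <- as.numeric(names(tab)[which.max(tab)])
    ci <- unname(quantile(v, c(0.16, 0.84), type = 1))
    data.frame(parameter = name, mode = mode, lower = ci[1], upper = ci[2],
               n_accepted = length(v))
  }
  out <- rbind(one(post$k, "k"), one(post$s, "s"), one(post$q, "q"))
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("ABC posterior summary (mode, central 68% interval):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s = %g -%g +%g\n", x$parameter[i], x$mode[i],
                x$mode[i] - x$lower[i], x$upper[i] - x$mode[i]))
  }
  invisible(x)
}
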
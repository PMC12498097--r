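#' Configuration for wild-type plus variant ecDNA runs
#'
#' Parameterizes tumors carrying a wild-type oncogene on ecDNA (e.g.
#' EGFRwt) alongside an activating variant on the same ecDNA backbone
#' (e.g. EGFRvIII). The variant either exists in the founder cell
#' (`kvar > 0`, `vvar = 0`, "pre-expansion") or arises once the growing
#' population first reaches `vvar` cells, when one wild-type copy --
#' chosen with probability proportional to each cell's wild-type count --
#' is converted to a variant copy ("post-expansion"). Wild-type and
#' variant copies segregate binomially and independently at division.
#' Fitness follows the constant-selection rule with the variant dominant:
#' rate 1 for ecDNA-free cells, `1 + s_var` for cells with any variant
#' copy, `1 + s_wt` otherwise.
#'
#' @param kwt Founder wild-type copies.
#' @param kvar Founder variant copies.
#' @param vvar Population size at which the variant arises (0 = present at
#'   initiation via `kvar`).
#' @param s_wt Selection coefficient for cells with only wild-type copies.
#' @param s_var Selection coefficient for cells with any variant copy.
#' @param mu Per-copy per-replication mutation probability, used by
#'   [mutation_origin_distribution()].
#' @return A `variant_config` object.
#' @export
variant_config <- function(kwt, kvar = 0, vvar = 0, s_wt = 0, s_var = s_wt,
                           mu = 0) {
  kwt <- check_count(kwt, "kwt")
  kvar <- check_count(kvar, "kvar")
  vvar <- check_count(vvar, "vvar")
  stopifnot(s_wt > -1, s_var > -1, mu >= 0, mu <= 1)
  structure(list(kwt = kwt, kvar = kvar, vvar = vvar, s_wt = s_wt,
                 s_var = s_var, mu = mu),
            class = "variant_config")
}

#' Simulate a tumor with wild-type and variant ecDNA
#'
#' Runs the spatial engine (or its well-mixed limit) with two copy types
#' per cell under the rules described in [variant_config()].
#'
#' @param vc A [variant_config()].
#' @param config A [sim_config()]; its `k` and `s` fields are ignored in
#'   favor of the variant parameters, while `q`, `d`, `n_final`, `seed`,
#'   and `lattice_span` apply as usual.
#' @param engine `"lattice"` (spatial, default) or `"well_mixed"`.
#' @param check Verify per-event invariants (slow).
#' @return A `tumor_state` (or `well_mixed_pop`) whose `copies` matrix has
#'   columns `wt` and `variant`; `variant_arrival_n` records the
#'   population size at which a `vvar`-triggered mutation occurred.
#' @export
run_variant_sim <- function(vc, config, engine = c("lattice", "well_mixed"),
                            check = FALSE) {
  stopifnot(inherits(vc, "variant_config"), inherits(config, "sim_config"))
  engine <- match.arg(engine)
  if (vc$vvar > config$n_final) {
    stop("`vvar` exceeds `n_final`: the mutation size is never reached",
         call. = FALSE)
  }
  seed_used <- seed_rng(config$seed)
  if (engine == "lattice") {
    res <- cpp_run_lattice(
      k1 = vc$kwt, k2 = vc$kvar, model = 1L, s_a = vc$s_wt, s_b = vc$s_var,
      rho = 0, d = config$d, q_inf = is.infinite(config$q),
      q = if (is.infinite(config$q)) 0L else as.integer(config$q),
      n_final = config$n_final, span = config$lattice_span, vvar = vc$vvar,
      check = check
    )
    new_tumor_state(res, config, species = c("wt", "variant"),
                    seed_used = seed_used,
                    extra = list(variant_arrival_n = res$variant_arrival_n,
                                 variant_config = vc))
  } else {
    res <- cpp_run_wellmixed(
      k1 = vc$kwt, k2 = vc$kvar, model = 1L, s_a = vc$s_wt, s_b = vc$s_var,
      rho = 0, d = config$d, n_final = config$n_final, vvar = vc$vvar,
      record_history = TRUE, passage_n0 = 0L, passage_g = 0L,
      passage_rounds = 0L, check = check
    )
    new_well_mixed(res, species = c("wt", "variant"), seed_used = seed_used,
                   params = list(variant_config = vc, config = config))
  }
}

#' ecDNA heteroplasmy of a sample
#'
#' The percentage of all ecDNA copies in the sample that are wild type:
#' `100 * sum(wt) / sum(wt + variant)`.
#'
#' @param sample A `region_sample`, `tumor_state`, `well_mixed_pop`, or a
#'   two-column matrix with wild-type copies in the first column.
#' @return A percentage in `[0, 100]`.
#' @examples
#' heteroplasmy(cbind(wt = c(10, 10), variant = c(1, 1))) # 90.909...
#' @export
heteroplasmy <- function(sample) {
  counts <- if (inherits(sample, "region_sample")) sample$counts
            else if (inherits(sample, c("tumor_state", "well_mixed_pop"))) sample$copies
            else sample
  if (!is.matrix(counts) || ncol(counts) != 2L) {
    stop("heteroplasmy needs two copy types (wild type and variant)",
         call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) {
    stop("sample contains no ecDNA copies; heteroplasmy is undefined",
         call. = FALSE)
  }
  100 * sum(counts[, 1]) / total
}

#' Probability of detecting the variant in both core and margin
#'
#' The spatial covariegation probability: across replicate simulated
#' tumors, the fraction in which at least one sampled core cell AND at
#' least one sampled cell of one random margin region carry a variant
#' copy. Early-arising variants (small `vvar`) spread through the whole
#' tumor and are seen in both regions; late variants remain spatially
#' variegated and are frequently missed in one region.
#'
#' @param vc A [variant_config()].
#' @param config A [sim_config()] (its `seed` is ignored here).
#' @param n_sample Cells sampled per region.
#' @param replicates Number of replicate tumors.
#' @param seed Optional seed for the whole experiment.
#' @return List with `probability`, the per-replicate logical `detail`,
#'   and the number of `replicates`.
#' @export
covariegation_probability <- function(vc, config, n_sample = 500,
                                      replicates = 200, seed = NULL) {
  stopifnot(replicates >= 1)
  seed_rng(seed)
  cfg <- config
  cfg$seed <- NULL
  both <- vapply(seq_len(replicates), function(i) {
    st <- run_variant_sim(vc, cfg)
    core <- core_sample(st, n_sample)
    margin <- margin_samples(st, n_sample, count = 1)[[1]]
    any(core$counts[, "variant"] > 0) && any(margin$counts[, "variant"] > 0)
  }, TRUE)
  list(probability = mean(both), detail = both, replicates = replicates)
}

#' Wild-type abundance in the cell acquiring the first ecDNA mutation
#'
#' Simulates precancerous accumulation of wild-type ecDNA in a growing
#' (well-mixed) population in which every newly replicated copy mutates
#' with probability `mu`, and records, per replicate, the wild-type copy
#' number of the cell that ends up carrying the first variant copy. When
#' the mutation falls among the founder's `k` copies the recorded
#' abundance is `k - 1` (the remaining copy carries the variant); at a
#' later division it is the wild-type share inherited by the daughter that
#' receives the variant copy.
#'
#' @param k Initial wild-type copies in the founder.
#' @param s Selection coefficient of ecDNA-positive cells.
#' @param mu Per-copy per-replication mutation probability.
#' @param n_final Population size at which a replicate gives up.
#' @param replicates Number of replicates.
#' @param seed Optional seed.
#' @return List with `values` (wild-type abundances over replicates in
#'   which a mutation occurred), `n_no_mutation`, and `replicates`.
#' @export
mutation_origin_distribution <- function(k, s, mu, n_final = 1000,
                                         replicates = 500, seed = NULL) {
  k <- check_count(k, "k")
  stopifnot(mu >= 0, mu <= 1, s > -1)
  seed_rng(seed)
  raw <- cpp_mutation_origin(k, s, mu, as.integer(n_final),
                             as.integer(replicates))
  list(values = raw[!is.na(raw)], n_no_mutation = sum(is.na(raw)),
       replicates = replicates)
}
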
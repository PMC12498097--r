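COPY_TABLE_SCHEMA <- "ecdnasim_copy_table_v1"
COPY_TABLE_COLS <- c("tumor_id", "region", "replicate", "cell_id", "copies")
REGION_LEVELS <- c("core", "margin", "leading_edge")

#' Validate a per-cell copy-number table
#'
#' The interchange format for per-cell ecDNA counts (standing in for
#' QuPath-style per-nucleus FISH foci exports): one row per cell with
#' columns `tumor_id`, `region` (core / margin / leading_edge),
#' `replicate`, `cell_id`, `copies`, and optionally `copies2` for a
#' second ecDNA species.
#'
#' @param df A data frame with the required columns. A missing `replicate`
#'   column (as in single-measurement patient exports) defaults to 1.
#' @return The validated data frame with class `copy_table`.
#' @export
as_copy_table <- function(df) {
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  missing_cols <- setdiff(COPY_TABLE_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- validate_copy_rows(df)
  if (length(bad$which)) {
    stop(sprintf("invalid rows (%s) at line(s): %s",
                 bad$reason, paste(head(bad$which, 10), collapse = ", ")),
         call. = FALSE)
  }
  class(df) <- c("copy_table", "data.frame")
  df
}

validate_copy_rows <- function(df) {
  count_cols <- intersect(c("copies", "copies2"), names(df))
  for (cc in count_cols) {
    v <- df[[cc]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) return(list(which = bad, reason = paste0("negative or non-integer ", cc)))
  }
  bad <- which(!df$region %in% REGION_LEVELS)
  if (length(bad)) return(list(which = bad, reason = "unknown region label"))
  key <- paste(df$tumor_id, df$region, df$replicate, df$cell_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) return(list(which = dup, reason = "duplicate cell_id within region"))
  list(which = integer(0), reason = NULL)
}

#' Write / read a copy table
#'
#' Plain CSV with a one-line schema header comment; `write_copy_table()`
#' followed by [read_copy_table()] round-trips the table exactly.
#' Malformed rows are rejected with their file line numbers.
#'
#' @param table A `copy_table` (or coercible data frame).
#' @param path File path.
#' @return `read_copy_table()` returns a `copy_table`;
#'   `write_copy_table()` returns `path` invisibly.
#' @export
write_copy_table <- function(table, path) {
  table <- as_copy_table(as.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", COPY_TABLE_SCHEMA), con)
  write.csv(table, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_copy_table
#' @export
read_copy_table <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  missing_cols <- setdiff(COPY_TABLE_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- validate_copy_rows(df)
  if (length(bad$which)) {
    # +2 for the schema comment and the header line
    stop(sprintf("%s: invalid rows (%s) at line(s): %s", path, bad$reason,
                 paste(head(bad$which + 2L, 10), collapse = ", ")),
         call. = FALSE)
  }
  class(df) <- c("copy_table", "data.frame")
  df
}

# assemble a copy_table from region samples (list of region_sample; margin
# replicate numbering follows list order)
copy_table_from_samples <- function(samples, tumor_id) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    counts <- s$counts
    if (is.matrix(counts)) {
      data.frame(tumor_id = tumor_id, region = s$label,
                 replicate = attr(s, "replicate") %||% 1L,
                 cell_id = seq_len(nrow(counts)),
                 copies = counts[, 1], copies2 = counts[, 2])
    } else {
      data.frame(tumor_id = tumor_id, region = s$label,
                 replicate = attr(s, "replicate") %||% 1L,
                 cell_id = seq_along(counts), copies = counts)
    }
  })
  as_copy_table(do.call(rbind, rows))
}

#' Convert a copy table to per-region observed data
#'
#' Groups a [as_copy_table()] table for one tumor into the
#' [observed_patient_data()] structure consumed by [abc_rejection()].
#'
#' @param table A `copy_table`.
#' @param tumor_id Which tumor to extract (default: the only one present).
#' @return An `observed_patient_data`.
#' @export
observed_from_table <- function(table, tumor_id = NULL) {
  table <- as_copy_table(as.data.frame(table))
  ids <- unique(table$tumor_id)
  if (is.null(tumor_id)) {
    if (length(ids) > 1L) stop("multiple tumors present; give `tumor_id`",
                               call. = FALSE)
    tumor_id <- ids[1]
  }
  tb <- table[table$tumor_id == tumor_id, , drop = FALSE]
  two <- "copies2" %in% names(tb)
  grab <- function(sub) {
    if (two) cbind(sub$copies, sub$copies2) else sub$copies
  }
  core <- grab(tb[tb$region == "core", , drop = FALSE])
  mar <- tb[tb$region == "margin", , drop = FALSE]
  margins <- lapply(split(mar, mar$replicate), grab)
  edge_rows <- tb[tb$region == "leading_edge", , drop = FALSE]
  observed_patient_data(
    core = core, margins = unname(margins),
    leading_edge = if (nrow(edge_rows)) grab(edge_rows),
    tumor_id = tumor_id
  )
}

#' Generate a synthetic patient with known ground truth
#'
#' Simulates one tumor under known parameters and samples its regions at
#' requested sizes, producing observed-style data whose generating truth
#' is recorded alongside -- the workhorse for parameter-recovery
#' experiments, since real per-cell FISH tables carry no ground truth.
#' No copy filtering is applied here; filtering is the consumer's job.
#'
#' @param truth Named list of generating parameters. `list(k=, s=, q=)`
#'   for a single species; add `kwt`, `kvar`, `vvar`, `s_wt`, `s_var` for
#'   wild-type/variant runs, or `k1`, `k2`, `s_p`, `s_m`, `rho` for two
#'   species. Optional `d` (death rate, default 0).
#' @param sizes List with `core` (cells in the core sample), `margins`
#'   (vector of margin sample sizes, one per margin), and optionally
#'   `leading_edge`.
#' @param n_final Simulated tumor size.
#' @param seed Seed; retries after extinction increment it.
#' @param tumor_id Identifier written into the table.
#' @param dir Optional directory: when given, writes `<tumor_id>.csv`
#'   (the copy table) and `<tumor_id>_truth.yaml` (truth parameters, seed
#'   used, and the table's md5 checksum).
#' @param max_retries Attempts before giving up on an extinct lineage.
#' @return A `synthetic_patient`: list with `truth`, `observed`
#'   ([observed_patient_data()]), `table` (`copy_table`), `state` (the
#'   simulated `tumor_state`), `seed` (the seed that produced it), and
#'   `retries`.
#' @export
generate_synthetic_patient <- function(truth,
                                       sizes = list(core = 1000, margins = 1000),
                                       n_final = 10000, seed = NULL,
                                       tumor_id = "synthetic_patient",
                                       dir = NULL, max_retries = 10) {
  seed <- if (is.null(seed)) sample.int(1e6, 1) else check_count(seed, "seed")
  d <- truth$d %||% 0
  model <- if (!is.null(truth$k1)) "two_species" else
           if (!is.null(truth$kwt)) "variant" else "single"
  retries <- 0L
  state <- NULL
  for (attempt in seq_len(max_retries)) {
    use_seed <- seed + retries
    cfg <- sim_config(k = truth$k %||% 0L, s = truth$s %||% 0,
                      q = truth$q %||% Inf, d = d, n_final = n_final,
                      seed = use_seed)
    state <- switch(model,
      single = run_tumor(cfg),
      variant = run_variant_sim(
        variant_config(kwt = truth$kwt, kvar = truth$kvar %||% 0,
                       vvar = truth$vvar %||% 0, s_wt = truth$s_wt %||% 0,
                       s_var = truth$s_var %||% truth$s_wt %||% 0),
        cfg),
      two_species = run_two_species(
        two_species_config(k1 = truth$k1, k2 = truth$k2 %||% 0,
                           s_p = truth$s_p %||% 0,
                           s_m = truth$s_m %||% truth$s_p %||% 0,
                           rho = truth$rho %||% 0),
        cfg)
    )
    if (!state$extinct) break
    retries <- retries + 1L
  }
  if (state$extinct) {
    stop(sprintf("population went extinct in all %d attempts", max_retries),
         call. = FALSE)
  }

  core <- core_sample(state, sizes$core)
  margins <- margin_samples(state, n = sizes$margins,
                            count = length(sizes$margins))
  margins <- lapply(seq_along(margins), function(i) {
    attr(margins[[i]], "replicate") <- i
    margins[[i]]
  })
  samples <- c(list(core), margins)
  if (!is.null(sizes$leading_edge)) {
    samples <- c(samples, list(leading_edge_sample(state, sizes$leading_edge)))
  }
  table <- copy_table_from_samples(samples, tumor_id)
  out <- structure(
    list(truth = truth, observed = observed_from_table(table),
         table = table, state = state, seed = use_seed, retries = retries,
         n_final = n_final),
    class = "synthetic_patient"
  )
  if (!is.null(dir)) write_synthetic_patient(out, dir)
  out
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s (seed %d, %d retries)\n",
              x$table$tumor_id[1], x$seed, x$retries))
  cat("  truth:", paste(names(x$truth), unlist(x$truth), sep = "=",
                        collapse = ", "), "\n")
  print(x$observed)
  invisible(x)
}

write_synthetic_patient <- function(sp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- sp$table$tumor_id[1]
  data_path <- file.path(dir, paste0(id, ".csv"))
  write_copy_table(sp$table, data_path)
  sidecar <- list(truth = sp$truth, seed = sp$seed, n_final = sp$n_final,
                  data_file = basename(data_path),
                  data_md5 = unname(tools::md5sum(data_path)))
  yaml::write_yaml(sidecar, file.path(dir, paste0(id, "_truth.yaml")))
  invisible(data_path)
}

#' Export / import a full tumor snapshot
#'
#' Lossless round trip of a simulated tumor's occupancy and per-cell copy
#' counts as tab-separated text: `#`-prefixed header lines echo the
#' configuration, seed, founder site, and elapsed time, followed by one
#' row per cell with columns `x`, `y`, `copies_species1`
#' (and `copies_species2` for two-species states).
#'
#' @param state A `tumor_state`.
#' @param path File path.
#' @return `import_grid_snapshot()` returns the reconstructed
#'   `tumor_state`; `export_grid_snapshot()` returns `path` invisibly.
#' @export
export_grid_snapshot <- function(state, path) {
  stopifnot(inherits(state, "tumor_state"))
  cfg <- state$config
  hdr <- c(
    "# ecdnasim_grid_snapshot_v1",
    sprintf("# k=%d s=%g q=%s d=%g n_final=%d lattice_span=%d", cfg$k, cfg$s,
            if (is.infinite(cfg$q)) "inf" else format(cfg$q), cfg$d,
            cfg$n_final, cfg$lattice_span),
    sprintf("# seed=%s time=%.10g founder=%d,%d species=%s",
            if (is.na(state$seed)) "NA" else format(state$seed), state$time,
            state$founder_site[1], state$founder_site[2],
            paste(colnames(state$copies), collapse = ","))
  )
  df <- data.frame(x = state$x, y = state$y)
  for (i in seq_len(ncol(state$copies))) {
    df[[paste0("copies_species", i)]] <- state$copies[, i]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_grid_snapshot
#' @export
import_grid_snapshot <- function(path) {
  lines <- readLines(path, n = 5)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- function(key, text) {
    m <- regmatches(text, regexpr(paste0(" ", key, "=[^ ]+"), text))
    if (length(m)) sub(paste0(" ", key, "="), "", m) else NA_character_
  }
  meta <- paste(hdr, collapse = " ")
  df <- read.csv(path, sep = "\t", comment.char = "#",
                 stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("x", "y")])) {
    stop("snapshot contains overlapping coordinates", call. = FALSE)
  }
  qv <- kv("q", meta)
  cfg <- sim_config(
    k = as.integer(kv("k", meta)), s = as.numeric(kv("s", meta)),
    q = if (qv == "inf") Inf else as.numeric(qv),
    d = as.numeric(kv("d", meta)), n_final = as.integer(kv("n_final", meta)),
    lattice_span = as.integer(kv("lattice_span", meta))
  )
  species <- strsplit(kv("species", meta), ",")[[1]]
  copy_cols <- grep("^copies_species", names(df), value = TRUE)
  res <- list(
    x = df$x, y = df$y,
    copies1 = df[[copy_cols[1]]],
    copies2 = if (length(copy_cols) > 1) df[[copy_cols[2]]] else
      rep(0L, nrow(df)),
    time = as.numeric(kv("time", meta)), n_cells = nrow(df),
    extinct = nrow(df) == 0L, events = NA_real_, blocked = NA_real_
  )
  seed_txt <- kv("seed", meta)
  new_tumor_state(res, cfg, species = species,
                  seed_used = if (seed_txt == "NA") NA_integer_ else
                    as.integer(seed_txt))
}
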
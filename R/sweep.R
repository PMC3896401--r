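#' Specify a replicate sweep over a parameter grid
#'
#' @param base A [sim_params()] object giving the fixed parameters.
#' @param varied Named list mapping parameter names (any [sim_params()]
#'   argument, e.g. `m`, `r`, `p0`, `scenario`, `boundary_duration`) to the
#'   values to cross. The full factorial grid is run. May be empty for a
#'   plain replicated run of `base`.
#' @param n_replicates Independent replicates per parameter combination.
#'   Desk-scale default 10; published-style runs use 100.
#' @param base_seed Replicate `i` of every combination runs with seed
#'   `base_seed + i - 1`, so matched replicates across combinations share
#'   seeds and a sweep is fully reproducible.
#' @param output_dir Directory to write per-combination tables into, or `NULL`
#'   to keep results in memory only.
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(base, varied = list(), n_replicates = 10,
                       base_seed = 1, output_dir = NULL) {
  stopifnot(inherits(base, "sim_params"), is.list(varied))
  if (length(varied)) {
    ok <- names(varied) %in% names(formals(sim_params))
    if (is.null(names(varied)) || !all(ok))
      stop("varied names must be sim_params arguments; offending: ",
           paste(names(varied)[!ok], collapse = ", "), call. = FALSE)
  }
  stop_unless(is_count(n_replicates) && n_replicates >= 1,
              "n_replicates must be a positive integer")
  structure(list(base = base, varied = varied,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 output_dir = output_dir),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  n_combo <- if (length(x$varied)) prod(lengths(x$varied)) else 1L
  cat(sprintf("Sweep: %d combination(s) x %d replicate(s), base seed %d\n",
              n_combo, x$n_replicates, x$base_seed))
  for (nm in names(x$varied))
    cat("  ", nm, ": ", paste(x$varied[[nm]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

params_args <- function(params) {
  a <- unclass(params)
  a[!vapply(a, is.null, logical(1))]
}

combo_grid <- function(varied) {
  if (!length(varied)) return(data.frame(row.names = 1L))
  expand.grid(varied, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

combo_label <- function(grid_row) {
  if (!ncol(grid_row)) return("base")
  paste(sprintf("%s=%s", names(grid_row), vapply(grid_row, format, character(1))),
        collapse = "_")
}

#' Run a replicate sweep
#'
#' Runs `n_replicates` independent simulations for every combination of the
#' varied parameters, computes [front_stats_table()] on each run's frozen
#' records, and averages the statistics per column across replicates.
#' Deterministic given `base_seed`. If the spec names an `output_dir`, each
#' combination gets a subdirectory with `replicates.tsv` (per-replicate
#' per-column statistics), `averaged.tsv`, and `manifest.json` recording the
#' exact parameters, seeds and per-replicate expansion times.
#'
#' @param spec A [sweep_spec()].
#' @param stop_when_complete Forwarded to [run_simulation()].
#' @return A `sweep_result`: list of per-combination results, each holding
#'   `params`, `label`, `replicates` (data.frame), `averaged` (data.frame),
#'   `expansion_time` (per-replicate vector) and `mean_expansion_time`.
#' @examples
#' base <- sim_params(n_rows = 11, n_cols = 30, K = 30, max_generations = 300)
#' res <- run_sweep(sweep_spec(base, list(m = c(0.1, 0.4)), n_replicates = 2))
#' names(res$combinations)
#' @export
run_sweep <- function(spec, stop_when_complete = TRUE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- combo_grid(spec$varied)
  n_combo <- nrow(grid)
  out <- vector("list", n_combo)
  labels <- character(n_combo)
  base_args <- params_args(spec$base)
  base_args$seed <- NULL

  for (ci in seq_len(n_combo)) {
    args <- base_args
    for (nm in names(grid)) args[[nm]] <- grid[[nm]][ci]
    if (identical(args$scenario, "BLRE") && is.null(args$boundary_duration))
      stop("BLRE combinations need a boundary_duration", call. = FALSE)
    label <- combo_label(grid[ci, , drop = FALSE])
    labels[ci] <- label

    reps <- vector("list", spec$n_replicates)
    etimes <- rep(NA_integer_, spec$n_replicates)
    seeds <- spec$base_seed + seq_len(spec$n_replicates) - 1L
    for (i in seq_len(spec$n_replicates)) {
      args$seed <- seeds[i]
      params <- do.call(sim_params, args)
      run <- tryCatch(
        run_simulation(params, stop_when_complete = stop_when_complete),
        error = function(e) stop(sprintf(
          "replicate %d (seed %d) of combination '%s' failed: %s",
          i, seeds[i], label, conditionMessage(e)), call. = FALSE))
      st <- front_stats_table(run)
      if (nrow(st)) st$replicate <- i
      reps[[i]] <- st
      etimes[i] <- run$expansion_time
    }
    replicates <- do.call(rbind, reps)
    averaged <- average_replicates(replicates)
    args$seed <- NULL
    combo <- list(params = do.call(sim_params, args), label = label,
                  replicates = replicates, averaged = averaged,
                  expansion_time = etimes,
                  mean_expansion_time = if (all(is.na(etimes))) NA_real_
                                        else mean(etimes, na.rm = TRUE))
    out[[ci]] <- combo
    if (!is.null(spec$output_dir))
      write_combo(spec$output_dir, combo, seeds)
  }
  names(out) <- labels
  structure(list(spec = spec, grid = grid, combinations = out),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep result: %d combination(s), %d replicate(s) each\n",
              length(x$combinations), x$spec$n_replicates))
  for (co in x$combinations)
    cat(sprintf("  %s: mean expansion_time %s over %d replicate(s)\n",
                co$label, format(co$mean_expansion_time),
                sum(!is.na(co$expansion_time))))
  invisible(x)
}

#' Average per-column front statistics across replicates
#'
#' For every `column_index` present, computes the mean and standard deviation
#' of each statistic over replicates. `NA` entries (e.g. `mean_cline_width`
#' for a replicate whose column has no cline) are dropped from the average and
#' the contributing count is recorded.
#'
#' @param replicates Data.frame as produced inside [run_sweep()]: the
#'   row-bound [front_stats_table()]s of the replicates.
#' @return Data.frame keyed by `column_index` with `<stat>_mean`,
#'   `<stat>_sd`, `<stat>_n` columns plus `n_replicates_recorded`.
#' @export
average_replicates <- function(replicates) {
  stats_cols <- c("generation_recorded", "n_domains", "n_clines",
                  "mean_domain_width", "mean_cline_width",
                  "PX", "PXY", "Pc", "fbar")
  if (is.null(replicates) || !nrow(replicates)) {
    empty <- data.frame(column_index = integer(0), n_replicates_recorded = integer(0))
    for (s in stats_cols)
      for (suf in c("_mean", "_sd", "_n")) empty[[paste0(s, suf)]] <- numeric(0)
    return(empty)
  }
  pieces <- lapply(split(replicates, replicates$column_index), function(d) {
    row <- data.frame(column_index = d$column_index[1L],
                      n_replicates_recorded = length(unique(d$replicate)))
    for (s in stats_cols) {
      v <- d[[s]][!is.na(d[[s]])]
      row[[paste0(s, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(s, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
      row[[paste0(s, "_n")]] <- length(v)
    }
    row
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$column_index), ]
  rownames(out) <- NULL
  out
}

write_combo <- function(dir, combo, seeds) {
  d <- file.path(dir, combo$label)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(combo$replicates, file.path(d, "replicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(combo$averaged, file.path(d, "averaged.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(params = params_args(combo$params), seeds = seeds,
                   expansion_time = combo$expansion_time,
                   mean_expansion_time = combo$mean_expansion_time)
  jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(d)
}
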
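#' Run one replicate simulation
#'
#' Evolves the lattice from [init_state()] for up to `max_generations`
#' generations, capturing a frozen record of every column beyond the founding
#' block at the first generation (evaluated after culling) at which all of its
#' demes simultaneously sit exactly at carrying capacity. For the stationary
#' scenario, the last suitable column is additionally snapshotted at
#' `snapshot_generations`.
#'
#' @param params A [sim_params()] object. If `params$seed` is set, the RNG is
#'   seeded at the start of the run so the replicate is fully reproducible.
#' @param stop_when_complete Stop iterating once every column has its frozen
#'   record (and, for the stationary scenario, once the last snapshot is
#'   taken): no later generation can alter any recorded output, only the final
#'   lattice state. Set to `FALSE` to run out the full generation budget.
#' @param log_every Emit a progress line (generation, occupied columns, total
#'   individuals, recorded columns) to stderr every `log_every` generations;
#'   0 (default) disables logging.
#' @return An object of class `sim_run`: list with
#'   \describe{
#'     \item{`params`}{the input parameters;}
#'     \item{`freq`}{`n_rows x n_cols` matrix of frozen-record allele-A
#'       frequencies (`NA` for unrecorded columns, including the founding
#'       block);}
#'     \item{`generation_recorded`}{length-`n_cols` integer vector (`NA` where
#'       no record);}
#'     \item{`expansion_time`}{first generation at which every column beyond
#'       the founding block has been recorded, or `NA` if the expansion never
#'       completed;}
#'     \item{`snapshots`}{for the stationary scenario, a named list (one entry
#'       per snapshot generation) of allele-A frequency vectors of the
#'       stationary-front column;}
#'     \item{`final_state`}{the `lattice_state` at the last simulated
#'       generation.}
#'   }
#' @examples
#' run <- run_simulation(sim_params(n_rows = 11, n_cols = 30, K = 30,
#'                                  max_generations = 400, seed = 1))
#' run$expansion_time
#' @export
run_simulation <- function(params, stop_when_complete = TRUE, log_every = 0) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  schedule <- habitat_schedule(params)
  state <- init_state(params)

  n_cols <- params$n_cols
  n_rows <- params$n_rows
  track <- (params$n_init_cols + 1L) <= n_cols
  pending <- if (track) seq.int(params$n_init_cols + 1L, n_cols) else integer(0)
  gen_recorded <- rep(NA_integer_, n_cols)
  freq <- matrix(NA_real_, n_rows, n_cols)
  expansion_time <- NA_integer_

  stationary <- params$scenario == "stationary"
  snapshots <- if (stationary) {
    stats::setNames(vector("list", length(params$snapshot_generations)),
                    paste0("generation_", params$snapshot_generations))
  }
  snap_pending <- params$snapshot_generations

  for (g in seq_len(params$max_generations)) {
    state <- step_generation(state, params, schedule)

    if (length(pending)) {
      tot <- state$nA[, pending, drop = FALSE] + state$na[, pending, drop = FALSE]
      full <- pending[colSums(tot == params$K) == n_rows]
      if (length(full)) {
        gen_recorded[full] <- g
        freq[, full] <- state$nA[, full, drop = FALSE] / params$K
        pending <- setdiff(pending, full)
        if (!length(pending)) expansion_time <- g
      }
    }
    if (stationary && length(snap_pending) && g == snap_pending[1L]) {
      jc <- params$n_init_cols
      tot <- state$nA[, jc] + state$na[, jc]
      snapshots[[paste0("generation_", g)]] <- ifelse(tot > 0, state$nA[, jc] / tot, NA_real_)
      snap_pending <- snap_pending[-1L]
    }

    if (log_every > 0 && g %% log_every == 0) {
      tot_all <- state$nA + state$na
      message(sprintf(
        "generation %d: %d occupied columns, %d individuals, %d columns recorded",
        g, sum(colSums(tot_all) > 0), sum(tot_all),
        sum(!is.na(gen_recorded))))
    }

    if (stop_when_complete) {
      done <- if (stationary) length(snap_pending) == 0L else length(pending) == 0L
      if (done) break
    }
  }

  structure(list(
    params = params,
    freq = freq,
    generation_recorded = gen_recorded,
    expansion_time = expansion_time,
    snapshots = snapshots,
    final_state = state
  ), class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("Simulation run (%s): %d x %d lattice, K = %d, r = %g, m = %g\n",
              x$params$scenario, x$params$n_rows, x$params$n_cols,
              x$params$K, x$params$r, x$params$m))
  nrec <- sum(!is.na(x$generation_recorded))
  cat(sprintf("  %d frozen-record columns; expansion_time = %s; final generation %d\n",
              nrec,
              if (is.na(x$expansion_time)) "not reached" else x$expansion_time,
              x$final_state$generation))
  invisible(x)
}

#' Frozen records as a long-format table
#'
#' @param run A `sim_run` object.
#' @param replicate Optional replicate label stored in the first column.
#' @return A data.frame with columns `replicate`, `column_index`,
#'   `generation_recorded`, `row_index`, `frequency` (one row per deme of each
#'   recorded column; stationary snapshots are included with the snapshot
#'   generation as `generation_recorded`).
#' @export
frozen_records_table <- function(run, replicate = 1L) {
  stopifnot(inherits(run, "sim_run"))
  cols <- which(!is.na(run$generation_recorded))
  n_rows <- run$params$n_rows
  out <- if (length(cols)) {
    data.frame(
      replicate = replicate,
      column_index = rep(cols, each = n_rows),
      generation_recorded = rep(run$generation_recorded[cols], each = n_rows),
      row_index = rep.int(seq_len(n_rows), length(cols)),
      frequency = as.vector(run$freq[, cols, drop = FALSE])
    )
  } else {
    data.frame(replicate = integer(0), column_index = integer(0),
               generation_recorded = integer(0), row_index = integer(0),
               frequency = numeric(0))
  }
  if (!is.null(run$snapshots) && length(run$snapshots)) {
    gens <- as.integer(sub("generation_", "", names(run$snapshots)))
    snap <- data.frame(
      replicate = replicate,
      column_index = rep(run$params$n_init_cols, n_rows * length(gens)),
      generation_recorded = rep(gens, each = n_rows),
      row_index = rep.int(seq_len(n_rows), length(gens)),
      frequency = unlist(run$snapshots, use.names = FALSE)
    )
    out <- rbind(out, snap)
  }
  out
}
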
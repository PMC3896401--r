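#' Habitat schedule for a simulation scenario
#'
#' Describe which lattice columns are suitable habitat at each generation.
#' Suitability only ever grows, column by column from the left edge:
#' \itemize{
#'   \item PhLRE: all `n_cols` columns suitable at every generation;
#'   \item stationary: the first `n_init_cols` columns suitable forever;
#'   \item BLRE: `n_init_cols` columns at generation 0, then columns open at
#'     evenly spaced times so that
#'     `n_suitable(g) = n_init_cols + floor((n_cols - n_init_cols) * g / boundary_duration)`,
#'     capped at `n_cols`.
#' }
#'
#' @param params A [sim_params()] object.
#' @return An object of class `habitat_schedule`.
#' @examples
#' sched <- habitat_schedule(sim_params(scenario = "BLRE", boundary_duration = 6000))
#' n_suitable_cols(sched, 3000)  # 110
#' @export
habitat_schedule <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  structure(list(
    scenario = params$scenario,
    n_cols = params$n_cols,
    n_init_cols = params$n_init_cols,
    boundary_duration = params$boundary_duration
  ), class = "habitat_schedule")
}

#' Number of suitable columns at a generation
#'
#' @param schedule A [habitat_schedule()] object.
#' @param generation Non-negative integer generation (vectorised).
#' @return Integer vector: suitable columns `1..n` at each generation.
#' @export
n_suitable_cols <- function(schedule, generation) {
  stopifnot(inherits(schedule, "habitat_schedule"), all(generation >= 0))
  switch(schedule$scenario,
    PhLRE = rep.int(schedule$n_cols, length(generation)),
    stationary = rep.int(schedule$n_init_cols, length(generation)),
    BLRE = {
      extra <- floor((schedule$n_cols - schedule$n_init_cols) * generation /
                       schedule$boundary_duration)
      as.integer(pmin(schedule$n_init_cols + extra, schedule$n_cols))
    }
  )
}

#' @export
print.habitat_schedule <- function(x, ...) {
  cat("Habitat schedule:", x$scenario, "\n")
  cat(sprintf("  %d columns; %d suitable at generation 0\n", x$n_cols,
              n_suitable_cols(x, 0L)))
  if (x$scenario == "BLRE")
    cat(sprintf("  fully suitable from generation %d\n", x$boundary_duration))
  invisible(x)
}
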
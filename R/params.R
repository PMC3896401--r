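#' Simulation parameters
#'
#' Bundle and validate the parameters of a single lattice simulation.
#'
#' The model is a rectangular lattice of demes, each holding haploid
#' individuals typed at one neutral diallelic locus (alleles `A` and `a`).
#' Every generation applies, in order: reproduction (independent Poisson
#' offspring with mean `r` per individual, only in suitable habitat; parents
#' die), migration (each individual leaves its deme with probability `m`,
#' destination uniform over the orthogonally adjacent demes), and culling
#' (demes above the carrying capacity `K` are thinned to exactly `K` by
#' uniform removal).
#'
#' Three habitat scenarios are supported:
#' \describe{
#'   \item{`"PhLRE"`}{phenotype-limited range expansion: the whole lattice is
#'     suitable from generation 0; expansion speed is set by `r` and `m`.}
#'   \item{`"BLRE"`}{boundary-limited range expansion: only the first
#'     `n_init_cols` columns are suitable at generation 0 and the remaining
#'     columns become suitable one by one, linearly in time, so that the whole
#'     lattice is suitable after `boundary_duration` generations.}
#'   \item{`"stationary"`}{the habitat never grows beyond the initial
#'     `n_init_cols` columns; the last suitable column is the "stationary
#'     front" reference.}
#' }
#'
#' @param n_rows Number of lattice rows; must be odd (the spectral statistic
#'   assumes an odd column length). Default 75.
#' @param n_cols Number of lattice columns. Default 200.
#' @param K Carrying capacity per deme (individuals). Default 100.
#' @param r Mean offspring number per individual per generation. Default 3.
#' @param m Per-individual emigration probability per generation, in `[0, 1]`.
#'   Default 0.2.
#' @param p0 Initial frequency of allele `A` in the founding columns, in
#'   `[0, 1]`. Default 0.5.
#' @param n_init_cols Number of initially occupied columns at the left edge.
#'   Default 20.
#' @param max_generations Number of generations to simulate. Default 8000.
#' @param scenario One of `"PhLRE"`, `"BLRE"`, `"stationary"`.
#' @param migration_model Convention for the per-individual migration
#'   probability. `"m_over_n"` (default): an individual with `n` orthogonally
#'   adjacent demes migrates with probability `m / n`, the destination uniform
#'   over those `n` demes. `"total_m"`: every individual migrates with total
#'   probability `m` regardless of position (per-neighbor probability
#'   `m / n`). See the methods vignette for how the default was fixed.
#' @param boundary_duration BLRE only: generations for the whole lattice to
#'   become suitable.
#' @param snapshot_generations Stationary scenario only: generations at which
#'   the last suitable column is snapshotted (default: `max_generations`).
#' @param seed Integer RNG seed for the replicate, or `NULL` to use the
#'   current RNG state.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' sim_params(scenario = "BLRE", boundary_duration = 6000, seed = 1)
#' @export
sim_params <- function(n_rows = 75, n_cols = 200, K = 100, r = 3, m = 0.2,
                       p0 = 0.5, n_init_cols = 20, max_generations = 8000,
                       scenario = c("PhLRE", "BLRE", "stationary"),
                       migration_model = c("m_over_n", "total_m"),
                       boundary_duration = NULL,
                       snapshot_generations = NULL,
                       seed = NULL) {
  scenario <- match.arg(scenario)
  migration_model <- match.arg(migration_model)
  stop_unless(is_count(n_rows) && n_rows >= 1, "n_rows must be a positive integer")
  stop_unless(n_rows %% 2 == 1, "n_rows must be odd (spectral statistic convention)")
  stop_unless(is_count(n_cols) && n_cols >= 1, "n_cols must be a positive integer")
  stop_unless(is_count(K) && K >= 1, "K must be a positive integer")
  stop_unless(is.numeric(r) && length(r) == 1 && r >= 0, "r must be a non-negative number")
  stop_unless(is.numeric(m) && length(m) == 1 && m >= 0 && m <= 1, "m must lie in [0, 1]")
  stop_unless(is.numeric(p0) && length(p0) == 1 && p0 >= 0 && p0 <= 1, "p0 must lie in [0, 1]")
  stop_unless(is_count(n_init_cols) && n_init_cols >= 1 && n_init_cols <= n_cols,
              "n_init_cols must lie in [1, n_cols]")
  stop_unless(is_count(max_generations) && max_generations >= 0,
              "max_generations must be a non-negative integer")
  if (scenario == "BLRE") {
    stop_unless(is_count(boundary_duration) && boundary_duration >= 1,
                "boundary_duration must be a positive integer for BLRE")
  } else {
    boundary_duration <- NULL
  }
  if (scenario == "stationary") {
    if (is.null(snapshot_generations)) snapshot_generations <- max_generations
    stop_unless(all(vapply(snapshot_generations, is_count, logical(1))) &&
                  all(snapshot_generations >= 0),
                "snapshot_generations must be non-negative integers")
    snapshot_generations <- sort(unique(as.integer(snapshot_generations)))
  } else {
    snapshot_generations <- NULL
  }
  if (!is.null(seed)) {
    stop_unless(is_count(abs(seed)), "seed must be an integer")
    seed <- as.integer(seed)
  }

  nA0 <- round(p0 * K)
  if (abs(nA0 - p0 * K) > 1e-9) {
    warning(sprintf("p0 * K = %g is not an integer; initial allele-A count rounded to %d",
                    p0 * K, as.integer(nA0)))
  }

  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    K = as.integer(K), r = r, m = m, p0 = p0,
    n_init_cols = as.integer(n_init_cols),
    max_generations = as.integer(max_generations),
    scenario = scenario,
    migration_model = migration_model,
    boundary_duration = if (is.null(boundary_duration)) NULL else as.integer(boundary_duration),
    snapshot_generations = snapshot_generations,
    seed = seed
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Lattice simulation parameters (", x$scenario, ")\n", sep = "")
  cat(sprintf("  lattice: %d rows x %d cols, %d founding columns\n",
              x$n_rows, x$n_cols, x$n_init_cols))
  cat(sprintf("  K = %d, r = %g, m = %g (%s), p0 = %g\n", x$K, x$r, x$m,
              x$migration_model, x$p0))
  cat(sprintf("  generations: %d", x$max_generations))
  if (!is.null(x$boundary_duration))
    cat(sprintf(", boundary motion over %d generations", x$boundary_duration))
  if (!is.null(x$seed)) cat(sprintf(", seed = %d", x$seed))
  cat("\n")
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && abs(x - round(x)) < 1e-9
}

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
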
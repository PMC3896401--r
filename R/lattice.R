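#' Initial lattice state
#'
#' Build the generation-0 state: the first `n_init_cols` columns hold demes at
#' carrying capacity with `round(p0 * K)` copies of allele A, all other demes
#' are empty.
#'
#' @param params A [sim_params()] object.
#' @return A `lattice_state`: list with integer matrices `nA`, `na`
#'   (`n_rows x n_cols` allele counts) and the `generation` counter.
#' @export
init_state <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  nA <- matrix(0L, params$n_rows, params$n_cols)
  na <- matrix(0L, params$n_rows, params$n_cols)
  init <- seq_len(params$n_init_cols)
  nA0 <- as.integer(round(params$p0 * params$K))
  nA[, init] <- nA0
  na[, init] <- params$K - nA0
  structure(list(nA = nA, na = na, generation = 0L), class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  tot <- x$nA + x$na
  occ <- which(colSums(tot) > 0)
  cat(sprintf("Lattice state: %d x %d demes, generation %d\n",
              nrow(x$nA), ncol(x$nA), x$generation))
  cat(sprintf("  %d individuals; occupied columns %s\n", sum(tot),
              if (length(occ)) paste0(min(occ), "-", max(occ)) else "none"))
  invisible(x)
}

# Poisson reproduction on the active window. Each parent leaves an independent
# Poisson(r) number of offspring and dies; by Poisson additivity a deme's new
# per-allele count is Poisson(r * count). Only columns 1..n_suitable reproduce;
# occupants of unsuitable habitat die without offspring.
reproduce_window <- function(nA, na, r, n_suitable) {
  w <- ncol(nA)
  newA <- matrix(0L, nrow(nA), w)
  newa <- matrix(0L, nrow(nA), w)
  s <- seq_len(min(n_suitable, w))
  newA[, s] <- stats::rpois(length(s) * nrow(nA), r * nA[, s, drop = FALSE])
  newa[, s] <- stats::rpois(length(s) * nrow(nA), r * na[, s, drop = FALSE])
  list(nA = newA, na = newa)
}

# Multinomial migration of one allele's counts on the active window.
# An individual with n orthogonally adjacent demes on the FULL lattice
# (n = 2 at corners, 3 at edges, 4 in the interior) leaves its deme with
# probability m/n under the default "m_over_n" convention, or with total
# probability m under "total_m"; conditional on leaving, the destination is
# uniform over those n demes. Implemented as a binomial chain over the four
# directions, which is exactly the uniform multinomial split of the leavers.
migrate_counts <- function(X, m, n_cols_total, model = "m_over_n") {
  R <- nrow(X); w <- ncol(X)
  ex_up    <- matrix(c(FALSE, rep(TRUE, R - 1L)), R, w)
  ex_down  <- matrix(c(rep(TRUE, R - 1L), FALSE), R, w)
  ex_left  <- matrix(rep(c(FALSE, rep(TRUE, w - 1L)), each = R), R, w)
  ex_right <- matrix(rep(seq_len(w) < n_cols_total, each = R), R, w)
  n_nb <- ex_up + ex_down + ex_left + ex_right

  p_leave <- switch(model, m_over_n = m / pmax(n_nb, 1L), total_m = m,
                    stop("unknown migration model: ", model, call. = FALSE))
  # a 1 x 1 lattice has no neighbors; nobody can leave
  if (any(n_nb == 0L)) p_leave <- p_leave * (n_nb > 0L)
  leave <- stats::rbinom(length(X), X, p_leave)
  dim(leave) <- dim(X)
  out <- X - leave

  cnt <- n_nb
  rem <- leave
  split_dir <- function(ex) {
    p <- ifelse(ex, 1 / cnt, 0)
    x <- stats::rbinom(length(rem), rem, p)
    dim(x) <- dim(rem)
    rem <<- rem - x
    cnt <<- cnt - ex
    x
  }
  go_up    <- split_dir(ex_up)
  go_down  <- split_dir(ex_down)
  go_left  <- split_dir(ex_left)
  go_right <- split_dir(ex_right)

  zr <- integer(w)
  out <- out + rbind(go_up[-1L, , drop = FALSE], zr)         # arrive one row up
  out <- out + rbind(zr, go_down[-R, , drop = FALSE])        # one row down
  zc <- integer(R)
  out <- out + cbind(go_left[, -1L, drop = FALSE], zc)       # one column left
  if (w > 1L) out <- out + cbind(zc, go_right[, -w, drop = FALSE])
  dimnames(out) <- NULL
  out
}

# Cull demes above carrying capacity: keep exactly K survivors by uniform
# sampling without replacement, i.e. the retained allele-A count is
# hypergeometric(nA, na, K).
cull_window <- function(nA, na, K) {
  tot <- nA + na
  over <- which(tot > K)
  if (length(over)) {
    keepA <- stats::rhyper(length(over), nA[over], na[over], K)
    nA[over] <- keepA
    na[over] <- K - keepA
  }
  list(nA = nA, na = na)
}

#' Advance a lattice state by one generation
#'
#' Applies the generation cycle on the incoming generation's habitat:
#' suitability is refreshed from the schedule, then reproduction, migration and
#' culling run in that order, and the generation counter increments. Migration
#' conserves the total number of individuals; after culling every deme holds at
#' most `K` individuals.
#'
#' @param state A `lattice_state` (see [init_state()]).
#' @param params A [sim_params()] object.
#' @param schedule A [habitat_schedule()]; defaults to the one implied by
#'   `params`.
#' @return The updated `lattice_state`.
#' @export
step_generation <- function(state, params, schedule = habitat_schedule(params)) {
  stopifnot(inherits(state, "lattice_state"))
  gen_new <- state$generation + 1L
  ns <- n_suitable_cols(schedule, gen_new)

  # Active window: migration reaches at most one column beyond the occupied
  # range, and nothing beyond it can hold individuals, so the window is exact.
  occ <- colSums(state$nA + state$na) > 0L
  rmax <- if (any(occ)) max(which(occ)) else 0L
  w <- min(rmax + 1L, params$n_cols)
  if (w < 1L) {
    state$generation <- gen_new
    return(state)
  }
  nA <- state$nA[, seq_len(w), drop = FALSE]
  na <- state$na[, seq_len(w), drop = FALSE]

  rep_ <- reproduce_window(nA, na, params$r, ns)
  nA <- migrate_counts(rep_$nA, params$m, params$n_cols, params$migration_model)
  na <- migrate_counts(rep_$na, params$m, params$n_cols, params$migration_model)
  cu <- cull_window(nA, na, params$K)

  state$nA[, seq_len(w)] <- cu$nA
  state$na[, seq_len(w)] <- cu$na
  state$generation <- gen_new
  state
}
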
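# Closed-form homeostasis bounds and trajectory verifiers. The model's
# headline properties are theorems; these functions state the bounds as
# arithmetic and check them mechanically on recorded trajectories.

#' Bound on the time for a vertex to become a stem cell
#'
#' If some vertex holds a stem cell, a vertex at graph distance `rho` from
#' it becomes a stem cell within `phi + rho * mu * psi` steps: at worst a
#' differentiated cell must mature away (`phi`), and at each unit of
#' distance a neighbouring stem needs at most `mu` maturity periods of
#' `psi` steps to proliferate toward the target.
#'
#' @param params A [marrow_params()].
#' @param rho Non-negative integer graph distance.
#' @return The integer bound.
#' @export
occupation_bound <- function(params, rho) {
  rho <- as.integer(rho)
  if (is.na(rho) || rho < 0L) stop("`rho` must be a non-negative integer")
  params$phi + rho * params$mu * params$psi
}

#' Lower bound on long-run stem density of a ball
#'
#' Once a vertex has hosted a stem cell, every ball of radius `M * eta`
#' around it keeps a stem cell in any two consecutive steps; since such a
#' ball holds at most `(mu^(M*eta) - 1) / (mu - 1)` vertices, its long-run
#' stem density is at least `(mu - 1) / (mu^(M*eta) - 1)`.
#'
#' @param params A [marrow_params()].
#' @return A ratio in `(0, 1]`.
#' @export
density_bound <- function(params) {
  r <- params$M * params$eta
  (params$mu - 1) / (params$mu^r - 1)
}

#' Bound on the differentiated-cell supply interval
#'
#' Outside the resonant state, every ball of radius `2 * M * eta` around a
#' stem-occupied vertex releases at least one matured differentiated cell
#' within `(mu + 1) * psi + M * theta + 1 + phi` steps.
#'
#' @param params A [marrow_params()].
#' @return The integer bound.
#' @export
supply_bound <- function(params) {
  (params$mu + 1L) * params$psi + params$M * params$theta + 1L + params$phi
}

bound_report <- function(bound_name, bound_value, observed_value, satisfied,
                         witness = NA_character_) {
  data.frame(bound_name = bound_name, bound_value = bound_value,
             observed_value = observed_value, satisfied = satisfied,
             witness = witness, stringsAsFactors = FALSE)
}

# first time >= t at which the trajectory's snapshots satisfy pred at idx
first_stem_time <- function(states, idx) {
  for (s in states) {
    if (s$type[idx] == CELL_STEM) return(s$t)
  }
  NA_integer_
}

#' Verify the stem-occupation time bound on a trajectory
#'
#' For a single-stem start at vertex `origin`, checks that every vertex's
#' first stem-occupation time is at most
#' `occupation_bound(params, rho(origin, v))`. Requires snapshots.
#'
#' @param trajectory A `marrow_trajectory` with snapshots.
#' @param params A [marrow_params()].
#' @param origin The initially stem-occupied vertex `c(row, col)`; if
#'   `NULL`, taken from the first snapshot (which must then hold exactly
#'   one stem cell).
#' @return A one-row bound report (`bound_name = "occupation"`), with the
#'   worst margin vertex as witness; `satisfied` is `FALSE` if any vertex
#'   misses its bound (or is never occupied within the horizon).
#' @export
verify_occupation <- function(trajectory, params, origin = NULL) {
  states <- trajectory$states
  if (is.null(states)) stop("trajectory was not recorded with snapshots")
  s0 <- states[[1L]]
  if (is.null(origin)) {
    stems <- which(s0$type == CELL_STEM)
    if (length(stems) != 1L) {
      stop("`origin` must be given unless the initial state has exactly one stem cell")
    }
    origin <- c((stems - 1L) %% s0$height, (stems - 1L) %/% s0$height)
  }
  grid <- state_grid(s0)
  worst_slack <- Inf
  worst <- NA_character_
  ok <- TRUE
  for (r in 0:(s0$height - 1L)) {
    for (cc in 0:(s0$width - 1L)) {
      v <- c(r, cc)
      idx <- cc * s0$height + r + 1L
      rho <- grid_distance(grid, origin, v)
      bound <- s0$t + occupation_bound(params, rho)
      t_first <- first_stem_time(states, idx)
      slack <- bound - ifelse(is.na(t_first), Inf, t_first)
      if (is.na(t_first) || t_first > bound) {
        ok <- FALSE
        worst <- sprintf("(%d,%d) first=%s bound=%d", r, cc,
                         ifelse(is.na(t_first), "never", t_first), bound)
        worst_slack <- -Inf
      } else if (slack < worst_slack) {
        worst_slack <- slack
        worst <- sprintf("(%d,%d) first=%d bound=%d", r, cc, t_first, bound)
      }
    }
  }
  bound_report("occupation", NA_real_, NA_real_, ok, worst)
}

#' Verify stem persistence around a vertex (two-step cover)
#'
#' From the first time `t0` at which `v` holds a stem cell, checks that for
#' every later step in the horizon the ball `B(v, M * eta)` contains a stem
#' cell at time `t` or `t + 1` (until global death, which is reported as a
#' violation with its time as witness).
#'
#' @param trajectory A `marrow_trajectory` with snapshots.
#' @param v Vertex `c(row, col)`.
#' @param t0 A time at which `v` holds a stem cell (checked).
#' @param params A [marrow_params()].
#' @return A one-row bound report (`bound_name = "persistence"`).
#' @export
verify_persistence <- function(trajectory, v, t0, params) {
  states <- trajectory$states
  if (is.null(states)) stop("trajectory was not recorded with snapshots")
  s0 <- states[[1L]]
  times <- vapply(states, function(s) s$t, integer(1))
  k0 <- match(t0, times)
  if (is.na(k0)) stop("`t0` is outside the recorded horizon")
  idx_v <- v[2L] * s0$height + v[1L] + 1L
  if (states[[k0]]$type[idx_v] != CELL_STEM) {
    stop("vertex does not hold a stem cell at `t0`")
  }
  ball <- grid_ball(state_grid(s0), v, params$M * params$eta)
  idx <- ball[, "col"] * s0$height + ball[, "row"] + 1L
  has_stem <- vapply(states, function(s) any(s$type[idx] == CELL_STEM),
                     logical(1))
  n <- length(states)
  for (k in k0:(n - 1L)) {
    if (!has_stem[k] && !has_stem[k + 1L]) {
      return(bound_report("persistence", NA_real_, NA_real_, FALSE,
                          sprintf("(%d,%d) t=%d", v[1L], v[2L], times[k])))
    }
  }
  bound_report("persistence", NA_real_, NA_real_, TRUE)
}

#' Verify the long-run stem-density bound
#'
#' For each given centre whose vertex has hosted a stem cell during the
#' run, checks that the stem density of `B(v, M * eta)` in the trailing
#' window of the trajectory stays at or above [density_bound()].
#'
#' @param trajectory A `marrow_trajectory` with snapshots.
#' @param params A [marrow_params()].
#' @param centers Matrix of vertices (columns `row`, `col`); defaults to
#'   the centre of the lattice.
#' @param window Number of trailing steps over which the minimum density
#'   is taken (default: last quarter of the run).
#' @return A one-row bound report (`bound_name = "density"`) with the
#'   bound, the smallest observed windowed density, and the centre
#'   attaining it as witness.
#' @export
verify_density <- function(trajectory, params, centers = NULL, window = NULL) {
  states <- trajectory$states
  if (is.null(states)) stop("trajectory was not recorded with snapshots")
  s0 <- states[[1L]]
  if (is.null(centers)) {
    centers <- rbind(c(s0$height %/% 2L, s0$width %/% 2L))
  }
  n <- length(states)
  if (is.null(window)) window <- max(2L, n %/% 4L)
  tail_states <- states[(n - window + 1L):n]
  bound <- density_bound(params)
  worst <- Inf
  wit <- NA_character_
  for (k in seq_len(nrow(centers))) {
    v <- centers[k, ]
    ball <- grid_ball(state_grid(s0), c(v[1L], v[2L]), params$M * params$eta)
    dmin <- min(vapply(tail_states, stem_density, numeric(1), region = ball))
    if (dmin < worst) {
      worst <- dmin
      wit <- sprintf("(%d,%d)", v[1L], v[2L])
    }
  }
  bound_report("density", bound, worst, worst >= bound, wit)
}

#' Verify the differentiated-cell supply bound
#'
#' The steady-supply theorem is a statement about recurrence: from a
#' certain moment onwards, every ball of radius `2 * M * eta` around a
#' stem-occupied vertex releases at least one matured differentiated cell
#' in every window of [supply_bound()] steps. The cold-start transient —
#' the first expansion of the colony, before any cell has differentiated —
#' is excluded. The verifier therefore requires, for each centre whose
#' vertex hosts a stem cell at some recorded time, that the ball emits at
#' least once, and that from its first emission onwards no gap between
#' consecutive emissions (including the tail up to the recorded horizon)
#' exceeds the bound.
#'
#' @param trajectory A `marrow_trajectory` recorded with snapshots and
#'   emissions, long enough to contain several bound-lengths.
#' @param params A [marrow_params()].
#' @param centers Matrix of vertices; defaults to the lattice centre.
#' @return A one-row bound report (`bound_name = "supply"`); the observed
#'   value is the largest post-transient emission gap over the centres.
#' @export
verify_supply <- function(trajectory, params, centers = NULL) {
  states <- trajectory$states
  emis <- trajectory$emissions
  if (is.null(states) || is.null(emis)) {
    stop("trajectory must be recorded with snapshots and emissions")
  }
  s0 <- states[[1L]]
  if (is.null(centers)) {
    centers <- rbind(c(s0$height %/% 2L, s0$width %/% 2L))
  }
  bound <- supply_bound(params)
  n_steps <- length(emis)
  worst <- -Inf
  wit <- NA_character_
  ok <- TRUE
  for (k in seq_len(nrow(centers))) {
    v <- c(centers[k, 1L], centers[k, 2L])
    idx_v <- v[2L] * s0$height + v[1L] + 1L
    ever_stem <- any(vapply(states, function(s) s$type[idx_v] == CELL_STEM,
                            logical(1)))
    if (!ever_stem) next  # guarantee's premise not met at this centre
    ball <- grid_ball(state_grid(s0), v, 2L * params$M * params$eta)
    bidx <- cbind(ball[, "row"] + 1L, ball[, "col"] + 1L)
    et <- which(vapply(emis, function(m) any(m[bidx]), logical(1)))
    if (length(et) == 0L) {
      ok <- FALSE
      worst <- Inf
      wit <- sprintf("(%d,%d) no emission", v[1L], v[2L])
      next
    }
    gaps <- c(diff(et), n_steps - et[length(et)])
    gk <- if (length(gaps)) max(gaps) else 0L
    if (gk > worst) {
      worst <- gk
      wit <- sprintf("(%d,%d)", v[1L], v[2L])
    }
    if (gk > bound) ok <- FALSE
  }
  if (identical(worst, -Inf)) {
    # no centre met the guarantee's premise: vacuously satisfied
    return(bound_report("supply", bound, NA_real_, TRUE, "no stem centre"))
  }
  bound_report("supply", bound, worst, ok, wit)
}
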
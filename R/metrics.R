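# Trajectory metrics and state classification.

#' Stem-cell density of a region
#'
#' The ratio of stem-occupied vertices to all vertices in `region`, the
#' quantity bounded below (in the long run, for balls of radius `M * eta`)
#' by [density_bound()].
#'
#' @param state A `marrow_state`.
#' @param region Integer matrix with columns `row`, `col` (as returned by
#'   [grid_ball()]); must be nonempty.
#' @return A ratio in `[0, 1]`.
#' @export
stem_density <- function(state, region) {
  if (is.null(dim(region)) || nrow(region) == 0L) {
    stop("`region` must be a nonempty vertex matrix")
  }
  idx <- region[, "col"] * state$height + region[, "row"] + 1L
  sum(state$type[idx] == CELL_STEM) / nrow(region)
}

#' Quiescent stem fraction of a step
#'
#' Percentage of stem cells whose executed intent in the step that
#' produced `state` was quiescence: mature stem cells that neither died,
#' converted, nor found (or kept, after conflict resolution) an empty site
#' to proliferate into. Reported as a percentage of the stem cells present
#' after the step; 0 when no stem cells exist.
#'
#' @param report A one-row step report from [marrow_step()] (or one row of
#'   a trajectory's `reports`).
#' @param state The `marrow_state` produced by that same step.
#' @return A percentage in `[0, 100]`.
#' @export
quiescent_fraction <- function(report, state) {
  n_stem <- sum(state$type == CELL_STEM)
  if (!is.null(report$t) && !is.null(state$t) && report$t != state$t) {
    stop("`report` does not belong to the step that produced `state`")
  }
  if (!is.null(report$n_stem) && report$n_stem != n_stem) {
    stop("`report` does not belong to the step that produced `state`")
  }
  if (n_stem == 0L) return(0)
  100 * report$quiescent / n_stem
}

#' Quiescent share of the marrow
#'
#' Like [quiescent_fraction()], but with an explicit denominator choice:
#' `"stems"` divides the step's quiescence events by the stem cells
#' present after the step, `"sites"` by all lattice sites. The per-site
#' share is the convention under which the package's reference quiescence
#' trajectory reproduces its published checkpoint values (see the
#' vignette); the two coincide in shape but not scale once the lattice is
#' crowded.
#'
#' @inheritParams quiescent_fraction
#' @param denominator `"stems"` or `"sites"`.
#' @return A percentage in `[0, 100]`.
#' @export
quiescent_share <- function(report, state, denominator = c("stems", "sites")) {
  denominator <- match.arg(denominator)
  if (denominator == "stems") {
    return(quiescent_fraction(report, state))
  }
  100 * report$quiescent / (state$height * state$width)
}

#' Quiescence checkpoints of a trajectory
#'
#' Reads the quiescent share of the marrow — quiescence events per lattice
#' site, as a percentage — at a set of time steps of a recorded run. This
#' is the per-site convention of the reference quiescence experiment (see
#' [quiescent_share()] and the vignette).
#'
#' @param trajectory A `marrow_trajectory`.
#' @param at Integer vector of steps to read (defaults to the reference
#'   checkpoints 20, 50, 100, 200, 500).
#' @return Named numeric vector of percentages (`q20`, `q50`, ...).
#' @export
reference_quiescence <- function(trajectory, at = c(20L, 50L, 100L, 200L, 500L)) {
  r <- trajectory$reports
  if (max(at) > nrow(r)) stop("trajectory is shorter than the requested checkpoints")
  n_sites <- with(r[1L, ], n_stem + n_transitive + n_differentiated + n_empty)
  out <- 100 * r$quiescent[at] / n_sites
  names(out) <- paste0("q", at)
  out
}

#' Cumulative differentiated-cell output of a trajectory
#'
#' Total number of matured differentiated cells released to the blood
#' stream (sites turning from differentiated to empty at maturity) over
#' the whole run.
#'
#' @param trajectory A `marrow_trajectory`.
#' @return Non-negative count.
#' @export
cumulative_output <- function(trajectory) {
  n <- nrow(trajectory$reports)
  if (n == 0L) return(0L)
  trajectory$reports$cumulative_output[n]
}

#' Classify a marrow state
#'
#' * `death` — every vertex empty (the absorbing death state).
#' * `dying_out` — a state that deterministically reaches death: no stem
#'   and no transitive cells, or an all-stem lattice with every counter at
#'   `psi` and every renewal count at `delta` (synchronized apoptosis).
#' * `resonant` — all vertices stem with identical counters (the
#'   synchronized precursor of the stem/transitive oscillation that
#'   produces no differentiated output).
#' * `active` — anything else.
#'
#' @param state A `marrow_state`.
#' @param params A [marrow_params()].
#' @return A list with `class` (one of the above) and `evidence` (short
#'   text tag).
#' @export
classify_state <- function(state, params) {
  type <- state$type
  n <- length(type)
  if (all(type == CELL_EMPTY)) {
    return(list(class = "death", evidence = "all vertices empty"))
  }
  n_stem <- sum(type == CELL_STEM)
  n_trans <- sum(type == CELL_TRANSITIVE)
  if (n_stem == 0L && n_trans == 0L) {
    return(list(class = "dying_out",
                evidence = "no stem or transitive cells; dies within phi + 1 steps"))
  }
  if (n_stem == n) {
    if (all(state$tau == params$psi) && all(state$p == params$delta)) {
      return(list(class = "dying_out",
                  evidence = "synchronized mature stems at the renewal limit"))
    }
    if (length(unique(as.vector(state$tau))) == 1L) {
      return(list(class = "resonant",
                  evidence = "all-stem lattice with synchronized counters"))
    }
  }
  list(class = "active", evidence = "mixed composition")
}

#' Detect a state cycle in a recorded trajectory
#'
#' The state space is finite, so every trajectory eventually repeats a
#' configuration and from then on cycles (the model's steady states).
#' Hashes every recorded snapshot (full tuple content: type, direction,
#' counters, generation, renewals) and reports the first repeat.
#'
#' @param trajectory A `marrow_trajectory` recorded with
#'   `record_snapshots = TRUE`.
#' @return A list with `entry_time` (time of the first occurrence of the
#'   repeated configuration) and `period`, or `NULL` if no repeat occurs
#'   within the recorded horizon.
#' @export
detect_cycle <- function(trajectory) {
  states <- trajectory$states
  if (is.null(states)) {
    stop("trajectory was not recorded with snapshots; rerun with record_snapshots = TRUE")
  }
  seen <- new.env(parent = emptyenv())
  for (s in states) {
    key <- state_key(s)
    first <- seen[[key]]
    if (!is.null(first)) {
      return(list(entry_time = first, period = s$t - first))
    }
    seen[[key]] <- s$t
  }
  NULL
}
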
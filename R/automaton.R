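# The iterative operator. All four rules read the time-t configuration and
# write time t+1 synchronously:
#
# Rule 1 (stem), subrules in order: (a) apoptosis when tau = psi and
#   p = delta; (b) conversion to a generation-1 transitive cell when
#   tau = psi and every existing immediate neighbour is a stem cell;
#   (c) proliferation into the first empty neighbour found by scanning the
#   eight directions round-robin from the cell's direction component d;
#   (d) quiescence (state retained) when mature but neither saturated nor
#   next to empty space; (e) otherwise tick tau.
# Rule 2 (transitive): dedifferentiate to a stem cell when no stem cell
#   lies within the ball of radius g*eta; advance a generation at the
#   cumulative counter g*theta (differentiate when g = M); otherwise tick.
# Rule 3 (differentiated): emigrate to the blood stream (become empty) at
#   tau = phi; otherwise tick.
# Rule 4 (empty): empty space never changes by itself.
#
# Simultaneous proliferation claims on one empty site are resolved in
# row-major vertex order: the earlier stem keeps its target, later stems
# re-scan their remaining directions, and a stem left with no free empty
# neighbour quiesces. This keeps the update fully deterministic.

#' Decide what a stem cell will do this step
#'
#' Evaluates Rule 1's subrules, strictly in order, on the time-t
#' configuration: apoptosis, conversion to transitive, proliferation,
#' quiescence, or a counter tick. Proliferation targets the first empty
#' neighbour found scanning the eight directions round-robin from the
#' cell's direction component.
#'
#' Note this is the *intent* before conflict resolution; when several stem
#' cells target the same empty site, [resolve_proliferation()] arbitrates.
#'
#' @param state A `marrow_state`.
#' @param v Vertex `c(row, col)` holding a stem cell.
#' @param params A [marrow_params()].
#' @return A list with `action` in `c("die", "convert", "proliferate",
#'   "quiesce", "tick")` and, for proliferation, `target` (vertex) and
#'   `used_direction` (0..7).
#' @export
stem_intent <- function(state, v, params) {
  i <- state_index(state, v)
  if (state$type[i] != CELL_STEM) {
    stop("stem_intent() called on a vertex that does not hold a stem cell")
  }
  if (state$tau[i] < params$psi) {
    return(list(action = "tick"))
  }
  if (state$p[i] >= params$delta) {
    return(list(action = "die"))
  }
  grid <- state_grid(state)
  nb <- grid_neighbors(grid, v)
  nb_types <- state$type[nb[, "col"] * state$height + nb[, "row"] + 1L]
  if (all(nb_types == CELL_STEM)) {
    return(list(action = "convert"))
  }
  # round-robin scan from the direction component
  d0 <- state$d[i]
  for (k in 0:7) {
    dir <- (d0 + k) %% 8L
    tv <- v + MOORE_OFFSETS[dir + 1L, ]
    tv <- wrap_vertex(state, tv)
    if (is.null(tv)) next
    if (state$type[tv[2L] * state$height + tv[1L] + 1L] == CELL_EMPTY) {
      return(list(action = "proliferate", target = unname(tv),
                  used_direction = dir))
    }
  }
  list(action = "quiesce")
}

# NULL when off a bounded lattice; wrapped coordinates on a torus.
wrap_vertex <- function(state, v) {
  if (state$topology == "torus") {
    return(c(v[1L] %% state$height, v[2L] %% state$width))
  }
  if (v[1L] < 0L || v[1L] >= state$height ||
      v[2L] < 0L || v[2L] >= state$width) {
    return(NULL)
  }
  v
}

state_grid <- function(state) {
  marrow_grid(state$width, state$height, state$topology)
}

#' Resolve simultaneous proliferation claims
#'
#' The per-cell rules never define what happens when two mature stem cells
#' target the same empty site in the same step. Claims are processed in
#' row-major vertex order: each proliferating stem keeps its target if it
#' is still unclaimed; otherwise it re-scans its remaining directions
#' (continuing round-robin past the failed one) for an empty, unclaimed
#' neighbour, and quiesces if none remains. Each empty site ends up claimed
#' by at most one stem, deterministically.
#'
#' @param intents Named list of intent lists (as from [stem_intent()]),
#'   with names `"row,col"`, covering every stem vertex of `state`.
#' @param state The time-t `marrow_state` the intents were computed from.
#' @param params A [marrow_params()].
#' @return The intents list with conflicting proliferations re-targeted or
#'   downgraded to quiescence.
#' @export
resolve_proliferation <- function(intents, state, params) {
  prolif <- names(intents)[vapply(intents, function(x) x$action == "proliferate",
                                  logical(1))]
  if (length(prolif) == 0L) return(intents)
  coords <- do.call(rbind, lapply(strsplit(prolif, ","), as.integer))
  ord <- order(coords[, 1L], coords[, 2L])
  claimed <- matrix(FALSE, state$height, state$width)
  for (k in ord) {
    v <- coords[k, ]
    key <- prolif[k]
    it <- intents[[key]]
    tgt <- it$target
    if (!claimed[tgt[1L] + 1L, tgt[2L] + 1L]) {
      claimed[tgt[1L] + 1L, tgt[2L] + 1L] <- TRUE
      next
    }
    # re-scan the remaining directions, continuing past the failed one
    found <- FALSE
    for (s in 1:7) {
      dir <- (it$used_direction + s) %% 8L
      tv <- wrap_vertex(state, v + MOORE_OFFSETS[dir + 1L, ])
      if (is.null(tv)) next
      if (state$type[tv[2L] * state$height + tv[1L] + 1L] == CELL_EMPTY &&
          !claimed[tv[1L] + 1L, tv[2L] + 1L]) {
        claimed[tv[1L] + 1L, tv[2L] + 1L] <- TRUE
        intents[[key]] <- list(action = "proliferate", target = unname(tv),
                               used_direction = dir)
        found <- TRUE
        break
      }
    }
    if (!found) intents[[key]] <- list(action = "quiesce", downgraded = TRUE)
  }
  intents
}

#' Rule 2: next state of a transitive cell
#'
#' Read from the time-t configuration: if no stem cell lies within
#' `ball(v, g * eta)`, the cell dedifferentiates to a mature stem cell
#' (`tau = psi`, zero renewals, direction 0). Otherwise, at the cumulative
#' counter `tau = g * theta` it advances a generation (keeping `tau`), or
#' differentiates if already in generation `M`; below the threshold the
#' counter ticks.
#'
#' @param state A `marrow_state`.
#' @param v Vertex holding a transitive cell.
#' @param params A [marrow_params()].
#' @return The `marrow_cell` the vertex holds at t+1.
#' @export
transitive_update <- function(state, v, params) {
  i <- state_index(state, v)
  if (state$type[i] != CELL_TRANSITIVE) {
    stop("transitive_update() called on a vertex that does not hold a transitive cell")
  }
  g <- state$g[i]
  tau <- state$tau[i]
  ball <- grid_ball(state_grid(state), v, g * params$eta)
  ball_types <- state$type[ball[, "col"] * state$height + ball[, "row"] + 1L]
  if (!any(ball_types == CELL_STEM)) {
    return(stem_cell(d = 0L, tau = params$psi, p = 0L))
  }
  if (tau == g * params$theta) {
    if (g < params$M) {
      return(transitive_cell(g = g + 1L, tau = tau))
    }
    return(differentiated_cell(tau = 0L))
  }
  transitive_cell(g = g, tau = tau + 1L)
}

#' Rule 3: next state of a differentiated cell
#'
#' At `tau = phi` the cell has matured and emigrates to the blood stream,
#' leaving empty space; below the threshold the counter ticks.
#'
#' @inheritParams transitive_update
#' @return The `marrow_cell` the vertex holds at t+1.
#' @export
differentiated_update <- function(state, v, params) {
  i <- state_index(state, v)
  if (state$type[i] != CELL_DIFFERENTIATED) {
    stop("differentiated_update() called on a vertex that does not hold a differentiated cell")
  }
  if (state$tau[i] == params$phi) {
    return(empty_cell())
  }
  differentiated_cell(tau = state$tau[i] + 1L)
}

#' One synchronous step of the automaton
#'
#' Computes every cell's update from the time-t configuration and commits
#' them all at once. Stem proliferation places a fresh daughter
#' (`d = 0, tau = 0, p = 0`) on the claimed empty site and renews the
#' parent (`tau = 0`, `p + 1`, direction advanced past the one used).
#' Empty sites not claimed stay empty and take part in no computation.
#'
#' @param state A `marrow_state` at time t.
#' @param params A [marrow_params()].
#' @return A list with `state` (time t+1) and `report`, a one-row
#'   data.frame tallying the step's events: `deaths`, `conversions_st`
#'   (stem to transitive), `proliferations`, `quiescent` (stems whose
#'   executed intent was quiescence), `gen_advances`, `conversions_td`
#'   (transitive to differentiated), `dedifferentiations`, `emitted`
#'   (matured differentiated cells released to the blood stream).
#' @export
marrow_step <- function(state, params) {
  h <- state$height
  w <- state$width
  topo <- state$topology
  type <- state$type
  S <- type == CELL_STEM
  TT <- type == CELL_TRANSITIVE
  D <- type == CELL_DIFFERENTIATED

  new_type <- type
  new_d <- state$d
  new_tau <- state$tau
  new_g <- state$g
  new_p <- state$p

  n_die <- 0L; n_st <- 0L; n_prolif <- 0L; n_quiesce <- 0L
  n_adv <- 0L; n_td <- 0L; n_dediff <- 0L; n_emit <- 0L
  emit_mask <- matrix(FALSE, h, w)

  # ---- Rule 1: stem cells -------------------------------------------------
  if (any(S)) {
    mature <- S & state$tau == params$psi
    tick <- S & !mature
    if (any(tick)) new_tau[tick] <- state$tau[tick] + 1L

    if (any(mature)) {
      die <- mature & state$p >= params$delta
      live <- mature & !die
      # neighbour masks: off-lattice positions count as "stem" for the
      # saturation test (vacuously) and as "not empty" for proliferation
      all_stem <- matrix(TRUE, h, w)
      any_empty <- matrix(FALSE, h, w)
      E_mat <- matrix(type == CELL_EMPTY, h, w)
      S_mat <- matrix(S, h, w)
      for (dir in 1:8) {
        off <- MOORE_OFFSETS[dir, ]
        all_stem <- all_stem &
          shift_matrix(S_mat, off[1L], off[2L], topo, fill = TRUE)
        any_empty <- any_empty |
          shift_matrix(E_mat, off[1L], off[2L], topo, fill = FALSE)
      }
      convert <- live & all_stem
      prolif_cand <- live & !convert & any_empty
      quiesce <- live & !convert & !any_empty

      if (any(die)) {
        n_die <- sum(die)
        new_type[die] <- CELL_EMPTY
        new_d[die] <- 0L; new_tau[die] <- 0L; new_p[die] <- 0L
      }
      if (any(convert)) {
        n_st <- sum(convert)
        new_type[convert] <- CELL_TRANSITIVE
        new_g[convert] <- 1L
        new_tau[convert] <- 0L
        new_d[convert] <- 0L; new_p[convert] <- 0L
      }
      n_quiesce <- sum(quiesce)  # quiescent stems retain their state as-is

      if (any(prolif_cand)) {
        idx <- which(matrix(prolif_cand, h, w), arr.ind = TRUE)
        ord <- order(idx[, 1L], idx[, 2L])  # row-major claim order
        claimed <- matrix(FALSE, h, w)
        for (k in ord) {
          r <- idx[k, 1L]; cc <- idx[k, 2L]   # 1-based
          i <- (cc - 1L) * h + r
          d0 <- state$d[i]
          placed <- FALSE
          for (s in 0:7) {
            dir <- (d0 + s) %% 8L
            tr <- r + MOORE_OFFSETS[dir + 1L, 1L]
            tc <- cc + MOORE_OFFSETS[dir + 1L, 2L]
            if (topo == "torus") {
              tr <- ((tr - 1L) %% h) + 1L
              tc <- ((tc - 1L) %% w) + 1L
            } else if (tr < 1L || tr > h || tc < 1L || tc > w) {
              next
            }
            ti <- (tc - 1L) * h + tr
            if (type[ti] == CELL_EMPTY && !claimed[tr, tc]) {
              claimed[tr, tc] <- TRUE
              # daughter: fresh stem cell
              new_type[ti] <- CELL_STEM
              new_d[ti] <- 0L; new_tau[ti] <- 0L; new_p[ti] <- 0L
              new_g[ti] <- 0L
              # parent: renewed biological time, one more renewal,
              # direction advanced past the one used
              new_tau[i] <- 0L
              new_p[i] <- state$p[i] + 1L
              new_d[i] <- (dir + 1L) %% 8L
              placed <- TRUE
              n_prolif <- n_prolif + 1L
              break
            }
          }
          if (!placed) n_quiesce <- n_quiesce + 1L  # downgraded to quiescence
        }
      }
    }
  }

  # ---- Rule 2: transitive cells ------------------------------------------
  if (any(TT)) {
    # distance-to-nearest-stem, capped at M*eta, via iterated Moore dilation
    # (on this lattice the graph metric is the Chebyshev distance, so each
    # dilation grows the reached set by one unit of distance)
    maxr <- params$M * params$eta
    S_mat <- matrix(S, h, w)
    dist_stem <- matrix(Inf, h, w)
    dist_stem[S_mat] <- 0
    reach <- S_mat
    r <- 1L
    while (r <= maxr && any(TT & !as.vector(reach))) {
      grown <- reach
      for (dir in 1:8) {
        off <- MOORE_OFFSETS[dir, ]
        grown <- grown | shift_matrix(reach, off[1L], off[2L], topo, fill = FALSE)
      }
      newly <- grown & !reach
      dist_stem[newly] <- r
      reach <- grown
      r <- r + 1L
    }
    dediff <- TT & as.vector(dist_stem > state$g * params$eta)
    if (any(dediff)) {
      n_dediff <- sum(dediff)
      new_type[dediff] <- CELL_STEM
      new_d[dediff] <- 0L
      new_tau[dediff] <- params$psi  # re-enters at stem maturity
      new_p[dediff] <- 0L
      new_g[dediff] <- 0L
    }
    stay <- TT & !dediff
    at_thr <- stay & state$tau == state$g * params$theta
    adv <- at_thr & state$g < params$M
    to_d <- at_thr & state$g >= params$M
    tickT <- stay & !at_thr
    if (any(adv)) {
      n_adv <- sum(adv)
      new_g[adv] <- state$g[adv] + 1L  # cumulative counter kept
    }
    if (any(to_d)) {
      n_td <- sum(to_d)
      new_type[to_d] <- CELL_DIFFERENTIATED
      new_tau[to_d] <- 0L
      new_g[to_d] <- 0L
    }
    if (any(tickT)) new_tau[tickT] <- state$tau[tickT] + 1L
  }

  # ---- Rule 3: differentiated cells --------------------------------------
  if (any(D)) {
    emit <- D & state$tau == params$phi
    tickD <- D & !emit
    if (any(emit)) {
      n_emit <- sum(emit)
      emit_mask[matrix(emit, h, w)] <- TRUE
      new_type[emit] <- CELL_EMPTY
      new_tau[emit] <- 0L
    }
    if (any(tickD)) new_tau[tickD] <- state$tau[tickD] + 1L
  }

  # ---- Rule 4: empty space does not change by itself ----------------------

  out <- state
  out$t <- state$t + 1L
  out$type <- new_type
  out$d <- new_d
  out$tau <- new_tau
  out$g <- new_g
  out$p <- new_p

  n_stem_after <- sum(new_type == CELL_STEM)
  report <- data.frame(
    t = out$t,
    deaths = n_die,
    conversions_st = n_st,
    proliferations = n_prolif,
    quiescent = n_quiesce,
    gen_advances = n_adv,
    conversions_td = n_td,
    dedifferentiations = n_dediff,
    emitted = n_emit,
    n_stem = n_stem_after,
    n_transitive = sum(new_type == CELL_TRANSITIVE),
    n_differentiated = sum(new_type == CELL_DIFFERENTIATED),
    n_empty = sum(new_type == CELL_EMPTY),
    quiescent_fraction_pct = if (n_stem_after > 0L) 100 * n_quiesce / n_stem_after else 0
  )
  list(state = out, report = report, emitted_at = emit_mask)
}

#' Run the automaton for a number of steps
#'
#' Applies [marrow_step()] `steps` times. The model has no random element:
#' identical inputs give bit-identical trajectories.
#'
#' @param initial A `marrow_state`.
#' @param params A [marrow_params()].
#' @param steps Number of steps (>= 1).
#' @param record_snapshots If `TRUE`, keep every intermediate state (needed
#'   by [detect_cycle()] and the trajectory verifiers); the initial and
#'   final states are always kept.
#' @param record_emissions If `TRUE`, keep the per-step logical mask of
#'   sites that released a matured cell (used by the supply-bound
#'   verifier).
#' @param perturbations Optional list of ablation events, each a list with
#'   `time`, `fraction`, `seed`: just before computing the step that leaves
#'   time `time`, that fraction of stem cells is removed (see
#'   [ablate_stems()]).
#' @return A `marrow_trajectory`: list with `initial`, `final`, `reports`
#'   (one data.frame row per step, including cumulative output), `states`
#'   (when recorded) and `emissions` (when recorded).
#' @export
marrow_run <- function(initial, params, steps, record_snapshots = FALSE,
                       record_emissions = FALSE, perturbations = NULL) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("`steps` must be a positive integer")
  state <- initial
  reports <- vector("list", steps)
  states <- if (record_snapshots) vector("list", steps + 1L) else NULL
  emissions <- if (record_emissions) vector("list", steps) else NULL
  if (record_snapshots) states[[1L]] <- state
  pert_times <- if (length(perturbations)) {
    vapply(perturbations, function(p) as.integer(p$time), integer(1))
  } else integer(0)
  for (k in seq_len(steps)) {
    hit <- which(pert_times == state$t)
    for (j in hit) {
      p <- perturbations[[j]]
      state <- ablate_stems(state, p$fraction, p$seed)
    }
    res <- marrow_step(state, params)
    state <- res$state
    reports[[k]] <- res$report
    if (record_snapshots) states[[k + 1L]] <- state
    if (record_emissions) emissions[[k]] <- res$emitted_at
  }
  reports <- do.call(rbind, reports)
  reports$cumulative_output <- cumsum(reports$emitted)
  structure(
    list(initial = initial, final = state, reports = reports,
         states = states, emissions = emissions, params = params),
    class = "marrow_trajectory"
  )
}

#' @export
print.marrow_trajectory <- function(x, ...) {
  n <- nrow(x$reports)
  cat(sprintf(
    "<marrow_trajectory %d steps, t=%d..%d; final: %d S, %d T, %d D; output %d>\n",
    n, x$initial$t, x$final$t,
    x$reports$n_stem[n], x$reports$n_transitive[n],
    x$reports$n_differentiated[n], x$reports$cumulative_output[n]))
  invisible(x)
}
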
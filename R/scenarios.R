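# Scenario builders: deterministic (and, where stated, seeded) initial
# lattice configurations and mid-run perturbations. These generate every
# input the simulations use; the model itself consumes no external data.

#' Single stem cell at the lattice centre
#'
#' The canonical repopulation experiment: one fresh stem cell
#' (`d = 0, tau = 0, p = 0`) at the central vertex
#' `(floor(height/2), floor(width/2))` — for even side lengths, the
#' lower-right of the four central sites — and empty space everywhere else.
#'
#' @param params A [marrow_params()].
#' @return A `marrow_state` at `t = 0`.
#' @export
single_center_stem <- function(params) {
  state <- empty_state(params)
  v <- c(params$height %/% 2L, params$width %/% 2L)
  set_cell(state, v, stem_cell())
}

#' Evenly distributed stem cells at a given fraction
#'
#' Deterministically places `round(fraction * width * height)` fresh stem
#' cells on an evenly spaced sublattice of stride
#' `floor(sqrt(1 / fraction))`, taking sublattice sites in row-major order;
#' if the sublattice has too few sites, the remainder is filled row-major
#' over the still-empty sites. Everything else is empty space.
#'
#' @param params A [marrow_params()].
#' @param fraction Target stem fraction in `[0, 1]`.
#' @return A `marrow_state` at `t = 0`.
#' @export
even_fraction_stem <- function(params, fraction) {
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]")
  }
  state <- empty_state(params)
  n_total <- params$width * params$height
  n_stem <- round(fraction * n_total)
  if (n_stem == 0L) return(state)
  stride <- max(1L, floor(sqrt(1 / fraction)))
  rows <- seq.int(0L, params$height - 1L, by = stride)
  cols <- seq.int(0L, params$width - 1L, by = stride)
  lattice <- cbind(row = rep(rows, each = length(cols)),
                   col = rep(cols, times = length(rows)))
  take <- min(nrow(lattice), n_stem)
  sel <- lattice[seq_len(take), , drop = FALSE]
  idx <- sel[, "col"] * params$height + sel[, "row"] + 1L
  state$type[idx] <- CELL_STEM
  short <- n_stem - take
  if (short > 0L) {
    # row-major fill of the remainder over still-empty sites
    all_idx <- order_row_major(params$height, params$width)
    free <- all_idx[state$type[all_idx] == CELL_EMPTY]
    state$type[free[seq_len(short)]] <- CELL_STEM
  }
  state
}

# column-major storage indices enumerated in row-major (row, col) order
order_row_major <- function(h, w) {
  as.vector(t(matrix(seq_len(h * w), h, w)))
}

#' All-stem lattice with synchronized counters
#'
#' Every vertex holds a stem cell `(S, d = 0, tau, p)`. With `tau = psi`
#' and `p = delta` the whole marrow undergoes apoptosis in one step (the
#' death state); with `tau = psi` and `p < delta` it enters the resonant
#' oscillation between all-stem and all-transitive phases.
#'
#' @param params A [marrow_params()].
#' @param tau Shared internal counter, `0..psi`.
#' @param p Shared renewal count, `0..delta`.
#' @return A `marrow_state` at `t = 0`.
#' @export
all_stem_synchronized <- function(params, tau = 0L, p = 0L) {
  tau <- as.integer(tau); p <- as.integer(p)
  if (is.na(tau) || tau < 0L || tau > params$psi) {
    stop("`tau` must lie in 0..psi")
  }
  if (is.na(p) || p < 0L || p > params$delta) {
    stop("`p` must lie in 0..delta")
  }
  state <- empty_state(params)
  state$type[] <- CELL_STEM
  state$tau[] <- tau
  state$p[] <- p
  state
}

#' Random mixture of stem cells and empty space
#'
#' Seeded pseudorandom placement of `round(fraction * width * height)`
#' fresh stem cells; the complement is empty space. Unlike
#' [even_fraction_stem()], placement is random (but reproducible for a
#' given seed).
#'
#' @param params A [marrow_params()].
#' @param fraction Stem fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `marrow_state` at `t = 0`.
#' @export
random_mixture <- function(params, fraction, seed) {
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]")
  }
  state <- empty_state(params)
  n_total <- params$width * params$height
  n_stem <- round(fraction * n_total)
  if (n_stem > 0L) {
    idx <- local_seed(seed, sample.int(n_total, n_stem))
    state$type[idx] <- CELL_STEM
  }
  state
}

#' Remove a fraction of stem cells (ablation perturbation)
#'
#' Models a severe perturbation of the marrow (e.g. irradiation): a
#' seeded-pseudorandom subset of `round(fraction * n_stems)` stem vertices
#' becomes empty space. All other cells are untouched; the same seed gives
#' the same ablation.
#'
#' @param state A `marrow_state`.
#' @param fraction Fraction of current stem cells to remove, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The perturbed `marrow_state` (same time `t`).
#' @export
ablate_stems <- function(state, fraction, seed) {
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 || fraction > 1) {
    stop("`fraction` must lie in [0, 1]")
  }
  stems <- which(state$type == CELL_STEM)
  n_drop <- round(fraction * length(stems))
  if (n_drop == 0L) return(state)
  drop <- stems[local_seed(seed, sample.int(length(stems), n_drop))]
  state$type[drop] <- CELL_EMPTY
  state$d[drop] <- 0L; state$tau[drop] <- 0L; state$p[drop] <- 0L
  state
}

# evaluate `expr` under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
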
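# A naive, per-cell reference implementation of the update rules, written
# independently of the production engine (plain loops over vertices; its
# own direction table). Used as the oracle for trajectory-equivalence
# tests.

# direction k -> (drow, dcol), 0..7 clockwise from the top-right diagonal
REF_OFFSETS <- list(
  c(-1L, 1L), c(0L, 1L), c(1L, 1L), c(1L, 0L),
  c(1L, -1L), c(0L, -1L), c(-1L, -1L), c(-1L, 0L)
)

ref_neighbor <- function(state, v, dir) {
  u <- v + REF_OFFSETS[[dir + 1L]]
  if (state$topology == "torus") {
    return(c(u[1L] %% state$height, u[2L] %% state$width))
  }
  if (u[1L] < 0L || u[1L] >= state$height ||
      u[2L] < 0L || u[2L] >= state$width) return(NULL)
  u
}

ref_type <- function(state, v) {
  c("E", "S", "T", "D")[state$type[v[2L] * state$height + v[1L] + 1L] + 1L]
}

# is there a stem cell within Chebyshev/graph distance n of v at time t?
ref_stem_within <- function(state, v, n) {
  for (r in 0:(state$height - 1L)) {
    for (cc in 0:(state$width - 1L)) {
      if (ref_type(state, c(r, cc)) != "S") next
      dr <- abs(r - v[1L]); dc <- abs(cc - v[2L])
      if (state$topology == "torus") {
        dr <- min(dr, state$height - dr)
        dc <- min(dc, state$width - dc)
      }
      if (max(dr, dc) <= n) return(TRUE)
    }
  }
  FALSE
}

reference_step <- function(state, params) {
  h <- state$height; w <- state$width
  out <- state
  out$t <- state$t + 1L
  claimed <- matrix(FALSE, h, w)
  n_quiesce <- 0L
  n_emit <- 0L
  for (r in 0:(h - 1L)) {
    for (cc in 0:(w - 1L)) {
      v <- c(r, cc)
      cell <- cell_at(state, v)
      nxt <- NULL
      if (cell$type == "S") {
        if (cell$tau < params$psi) {
          nxt <- stem_cell(cell$d, cell$tau + 1L, cell$p)
        } else if (cell$p >= params$delta) {
          nxt <- empty_cell()
        } else {
          all_stem <- TRUE
          for (dir in 0:7) {
            u <- ref_neighbor(state, v, dir)
            if (!is.null(u) && ref_type(state, u) != "S") { all_stem <- FALSE; break }
          }
          if (all_stem) {
            nxt <- transitive_cell(g = 1L, tau = 0L)
          } else {
            placed <- FALSE
            for (s in 0:7) {
              dir <- (cell$d + s) %% 8L
              u <- ref_neighbor(state, v, dir)
              if (is.null(u)) next
              if (ref_type(state, u) == "E" && !claimed[u[1L] + 1L, u[2L] + 1L]) {
                claimed[u[1L] + 1L, u[2L] + 1L] <- TRUE
                out <- set_cell(out, u, stem_cell(0L, 0L, 0L))
                nxt <- stem_cell(d = (dir + 1L) %% 8L, tau = 0L, p = cell$p + 1L)
                placed <- TRUE
                break
              }
            }
            if (!placed) {
              nxt <- cell  # quiescent: retains its state
              n_quiesce <- n_quiesce + 1L
            }
          }
        }
      } else if (cell$type == "T") {
        if (!ref_stem_within(state, v, cell$g * params$eta)) {
          nxt <- stem_cell(d = 0L, tau = params$psi, p = 0L)
        } else if (cell$tau == cell$g * params$theta) {
          nxt <- if (cell$g < params$M) {
            transitive_cell(g = cell$g + 1L, tau = cell$tau)
          } else {
            differentiated_cell(tau = 0L)
          }
        } else {
          nxt <- transitive_cell(g = cell$g, tau = cell$tau + 1L)
        }
      } else if (cell$type == "D") {
        if (cell$tau == params$phi) {
          nxt <- empty_cell()
          n_emit <- n_emit + 1L
        } else {
          nxt <- differentiated_cell(cell$tau + 1L)
        }
      }
      if (!is.null(nxt)) out <- set_cell(out, v, nxt)
    }
  }
  attr(out, "quiesced") <- n_quiesce
  attr(out, "emitted") <- n_emit
  out
}

# random well-formed lattice state with all four cell types
random_state <- function(params, seed, probs = c(E = 0.3, S = 0.4, T = 0.2, D = 0.1)) {
  set.seed(seed)
  state <- empty_state(params)
  n <- params$width * params$height
  types <- sample(c(0L, 1L, 2L, 3L), n, replace = TRUE, prob = probs)
  state$type[] <- types
  S <- types == 1L
  state$d[S] <- sample(0:7, sum(S), replace = TRUE)
  state$tau[S] <- sample(0:params$psi, sum(S), replace = TRUE)
  state$p[S] <- sample(0:min(params$delta, 5L), sum(S), replace = TRUE)
  TT <- types == 2L
  g <- sample(seq_len(params$M), sum(TT), replace = TRUE)
  state$g[TT] <- g
  state$tau[TT] <- vapply(g, function(gg) sample(0:(gg * params$theta), 1L),
                          integer(1))
  D <- types == 3L
  state$tau[D] <- sample(0:params$phi, sum(D), replace = TRUE)
  state
}

states_equal <- function(a, b) {
  identical(a$type, b$type) && identical(a$d, b$d) &&
    identical(a$tau, b$tau) && identical(a$g, b$g) && identical(a$p, b$p)
}
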
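# Lattice state. Every vertex carries exactly one cell state:
#   Empty          (E)            -- 1-tuple
#   Differentiated (D, tau)       -- 2-tuple
#   Transitive     (T, g, tau)    -- 3-tuple, g in 1..M, tau cumulative
#   Stem           (S, d, tau, p) -- 4-tuple: direction d in 0..7,
#                                    counter tau in 0..psi, renewals p in 0..delta
#
# Internally the state is a set of parallel integer matrices (height x width),
# which keeps the synchronous update vectorised. Fields that do not apply to
# a vertex's type are held at 0 so that two states are equal iff their
# matrices are equal.

CELL_EMPTY <- 0L
CELL_STEM <- 1L
CELL_TRANSITIVE <- 2L
CELL_DIFFERENTIATED <- 3L

CELL_CODES <- c(E = CELL_EMPTY, S = CELL_STEM, T = CELL_TRANSITIVE,
                D = CELL_DIFFERENTIATED)

#' Create an all-empty marrow state
#'
#' @param params A [marrow_params()] (geometry is taken from it).
#' @param t Initial time (default 0).
#' @return A `marrow_state`: time `t` plus parallel integer matrices
#'   `type`, `d`, `tau`, `g`, `p` of dimension `height x width`.
#' @export
empty_state <- function(params, t = 0L) {
  z <- matrix(0L, params$height, params$width)
  structure(
    list(t = as.integer(t), type = z, d = z, tau = z, g = z, p = z,
         width = params$width, height = params$height,
         topology = params$topology),
    class = "marrow_state"
  )
}

#' @export
print.marrow_state <- function(x, ...) {
  cat(sprintf("<marrow_state t=%d, %dx%d: %d S, %d T, %d D, %d E>\n",
              x$t, x$height, x$width,
              sum(x$type == CELL_STEM), sum(x$type == CELL_TRANSITIVE),
              sum(x$type == CELL_DIFFERENTIATED), sum(x$type == CELL_EMPTY)))
  lines <- render_grid(x)
  if (x$height <= 25L && x$width <= 60L) cat(lines, sep = "\n")
  invisible(x)
}

# Cell state constructors (tagged lists), the user-facing view of one vertex.

#' Cell state constructors
#'
#' Build single-cell states: the 4-tuple stem state, 3-tuple transitive
#' state, 2-tuple differentiated state and the empty space.
#'
#' @param d Stem proliferation direction, 0..7 (0 = top-right diagonal,
#'   then clockwise).
#' @param tau Internal counter.
#' @param p Number of renewals already performed.
#' @param g Transitive generation (starts at 1).
#' @return A list with class `marrow_cell` and a `type` field in
#'   `c("S", "T", "D", "E")`.
#' @export
stem_cell <- function(d = 0L, tau = 0L, p = 0L) {
  structure(list(type = "S", d = as.integer(d), tau = as.integer(tau),
                 p = as.integer(p)), class = "marrow_cell")
}

#' @rdname stem_cell
#' @export
transitive_cell <- function(g = 1L, tau = 0L) {
  structure(list(type = "T", g = as.integer(g), tau = as.integer(tau)),
            class = "marrow_cell")
}

#' @rdname stem_cell
#' @export
differentiated_cell <- function(tau = 0L) {
  structure(list(type = "D", tau = as.integer(tau)), class = "marrow_cell")
}

#' @rdname stem_cell
#' @export
empty_cell <- function() {
  structure(list(type = "E"), class = "marrow_cell")
}

#' @export
print.marrow_cell <- function(x, ...) {
  cat(switch(x$type,
    S = sprintf("(S, d=%d, tau=%d, p=%d)", x$d, x$tau, x$p),
    T = sprintf("(T, g=%d, tau=%d)", x$g, x$tau),
    D = sprintf("(D, tau=%d)", x$tau),
    E = "(E)"), "\n")
  invisible(x)
}

#' Read or write one vertex of a state
#'
#' Vertices are 0-based `c(row, col)` pairs, row 0 at the top.
#'
#' @param state A `marrow_state`.
#' @param v Integer pair `c(row, col)`.
#' @return `cell_at()` returns a `marrow_cell`; `set_cell()` returns the
#'   modified state.
#' @export
cell_at <- function(state, v) {
  i <- state_index(state, v)
  switch(as.character(state$type[i]),
    "0" = empty_cell(),
    "1" = stem_cell(state$d[i], state$tau[i], state$p[i]),
    "2" = transitive_cell(state$g[i], state$tau[i]),
    "3" = differentiated_cell(state$tau[i])
  )
}

#' @rdname cell_at
#' @param cell A `marrow_cell` to place at `v`.
#' @export
set_cell <- function(state, v, cell) {
  i <- state_index(state, v)
  state$type[i] <- CELL_CODES[[cell$type]]
  state$d[i] <- if (cell$type == "S") cell$d else 0L
  state$tau[i] <- if (cell$type == "E") 0L else cell$tau
  state$g[i] <- if (cell$type == "T") cell$g else 0L
  state$p[i] <- if (cell$type == "S") cell$p else 0L
  state
}

state_index <- function(state, v) {
  v <- as.integer(v)
  if (length(v) != 2L || anyNA(v) ||
      v[1L] < 0L || v[1L] >= state$height ||
      v[2L] < 0L || v[2L] >= state$width) {
    stop(sprintf("vertex (%s) out of range for a %dx%d grid",
                 paste(v, collapse = ", "), state$height, state$width))
  }
  # matrices are stored column-major with 1-based indices
  (v[2L]) * state$height + v[1L] + 1L
}

#' Count cells of each type
#'
#' @param state A `marrow_state`.
#' @return Named integer vector with entries `S`, `T`, `D`, `E`.
#' @export
cell_counts <- function(state) {
  c(S = sum(state$type == CELL_STEM),
    T = sum(state$type == CELL_TRANSITIVE),
    D = sum(state$type == CELL_DIFFERENTIATED),
    E = sum(state$type == CELL_EMPTY))
}

#' Render a state as a character grid
#'
#' One string per lattice row; `S`, `T`, `D` mark cell types and `.` marks
#' empty space, matching the visual style of the model's published grids.
#'
#' @param state A `marrow_state`.
#' @return Character vector of length `height`.
#' @export
render_grid <- function(state) {
  glyphs <- c("E" = ".", "S" = "S", "T" = "T", "D" = "D")
  m <- matrix(glyphs[state$type + 1L], state$height, state$width)
  apply(m, 1L, paste0, collapse = "")
}

# Canonical scalar key of a full state (type and all counters, not time);
# used for cycle detection. Two configurations hash equal iff all five
# matrices are equal.
state_key <- function(state) {
  paste(c(state$type, state$d, state$tau, state$g, state$p), collapse = ",")
}

#' Validate the internal invariants of a state
#'
#' Checks that every counter respects its type's bound: stem `tau <= psi`
#' and `p <= delta`, transitive `1 <= g <= M` and `tau <= g * theta`,
#' differentiated `tau <= phi`, and that fields not applicable to a type
#' are zero.
#'
#' @param state A `marrow_state`.
#' @param params A [marrow_params()].
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_state <- function(state, params) {
  S <- state$type == CELL_STEM
  Tm <- state$type == CELL_TRANSITIVE
  D <- state$type == CELL_DIFFERENTIATED
  E <- state$type == CELL_EMPTY
  ok <- TRUE
  fail <- function(msg) stop("invalid marrow_state: ", msg)
  if (any(S & (state$tau > params$psi))) fail("stem tau exceeds psi")
  if (any(S & (state$p > params$delta))) fail("stem renewals exceed delta")
  if (any(S & (state$d < 0L | state$d > 7L))) fail("stem direction out of 0..7")
  if (any(Tm & (state$g < 1L | state$g > params$M))) fail("transitive generation out of 1..M")
  if (any(Tm & (state$tau > state$g * params$theta))) fail("transitive tau exceeds g*theta")
  if (any(D & (state$tau > params$phi))) fail("differentiated tau exceeds phi")
  if (any(E & (state$tau != 0L | state$d != 0L | state$g != 0L | state$p != 0L)))
    fail("empty space carries counters")
  if (any(!S & state$d != 0L) || any(!S & state$p != 0L) || any(!Tm & state$g != 0L))
    fail("inapplicable fields must be zero")
  invisible(TRUE)
}
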
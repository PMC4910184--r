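# Lattice geometry: the bone marrow as a connected, locally finite graph.
# The shipped geometry is the regular 2D Moore lattice (8-connectivity),
# either bounded (cells on the border have truncated neighbourhoods) or
# wrapped into a torus.

# The eight Moore directions, indexed 0..7 clockwise starting at the
# top-right diagonal, in screen orientation (row 0 at the top):
# NE, E, SE, S, SW, W, NW, N.
MOORE_OFFSETS <- matrix(
  c(-1L, 1L,   # NE
     0L, 1L,   # E
     1L, 1L,   # SE
     1L, 0L,   # S
     1L, -1L,  # SW
     0L, -1L,  # W
    -1L, -1L,  # NW
    -1L, 0L),  # N
  ncol = 2L, byrow = TRUE,
  dimnames = list(c("NE", "E", "SE", "S", "SW", "W", "NW", "N"),
                  c("drow", "dcol"))
)

#' Construct a bone-marrow lattice
#'
#' The marrow is modelled as a connected, locally finite undirected graph.
#' Every vertex is a cell site with up to `mu = 8` immediate neighbours
#' (Moore scheme). On a `bounded` grid, border vertices keep only their
#' on-lattice neighbours (3 at a corner, 5 on an edge); on a `torus` every
#' vertex has exactly 8.
#'
#' @param width,height Positive integer lattice dimensions.
#' @param topology `"bounded"` (default) or `"torus"`.
#'
#' @return An object of class `marrow_grid` with fields `width`, `height`,
#'   `topology` and `mu` (the degree bound, 8).
#' @export
#' @examples
#' g <- marrow_grid(10, 10)
#' grid_neighbors(g, c(0, 0))   # corner: 3 neighbours
marrow_grid <- function(width, height, topology = c("bounded", "torus")) {
  topology <- match.arg(topology)
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || width < 1L) stop("`width` must be a positive integer")
  if (is.na(height) || height < 1L) stop("`height` must be a positive integer")
  structure(
    list(width = width, height = height, topology = topology, mu = 8L),
    class = "marrow_grid"
  )
}

#' @export
print.marrow_grid <- function(x, ...) {
  cat(sprintf("<marrow_grid %dx%d, %s, mu = %d>\n",
              x$height, x$width, x$topology, x$mu))
  invisible(x)
}

check_vertex <- function(grid, v) {
  v <- as.integer(v)
  if (length(v) != 2L || anyNA(v)) {
    stop("a vertex is an integer pair (row, col)")
  }
  if (v[1L] < 0L || v[1L] >= grid$height || v[2L] < 0L || v[2L] >= grid$width) {
    stop(sprintf("vertex (%d, %d) out of range for a %dx%d grid",
                 v[1L], v[2L], grid$height, grid$width))
  }
  v
}

#' Immediate Moore neighbourhood of a vertex
#'
#' Returns the neighbours `N(v)` of `v` in the fixed clockwise direction
#' order NE, E, SE, S, SW, W, NW, N. On a bounded grid, off-lattice
#' positions are dropped (the order of the remaining neighbours is kept);
#' on a torus, coordinates wrap.
#'
#' @param grid A [marrow_grid()].
#' @param v Integer pair `c(row, col)`, 0-based.
#'
#' @return Integer matrix with columns `row`, `col` and one row per
#'   neighbour; direction names as rownames.
#' @export
grid_neighbors <- function(grid, v) {
  v <- check_vertex(grid, v)
  rows <- v[1L] + MOORE_OFFSETS[, "drow"]
  cols <- v[2L] + MOORE_OFFSETS[, "dcol"]
  if (grid$topology == "torus") {
    rows <- rows %% grid$height
    cols <- cols %% grid$width
    keep <- rep(TRUE, 8L)
    # degenerate wrap (width or height <= 2) can alias neighbours onto v
    keep <- !(rows == v[1L] & cols == v[2L])
  } else {
    keep <- rows >= 0L & rows < grid$height & cols >= 0L & cols < grid$width
  }
  out <- cbind(row = rows[keep], col = cols[keep])
  rownames(out) <- rownames(MOORE_OFFSETS)[keep]
  # a torus thinner than 3 duplicates neighbours; keep first occurrence
  out[!duplicated(out), , drop = FALSE]
}

#' Shortest-path distance between two vertices
#'
#' The graph metric \eqn{\rho(u, v)} induced by the Moore lattice: the
#' Chebyshev distance `max(|drow|, |dcol|)` on a bounded grid, its wrapped
#' form on a torus.
#'
#' @param grid A [marrow_grid()].
#' @param u,v Integer pairs `c(row, col)`, 0-based.
#' @return Non-negative integer distance.
#' @export
grid_distance <- function(grid, u, v) {
  u <- check_vertex(grid, u)
  v <- check_vertex(grid, v)
  dr <- abs(u[1L] - v[1L])
  dc <- abs(u[2L] - v[2L])
  if (grid$topology == "torus") {
    dr <- min(dr, grid$height - dr)
    dc <- min(dc, grid$width - dc)
  }
  max(dr, dc)
}

#' Ball of radius n around a vertex
#'
#' `B(v, n)`: all vertices within shortest-path distance `n` of `v`,
#' including `v` itself. This is the "near neighbourhood" used by the
#' dedifferentiation rule, whose radius grows with the transitive cell's
#' generation.
#'
#' @param grid A [marrow_grid()].
#' @param v Integer pair `c(row, col)`, 0-based.
#' @param n Non-negative integer radius.
#' @return Integer matrix with columns `row`, `col`, one row per vertex,
#'   in row-major order.
#' @export
grid_ball <- function(grid, v, n) {
  v <- check_vertex(grid, v)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be a non-negative integer")
  rows <- 0:(grid$height - 1L)
  cols <- 0:(grid$width - 1L)
  dr <- abs(rows - v[1L])
  dc <- abs(cols - v[2L])
  if (grid$topology == "torus") {
    dr <- pmin(dr, grid$height - dr)
    dc <- pmin(dc, grid$width - dc)
  }
  keep_r <- rows[dr <= n]
  keep_c <- cols[dc <= n]
  out <- cbind(row = rep(keep_r, each = length(keep_c)),
               col = rep(keep_c, times = length(keep_r)))
  out
}

# Value of `m` at each cell's neighbour in offset (dr, dc); `fill` is used
# for off-lattice neighbours on bounded grids.
shift_matrix <- function(m, dr, dc, topology, fill) {
  h <- nrow(m)
  w <- ncol(m)
  if (topology == "torus") {
    ri <- ((seq_len(h) - 1L + dr) %% h) + 1L
    ci <- ((seq_len(w) - 1L + dc) %% w) + 1L
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(fill, h, w)
  rs <- seq_len(h) + dr
  cs <- seq_len(w) + dc
  vr <- rs >= 1L & rs <= h
  vc <- cs >= 1L & cs <= w
  if (any(vr) && any(vc)) {
    out[vr, vc] <- m[rs[vr], cs[vc], drop = FALSE]
  }
  out
}
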
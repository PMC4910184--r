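# Configuration, snapshot and time-series I/O. All tables are plain CSV
# with a header row; the snapshot pair couples a human-readable character
# grid with a full per-vertex table. Outputs are bit-stable across
# identical runs (the model is deterministic).

CONFIG_KEYS <- c("psi", "theta", "phi", "delta", "M", "eta",
                 "width", "height", "topology",
                 "scenario", "fraction", "seed", "sync_tau", "sync_p",
                 "steps", "snapshot_every", "perturbations", "output_dir")

SCENARIO_KINDS <- c("single_center_stem", "even_fraction_stem",
                    "random_mixture", "all_stem_synchronized",
                    "custom_snapshot")

#' Load a run configuration
#'
#' Reads a flat YAML document holding the model parameters, the initial
#' scenario, the run length and optional perturbation schedule. All
#' parameter invariants are validated (the four maturities and the renewal
#' limit must be positive nonzero integers); unknown keys are rejected.
#' Every offending key is reported in a single error message.
#'
#' Recognised keys: `psi`, `theta`, `phi`, `delta`, `M`, `eta`, `width`,
#' `height`, `topology`, `scenario` (one of `single_center_stem`,
#' `even_fraction_stem`, `random_mixture`, `all_stem_synchronized`,
#' `custom_snapshot`), `fraction`, `seed`, `sync_tau`, `sync_p`, `steps`,
#' `snapshot_every` (0 = no snapshots), `perturbations` (list of `time`,
#' `fraction`, `seed`), `output_dir`, `snapshot` (path, for
#' `custom_snapshot`).
#'
#' @param path Path to a YAML config file.
#' @return A `marrow_config`: list with `params` (a [marrow_params()]),
#'   `scenario`, scenario arguments, `steps`, `snapshot_every`,
#'   `perturbations` and `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  build_config(raw)
}

build_config <- function(raw) {
  errs <- character(0)
  unknown <- setdiff(names(raw), c(CONFIG_KEYS, "snapshot"))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  need_pos <- c("psi", "theta", "phi", "delta", "M", "eta", "width", "height")
  for (k in need_pos) {
    v <- raw[[k]]
    if (is.null(v)) next  # defaults apply
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != as.integer(v) || v < 1) {
      errs <- c(errs, sprintf("`%s` must be a positive nonzero integer (got %s)",
                              k, deparse(v)))
    }
  }
  topo <- raw$topology %||% "bounded"
  if (!topo %in% c("bounded", "torus")) {
    errs <- c(errs, sprintf("`topology` must be \"bounded\" or \"torus\" (got %s)",
                            deparse(topo)))
  }
  scen <- raw$scenario %||% "single_center_stem"
  if (!scen %in% SCENARIO_KINDS) {
    errs <- c(errs, sprintf("`scenario` must be one of %s",
                            paste(SCENARIO_KINDS, collapse = ", ")))
  }
  steps <- raw$steps %||% 100L
  if (!is.numeric(steps) || length(steps) != 1L || is.na(steps) || steps < 1) {
    errs <- c(errs, "`steps` must be a positive integer")
  }
  frac <- raw$fraction
  if (!is.null(frac) && (!is.numeric(frac) || is.na(frac) || frac < 0 || frac > 1)) {
    errs <- c(errs, "`fraction` must lie in [0, 1]")
  }
  if (identical(scen, "random_mixture") && is.null(raw$seed)) {
    errs <- c(errs, "`seed` is required for the random_mixture scenario")
  }
  perts <- raw$perturbations
  if (!is.null(perts)) {
    for (i in seq_along(perts)) {
      p <- perts[[i]]
      if (is.null(p$time) || is.null(p$fraction) ||
          !is.numeric(p$time) || p$time < 0 ||
          !is.numeric(p$fraction) || p$fraction < 0 || p$fraction > 1 ||
          (is.numeric(steps) && length(steps) == 1L && !is.na(steps) && p$time >= steps)) {
        errs <- c(errs, sprintf(
          "perturbation %d needs `time` in [0, steps) and `fraction` in [0, 1]", i))
      }
    }
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  params <- marrow_params(
    psi = raw$psi %||% 2, theta = raw$theta %||% 2, phi = raw$phi %||% 50,
    delta = raw$delta %||% 1e6, M = raw$M %||% 2, eta = raw$eta %||% 1,
    width = raw$width %||% 41, height = raw$height %||% 41,
    topology = topo)
  structure(
    list(params = params, scenario = scen,
         fraction = frac %||% 0.2,
         seed = raw$seed %||% 1L,
         sync_tau = raw$sync_tau %||% 0L,
         sync_p = raw$sync_p %||% 0L,
         snapshot = raw$snapshot,
         steps = as.integer(steps),
         snapshot_every = as.integer(raw$snapshot_every %||% 0L),
         perturbations = perts,
         output_dir = raw$output_dir %||% "."),
    class = "marrow_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param config A `marrow_config`.
#' @export
save_config <- function(config, path) {
  p <- config$params
  out <- list(psi = p$psi, theta = p$theta, phi = p$phi, delta = p$delta,
              M = p$M, eta = p$eta, width = p$width, height = p$height,
              topology = p$topology,
              scenario = config$scenario, fraction = config$fraction,
              seed = config$seed, sync_tau = config$sync_tau,
              sync_p = config$sync_p,
              steps = config$steps, snapshot_every = config$snapshot_every,
              output_dir = config$output_dir)
  if (!is.null(config$perturbations)) out$perturbations <- config$perturbations
  if (!is.null(config$snapshot)) out$snapshot <- config$snapshot
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build the initial state described by a configuration
#'
#' @param config A `marrow_config` from [load_config()].
#' @return A `marrow_state` at `t = 0`.
#' @export
initial_state <- function(config) {
  p <- config$params
  switch(config$scenario,
    single_center_stem = single_center_stem(p),
    even_fraction_stem = even_fraction_stem(p, config$fraction),
    random_mixture = random_mixture(p, config$fraction, config$seed),
    all_stem_synchronized = all_stem_synchronized(p, config$sync_tau,
                                                  config$sync_p),
    custom_snapshot = {
      if (is.null(config$snapshot)) stop("custom_snapshot needs a `snapshot` path")
      read_snapshot(config$snapshot)
    })
}

#' Write / read a full state snapshot
#'
#' Writes two coupled files: `<path>.grid.txt`, a character grid with one
#' row per lattice row over the alphabet `S`, `T`, `D`, `.` (empty), and
#' `<path>.cells.csv`, a table with columns `row`, `col`, `type`, `d`,
#' `tau`, `g`, `p` carrying the full state. `read_snapshot()` restores the
#' state from the table (the grid is for the human); read after write is
#' the identity.
#'
#' @param state A `marrow_state`.
#' @param path Base path (extensions are appended).
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns a `marrow_state`.
#' @export
write_snapshot <- function(state, path) {
  writeLines(c(sprintf("# t=%d %dx%d %s", state$t, state$height, state$width,
                       state$topology),
               render_grid(state)),
             paste0(path, ".grid.txt"))
  idx <- order_row_major(state$height, state$width)
  glyphs <- c("E", "S", "T", "D")
  df <- data.frame(
    row = (idx - 1L) %% state$height,
    col = (idx - 1L) %/% state$height,
    type = glyphs[state$type[idx] + 1L],
    d = state$d[idx], tau = state$tau[idx], g = state$g[idx], p = state$p[idx])
  con <- file(paste0(path, ".cells.csv"), open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# t=%d height=%d width=%d topology=%s",
                     state$t, state$height, state$width, state$topology), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  csv <- paste0(path, ".cells.csv")
  if (!file.exists(csv)) stop("snapshot table not found: ", csv)
  hdr <- readLines(csv, n = 1L)
  m <- regmatches(hdr, regexec(
    "^# t=(\\d+) height=(\\d+) width=(\\d+) topology=(\\w+)$", hdr))[[1]]
  if (length(m) != 5L) stop("malformed snapshot header: ", hdr)
  t0 <- as.integer(m[2]); h <- as.integer(m[3]); w <- as.integer(m[4])
  df <- utils::read.csv(csv, skip = 1L, stringsAsFactors = FALSE)
  if (nrow(df) != h * w) {
    stop(sprintf("snapshot table has %d rows, expected %d", nrow(df), h * w))
  }
  params <- marrow_params(width = w, height = h, topology = m[5])
  state <- empty_state(params, t = t0)
  key <- df$col * h + df$row + 1L
  if (anyDuplicated(key)) {
    stop("duplicate vertex at table line ",
         which(duplicated(key))[1L] + 2L)
  }
  bad <- which(!df$type %in% c("E", "S", "T", "D") |
               df$row < 0 | df$row >= h | df$col < 0 | df$col >= w)
  if (length(bad)) {
    stop("out-of-range field at table line ", bad[1L] + 2L)
  }
  state$type[key] <- CELL_CODES[df$type]
  state$d[key] <- as.integer(df$d)
  state$tau[key] <- as.integer(df$tau)
  state$g[key] <- as.integer(df$g)
  state$p[key] <- as.integer(df$p)
  state
}

#' Write a trajectory time series
#'
#' One CSV row per step with the columns `t`, `n_stem`, `n_transitive`,
#' `n_differentiated`, `n_empty`, `quiescent_fraction_pct`, `deaths`,
#' `proliferations`, `dedifferentiations`, `matured_emitted`,
#' `cumulative_output`.
#'
#' @param trajectory A `marrow_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(trajectory, path) {
  r <- trajectory$reports
  df <- data.frame(
    t = r$t, n_stem = r$n_stem, n_transitive = r$n_transitive,
    n_differentiated = r$n_differentiated, n_empty = r$n_empty,
    quiescent_fraction_pct = r$quiescent_fraction_pct,
    deaths = r$deaths, proliferations = r$proliferations,
    dedifferentiations = r$dedifferentiations,
    matured_emitted = r$emitted, cumulative_output = r$cumulative_output)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
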
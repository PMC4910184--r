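params5 <- marrow_params(psi = 1, theta = 2, phi = 5, delta = 1e6,
                        M = 2, eta = 1, width = 5, height = 5)

test_that("stem subrules fire in order: apoptosis, conversion, proliferation, tick", {
  p <- marrow_params(psi = 3, theta = 1, phi = 1, delta = 4, M = 1, eta = 1,
                     width = 5, height = 5)
  s <- empty_state(p)
  # apoptosis wins even with empty neighbours
  s1 <- set_cell(s, c(2, 2), stem_cell(d = 0, tau = p$psi, p = p$delta))
  expect_equal(stem_intent(s1, c(2, 2), p)$action, "die")
  # below threshold: tick
  s2 <- set_cell(s, c(2, 2), stem_cell(d = 0, tau = 1, p = 0))
  expect_equal(stem_intent(s2, c(2, 2), p)$action, "tick")
  # mature at centre, all 8 empty, d = 0: proliferate into the NE neighbour
  s3 <- set_cell(s, c(2, 2), stem_cell(d = 0, tau = p$psi, p = 0))
  it <- stem_intent(s3, c(2, 2), p)
  expect_equal(it$action, "proliferate")
  expect_equal(it$target, c(1, 3))
  expect_equal(it$used_direction, 0)
  # saturated neighbourhood: conversion
  s4 <- s3
  for (k in seq_len(nrow(grid_neighbors(params_grid(p), c(2, 2))))) {
    nb <- grid_neighbors(params_grid(p), c(2, 2))
    s4 <- set_cell(s4, nb[k, ], stem_cell())
  }
  expect_equal(stem_intent(s4, c(2, 2), p)$action, "convert")
  expect_error(stem_intent(s, c(0, 0), p), "stem")
})

test_that("round-robin scan skips occupied directions", {
  p <- params5
  s <- empty_state(p)
  s <- set_cell(s, c(2, 2), stem_cell(d = 0, tau = 1, p = 0))
  s <- set_cell(s, c(1, 3), transitive_cell(1, 0))  # NE blocked
  s <- set_cell(s, c(2, 3), differentiated_cell(0)) # E blocked
  it <- stem_intent(s, c(2, 2), p)
  expect_equal(it$used_direction, 2)  # SE
  expect_equal(it$target, c(3, 3))
})

test_that("conflicting proliferation claims resolve in row-major order", {
  p <- marrow_params(psi = 1, theta = 1, phi = 1, delta = 10, M = 1, eta = 1,
                     width = 3, height = 3)
  # two mature stems flank the single empty site (1, 1); everything else
  # is transitive so neither stem can convert
  s <- empty_state(p)
  for (r in 0:2) for (cc in 0:2) s <- set_cell(s, c(r, cc), transitive_cell(1, 0))
  s <- set_cell(s, c(1, 0), stem_cell(d = 1, tau = 1, p = 0))  # targets E=(1,1)
  s <- set_cell(s, c(1, 2), stem_cell(d = 5, tau = 1, p = 0))  # targets W=(1,1)
  s <- set_cell(s, c(1, 1), empty_cell())
  intents <- list(
    "1,0" = stem_intent(s, c(1, 0), p),
    "1,2" = stem_intent(s, c(1, 2), p))
  expect_equal(intents[["1,0"]]$target, c(1, 1))
  expect_equal(intents[["1,2"]]$target, c(1, 1))
  res <- resolve_proliferation(intents, s, p)
  expect_equal(res[["1,0"]]$action, "proliferate")  # row-major earlier wins
  expect_equal(res[["1,2"]]$action, "quiesce")
  # the full step agrees: exactly one proliferation, one quiescence event
  out <- marrow_step(s, p)
  expect_equal(out$report$proliferations, 1)
  expect_equal(out$report$quiescent, 1)
  expect_equal(cell_at(out$state, c(1, 1))$type, "S")

  # disjoint targets are left unchanged
  s2 <- empty_state(p)
  s2 <- set_cell(s2, c(0, 0), stem_cell(d = 1, tau = 1, p = 0))
  s2 <- set_cell(s2, c(2, 2), stem_cell(d = 1, tau = 1, p = 0))
  intents2 <- list(
    "0,0" = stem_intent(s2, c(0, 0), p),
    "2,2" = stem_intent(s2, c(2, 2), p))
  expect_identical(resolve_proliferation(intents2, s2, p), intents2)
})

test_that("a stem whose target is taken mid-resolution re-scans and proliferates", {
  p <- marrow_params(psi = 1, theta = 1, phi = 1, delta = 10, M = 1, eta = 1,
                     width = 4, height = 3)
  # stems at (0,1) and (1,0) both initially target (0, 2) and (0, 1)... build
  # a fixture where the row-major earlier stem takes the later stem's target,
  # and the later stem still has another empty neighbour to fall back to.
  s <- empty_state(p)
  for (r in 0:2) for (cc in 0:3) s <- set_cell(s, c(r, cc), transitive_cell(1, 0))
  s <- set_cell(s, c(0, 2), empty_cell())
  s <- set_cell(s, c(2, 2), empty_cell())
  s <- set_cell(s, c(0, 1), stem_cell(d = 1, tau = 1, p = 0))  # E -> (0,2)
  s <- set_cell(s, c(1, 1), stem_cell(d = 0, tau = 1, p = 0))  # NE -> (0,2)
  intents <- list(
    "0,1" = stem_intent(s, c(0, 1), p),
    "1,1" = stem_intent(s, c(1, 1), p))
  expect_equal(intents[["0,1"]]$target, c(0, 2))
  expect_equal(intents[["1,1"]]$target, c(0, 2))
  res <- resolve_proliferation(intents, s, p)
  expect_equal(res[["0,1"]]$target, c(0, 2))
  # (1,1) re-scans clockwise from the failed NE direction and finds SE=(2,2)
  expect_equal(res[["1,1"]]$action, "proliferate")
  expect_equal(res[["1,1"]]$target, c(2, 2))
  expect_equal(res[["1,1"]]$used_direction, 2)
})

test_that("transitive cells mature cumulatively, differentiate, and dedifferentiate", {
  p <- marrow_params(psi = 2, theta = 3, phi = 4, delta = 10, M = 2, eta = 1,
                     width = 7, height = 7)
  s <- empty_state(p)
  s <- set_cell(s, c(3, 3), transitive_cell(g = 2, tau = 2 * p$theta))
  s <- set_cell(s, c(3, 4), stem_cell())  # stem within ball(v, g*eta)
  expect_equal(transitive_update(s, c(3, 3), p)$type, "D")
  expect_equal(transitive_update(s, c(3, 3), p)$tau, 0)

  # generation advance keeps the cumulative counter
  s2 <- set_cell(s, c(3, 3), transitive_cell(g = 1, tau = p$theta))
  up <- transitive_update(s2, c(3, 3), p)
  expect_equal(up$g, 2)
  expect_equal(up$tau, p$theta)

  # no stem anywhere: dedifferentiation to a mature stem cell
  s3 <- empty_state(p)
  s3 <- set_cell(s3, c(3, 3), transitive_cell(g = 1, tau = 0))
  up3 <- transitive_update(s3, c(3, 3), p)
  expect_equal(up3$type, "S")
  expect_equal(up3$tau, p$psi)
  expect_equal(up3$p, 0)

  # a stem just outside ball(v, g*eta) does not prevent dedifferentiation
  s4 <- set_cell(s3, c(3, 5), stem_cell())   # distance 2 > 1*eta
  expect_equal(transitive_update(s4, c(3, 3), p)$type, "S")
  s5 <- set_cell(s3, c(1, 1), stem_cell())   # distance 2 <= 2*eta for g=2
  s5 <- set_cell(s5, c(3, 3), transitive_cell(g = 2, tau = 1))
  expect_equal(transitive_update(s5, c(3, 3), p)$type, "T")

  # plain tick
  s6 <- set_cell(s, c(3, 3), transitive_cell(g = 1, tau = 0))
  expect_equal(transitive_update(s6, c(3, 3), p)$tau, 1)
  expect_error(transitive_update(s, c(0, 0), p), "transitive")
})

test_that("differentiated cells tick and emigrate at maturity", {
  p <- params5
  s <- empty_state(p)
  s <- set_cell(s, c(2, 2), differentiated_cell(p$phi))
  expect_equal(differentiated_update(s, c(2, 2), p)$type, "E")
  s2 <- set_cell(s, c(2, 2), differentiated_cell(0))
  expect_equal(differentiated_update(s2, c(2, 2), p)$tau, 1)

  # a lattice of mature differentiated cells empties in one step
  s3 <- empty_state(p)
  s3$type[] <- 3L
  s3$tau[] <- p$phi
  out <- marrow_step(s3, p)
  expect_equal(unname(cell_counts(out$state)["E"]), 25)
  expect_equal(out$report$emitted, 25)
})

test_that("empty lattice is a fixed point and a dying stem empties its site", {
  p <- params5
  s <- empty_state(p)
  out <- marrow_step(s, p)
  expect_true(all(out$state$type == 0L))
  expect_equal(out$report$proliferations, 0)

  p2 <- marrow_params(psi = 1, theta = 1, phi = 1, delta = 3, M = 1, eta = 1,
                      width = 5, height = 5)
  s2 <- set_cell(empty_state(p2), c(2, 2), stem_cell(d = 0, tau = 1, p = 3))
  out2 <- marrow_step(s2, p2)
  expect_equal(sum(cell_counts(out2$state)[c("S", "T", "D")]), 0)
  expect_equal(out2$report$deaths, 1)
})

test_that("single-stem expansion follows the clockwise fill, step by step", {
  # hand-simulated expected grids for psi = 1 on a 5x5 lattice: the first
  # daughter goes to the top-right diagonal, later ones continue clockwise,
  # and by t = 8 the first saturated stem has converted to a transitive
  # cell while two blocked stems quiesce
  s <- single_center_stem(params5)
  expected <- list(
    `2` = c(".....",
            "...S.",
            "..S..",
            ".....",
            "....."),
    `4` = c("....S",
            "...S.",
            "..SS.",
            ".....",
            "....."),
    `6` = c("....S",
            "...SS",
            "..SSS",
            "...SS",
            "....."),
    `8` = c("...SS",
            "..SSS",
            "..SST",
            "..SSS",
            "...SS"))
  for (k in 1:8) {
    res <- marrow_step(s, params5)
    s <- res$state
    if (as.character(k) %in% names(expected)) {
      expect_equal(render_grid(s), expected[[as.character(k)]],
                   info = paste("t =", k))
    }
  }
  expect_equal(res$report$conversions_st, 1)
  expect_equal(res$report$quiescent, 2)
  expect_equal(res$report$proliferations, 5)
})

test_that("the step operator is a semigroup and conserves lattice sites", {
  p <- marrow_params(psi = 2, theta = 2, phi = 3, delta = 5, M = 2, eta = 1,
                     width = 8, height = 8)
  s0 <- random_state(p, seed = 11)
  whole <- marrow_run(s0, p, 30)
  part1 <- marrow_run(s0, p, 12)
  part2 <- marrow_run(part1$final, p, 18)
  expect_true(states_equal(whole$final, part2$final))
  expect_equal(whole$final$t, 30)
  # conservation of sites at every step
  tr <- marrow_run(s0, p, 30, record_snapshots = TRUE)
  for (s in tr$states) {
    expect_equal(sum(cell_counts(s)), 64)
    expect_silent(validate_state(s, p))
  }
})

test_that("all counter invariants hold along random trajectories", {
  for (seed in 1:4) {
    p <- marrow_params(psi = 1 + seed %% 3, theta = 1 + seed %% 2,
                       phi = 2, delta = 3, M = 2, eta = 1,
                       width = 7, height = 7,
                       topology = if (seed %% 2 == 0) "torus" else "bounded")
    s <- random_state(p, seed = seed)
    tr <- marrow_run(s, p, 40, record_snapshots = TRUE)
    for (snap in tr$states) expect_silent(validate_state(snap, p))
    # events are consistent: proliferations never exceed prior empties
    prev_empty <- vapply(tr$states[-length(tr$states)],
                         function(x) sum(x$type == 0L), integer(1))
    expect_true(all(tr$reports$proliferations <= prev_empty))
  }
})

test_that("production engine matches the per-cell reference on random states", {
  p <- marrow_params(psi = 2, theta = 2, phi = 3, delta = 4, M = 2, eta = 1,
                     width = 8, height = 8)
  for (seed in c(3, 14)) {
    prod <- random_state(p, seed = seed)
    ref <- prod
    for (k in 1:25) {
      out <- marrow_step(prod, p)
      ref2 <- reference_step(ref, p)
      expect_true(states_equal(out$state, ref2),
                  info = sprintf("seed %d step %d", seed, k))
      expect_equal(out$report$quiescent, attr(ref2, "quiesced"))
      expect_equal(out$report$emitted, attr(ref2, "emitted"))
      prod <- out$state
      ref <- ref2
    }
  }
})

test_that("identical runs are bit-identical (the model has no random element)", {
  p <- marrow_params(psi = 2, theta = 1, phi = 2, delta = 10, M = 1, eta = 1,
                     width = 9, height = 9)
  a <- marrow_run(single_center_stem(p), p, 60)
  b <- marrow_run(single_center_stem(p), p, 60)
  expect_identical(a$reports, b$reports)
  expect_true(states_equal(a$final, b$final))
})
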
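sde_params <- function(q = 2) {
  set_circuit_q(generic_params(a = 1, f = 1, b = 0.5, c = 0.5, d = 0.5), q)
}

test_that("noiseless simulation is exactly deterministic Euler", {
  p <- sde_params(2)
  tr <- simulate_circuit(p, sigma = 0, dt = 0.01, n_steps = 5000,
                         init = c(0.3, 0.8), seed = 5)
  eu <- integrate_euler(p, dt = 0.01, n_steps = 5000, init = c(0.3, 0.8))
  expect_identical(tr$x, eu$x)
  expect_identical(tr$y, eu$y)

  # a fixed point stays fixed to machine precision
  tr_fix <- simulate_circuit(p, sigma = 0, dt = 0.01, n_steps = 2000,
                             init = c(2, 0))
  expect_lt(max(abs(tr_fix$x - 2)), 1e-13)
  expect_identical(max(tr_fix$y), 0)
})

test_that("the deterministic flow reaches the symmetric attractor below q = 1", {
  p <- sde_params(0.5)
  tr <- simulate_circuit(p, sigma = 0, dt = 0.01, n_steps = 1e5,
                         init = c(0.1, 0.1))
  s <- -3 + sqrt(17)
  expect_equal(tr$x[nrow(tr)], s, tolerance = 1e-6)
  expect_equal(tr$y[nrow(tr)], s, tolerance = 1e-6)
})

test_that("equal seeds give bit-identical trajectories, unequal seeds differ", {
  p <- sde_params(2)
  t1 <- simulate_circuit(p, sigma = 0.05, n_steps = 2000, seed = 42)
  t2 <- simulate_circuit(p, sigma = 0.05, n_steps = 2000, seed = 42)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  t3 <- simulate_circuit(p, sigma = 0.05, n_steps = 2000, seed = 43)
  expect_false(identical(t1$x, t3$x))

  e1 <- simulate_ensemble(p, sigma = 0.05, n_steps = 500, seed = 7)
  e2 <- simulate_ensemble(p, sigma = 0.05, n_steps = 500, seed = 7)
  expect_identical(e1, e2)
})

test_that("the zero clamp never fires for the noiseless interior flow", {
  p <- sde_params(2)
  for (init in list(c(0.1, 0.1), c(1, 1), c(2.5, 0.5))) {
    tr <- simulate_circuit(p, sigma = 0, dt = 0.01, n_steps = 5000,
                           init = init)
    expect_true(all(tr$x > 0))
    expect_true(all(tr$y > 0))
  }
})

test_that("saturating production keeps even wildly unstable steps bounded", {
  # production is bounded by a/b, so the explicit step cannot run away; the
  # clamp turns the overshoot into a bounded oscillation rather than an error
  p <- sde_params(2)
  tr <- simulate_circuit(p, sigma = 0, dt = 25, n_steps = 200,
                         init = c(2.1, 0.3))
  expect_true(all(is.finite(tr$x) & is.finite(tr$y)))
  expect_lt(max(tr$x, tr$y), 10)
})

test_that("stationary density is a normalized histogram with sane support", {
  p <- sde_params(2)
  tr <- simulate_circuit(p, sigma = 0.05, n_steps = 2e4, seed = 3)
  g <- stationary_density(tr, n_bins = 60)
  expect_equal(sum(g$prob), 1, tolerance = 1e-12)
  expect_true(all(g$prob >= 0))
  expect_equal(dim(g$prob), c(60, 60))

  # a constant trajectory concentrates all mass in a single bin
  const <- tibble::tibble(x = rep(2, 1000), y = rep(0, 1000))
  gc <- stationary_density(const, n_bins = 50, lim = 2.4, smooth = FALSE)
  expect_equal(max(gc$prob), 1)
  expect_equal(sum(gc$prob > 0), 1)
  expect_equal(nrow(count_modes(gc)), 1)
})

test_that("mode detection finds, thresholds and merges local maxima", {
  mids <- seq(0.025, 2.475, by = 0.05)  # 50 bins on [0, 2.5]
  bump <- function(cx, cy, h) {
    outer(mids, mids, function(x, y) h * exp(-((x - cx)^2 + (y - cy)^2) / 0.02))
  }
  two <- bump(2.025, 0.125, 1) + bump(0.125, 2.025, 0.8)
  g <- structure(list(prob = two / sum(two), x_mid = mids, y_mid = mids,
                      config = NULL, smooth = TRUE), class = "density_grid")
  m <- count_modes(g)
  expect_equal(nrow(m), 2)
  expect_equal(m$x[1], 2.025, tolerance = 1e-12)
  expect_equal(m$y[1], 0.125, tolerance = 1e-12)

  # a sub-threshold third peak is ignored
  three <- two + bump(1.2, 1.2, 0.05)
  g3 <- g; g3$prob <- three / sum(three)
  expect_equal(nrow(count_modes(g3, rel_threshold = 0.1)), 2)
  expect_equal(nrow(count_modes(g3, rel_threshold = 0.01)), 3)

  # two peaks closer than min_separation merge into the higher one
  near <- bump(1, 1, 1) + bump(1.3, 1, 0.9)
  gn <- g; gn$prob <- near / sum(near)
  merged <- count_modes(gn, min_separation = 0.5)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$x, 1, tolerance = 0.05)
  expect_equal(nrow(count_modes(gn, min_separation = 0.2)), 2)
})

test_that("ensemble landscapes show one attractor below q = 1 and two above", {
  for (seed in 1:2) {
    low <- simulate_ensemble(sde_params(0.5), sigma = 0.05, n_steps = 5e4,
                             seed = seed)
    g_low <- stationary_density(low)
    expect_equal(nrow(g_low$modes), 1)
    s <- -3 + sqrt(17)
    expect_lt(sqrt((g_low$modes$x - s)^2 + (g_low$modes$y - s)^2), 0.25)

    high <- simulate_ensemble(sde_params(2), sigma = 0.05, n_steps = 5e4,
                              seed = seed)
    g_high <- stationary_density(high)
    expect_equal(nrow(g_high$modes), 2)
    d_to <- function(m, tx, ty) min(sqrt((m$x - tx)^2 + (m$y - ty)^2))
    expect_lt(d_to(g_high$modes, 2, 0), 0.25)
    expect_lt(d_to(g_high$modes, 0, 2), 0.25)
  }
})

test_that("noisy dynamics stay on the degenerate manifold and straddle its center", {
  p <- sde_params(1)
  expect_error(manifold_residence(simulate_circuit(p, sigma = 0, n_steps = 10),
                                  sde_params(2)), "degenerate")

  # a noiseless start on the manifold never leaves it
  x0 <- 0.5
  tr0 <- simulate_circuit(p, sigma = 0, dt = 0.01, n_steps = 1000,
                          init = c(x0, manifold_y_of_x(x0, p)))
  expect_equal(manifold_residence(tr0, p, dist_tol = 1e-6), 1)

  # diffusion along the flat direction of the manifold is slow, so the
  # time-average needs the full-length run to settle near the deepest point
  tr <- simulate_circuit(p, sigma = 0.05, dt = 0.01, n_steps = 1e6,
                         init = c(1, 1), seed = 9)
  expect_gt(manifold_residence(tr, p, dist_tol = 0.3), 0.9)

  kept <- tr[-(1:1e5), ]
  # anti-diagonal spreading: inversely related levels of the two factors
  expect_lt(stats::cor(kept$x, kept$y), 0)

  # the time-averaged state sits nearer the most attracting point than the ends
  lm <- lambda_min(p)
  ctr <- c(mean(kept$x), mean(kept$y))
  d_star <- sqrt(sum((ctr - c(lm$x, lm$y))^2))
  expect_lt(d_star, sqrt(sum((ctr - c(2, 0))^2)))
  expect_lt(d_star, sqrt(sum((ctr - c(0, 2))^2)))
})
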
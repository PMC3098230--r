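test_that("effective activation rate saturates and validates its domain", {
  expect_equal(effective_activation_rate(K = 1, alpha = 1, conc = 0), 0)
  expect_equal(effective_activation_rate(K = 1, alpha = 1, conc = 1), 0.5)
  expect_equal(effective_activation_rate(K = 1, alpha = 1, conc = 1e9), 1,
               tolerance = 1e-8)
  conc <- seq(0, 10, by = 0.5)
  rate <- effective_activation_rate(K = 2, alpha = 3, conc = conc)
  expect_true(all(diff(rate) > 0))
  expect_true(all(rate < 3))
  expect_error(effective_activation_rate(K = -1, alpha = 1, conc = 1), "K")
  expect_error(effective_activation_rate(K = 1, alpha = 0, conc = 1), "alpha")
  expect_error(effective_activation_rate(K = 1, alpha = 1, conc = -1), "conc")
})

test_that("model 1 reduction maps kinetic constants to the generic system", {
  m <- model1_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 1,
                     delta_x = 0.5)
  g <- reduce_model1(m)
  expect_equal(g$a, 1); expect_equal(g$f, 1)
  expect_equal(g$bx, 1); expect_equal(g$cx, 1)
  expect_equal(g$dx, 0.5)

  m2 <- model1_params(alpha_x = 1, x_tot = 1, K_x = 0.5, K_yx = 0.25,
                      delta_x = 0.5)
  g2 <- reduce_model1(m2)
  expect_equal(g2$a, 0.5)
  expect_equal(g2$bx, 0.5)
  expect_equal(g2$cx, 0.25)
  expect_equal(g2$dx, 0.5)
})

test_that("reduced rate law agrees with numeric promoter-equilibrium elimination", {
  # asymmetric parameters so every constant is exercised
  m <- model1_params(alpha_x = 1.5, alpha_y = 0.8, delta_x = 0.4,
                     delta_y = 0.6, K_x = 0.7, K_y = 1.3, K_yx = 0.9,
                     K_xy = 0.35, x_tot = 0.6, y_tot = 1.1)
  for (X in c(0, 0.5, 2)) {
    for (Y in c(0, 1.5)) {
      r <- reduced_rate(m, X, Y)
      expect_equal(r$dX, numeric_reduced_rate(m, X, Y, "x"), tolerance = 1e-8)
      expect_equal(r$dY, numeric_reduced_rate(m, X, Y, "y"), tolerance = 1e-8)
    }
  }
  # same check for the ternary-complex chemistry
  m2 <- model2_params(alpha_x = 1.5, alpha_y = 0.8, delta_x = 0.4,
                      delta_y = 0.6, K_x = 0.7, K_y = 1.3, K_yx = 0.9,
                      K_xy = 0.35, K_xxy = 2.2, K_yyx = 0.15,
                      x_tot = 0.6, y_tot = 1.1)
  for (X in c(0.5, 2)) {
    r <- reduced_rate(m2, X, 1.5)
    expect_equal(r$dX, numeric_reduced_rate(m2, X, 1.5, "x"), tolerance = 1e-8)
    expect_equal(r$dY, numeric_reduced_rate(m2, X, 1.5, "y"), tolerance = 1e-8)
  }
  # production vanishes with no activator present
  expect_equal(reduced_rate(m, 0, 2)$dX, 0)
  expect_equal(reduced_rate(m2, 0, 2)$dX, 0)
})

test_that("model 2 factorizes exactly when cross-binding is independent", {
  m_eq <- model2_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 1,
                        K_xxy = 1, delta_x = 0.5)
  red <- reduce_model2(m_eq)
  expect_true(red$factorizes)
  g1 <- reduce_model1(model1_params(alpha_x = 2, x_tot = 0.5, K_x = 1,
                                    K_yx = 1, delta_x = 0.5))
  expect_equal(unclass(red$generic), unclass(g1))

  m_ne <- model2_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 1,
                        K_xxy = 2, K_yyx = 1, delta_x = 0.5)
  red_ne <- suppressMessages(reduce_model2(m_ne))
  expect_false(red_ne$factorizes)
  expect_null(red_ne$generic)
  expect_equal(red_ne$coefficients$XY[red_ne$coefficients$gene == "x"], 2)

  # a near-miss is reported, never silently factorized
  m_near <- model2_params(K_x = 1, K_yx = 1, K_xxy = 1 + 1e-6, K_yyx = 1)
  expect_message(red_near <- reduce_model2(m_near), "near-factorization")
  expect_false(red_near$factorizes)
})

test_that("models 1 and 2 agree pointwise under the no-cooperativity condition", {
  m1 <- model1_params(alpha_x = 1.2, alpha_y = 0.7, delta_x = 0.5,
                      delta_y = 0.3, K_x = 0.8, K_y = 1.1, K_yx = 0.6,
                      K_xy = 1.4, x_tot = 0.9, y_tot = 0.4)
  m2 <- model2_params(alpha_x = 1.2, alpha_y = 0.7, delta_x = 0.5,
                      delta_y = 0.3, K_x = 0.8, K_y = 1.1, K_yx = 0.6,
                      K_xy = 1.4, K_xxy = 0.6, K_yyx = 1.4,
                      x_tot = 0.9, y_tot = 0.4)
  grid <- expand.grid(X = seq(0, 5, length.out = 20),
                      Y = seq(0, 5, length.out = 20))
  r1 <- reduced_rate(m1, grid$X, grid$Y)
  r2 <- reduced_rate(m2, grid$X, grid$Y)
  expect_lt(max(abs(r1$dX - r2$dX)), 1e-12)
  expect_lt(max(abs(r1$dY - r2$dY)), 1e-12)
})

test_that("full-network right-hand side conserves promoters and handles rest states", {
  m1 <- model1_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 2,
                      delta_x = 0.5)
  m2 <- model2_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 2,
                      K_xxy = 3, delta_x = 0.5)
  # no bound promoter and no protein: nothing moves
  rest <- full_network_state(m1, X = 0, Y = 0, promoters = "free")
  d <- full_network_rhs(rest, m1)
  expect_equal(unname(d[c("X", "Y")]), c(0, 0))

  set.seed(41)
  for (p in list(m1, m2)) {
    for (i in 1:5) {
      s <- full_network_state(p, X = runif(1, 0, 3), Y = runif(1, 0, 3),
                              promoters = "equilibrated")
      # scatter promoter mass away from equilibrium, keeping the totals
      mix <- runif(4); mix <- mix / sum(mix)
      s[c("x", "xX", "xY", "xXY")] <- p$x_tot * mix
      d <- full_network_rhs(s, p, rate_scale = 10)
      expect_equal(sum(d[c("x", "xX", "xY", "xXY")]), 0, tolerance = 1e-12)
      expect_equal(sum(d[c("y", "yY", "yX", "yYX")]), 0, tolerance = 1e-12)
    }
  }
  s_neg <- rest; s_neg["X"] <- -1
  expect_error(full_network_rhs(s_neg, m1), "negative")
})

test_that("full-network integration conserves promoter totals and fixes zero", {
  m <- model1_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 2,
                     delta_x = 0.5)
  init <- full_network_state(m, X = 1.5, Y = 0.3, promoters = "free")
  traj <- integrate_full_network(m, init, t_end = 20, rate_scale = 100)
  tot_x <- traj$x + traj$xX + traj$xY + traj$xXY
  tot_y <- traj$y + traj$yY + traj$yX + traj$yYX
  expect_lt(max(abs(tot_x - m$x_tot)), 1e-9 * m$x_tot)
  expect_lt(max(abs(tot_y - m$y_tot)), 1e-9 * m$y_tot)

  # the zero-protein subspace is invariant
  zero <- full_network_state(m, X = 0, Y = 0, promoters = "free")
  ztraj <- integrate_full_network(m, zero, t_end = 20, rate_scale = 10)
  expect_lt(max(abs(ztraj$X)), 1e-10)
  expect_lt(max(abs(ztraj$Y)), 1e-10)
})

test_that("full network converges to the reduced model as binding gets fast", {
  # small promoter totals: the reduction also neglects protein sequestration
  m1 <- model1_params(alpha_x = 100, x_tot = 0.02, K_x = 0.5, K_yx = 1,
                      delta_x = 0.5)
  m2 <- model2_params(alpha_x = 100, x_tot = 0.02, K_x = 0.5, K_yx = 1,
                      K_xxy = 1, delta_x = 0.5)
  for (m in list(m1, m2)) {
    g <- if (inherits(m, "model2_params")) reduce_model2(m)$generic else reduce_model1(m)
    # reduced-model reference transient from an off-equilibrium start
    red <- deSolve::ode(
      y = c(x = 0.2, y = 0.05), times = c(0, 10),
      func = function(t, s, pp) list(unname(circuit_rhs(pmax(s, 0), g))),
      parms = NULL, rtol = 1e-10, atol = 1e-12)
    ref <- red[2, c("x", "y")]
    errs <- vapply(c(1, 100, 1000), function(rs) {
      init <- full_network_state(m, X = 0.2, Y = 0.05,
                                 promoters = "equilibrated")
      tr <- integrate_full_network(m, init, t_end = 10, rate_scale = rs,
                                   n_out = 2)
      max(abs(c(tr$X[2], tr$Y[2]) - ref) / pmax(abs(ref), 1e-6))
    }, numeric(1))
    expect_true(all(diff(errs) < 0), label = "transient discrepancy decreases with rate_scale")
    expect_lt(errs[3], 1e-2)

    # steady states agree at every scale (promoter equilibrium is exact there)
    st <- steady_states(g)
    target <- st[st$label == "asym_x", ]
    for (rs in c(1, 1000)) {
      ss <- full_network_steady(m, X0 = target$x * 1.1, Y0 = 1e-3,
                                rate_scale = rs)
      expect_lt(abs(ss[["X"]] - target$x) / target$x, 1e-2)
    }
  }
})

test_that("a reduced-model steady state with equilibrated promoters stays put", {
  m <- model1_params(alpha_x = 100, x_tot = 0.02, K_x = 0.5, K_yx = 1,
                     delta_x = 0.5)
  g <- reduce_model1(m)
  st <- steady_states(g)
  sym <- st[st$label == "symmetric", ]
  init <- full_network_state(m, X = sym$x, Y = sym$y,
                             promoters = "equilibrated")
  traj <- integrate_full_network(m, init, t_end = 20, rate_scale = 1000)
  expect_lt(max(abs(traj$X - sym$x)), 5e-3)
  expect_lt(max(abs(traj$Y - sym$y)), 5e-3)
})

test_that("SBML export produces a well-formed level-3 document", {
  path <- withr::local_tempfile(fileext = ".xml")
  m <- model2_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 1, K_xxy = 2,
                     delta_x = 0.5)
  export_sbml(m, path, rate_scale = 10)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "sbml")
  ns <- xml2::xml_ns_strip(doc)
  species <- xml2::xml_find_all(doc, ".//species")
  expect_length(species, 10)
  reactions <- xml2::xml_find_all(doc, ".//reaction")
  # model 2: 6 reversible binding pairs + production/degradation per gene
  expect_length(reactions, 6 * 2 + 4)
})
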
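# Independent numerical oracles used across the suite. None of these share a
# code path with the implementation they check.

# central finite-difference Jacobian of the generic right-hand side
fd_jacobian <- function(state, p, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (circuit_rhs(up, p) - circuit_rhs(dn, p)) / (up[j] - dn[j])
  }
  J
}

# rapid-equilibrium elimination done numerically: integrate the promoter
# species of one gene with the free proteins clamped at (X, Y) until the
# binding reactions are stationary, then return production - degradation.
# Works for both models; `gene` picks the locus.
numeric_reduced_rate <- function(p, X, Y, gene = c("x", "y")) {
  gene <- match.arg(gene)
  model1 <- !inherits(p, "model2_params")
  if (gene == "x") {
    K_self <- p$K_x; K_cross <- p$K_yx
    K_ter <- if (model1) p$K_yx else p$K_xxy
    total <- p$x_tot; alpha <- p$alpha_x; delta <- p$delta_x
    A <- X; R <- Y   # activator / repressor seen by this locus
  } else {
    K_self <- p$K_y; K_cross <- p$K_xy
    K_ter <- if (model1) p$K_xy else p$K_yyx
    total <- p$y_tot; alpha <- p$alpha_y; delta <- p$delta_y
    A <- Y; R <- X
  }
  # species: free, self-complex, repressor-complex, ternary
  rhs <- function(t, s, parms) {
    v1 <- K_self * s[1] * A - s[2]
    v2 <- K_cross * s[1] * R - s[3]
    v3 <- K_ter * s[2] * R - s[4]
    v4 <- if (model1) K_self * s[3] * A - s[4] else 0
    list(c(-v1 - v2, v1 - v3, v2 - v4, v3 + v4))
  }
  sol <- deSolve::ode(y = c(total, 0, 0, 0), times = c(0, 1e4), func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  occupied <- unname(sol[2, 3])
  alpha * occupied - delta * A
}

# brute-force steady-state search: multi-start Nelder-Mead on the squared
# residual over [0, 5]^2, deduplicated
brute_steady_states <- function(p, grid_n = 6, box = 5, dedup_tol = 1e-4) {
  obj <- function(z) {
    z <- pmax(z, 0)
    sum(circuit_rhs(z, p)^2)
  }
  starts <- expand.grid(x = seq(0, box, length.out = grid_n),
                        y = seq(0, box, length.out = grid_n))
  found <- list()
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 2000))
    z <- pmax(fit$par, 0)
    z[z < 1e-7] <- 0
    if (obj(z) > 1e-14) next
    if (!any(vapply(found, function(s) max(abs(s - z)) < dedup_tol,
                    logical(1)))) {
      found <- c(found, list(z))
    }
  }
  found
}

# random admissible symmetric-coefficient parameter draw (positivity holds)
random_admissible_params <- function() {
  d <- stats::runif(1, 0.1, 1)
  a <- d * stats::runif(1, 1.2, 4)
  generic_params(a = a, f = a,
                 b = stats::runif(1, 0.2, 2),
                 c = stats::runif(1, 0.2, 2),
                 d = d)
}

expect_state_in_set <- function(set_tbl, x, y, tol = 1e-6) {
  hit <- any(abs(set_tbl$x - x) < tol & abs(set_tbl$y - y) < tol)
  expect_true(hit, label = sprintf("state (%g, %g) present", x, y))
}
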
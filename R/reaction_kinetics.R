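#' Effective activation rate of an auto-regulated locus
#'
#' With promoter binding at rapid equilibrium, the four elementary
#' self-activation reactions collapse to a single effective production rate
#' \deqn{g([X]) = \alpha K [X] / (1 + K [X]),}
#' a saturating (Michaelis-type) function of the factor's own level:
#' monotonically increasing and bounded above by `alpha`.
#'
#' @param K Self-binding equilibrium constant (1/concentration), positive.
#' @param alpha Production rate from the bound promoter, positive.
#' @param conc Free factor concentration(s), non-negative.
#' @return The effective rate, same length as `conc`.
#' @examples
#' effective_activation_rate(K = 1, alpha = 1, conc = 1)  # half-saturation
#' @export
effective_activation_rate <- function(K, alpha, conc) {
  check_positive_scalar(K, "K")
  check_positive_scalar(alpha, "alpha")
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("`conc` must be non-negative.", call. = FALSE)
  }
  alpha * K * conc / (1 + K * conc)
}

#' Reduce Model 1 to the generic dynamical system
#'
#' Eliminates the promoter species of the independent-binding model by the
#' rapid-equilibrium assumption and promoter mass conservation, giving
#' \deqn{d[X]/dt = \alpha_x x_{tot} K_x [X] /
#'   ((1 + K_x [X])(1 + K_{yx} [Y])) - \delta_x [X]}
#' (and mirrored for Y). The factorized denominator expands to contain the
#' cross-term `K_x K_yx [X][Y]` — an effective heterodimer contribution that
#' arises with no assumed cooperativity. The generic parameters are
#' `a = alpha_x x_tot K_x`, `b_x = K_x`, `c_x = K_yx`, `d_x = delta_x`
#' (mirrored: `f = alpha_y y_tot K_y`, `b_y = K_y`, `c_y = K_xy`,
#' `d_y = delta_y`).
#'
#' @param p A [model1_params()] object.
#' @return A [generic_params()] object.
#' @examples
#' p <- model1_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 1,
#'                    delta_x = 0.5)
#' reduce_model1(p)   # a = f = 1, b = c = 1, d = 0.5
#' @export
reduce_model1 <- function(p) {
  stopifnot(inherits(p, "model1_params"))
  generic_params(
    a = p$alpha_x * p$x_tot * p$K_x,
    f = p$alpha_y * p$y_tot * p$K_y,
    b = c(p$K_x, p$K_y),
    c = c(p$K_yx, p$K_xy),
    d = c(p$delta_x, p$delta_y)
  )
}

#' Reduce Model 2 (ternary-complex model) to its rate law
#'
#' The in-situ ternary complex (promoter + activator + repressor) gives the
#' reduced rate
#' \deqn{d[X]/dt = \alpha_x x_{tot} K_x [X] /
#'   (1 + K_x [X] + K_{yx} [Y] + K_x K_{xxy} [X][Y]) - \delta_x [X].}
#' The denominator factorizes as `(1 + K_x [X])(1 + K_yx [Y])` exactly when
#' `K_xxy = K_yx` (and mirrored `K_yyx = K_xy`) — i.e. when the repressor
#' binds free and activator-occupied promoter with equal affinity, the
#' no-cooperativity condition under which Model 2 coincides with Model 1.
#'
#' @param p A [model2_params()] object.
#' @param tol Relative tolerance for the factorization equalities (exact
#'   equality within `1e-12` by default; near-misses are reported via a
#'   message, never silently factorized).
#' @return A list of class `model2_reduction` with elements
#'   `coefficients` (a two-row tibble of denominator coefficients
#'   `const`, `X`, `Y`, `XY` per gene), `factorizes` (logical), and
#'   `generic` (the [generic_params()] mapping when `factorizes`, else
#'   `NULL`).
#' @examples
#' p <- model2_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 1,
#'                    K_xxy = 1, delta_x = 0.5)
#' reduce_model2(p)$factorizes
#' @export
reduce_model2 <- function(p, tol = 1e-12) {
  stopifnot(inherits(p, "model2_params"))
  coefficients <- tibble::tibble(
    gene = c("x", "y"),
    const = 1,
    X = c(p$K_x, p$K_xy),
    Y = c(p$K_yx, p$K_y),
    XY = c(p$K_x * p$K_xxy, p$K_y * p$K_yyx)
  )
  dx_rel <- abs(p$K_xxy - p$K_yx) / max(p$K_xxy, p$K_yx)
  dy_rel <- abs(p$K_yyx - p$K_xy) / max(p$K_yyx, p$K_xy)
  factorizes <- dx_rel <= tol && dy_rel <= tol
  if (!factorizes && max(dx_rel, dy_rel) <= 1e-3) {
    message(sprintf(
      "near-factorization: |K_xxy - K_yx|, |K_yyx - K_xy| within %.3g, %.3g relative (not factorized).",
      dx_rel, dy_rel))
  }
  generic <- NULL
  if (factorizes) {
    generic <- generic_params(
      a = p$alpha_x * p$x_tot * p$K_x,
      f = p$alpha_y * p$y_tot * p$K_y,
      b = c(p$K_x, p$K_y),
      c = c(p$K_yx, p$K_xy),
      d = c(p$delta_x, p$delta_y)
    )
  }
  structure(list(coefficients = coefficients, factorizes = factorizes,
                 generic = generic),
            class = "model2_reduction")
}

#' @export
print.model2_reduction <- function(x, ...) {
  cat("<model2_reduction>\n  denominator coefficients (per gene):\n")
  print(x$coefficients)
  cat(sprintf("  factorizes: %s\n", x$factorizes))
  invisible(x)
}

#' Reduced production-minus-degradation rates
#'
#' Evaluates the quasi-equilibrium reduced rate law of either elementary
#' model at given free-protein levels, without going through
#' [generic_params()]. Used to compare the two chemistries pointwise.
#'
#' @param p A [model1_params()] or [model2_params()] object.
#' @param X,Y Free protein concentrations (vectors of equal length).
#' @return A tibble with columns `dX`, `dY`.
#' @export
reduced_rate <- function(p, X, Y) {
  UseMethod("reduced_rate")
}

#' @export
reduced_rate.model1_params <- function(p, X, Y) {
  tibble::tibble(
    dX = p$alpha_x * p$x_tot * p$K_x * X /
      ((1 + p$K_x * X) * (1 + p$K_yx * Y)) - p$delta_x * X,
    dY = p$alpha_y * p$y_tot * p$K_y * Y /
      ((1 + p$K_y * Y) * (1 + p$K_xy * X)) - p$delta_y * Y
  )
}

#' @export
reduced_rate.model2_params <- function(p, X, Y) {
  den_x <- 1 + p$K_x * X + p$K_yx * Y + p$K_x * p$K_xxy * X * Y
  den_y <- 1 + p$K_y * Y + p$K_xy * X + p$K_y * p$K_yyx * X * Y
  tibble::tibble(
    dX = p$alpha_x * p$x_tot * p$K_x * X / den_x - p$delta_x * X,
    dY = p$alpha_y * p$y_tot * p$K_y * Y / den_y - p$delta_y * Y
  )
}

# --- full elementary mass-action network -----------------------------------

full_species <- c("x", "xX", "xY", "xXY", "y", "yY", "yX", "yYX", "X", "Y")

#' Build a state of the full elementary network
#'
#' Species are the free promoters `x`, `y`, the activator complexes `xX`,
#' `yY`, the repressor complexes `xY`, `yX`, the ternary complexes `xXY`,
#' `yYX`, and the free proteins `X`, `Y`. Promoter species of each gene sum
#' to the promoter total — a conserved quantity of the dynamics.
#'
#' @param p A [model1_params()] or [model2_params()] object.
#' @param X,Y Free protein concentrations.
#' @param promoters `"free"` (all promoter mass unbound) or
#'   `"equilibrated"` (occupancies at binding equilibrium given `X`, `Y`).
#' @return A named numeric vector over the ten species.
#' @export
full_network_state <- function(p, X = 0, Y = 0,
                               promoters = c("free", "equilibrated")) {
  stopifnot(inherits(p, "kinetic_params"))
  promoters <- match.arg(promoters)
  check_nonneg_scalar(X, "X"); check_nonneg_scalar(Y, "Y")
  s <- stats::setNames(numeric(10), full_species)
  s["X"] <- X; s["Y"] <- Y
  if (promoters == "free") {
    s["x"] <- p$x_tot; s["y"] <- p$y_tot
  } else {
    K3x <- ternary_K(p)["x"]; K3y <- ternary_K(p)["y"]
    den_x <- 1 + p$K_x * X + p$K_yx * Y + p$K_x * K3x * X * Y
    s["x"] <- p$x_tot / den_x
    s["xX"] <- p$K_x * X * s["x"]
    s["xY"] <- p$K_yx * Y * s["x"]
    s["xXY"] <- p$K_x * K3x * X * Y * s["x"]
    den_y <- 1 + p$K_y * Y + p$K_xy * X + p$K_y * K3y * X * Y
    s["y"] <- p$y_tot / den_y
    s["yY"] <- p$K_y * Y * s["y"]
    s["yX"] <- p$K_xy * X * s["y"]
    s["yYX"] <- p$K_y * K3y * X * Y * s["y"]
  }
  s
}

# equilibrium constants of the ternary-forming step per gene: Model 1 binds
# the occupied promoter with unchanged cross affinity (independence), Model 2
# with its own constants
ternary_K <- function(p) {
  if (inherits(p, "model2_params")) {
    c(x = p$K_xxy, y = p$K_yyx)
  } else {
    c(x = p$K_yx, y = p$K_xy)
  }
}

#' Mass-action right-hand side of the full elementary network
#'
#' Applies the law of mass action to every elementary reaction: reversible
#' binding of each factor to its own promoter (constants `K_x`, `K_y`),
#' reversible cross-binding of the repressor to the free promoter (`K_yx`,
#' `K_xy`) and to the activator-occupied complex (Model 1: unchanged
#' affinity; Model 2: `K_xxy`, `K_yyx`; in Model 1 the ternary complex is
#' also reachable by the activator binding the repressed promoter),
#' production of protein from the activator complex (`alpha`), and
#' first-order degradation (`delta`). Each binding/release pair is realized
#' as rates `(rate_scale * K, rate_scale)` so the equilibrium constant is
#' exact and `rate_scale` alone controls timescale separation.
#'
#' @param state Named numeric vector as from [full_network_state()].
#' @param p A [model1_params()] or [model2_params()] object.
#' @param rate_scale Positive multiplier of all binding and release rates.
#' @return Named numeric vector of species time-derivatives.
#' @export
full_network_rhs <- function(state, p, rate_scale = 1) {
  stopifnot(inherits(p, "kinetic_params"))
  check_positive_scalar(rate_scale, "rate_scale")
  if (any(state < 0)) stop("negative concentrations.", call. = FALSE)
  s <- state[full_species]
  ks <- rate_scale
  K3 <- ternary_K(p)
  model1 <- !inherits(p, "model2_params")

  v1 <- ks * (p$K_x * s["x"] * s["X"] - s["xX"])      # x + X <-> xX
  v2 <- ks * (p$K_yx * s["x"] * s["Y"] - s["xY"])     # x + Y <-> xY
  v3 <- ks * (K3["x"] * s["xX"] * s["Y"] - s["xXY"])  # xX + Y <-> xXY
  v4 <- if (model1) ks * (p$K_x * s["xY"] * s["X"] - s["xXY"]) else 0

  w1 <- ks * (p$K_y * s["y"] * s["Y"] - s["yY"])      # y + Y <-> yY
  w2 <- ks * (p$K_xy * s["y"] * s["X"] - s["yX"])     # y + X <-> yX
  w3 <- ks * (K3["y"] * s["yY"] * s["X"] - s["yYX"])  # yY + X <-> yYX
  w4 <- if (model1) ks * (p$K_y * s["yX"] * s["Y"] - s["yYX"]) else 0

  d <- stats::setNames(numeric(10), full_species)
  d["x"] <- -v1 - v2
  d["xX"] <- v1 - v3
  d["xY"] <- v2 - v4
  d["xXY"] <- v3 + v4
  d["y"] <- -w1 - w2
  d["yX"] <- w2 - w4
  d["yY"] <- w1 - w3
  d["yYX"] <- w3 + w4
  d["X"] <- p$alpha_x * s["xX"] - p$delta_x * s["X"] - v1 - v4 - w2 - w3
  d["Y"] <- p$alpha_y * s["yY"] - p$delta_y * s["Y"] - v2 - v3 - w1 - w4
  d
}

#' Integrate the full elementary network
#'
#' Stiff-safe integration (lsoda via deSolve) of the mass-action system;
#' serves as the brute-force oracle for the rapid-equilibrium reduction: as
#' `rate_scale` grows, binding equilibrates fast relative to production and
#' the free-protein dynamics converge to the reduced model's.
#'
#' @inheritParams full_network_rhs
#' @param initial Named state vector, e.g. from [full_network_state()].
#' @param t_end Final time (> 0).
#' @param n_out Number of output time points.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble with a `time` column and one column per species.
#' @export
integrate_full_network <- function(p, initial, t_end, rate_scale = 1,
                                   n_out = 101, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "kinetic_params"))
  check_positive_scalar(t_end, "t_end")
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(
    y = initial[full_species], times = times,
    func = function(t, y, parms) {
      list(unname(full_network_rhs(pmax(y, 0), p, rate_scale)))
    },
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol,
    maxsteps = 100000
  )
  diag <- attr(sol, "istate")
  if (!is.null(diag) && diag[1] < 0) {
    stop(sprintf("full-network integration failed (istate = %d).", diag[1]),
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out) <- c("time", full_species)
  out
}

#' Free-protein steady state of the full network
#'
#' Integrates from the given initial proteins until the full right-hand side
#' is small, doubling the horizon as needed.
#'
#' @inheritParams integrate_full_network
#' @param X0,Y0 Initial free-protein levels (promoters start equilibrated).
#' @param tol Convergence threshold on the free-protein time-derivatives
#'   (the slow equations; the fast binding fluxes balance only to integrator
#'   accuracy once multiplied by `rate_scale`).
#' @param t_max Give up beyond this horizon.
#' @return Named vector `c(X, Y)` of terminal free-protein concentrations.
#' @export
full_network_steady <- function(p, X0, Y0, rate_scale = 1, tol = 1e-8,
                                t_max = 1e5) {
  state <- full_network_state(p, X = X0, Y = Y0, promoters = "equilibrated")
  t_end <- 50
  repeat {
    traj <- integrate_full_network(p, state, t_end, rate_scale, n_out = 11)
    state <- unlist(traj[nrow(traj), full_species])
    names(state) <- full_species
    rhs <- full_network_rhs(pmax(state, 0), p, rate_scale)
    if (max(abs(rhs[c("X", "Y")])) < tol) break
    t_end <- t_end * 2
    if (t_end > t_max) {
      warning("full_network_steady: horizon exhausted before convergence")
      break
    }
  }
  c(X = unname(state["X"]), Y = unname(state["Y"]))
}
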
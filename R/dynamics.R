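#' Right-hand side of the generic circuit
#'
#' Evaluates the vector field
#' \deqn{dx/dt = a x / ((1 + b_x x)(1 + c_x y)) - d_x x}
#' \deqn{dy/dt = f y / ((1 + b_y y)(1 + c_y x)) - d_y y}
#' at one or more states. Production of each factor saturates in its own
#' level (self-activation with saturation `b`) and is inhibited by the
#' opposing factor (cross-repression `c`); degradation is first order.
#'
#' @param state Numeric vector `c(x, y)`, or a two-column matrix / data frame
#'   of states (columns `x`, `y`). Concentrations must be non-negative.
#' @param p A [generic_params()] object.
#' @return For a single state, a named numeric vector `c(dx, dy)`; for
#'   multiple states, a tibble with columns `dx`, `dy`.
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 1, d = 0.5)
#' circuit_rhs(c(2, 0), p)   # an asymmetric fixed point
#' @export
circuit_rhs <- function(state, p) {
  stopifnot(inherits(p, "generic_params"))
  xy <- as_state_matrix(state)
  x <- xy[, 1]; y <- xy[, 2]
  dx <- p$a * x / ((1 + p$bx * x) * (1 + p$cx * y)) - p$dx * x
  dy <- p$f * y / ((1 + p$by * y) * (1 + p$cy * x)) - p$dy * y
  if (nrow(xy) == 1L) c(dx = dx, dy = dy) else tibble::tibble(dx = dx, dy = dy)
}

#' Analytic Jacobian of the generic circuit
#'
#' @inheritParams circuit_rhs
#' @param state Numeric vector `c(x, y)` with non-negative entries.
#' @return A 2x2 numeric matrix of partial derivatives of [circuit_rhs()].
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 1, d = 0.5)
#' eigen(circuit_jacobian(c(2, 0), p))$values
#' @export
circuit_jacobian <- function(state, p) {
  stopifnot(inherits(p, "generic_params"))
  xy <- as_state_matrix(state)
  if (nrow(xy) != 1L) stop("`state` must be a single (x, y) pair.", call. = FALSE)
  x <- xy[1, 1]; y <- xy[1, 2]
  ux <- 1 + p$bx * x; vy <- 1 + p$cx * y   # gene-x denominator factors
  uy <- 1 + p$by * y; vx <- 1 + p$cy * x   # gene-y denominator factors
  matrix(c(
    p$a / (ux^2 * vy) - p$dx,        # d(dx)/dx
    -p$f * p$cy * y / (uy * vx^2),   # d(dy)/dx
    -p$a * p$cx * x / (ux * vy^2),   # d(dx)/dy
    p$f / (uy^2 * vx) - p$dy         # d(dy)/dy
  ), nrow = 2)
}

#' Positivity condition for the non-trivial steady states
#'
#' The asymmetric steady states sit at `x = (a - d)/(b d)` (and mirrored), so
#' all non-trivial states have strictly positive coordinates exactly when
#' production exceeds degradation at low abundance: `a > d_x` and `f > d_y`.
#'
#' @param p A [generic_params()] object.
#' @return `TRUE` if `a > d_x` and `f > d_y`, else `FALSE`.
#' @export
check_positivity <- function(p) {
  stopifnot(inherits(p, "generic_params"))
  p$a > p$dx && p$f > p$dy
}

#' Enumerate and classify the steady states of the circuit
#'
#' Away from the degenerate locus `b = c` the system has four steady states:
#' the trivial origin, two asymmetric states `((a-d)/(b d), 0)` and
#' `(0, (f-d)/(b d))` whose positions do not depend on the cross-repression
#' strength, and one interior (symmetric-branch) state, for symmetric
#' production the positive root of `(1 + b s)(1 + c s) = a/d` on the
#' diagonal. Closed forms are polished by damped Newton iteration on the full
#' system before classification; for asymmetric production the interior state
#' is located by multi-start Newton from a 5x5 grid. At `b = c` (with
#' `a = f`) the interior equilibria form a continuum and only the three
#' isolated states are returned, with attribute `degenerate = TRUE` (see
#' [manifold_points()]).
#'
#' @param p A [generic_params()] object.
#' @param zero_tol Eigenvalue magnitude below which a state is classified as
#'   degenerate. Default `1e-9 * max(|lambda|, |mu|, d)` (scale-aware).
#' @return A tibble with one row per steady state and columns `label`
#'   (`trivial`, `asym_x`, `asym_y`, `symmetric`), `x`, `y`, `lambda`, `mu`
#'   (Jacobian eigenvalues, `lambda <= mu`), and `stability` (`stable`,
#'   `saddle`, `unstable`, `degenerate`). If the positivity condition fails,
#'   states with a non-positive coordinate are dropped and listed in the
#'   `lost` attribute. Attribute `degenerate` flags the `b = c` continuum.
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 1, d = 0.5)  # q = 2
#' steady_states(p)
#' @export
steady_states <- function(p, zero_tol = NULL) {
  stopifnot(inherits(p, "generic_params"))
  degen <- detect_degeneracy(p)
  states <- list(list(label = "trivial", x = 0, y = 0))

  x1 <- (p$a - p$dx) / (p$bx * p$dx)
  y2 <- (p$f - p$dy) / (p$by * p$dy)
  lost <- character()
  if (x1 > 0) {
    states <- c(states, list(list(label = "asym_x", x = x1, y = 0)))
  } else {
    lost <- c(lost, "asym_x")
  }
  if (y2 > 0) {
    states <- c(states, list(list(label = "asym_y", x = 0, y = y2)))
  } else {
    lost <- c(lost, "asym_y")
  }

  if (!degen && length(lost) == 0L) {
    interior <- find_interior_states(p, x_max = x1, y_max = y2)
    for (s in interior) {
      states <- c(states, list(list(label = "symmetric", x = s[1], y = s[2])))
    }
    if (length(interior) == 0L) lost <- c(lost, "symmetric")
  } else if (!degen) {
    lost <- c(lost, "symmetric")
  }

  rows <- purrr::map(states, function(s) {
    z <- polish_steady_state(c(s$x, s$y), p)
    cls <- classify_state(z, p, zero_tol = zero_tol)
    tibble::tibble(label = s$label, x = z[1], y = z[2],
                   lambda = cls$lambda, mu = cls$mu,
                   stability = cls$stability)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::distinct(out,
                         round(.data$x / 1e-8), round(.data$y / 1e-8),
                         .keep_all = TRUE)[, names(out)]
  attr(out, "degenerate") <- degen
  attr(out, "lost") <- lost
  if (length(lost) > 0L) {
    message("Positivity condition violated; states not present: ",
            paste(lost, collapse = ", "))
  }
  out
}

#' Classify a steady state by its Jacobian eigenvalues
#'
#' @param state Numeric `c(x, y)`; must satisfy the steady-state condition
#'   (right-hand-side residual at most `1e-8`), or an error is raised.
#' @param p A [generic_params()] object.
#' @param zero_tol Magnitude below which an eigenvalue real part counts as
#'   zero; default `1e-9 * max(|lambda|, |mu|, d)`.
#' @return A list with `lambda`, `mu` (real parts, `lambda <= mu`),
#'   `stability` (`stable` / `saddle` / `unstable` / `degenerate`).
#'   Eigenvalues are real throughout the admissible parameter region; a
#'   complex pair triggers a warning and is classified by its real parts.
#' @export
classify_state <- function(state, p, zero_tol = NULL) {
  stopifnot(inherits(p, "generic_params"))
  res <- circuit_rhs(state, p)
  if (max(abs(res)) > 1e-8) {
    stop(sprintf("state (%g, %g) is not a steady state (residual %.3g)",
                 state[1], state[2], max(abs(res))), call. = FALSE)
  }
  ev <- eigen(circuit_jacobian(state, p), only.values = TRUE)$values
  if (is.complex(ev)) {
    if (max(abs(Im(ev))) > 1e-10 * max(abs(ev), 1)) {
      warning("complex Jacobian eigenvalues encountered; classifying by real parts")
    }
    ev <- Re(ev)
  }
  ev <- sort(ev)
  if (is.null(zero_tol)) {
    zero_tol <- 1e-9 * max(abs(ev), max(p$dx, p$dy))
  }
  n_pos <- sum(ev > zero_tol)
  n_neg <- sum(ev < -zero_tol)
  stability <- if (n_pos + n_neg < 2L) {
    "degenerate"
  } else if (n_neg == 2L) {
    "stable"
  } else if (n_pos == 2L) {
    "unstable"
  } else {
    "saddle"
  }
  list(lambda = ev[1], mu = ev[2], stability = stability)
}

# --- internal helpers ------------------------------------------------------

as_state_matrix <- function(state) {
  if (is.data.frame(state)) state <- as.matrix(state[, c("x", "y")])
  if (is.null(dim(state))) {
    if (length(state) != 2L) stop("`state` must be (x, y).", call. = FALSE)
    state <- matrix(state, nrow = 1)
  }
  if (ncol(state) != 2L) stop("`state` must have two columns.", call. = FALSE)
  if (any(state < 0)) {
    stop("concentrations must be non-negative.", call. = FALSE)
  }
  state
}

# damped Newton iteration from a closed-form or grid start; coordinates in
# (-1e-8, 0) are snapped to 0 (concentrations)
polish_steady_state <- function(z0, p, tol = 1e-12, max_iter = 60L) {
  z <- pmax(z0, 0)
  for (i in seq_len(max_iter)) {
    fz <- unname(circuit_rhs(pmax(z, 0), p))
    if (max(abs(fz)) <= tol * max(1, max(abs(z)))) break
    J <- circuit_jacobian(pmax(z, 0), p)
    step <- tryCatch(solve(J, fz), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      z_new <- z - lam * step
      f_new <- tryCatch(unname(circuit_rhs(pmax(z_new, 0), p)),
                        error = function(e) NULL)
      if (!is.null(f_new) && sum(f_new^2) < sum(fz^2)) break
      lam <- lam / 2
      if (lam < 1e-6) { z_new <- z; break }
    }
    if (identical(z_new, z)) break
    z <- z_new
  }
  z[z < 0 & z > -1e-8] <- 0
  unname(z)
}

# all interior (x > 0, y > 0) steady states: closed form on the diagonal for
# symmetric production, multi-start Newton on a 5x5 grid otherwise
find_interior_states <- function(p, x_max, y_max) {
  sym_coeff <- is_symmetric_params(p)
  if (sym_coeff && rel_eq(p$a, p$f, 1e-12)) {
    b <- p$bx; cc <- p$cx; R <- p$a / p$dx
    disc <- (b + cc)^2 - 4 * b * cc * (1 - R)
    if (disc <= 0) return(list())
    s <- (-(b + cc) + sqrt(disc)) / (2 * b * cc)
    if (s <= 0) return(list())
    return(list(polish_steady_state(c(s, s), p)))
  }
  starts <- expand.grid(
    x = seq(0, max(x_max, 1), length.out = 5)[-1],
    y = seq(0, max(y_max, 1), length.out = 5)[-1]
  )
  sols <- list()
  for (i in seq_len(nrow(starts))) {
    z <- polish_steady_state(c(starts$x[i], starts$y[i]), p)
    if (any(z < 1e-6)) next   # boundary state, already enumerated
    if (max(abs(circuit_rhs(z, p))) > 1e-8) next
    dup <- any(vapply(sols, function(s) max(abs(s - z)) < 1e-8, logical(1)))
    if (!dup) sols <- c(sols, list(z))
  }
  sols
}
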
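#' Detect the degenerate parameter configuration b = c
#'
#' At the critical ratio `q = c/b = 1` (with symmetric production `a = f`)
#' the interior steady-state equations lose uniqueness: every point of the
#' curve `(1 + b x)(1 + b y) = a/d` is an equilibrium.
#'
#' @param p A [generic_params()] object.
#' @param tol Relative tolerance for the equalities `b = c` and `a = f`.
#' @return `TRUE` iff `|b - c| <= tol * max(b, c)` and
#'   `|a - f| <= tol * max(a, f)` (gene-wise for b and c).
#' @export
detect_degeneracy <- function(p, tol = 1e-9) {
  stopifnot(inherits(p, "generic_params"))
  rel_eq(p$bx, p$cx, tol) && rel_eq(p$by, p$cy, tol) &&
    rel_eq(p$a, p$f, tol) && is_symmetric_params(p, tol)
}

check_degenerate <- function(p) {
  if (!detect_degeneracy(p, tol = 1e-12)) {
    stop("parameters are not degenerate: the steady-state manifold exists ",
         "only for b = c and a = f (within 1e-12 relative).", call. = FALSE)
  }
  invisible(p)
}

# upper end of the manifold's x-range: the asymmetric-state coordinate
manifold_x_max <- function(p) (p$a - p$dx) / (p$bx * p$dx)

#' The steady-state manifold y(x) at b = c
#'
#' Solves `(1 + b x)(1 + b y) = a/d` for `y`, i.e.
#' `y = ((a/d) / (1 + b x) - 1) / b`. The endpoints reproduce the asymmetric
#' states: `y(0) = x_max` and `y(x_max) = 0` with
#' `x_max = (a - d)/(b d)`.
#'
#' @param x Numeric vector of x-coordinates in `[0, x_max]`.
#' @param p A degenerate [generic_params()] object (`b = c`, `a = f`).
#' @return Numeric vector of manifold y-coordinates.
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 0.5, d = 0.5)
#' manifold_y_of_x(c(0, 2), p)   # endpoints: 2 and 0
#' @export
manifold_y_of_x <- function(x, p) {
  check_degenerate(p)
  xm <- manifold_x_max(p)
  if (any(x < -1e-12 | x > xm * (1 + 1e-12))) {
    stop(sprintf("x must lie in [0, x_max] = [0, %g].", xm), call. = FALSE)
  }
  x <- pmin(pmax(x, 0), xm)
  ((p$a / p$dx) / (1 + p$bx * x) - 1) / p$bx
}

#' Jacobian eigenvalues along the degenerate manifold
#'
#' On the manifold the Jacobian is rank-deficient: one eigenvalue `mu` is
#' exactly zero (no force along the manifold) and the other,
#' \deqn{\lambda(x) = -d\,b\left(\frac{x}{1 + b x} + \frac{y}{1 + b y}\right),}
#' with `y = manifold_y_of_x(x)`, is negative on the open interval, so the
#' manifold attracts transversally while every point on it is indifferently
#' stable longitudinally.
#'
#' @inheritParams manifold_y_of_x
#' @return A tibble with columns `x`, `y`, `lambda`, `mu` (`mu` is 0).
#' @export
manifold_eigenvalues <- function(x, p) {
  check_degenerate(p)
  y <- manifold_y_of_x(x, p)
  b <- p$bx; d <- p$dx
  lambda <- -d * b * (x / (1 + b * x) + y / (1 + b * y))
  tibble::tibble(x = x, y = y, lambda = lambda, mu = 0)
}

#' Sample the degenerate steady-state manifold
#'
#' Parameterizes the manifold by `x` on a uniform grid over `[0, x_max]` and
#' reports coordinates and Jacobian eigenvalues at each sample, together with
#' the raw eigensolver values for diagnostics.
#'
#' @param p A degenerate [generic_params()] object.
#' @param n Number of equispaced samples (default 200).
#' @return A tibble with columns `x`, `y`, `lambda`, `mu` (closed forms;
#'   `mu = 0`), and `lambda_num`, `mu_num` (dense-eigensolver values from the
#'   analytic Jacobian, retained for diagnostics).
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 0.5, d = 0.5)
#' manifold_points(p, n = 5)
#' @export
manifold_points <- function(p, n = 200) {
  check_degenerate(p)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  xm <- manifold_x_max(p)
  out <- manifold_eigenvalues(seq(0, xm, length.out = n), p)
  num <- purrr::map(seq_len(nrow(out)), function(i) {
    ev <- sort(Re(eigen(circuit_jacobian(c(out$x[i], out$y[i]), p),
                        only.values = TRUE)$values))
    tibble::tibble(lambda_num = ev[1], mu_num = ev[2])
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(num))
  class(out) <- c("manifold_tbl", class(out))
  out
}

#' Location and value of the most attracting manifold point
#'
#' `lambda(x)` has an interior minimum; with noise this point exerts the
#' strongest transversal pull and marks the indeterminate progenitor state.
#' For symmetric parameters the minimizer lies on the diagonal at
#' `x* = (sqrt(a/d) - 1)/b`.
#'
#' @param p A degenerate [generic_params()] object.
#' @return A list with `x` (minimizer), `lambda` (minimum value), and `y`
#'   (`= manifold_y_of_x(x)`, equal to `x` by symmetry).
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 0.5, d = 0.5)
#' lambda_min(p)   # x* = 2 (sqrt(2) - 1), lambda* = -2 d (1 - sqrt(d/a))
#' @export
lambda_min <- function(p) {
  check_degenerate(p)
  xm <- manifold_x_max(p)
  opt <- stats::optimize(function(x) manifold_eigenvalues(x, p)$lambda,
                         interval = c(0, xm), tol = 1e-12)
  x_star <- opt$minimum
  # polish with the closed-form symmetric candidate, which must beat or match
  x_sym <- (sqrt(p$a / p$dx) - 1) / p$bx
  if (manifold_eigenvalues(x_sym, p)$lambda <= opt$objective) {
    x_star <- x_sym
  }
  ev <- manifold_eigenvalues(x_star, p)
  list(x = x_star, y = ev$y, lambda = ev$lambda)
}

#' @method autoplot manifold_tbl
#' @export
autoplot.manifold_tbl <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(x = object$x, value = object$lambda, quantity = "lambda"),
    tibble::tibble(x = object$x, value = object$mu, quantity = "mu"),
    tibble::tibble(x = object$x, value = object$y, quantity = "y(x)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value,
                                     colour = .data$quantity,
                                     linetype = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c("lambda" = "solid", "mu" = "solid", "y(x)" = "dashed")) +
    ggplot2::labs(x = "x", y = NULL,
                  title = "Degenerate steady-state manifold",
                  subtitle = "eigenvalues and manifold position along x") +
    ggplot2::theme_minimal()
}
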
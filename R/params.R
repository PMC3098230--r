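#' Parameters of the generic two-gene dynamical system
#'
#' The coarse-grained circuit of two mutually repressing, self-activating
#' genes reduces (for both elementary chemistries, see [reduce_model1()] and
#' [reduce_model2()]) to
#' \deqn{dx/dt = a x / ((1 + b_x x)(1 + c_x y)) - d_x x}
#' \deqn{dy/dt = f y / ((1 + b_y y)(1 + c_y x)) - d_y y}
#' with production scales `a`, `f`, self-saturation coefficients `b`,
#' cross-repression coefficients `c` and degradation rates `d`. The
#' dimensionless bifurcation parameter is `q = c/b`.
#'
#' The gene-specific (asymmetric) system is carried everywhere; the symmetric
#' system is the constrained view `b_x = b_y`, `c_x = c_y`, `d_x = d_y`.
#' `b`, `c` and `d` may therefore each be a single value (shared by both
#' genes) or a length-2 vector `(gene-x, gene-y)`.
#'
#' @param a Production scale of gene x (1/time). Strictly positive.
#' @param f Production scale of gene y (1/time); defaults to `a`.
#' @param b Self-saturation coefficient(s) (1/concentration), length 1 or 2.
#' @param c Cross-repression coefficient(s) (1/concentration), length 1 or 2.
#' @param d Degradation rate(s) (1/time), length 1 or 2.
#'
#' @return An object of class `generic_params`: a named list with fields
#'   `a`, `f`, `bx`, `by`, `cx`, `cy`, `dx`, `dy`.
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 1, d = 0.5)
#' circuit_q(p)
#' @seealso [steady_states()], [bifurcation_sweep()], [manifold_points()]
#' @export
generic_params <- function(a = 1, f = a, b = 0.5, c = 0.5, d = 0.5) {
  check_positive_scalar(a, "a")
  check_positive_scalar(f, "f")
  b <- check_gene_pair(b, "b")
  c <- check_gene_pair(c, "c")
  d <- check_gene_pair(d, "d")
  structure(
    list(a = a, f = f,
         bx = b[[1]], by = b[[2]],
         cx = c[[1]], cy = c[[2]],
         dx = d[[1]], dy = d[[2]]),
    class = "generic_params"
  )
}

#' @export
print.generic_params <- function(x, ...) {
  cat("<generic_params>\n")
  cat(sprintf("  a = %g, f = %g\n", x$a, x$f))
  cat(sprintf("  b = (%g, %g), c = (%g, %g), d = (%g, %g)\n",
              x$bx, x$by, x$cx, x$cy, x$dx, x$dy))
  if (is_symmetric_params(x)) {
    cat(sprintf("  symmetric; q = c/b = %g\n", circuit_q(x)))
  }
  invisible(x)
}

#' Bifurcation parameter q = c/b
#'
#' @param p A [generic_params()] object.
#' @return The dimensionless ratio of cross-repression to self-saturation,
#'   computed from the gene-x coefficients (`cx / bx`). Never stored.
#' @export
circuit_q <- function(p) {
  stopifnot(inherits(p, "generic_params"))
  p$cx / p$bx
}

#' Set q by moving c at fixed b
#'
#' Returns a copy of `p` with both cross-repression coefficients set to
#' `q * b` (gene-wise), the convention under which the asymmetric steady
#' states are literally constant along a bifurcation sweep.
#'
#' @param p A [generic_params()] object.
#' @param q Positive ratio c/b.
#' @return A modified `generic_params` object.
#' @export
set_circuit_q <- function(p, q) {
  stopifnot(inherits(p, "generic_params"))
  check_positive_scalar(q, "q")
  p$cx <- q * p$bx
  p$cy <- q * p$by
  p
}

# symmetric in the rate coefficients (b, c, d shared between the genes)
is_symmetric_params <- function(p, tol = 1e-12) {
  rel_eq(p$bx, p$by, tol) && rel_eq(p$cx, p$cy, tol) && rel_eq(p$dx, p$dy, tol)
}

rel_eq <- function(x, y, tol) abs(x - y) <= tol * max(abs(x), abs(y))

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single strictly positive number.", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative number.", name),
         call. = FALSE)
  }
  invisible(x)
}

# a per-gene coefficient: scalar (shared) or length-2 (gene-x, gene-y)
check_gene_pair <- function(x, name) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 2L) ||
      any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf(
      "`%s` must be one or two strictly positive numbers (gene-x, gene-y).",
      name), call. = FALSE)
  }
  if (length(x) == 1L) x <- c(x, x)
  as.numeric(x)
}

#' Parameters of the elementary promoter-binding models
#'
#' Model 1 treats self-activation and cross-repression as independent
#' promoter-binding events: each factor binds its own promoter (equilibrium
#' constants `K_x`, `K_y`), the opposing factor binds as a repressor with the
#' same affinity whether or not the activator is bound (`K_yx` for Y on the
#' x-promoter, `K_xy` for X on the y-promoter). Model 2
#' ([model2_params()]) instead forms the ternary promoter-activator-repressor
#' complex in situ with its own equilibrium constants `K_xxy`, `K_yyx`.
#'
#' @param alpha_x,alpha_y Production rate of protein from the activator-bound
#'   promoter (concentration/time).
#' @param delta_x,delta_y First-order protein degradation rate (1/time).
#' @param K_x,K_y Self-binding equilibrium constant of each factor to its own
#'   promoter (1/concentration).
#' @param K_yx,K_xy Cross-binding equilibrium constant of the repressor to the
#'   opposite promoter (1/concentration): `K_yx` is Y on the x-promoter.
#' @param x_tot,y_tot Total promoter concentration of each gene.
#'
#' @return An object of class `model1_params` (also `kinetic_params`).
#' @examples
#' p <- model1_params(alpha_x = 2, x_tot = 0.5, K_x = 1, K_yx = 1,
#'                    delta_x = 0.5)
#' reduce_model1(p)
#' @export
model1_params <- function(alpha_x = 1, alpha_y = alpha_x,
                          delta_x = 0.5, delta_y = delta_x,
                          K_x = 1, K_y = K_x,
                          K_yx = 1, K_xy = K_yx,
                          x_tot = 1, y_tot = x_tot) {
  fields <- list(alpha_x = alpha_x, alpha_y = alpha_y,
                 delta_x = delta_x, delta_y = delta_y,
                 K_x = K_x, K_y = K_y, K_yx = K_yx, K_xy = K_xy,
                 x_tot = x_tot, y_tot = y_tot)
  for (nm in names(fields)) check_positive_scalar(fields[[nm]], nm)
  structure(fields, class = c("model1_params", "kinetic_params"))
}

#' @rdname model1_params
#' @param K_xxy,K_yyx Equilibrium constant for the repressor binding the
#'   already activator-occupied promoter (Y on the xX complex, X on the yY
#'   complex; 1/concentration). When `K_xxy = K_yx` and `K_yyx = K_xy` the
#'   reduced rate law factorizes and Model 2 coincides with Model 1.
#' @export
model2_params <- function(alpha_x = 1, alpha_y = alpha_x,
                          delta_x = 0.5, delta_y = delta_x,
                          K_x = 1, K_y = K_x,
                          K_yx = 1, K_xy = K_yx,
                          K_xxy = K_yx, K_yyx = K_xy,
                          x_tot = 1, y_tot = x_tot) {
  p <- model1_params(alpha_x, alpha_y, delta_x, delta_y,
                     K_x, K_y, K_yx, K_xy, x_tot, y_tot)
  check_positive_scalar(K_xxy, "K_xxy")
  check_positive_scalar(K_yyx, "K_yyx")
  p$K_xxy <- K_xxy
  p$K_yyx <- K_yyx
  class(p) <- c("model2_params", "kinetic_params")
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[[1]]))
  for (nm in names(x)) cat(sprintf("  %s = %g\n", nm, x[[nm]]))
  invisible(x)
}
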
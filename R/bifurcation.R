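#' Sweep the bifurcation parameter q = c/b
#'
#' For each value of the cross-repression to self-saturation ratio
#' `q = c/b`, sets `c = q b` at fixed `b` (so the asymmetric branches stay
#' literally constant), enumerates all steady states and classifies their
#' stability. Below the critical ratio the interior symmetric state is the
#' only stable state (the indeterminate progenitor attractor); above it the
#' symmetric state is a saddle and the two asymmetric states
#' (the differentiated fates) are stable.
#'
#' @param p_base A [generic_params()] object; its `c` is overridden per grid
#'   point. Must satisfy [check_positivity()].
#' @param q Optional vector of positive q values (sorted increasing). By
#'   default 101 logarithmically spaced points on `[q_min, q_max]`.
#' @param q_min,q_max Range of the default grid.
#' @param n_q Number of points of the default grid.
#' @param refine_critical If `TRUE` (default, symmetric production only) the
#'   critical ratio is refined by bisection via [critical_q()], not read off
#'   the grid.
#' @return An object of class `bifurcation_diagram`: list with `diagram` (a
#'   tibble with columns `q`, `label`, `x`, `y`, `lambda`, `mu`,
#'   `stability`, `degenerate`), `critical_q`, and `params`. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 0.5, d = 0.5)
#' bd <- bifurcation_sweep(p, q = c(0.5, 2))
#' tidy(bd)
#' @export
bifurcation_sweep <- function(p_base, q = NULL, q_min = 0.2, q_max = 5,
                              n_q = 101, refine_critical = TRUE) {
  stopifnot(inherits(p_base, "generic_params"))
  if (!check_positivity(p_base)) {
    stop("base parameters violate the positivity condition (need a > d, f > d).",
         call. = FALSE)
  }
  if (is.null(q)) {
    q <- exp(seq(log(q_min), log(q_max), length.out = n_q))
  }
  if (any(q <= 0) || is.unsorted(q)) {
    stop("`q` must be positive and sorted increasing.", call. = FALSE)
  }
  rows <- purrr::map(q, function(qi) {
    pq <- set_circuit_q(p_base, qi)
    st <- suppressMessages(steady_states(pq))
    tibble::tibble(q = qi, st, degenerate = isTRUE(attr(st, "degenerate")))
  })
  diagram <- dplyr::bind_rows(rows)
  diagram <- enforce_branch_continuity(diagram)
  cq <- NA_real_
  if (refine_critical && rel_eq(p_base$a, p_base$f, 1e-12) &&
      is_symmetric_params(p_base)) {
    cq <- critical_q(p_base)
  }
  structure(list(diagram = diagram, critical_q = cq, params = p_base),
            class = "bifurcation_diagram")
}

#' Critical bifurcation ratio by bisection
#'
#' The interior symmetric state exchanges stability where its transversal
#' Jacobian eigenvalue (the eigenvalue along the anti-diagonal direction
#' `(1, -1)`), `d s (c - b) / ((1 + b s)(1 + c s))`, changes sign. Bisection
#' on `q` locates that sign change; for symmetric production the result is
#' `q* = 1` for all admissible `(a, b, d)`.
#'
#' @param p_base A [generic_params()] object with `a = f` and symmetric
#'   coefficients; `c` is overridden during the search.
#' @param tol Bracket width at which bisection stops.
#' @param bracket Initial search interval for q.
#' @return The critical ratio `q*` (bracket midpoint at width `<= tol`).
#' @examples
#' critical_q(generic_params(a = 1, b = 0.5, c = 0.5, d = 0.5))
#' @export
critical_q <- function(p_base, tol = 1e-6, bracket = c(0.1, 10)) {
  stopifnot(inherits(p_base, "generic_params"))
  if (!rel_eq(p_base$a, p_base$f, 1e-12) || !is_symmetric_params(p_base)) {
    stop("critical_q() requires symmetric production (a = f) and shared ",
         "b, c, d coefficients.", call. = FALSE)
  }
  if (!check_positivity(p_base)) {
    stop("positivity condition (a > d) must hold.", call. = FALSE)
  }
  check_positive_scalar(tol, "tol")
  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- transversal_eigenvalue(p_base, lo)
  g_hi <- transversal_eigenvalue(p_base, hi)
  if (is.na(g_lo) || is.na(g_hi) || sign(g_lo) == sign(g_hi)) {
    stop(sprintf("no sign change of the transversal eigenvalue in [%g, %g].",
                 lo, hi), call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    g_mid <- transversal_eigenvalue(p_base, mid)
    if (sign(g_mid) == sign(g_lo)) {
      lo <- mid; g_lo <- g_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# transversal (anti-diagonal) eigenvalue of the interior symmetric state at
# ratio q; for a symmetric Jacobian [[A, B], [B, A]] this is A - B
transversal_eigenvalue <- function(p_base, q) {
  pq <- set_circuit_q(p_base, q)
  s <- symmetric_state_coord(pq)
  if (is.na(s)) return(NA_real_)
  J <- circuit_jacobian(c(s, s), pq)
  J[1, 1] - J[1, 2]
}

# positive diagonal root of (1 + b s)(1 + c s) = a/d, Newton-polished
symmetric_state_coord <- function(p) {
  b <- p$bx; cc <- p$cx; R <- p$a / p$dx
  disc <- (b + cc)^2 - 4 * b * cc * (1 - R)
  if (disc <= 0) return(NA_real_)
  s <- (-(b + cc) + sqrt(disc)) / (2 * b * cc)
  if (s <= 0) return(NA_real_)
  polish_steady_state(c(s, s), p)[1]
}

# nearest-neighbour matching between adjacent q grid points; ties broken by
# label (labels are already semantic, so this is a consistency pass)
enforce_branch_continuity <- function(diagram) {
  qs <- unique(diagram$q)
  if (length(qs) < 2L) return(diagram)
  for (i in seq_along(qs)[-1]) {
    prev <- diagram[diagram$q == qs[i - 1L], ]
    cur_idx <- which(diagram$q == qs[i])
    cur <- diagram[cur_idx, ]
    for (j in seq_len(nrow(cur))) {
      d2 <- (prev$x - cur$x[j])^2 + (prev$y - cur$y[j])^2
      k <- which(d2 == min(d2))
      if (length(k) > 1L) k <- k[match(cur$label[j], prev$label[k], nomatch = 1L)]
      # adopt the nearest previous label only when coordinates nearly coincide
      if (min(d2) < 1e-12 && prev$label[k] != cur$label[j]) {
        diagram$label[cur_idx[j]] <- prev$label[k]
      }
    }
  }
  diagram
}

#' @export
print.bifurcation_diagram <- function(x, ...) {
  cat("<bifurcation_diagram>\n")
  cat(sprintf("  %d steady states over %d values of q in [%g, %g]\n",
              nrow(x$diagram), length(unique(x$diagram$q)),
              min(x$diagram$q), max(x$diagram$q)))
  if (!is.na(x$critical_q)) {
    cat(sprintf("  critical q (bisection): %.8f\n", x$critical_q))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname bifurcation_sweep
#' @param x,object A `bifurcation_diagram`.
#' @param ... Unused.
#' @method tidy bifurcation_diagram
#' @export
tidy.bifurcation_diagram <- function(x, ...) x$diagram

#' @rdname bifurcation_sweep
#' @method glance bifurcation_diagram
#' @export
glance.bifurcation_diagram <- function(x, ...) {
  per_q <- dplyr::summarise(
    dplyr::group_by(x$diagram, .data$q),
    n_states = dplyr::n(),
    n_stable = sum(.data$stability == "stable"),
    .groups = "drop"
  )
  tibble::tibble(
    critical_q = x$critical_q,
    n_q = nrow(per_q),
    q_min = min(per_q$q),
    q_max = max(per_q$q),
    max_stable = max(per_q$n_stable)
  )
}

#' @rdname bifurcation_sweep
#' @method autoplot bifurcation_diagram
#' @export
autoplot.bifurcation_diagram <- function(object, ...) {
  dd <- object$diagram
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$q, y = .data$x,
                                   group = .data$label,
                                   colour = .data$label,
                                   linetype = .data$stability == "stable")) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      labels = c(`TRUE` = "stable", `FALSE` = "unstable/saddle"),
      name = NULL) +
    ggplot2::labs(x = "q = c / b", y = "steady-state x",
                  colour = "branch",
                  title = "Bifurcation of the fate-decision circuit") +
    ggplot2::theme_minimal()
}
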
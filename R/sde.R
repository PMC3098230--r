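#' Euler-Maruyama simulation of the noisy circuit
#'
#' Integrates the generic circuit with independent additive Gaussian noise
#' on each coordinate:
#' \deqn{x_{t+dt} = x_t + f_x(x_t, y_t)\,dt + \sigma \sqrt{dt}\,\xi_t}
#' (and likewise for y), where `f` is [circuit_rhs()] and the `xi` are
#' independent standard normal draws. Because the variables are protein
#' concentrations, each coordinate is clamped at zero from below after every
#' step. With `sigma = 0` the scheme is exactly the deterministic Euler
#' method (see [integrate_euler()]).
#'
#' @param p A [generic_params()] object.
#' @param sigma Noise standard deviation (concentration/sqrt(time)), >= 0.
#' @param dt Time step (> 0).
#' @param n_steps Number of steps; trajectory length is `T = n_steps * dt`.
#' @param init Initial state `c(x, y)`, non-negative.
#' @param seed Integer seed; every random draw comes from one generator
#'   seeded here, so equal seeds give bit-identical trajectories.
#' @param burn_in_fraction Fraction of the trajectory discarded as transient
#'   by downstream estimators (recorded as an attribute, nothing dropped
#'   here).
#' @return A tibble with columns `time`, `x`, `y` (`n_steps + 1` rows,
#'   including the initial state), of class `circuit_trajectory`, carrying
#'   the parameters and configuration as attributes.
#' @examples
#' p <- generic_params(a = 1, b = 0.5, c = 1, d = 0.5)
#' traj <- simulate_circuit(p, sigma = 0.05, n_steps = 1000, seed = 1)
#' @export
simulate_circuit <- function(p, sigma = 0.05, dt = 0.01, n_steps = 1e6,
                             init = c(1, 1), seed = NULL,
                             burn_in_fraction = 0.1) {
  stopifnot(inherits(p, "generic_params"))
  check_nonneg_scalar(sigma, "sigma")
  check_positive_scalar(dt, "dt")
  stopifnot(n_steps >= 1, length(init) == 2L, all(init >= 0),
            burn_in_fraction >= 0, burn_in_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(n_steps)

  # pre-generate the Gaussian increments; sigma = 0 draws nothing so the
  # trajectory is exactly deterministic Euler
  noise_x <- if (sigma > 0) stats::rnorm(n_steps, sd = sigma * sqrt(dt)) else numeric(n_steps)
  noise_y <- if (sigma > 0) stats::rnorm(n_steps, sd = sigma * sqrt(dt)) else numeric(n_steps)

  a <- p$a; f <- p$f; bx <- p$bx; by <- p$by
  cx <- p$cx; cy <- p$cy; dx_ <- p$dx; dy_ <- p$dy
  xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
  x <- init[1]; y <- init[2]
  xs[1L] <- x; ys[1L] <- y
  for (i in seq_len(n_steps)) {
    fx <- a * x / ((1 + bx * x) * (1 + cx * y)) - dx_ * x
    fy <- f * y / ((1 + by * y) * (1 + cy * x)) - dy_ * y
    x <- x + fx * dt + noise_x[i]
    y <- y + fy * dt + noise_y[i]
    if (x < 0) x <- 0
    if (y < 0) y <- 0
    xs[i + 1L] <- x; ys[i + 1L] <- y
  }
  if (max(xs[n_steps + 1L], ys[n_steps + 1L]) > 1e3) {
    stop("trajectory diverged (state exceeded 1e3); reduce `dt` ",
         "(the explicit Euler-Maruyama step is unstable at this step size).",
         call. = FALSE)
  }
  out <- tibble::tibble(time = seq(0, by = dt, length.out = n_steps + 1L),
                        x = xs, y = ys)
  class(out) <- c("circuit_trajectory", class(out))
  attr(out, "params") <- p
  attr(out, "config") <- list(sigma = sigma, dt = dt, n_steps = n_steps,
                              init = init, seed = seed,
                              burn_in_fraction = burn_in_fraction)
  out
}

#' Deterministic Euler integration of the generic circuit
#'
#' Fixed-step explicit Euler scheme for the noiseless system, with the same
#' non-negativity clamp as [simulate_circuit()]; the stochastic integrator
#' at `sigma = 0` reproduces it bitwise.
#'
#' @inheritParams simulate_circuit
#' @return A tibble with columns `time`, `x`, `y`.
#' @export
integrate_euler <- function(p, dt = 0.01, n_steps = 1e5, init = c(1, 1)) {
  stopifnot(inherits(p, "generic_params"))
  check_positive_scalar(dt, "dt")
  xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
  x <- init[1]; y <- init[2]
  xs[1L] <- x; ys[1L] <- y
  for (i in seq_len(n_steps)) {
    fx <- p$a * x / ((1 + p$bx * x) * (1 + p$cx * y)) - p$dx * x
    fy <- p$f * y / ((1 + p$by * y) * (1 + p$cy * x)) - p$dy * y
    x <- x + fx * dt
    y <- y + fy * dt
    if (x < 0) x <- 0
    if (y < 0) y <- 0
    xs[i + 1L] <- x; ys[i + 1L] <- y
  }
  tibble::tibble(time = seq(0, by = dt, length.out = n_steps + 1L),
                 x = xs, y = ys)
}

#' Ensemble simulation from several initial conditions
#'
#' At moderate noise the basins of the bistable regime are deep: the mean
#' escape time grows like `exp(dU / sigma^2)`, so a single finite trajectory
#' samples only the basin it first falls into. The global attractor
#' landscape is therefore estimated by pooling trajectories started from
#' initial conditions spread over the phase plane, all drawn from one
#' seeded generator.
#'
#' @inheritParams simulate_circuit
#' @param inits Two-column matrix of initial states (one row per
#'   trajectory). Default: the 2x2 grid at 0.25 and 0.75 of the
#'   asymmetric-state coordinate `x_max` in each dimension, which covers
#'   both sides of the diagonal.
#' @param n_steps Steps per trajectory (total sample size is
#'   `nrow(inits) * n_steps`).
#' @return A `circuit_trajectory` tibble with an extra `run` column;
#'   burn-in is applied per run by downstream estimators.
#' @export
simulate_ensemble <- function(p, sigma = 0.05, dt = 0.01, n_steps = 2.5e5,
                              inits = NULL, seed = NULL,
                              burn_in_fraction = 0.1) {
  stopifnot(inherits(p, "generic_params"))
  if (is.null(inits)) {
    xm <- manifold_x_max(p)
    g <- c(0.25, 0.75) * xm
    inits <- as.matrix(expand.grid(x = g, y = g))
  }
  inits <- as_state_matrix(inits)
  if (!is.null(seed)) set.seed(seed)
  runs <- purrr::map(seq_len(nrow(inits)), function(i) {
    tr <- simulate_circuit(p, sigma = sigma, dt = dt, n_steps = n_steps,
                           init = inits[i, ], seed = NULL,
                           burn_in_fraction = burn_in_fraction)
    dplyr::mutate(tibble::as_tibble(tr), run = i, .before = 1L)
  })
  out <- dplyr::bind_rows(runs)
  class(out) <- c("circuit_trajectory", class(out))
  attr(out, "params") <- p
  attr(out, "config") <- list(sigma = sigma, dt = dt, n_steps = n_steps,
                              inits = inits, seed = seed,
                              burn_in_fraction = burn_in_fraction)
  out
}

post_burn_in <- function(traj) {
  cfg <- attr(traj, "config")
  frac <- if (is.null(cfg)) 0 else cfg$burn_in_fraction
  if (!is.null(traj[["run"]])) {
    keep <- unlist(lapply(split(seq_len(nrow(traj)), traj$run), function(idx) {
      idx[(floor(frac * length(idx)) + 1L):length(idx)]
    }))
    return(traj[sort(keep), , drop = FALSE])
  }
  drop <- floor(frac * nrow(traj))
  traj[(drop + 1L):nrow(traj), , drop = FALSE]
}

#' Stationary density of a simulated trajectory
#'
#' Bins the post-burn-in samples of a trajectory on a square grid over
#' `[0, 1.2 x_max]^2` (with `x_max = (a - d)/(b d)`, the asymmetric-state
#' coordinate) and normalizes occupancies to sum to one — an estimate of the
#' stationary probability landscape whose peaks are the noisy attractors and
#' whose heights gesture at their relative depths. A Gaussian kernel of one
#' bin width is applied by default so that mode detection operates on a
#' smoothed surface.
#'
#' @param traj A `circuit_trajectory` from [simulate_circuit()] (or any
#'   tibble with `x`, `y` columns plus `params`/`config` attributes).
#' @param n_bins Number of bins per axis.
#' @param lim Upper edge of the grid on both axes; default `1.2 * x_max`
#'   from the trajectory's parameters (falls back to the data range).
#' @param smooth Apply the one-bin Gaussian smoothing.
#' @return An object of class `density_grid`: list with `prob` (n_bins x
#'   n_bins matrix, rows = x bins, summing to 1), `x_mid`, `y_mid` (bin
#'   centers), `modes` (tibble from [count_modes()] with the default
#'   thresholds), and the originating `config`. Supports `tidy()`,
#'   `glance()` and `autoplot()`.
#' @export
stationary_density <- function(traj, n_bins = 100, lim = NULL, smooth = TRUE) {
  stopifnot(all(c("x", "y") %in% names(traj)))
  kept <- post_burn_in(traj)
  if (nrow(kept) == 0L) stop("no samples left after burn-in.", call. = FALSE)
  if (is.null(lim)) {
    p <- attr(traj, "params")
    lim <- if (!is.null(p)) 1.2 * manifold_x_max(p) else max(kept$x, kept$y)
    lim <- max(lim, max(kept$x), max(kept$y)) # never truncate the sample
  }
  edges <- seq(0, lim, length.out = n_bins + 1L)
  ix <- pmin(pmax(findInterval(kept$x, edges, rightmost.closed = TRUE), 1L), n_bins)
  iy <- pmin(pmax(findInterval(kept$y, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(tabulate((iy - 1L) * n_bins + ix, nbins = n_bins^2),
                   nrow = n_bins)
  prob <- counts / sum(counts)
  if (smooth) {
    prob <- smooth_gaussian(prob)
    prob <- prob / sum(prob)
  }
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  g <- structure(
    list(prob = prob, x_mid = mids, y_mid = mids,
         config = attr(traj, "config"), smooth = smooth),
    class = "density_grid"
  )
  g$modes <- count_modes(g)
  g
}

# separable Gaussian convolution, kernel sd = 1 bin, truncated at 3 bins
smooth_gaussian <- function(m, sd_bins = 1) {
  half <- ceiling(3 * sd_bins)
  k <- stats::dnorm(-half:half, sd = sd_bins)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    padded <- c(rep(0, half), v, rep(0, half))
    out <- numeric(n)
    for (j in seq_along(k)) out <- out + k[j] * padded[j:(j + n - 1L)]
    out
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Detect density modes (noisy attractors)
#'
#' Local maxima of the smoothed stationary density — grid cells at least as
#' high as all eight neighbours — with height at least `rel_threshold` times
#' the global maximum; maxima closer than `min_separation` (in state units)
#' are merged, keeping the higher.
#'
#' @param g A `density_grid` from [stationary_density()].
#' @param rel_threshold Minimum height relative to the global maximum.
#' @param min_separation Merge radius in state units.
#' @return A tibble with columns `x`, `y`, `height`, ordered by decreasing
#'   height.
#' @export
count_modes <- function(g, rel_threshold = 0.1, min_separation = 0.5) {
  stopifnot(inherits(g, "density_grid"))
  m <- g$prob
  n <- nrow(m)
  pad <- matrix(-Inf, n + 2L, n + 2L)
  pad[2:(n + 1L), 2:(n + 1L)] <- m
  is_max <- matrix(TRUE, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (m >= pad[(2:(n + 1L)) + di, (2:(n + 1L)) + dj])
  }
  keep <- which(is_max & m >= rel_threshold * max(m), arr.ind = TRUE)
  cand <- tibble::tibble(
    x = g$x_mid[keep[, 1L]],
    y = g$y_mid[keep[, 2L]],
    height = m[keep]
  )
  cand <- dplyr::arrange(cand, dplyr::desc(.data$height))
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) == 0L ||
        all(sqrt((kept$x - cand$x[i])^2 + (kept$y - cand$y[i])^2) >=
            min_separation)) {
      kept <- dplyr::bind_rows(kept, cand[i, ])
    }
  }
  kept
}

#' Fraction of samples residing near the degenerate manifold
#'
#' For degenerate parameters (`b = c`, `a = f`) the continuum of equilibria
#' traps the noisy dynamics: this measures the fraction of post-burn-in
#' samples whose Euclidean distance to the manifold is at most `dist_tol`.
#' Distance is computed by projection onto a dense polyline of the
#' x-parameterized manifold.
#'
#' @param traj A `circuit_trajectory`.
#' @param p A degenerate [generic_params()] object.
#' @param dist_tol Distance threshold in state units.
#' @param n_grid Resolution of the manifold polyline used for projection.
#' @return The residence fraction in `[0, 1]`.
#' @export
manifold_residence <- function(traj, p, dist_tol = 0.3, n_grid = 501) {
  check_degenerate(p)
  kept <- post_burn_in(traj)
  xm <- manifold_x_max(p)
  gx <- seq(0, xm, length.out = n_grid)
  gy <- manifold_y_of_x(gx, p)
  # chunked nearest-vertex distance to the x-parameterized polyline; grid
  # spacing is far below dist_tol so vertex distance suffices
  n <- nrow(kept)
  block <- 20000L
  within <- logical(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2min <- rep(Inf, length(idx))
    for (jg in seq_len(n_grid)) {
      d2 <- (kept$x[idx] - gx[jg])^2 + (kept$y[idx] - gy[jg])^2
      d2min <- pmin(d2min, d2)
    }
    within[idx] <- sqrt(d2min) <= dist_tol
  }
  mean(within)
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>\n")
  cat(sprintf("  %d x %d bins; %d mode(s)\n",
              nrow(x$prob), ncol(x$prob), nrow(x$modes)))
  print(x$modes)
  invisible(x)
}

#' @rdname stationary_density
#' @param x,object A `density_grid`.
#' @param ... Unused.
#' @method tidy density_grid
#' @export
tidy.density_grid <- function(x, ...) {
  tibble::tibble(
    x_bin_center = rep(x$x_mid, times = length(x$y_mid)),
    y_bin_center = rep(x$y_mid, each = length(x$x_mid)),
    probability = as.vector(x$prob)
  )
}

#' @rdname stationary_density
#' @method glance density_grid
#' @export
glance.density_grid <- function(x, ...) {
  tibble::tibble(
    n_modes = nrow(x$modes),
    max_probability = max(x$prob),
    n_bins = nrow(x$prob),
    sigma = if (!is.null(x$config)) x$config$sigma else NA_real_,
    n_steps = if (!is.null(x$config)) x$config$n_steps else NA_integer_
  )
}

#' @rdname stationary_density
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x_bin_center, y = .data$y_bin_center,
                               fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::geom_point(data = object$modes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, colour = "white", shape = 4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", fill = "probability",
                  title = "Stationary density of the noisy circuit") +
    ggplot2::theme_minimal()
}
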
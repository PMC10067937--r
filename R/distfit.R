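#' Two-component localisation-error distance density
#'
#' Density of the Euclidean distance `r` between two points whose
#' coordinates carry isotropic 2D Gaussian localisation error (the
#' Rice/Churchman distance law), summed over two components:
#'
#' \deqn{DD(r) = \sum_k A_k \frac{r}{\sigma_k^2}
#'   \exp\!\left(-\frac{\mu_k^2 + r^2}{2\sigma_k^2}\right)
#'   I_0\!\left(\frac{r\,\mu_k}{\sigma_k^2}\right)}
#'
#' where \eqn{I_0} is the modified Bessel function of integer order zero,
#' \eqn{\mu_k} is the characteristic true separation and \eqn{\sigma_k} the
#' combined two-channel localisation dispersion. For \eqn{\mu \to 0} a
#' component reduces to the Rayleigh density
#' \eqn{(r/\sigma^2)\exp(-r^2/2\sigma^2)}. The density integrates to
#' `a1 + a2`.
#'
#' Evaluation is numerically stable for large \eqn{r\mu/\sigma^2}: the
#' exponential and Bessel factors are combined as
#' \eqn{\exp(-(r-\mu)^2/2\sigma^2)\,\tilde I_0(r\mu/\sigma^2)} with the
#' exponentially scaled Bessel function \eqn{\tilde I_0(x) = e^{-x} I_0(x)}.
#'
#' @param r Distances (µm, >= 0); vectorised.
#' @param params A [mixture_params] object or named vector with `a1, a2,
#'   mu1, mu2, sigma1, sigma2`.
#' @return Density values (per µm), zero at `r = 0`.
#' @export
#' @examples
#' dd_density(1, mixture_params(a1 = 1, a2 = 0, mu1 = 0, sigma1 = 1))
#' # Rayleigh limit: exp(-1/2)
dd_density <- function(r, params) {
  p <- validate_mixture_params(params)
  if (any(r < 0)) stop("`r` must be >= 0", call. = FALSE)
  dd_component(r, p["a1"], p["mu1"], p["sigma1"]) +
    dd_component(r, p["a2"], p["mu2"], p["sigma2"])
}

dd_component <- function(r, a, mu, sigma) {
  a <- unname(a); mu <- unname(mu); sigma <- unname(sigma)
  if (a == 0) return(numeric(length(r)) + 0)
  x <- r * mu / sigma^2
  a * (r / sigma^2) * exp(-(r - mu)^2 / (2 * sigma^2)) *
    besselI(x, 0, expon.scaled = TRUE)
}

# unnamed parameter vector <-> mixture for the optimiser
par_to_mixture <- function(par, n_components) {
  if (n_components == 2) {
    c(a1 = par[1], a2 = par[2], mu1 = par[3], mu2 = par[4],
      sigma1 = par[5], sigma2 = par[6])
  } else {
    c(a1 = par[1], a2 = 0, mu1 = par[2], mu2 = 0,
      sigma1 = par[3], sigma2 = 1)
  }
}

dd_model <- function(r, par, n_components) {
  p <- par_to_mixture(par, n_components)
  dd_component(r, p["a1"], p["mu1"], p["sigma1"]) +
    dd_component(r, p["a2"], p["mu2"], p["sigma2"])
}

#' Cumulative distribution of the mixture distance law
#'
#' Obtained by trapezoidal quadrature of [dd_density()] on a fine grid and
#' normalised by `a1 + a2`; useful as an independent check against sampled
#' distances.
#'
#' @param r Distances (µm) at which to evaluate the CDF.
#' @param params Mixture parameters as in [dd_density()].
#' @param n_grid Quadrature grid size.
#' @return CDF values in \[0, 1\].
#' @export
dd_cdf <- function(r, params, n_grid = 4096) {
  p <- validate_mixture_params(params)
  rmax <- max(max(r), max(p["mu1"], p["mu2"]) + 8 * max(p["sigma1"], p["sigma2"]))
  grid <- seq(0, rmax, length.out = n_grid)
  dens <- dd_density(grid, p)
  cdf <- pracma::cumtrapz(grid, dens)
  cdf <- cdf / (p["a1"] + p["a2"])
  pmin(pmax(stats::approx(grid, cdf, xout = r, rule = 2)$y, 0), 1)
}

# initial values per the package's initialisation policy: mu at the two
# most prominent maxima of a lightly smoothed histogram (mode and 3x mode
# if only one), sigma at twice the bin width, amplitudes by linear LS
initial_guess <- function(hist, n_components) {
  d <- hist$bins$density
  mid <- hist$bins$mid
  k <- stats::filter(d, rep(1 / 3, 3), sides = 2)
  k[is.na(k)] <- d[is.na(k)]
  k <- as.numeric(k)
  n <- length(k)
  is_max <- k > 0 &
    k >= c(-Inf, k[-n]) &
    k >= c(k[-1], -Inf)
  peaks <- order(k * is_max, decreasing = TRUE)
  peaks <- peaks[k[peaks] * is_max[peaks] > 0]
  mode1 <- if (length(peaks) >= 1) mid[peaks[1]] else mid[which.max(d)]
  sigma0 <- 2 * hist$bin_width_um
  if (n_components == 1) {
    par <- c(1, max(mode1, 0), sigma0)
  } else {
    mode2 <- if (length(peaks) >= 2) mid[peaks[2]] else 3 * mode1
    mus <- sort(c(mode1, mode2))
    par <- c(0.5, 0.5, mus[1], max(mus[2], mus[1] + sigma0), sigma0, 2 * sigma0)
  }
  amps_linear_ls(par, hist, n_components)
}

# solve amplitudes by linear least squares given (mu, sigma); clamp >= 1e-3
amps_linear_ls <- function(par, hist, n_components) {
  mid <- hist$bins$mid
  if (n_components == 1) {
    b <- dd_component(mid, 1, par[2], par[3])
    a <- sum(b * hist$bins$density) / max(sum(b^2), 1e-12)
    par[1] <- max(a, 1e-3)
  } else {
    b1 <- dd_component(mid, 1, par[3], par[5])
    b2 <- dd_component(mid, 1, par[4], par[6])
    X <- cbind(b1, b2)
    a <- tryCatch(stats::coef(stats::lm.fit(X, hist$bins$density)),
                  error = function(e) c(0.5, 0.5))
    a[!is.finite(a)] <- 0.5
    par[1:2] <- pmax(a, 1e-3)
  }
  par
}

#' Fit the distance distribution to a histogram
#'
#' Non-linear least squares of [dd_density()] evaluated at bin midpoints
#' against the histogram density (Levenberg–Marquardt with box
#' constraints: amplitudes and characteristic distances >= 0, dispersions
#' >= 1e-4 µm). Components are reported sorted by `mu`; the parameter
#' covariance comes from the least-squares solution and 95% confidence
#' half-widths are `1.96 * sqrt(diag(cov))`. A fit is flagged degenerate
#' when any active parameter's confidence half-width exceeds the magnitude
#' of its estimate — the signature of an uninformative model, as for
#' distances from unpaired scatter.
#'
#' On non-convergence, up to `max_restarts` perturbed reinitialisations are
#' tried and the best attempt is returned with `converged = FALSE` if none
#' succeeds.
#'
#' @param hist A `distance_histogram` from [build_histogram()].
#' @param n_components 1 or 2.
#' @param init Optional [mixture_params] (or named vector) used as starting
#'   values instead of the automatic peak-based initialisation.
#' @param weights `"poisson"` (default: bins weighted by the reciprocal
#'   Poisson standard error of their density, which makes the
#'   covariance-derived confidence intervals approximately calibrated) or
#'   `"none"` (plain least squares, the behaviour of generic curve-fitting
#'   routines; its covariance understates the uncertainty of parameters
#'   driven by high-count bins).
#' @param max_restarts Maximum perturbed restarts on non-convergence.
#'
#' @return An object of class `dd_fit`: list with `params`
#'   ([mixture_params]), `covariance` (named, free parameters only),
#'   `ci95` (half-widths), `residual_ss`, `converged`, `degenerate`,
#'   `offending` (tibble of parameters violating the degeneracy rule),
#'   `n_components`, `n`, `bin_width_um`, `histogram`.
#' @export
fit_distance_model <- function(hist, n_components = 2, init = NULL,
                               weights = c("poisson", "none"),
                               max_restarts = 5) {
  if (!inherits(hist, "distance_histogram")) {
    stop("`hist` must be a distance_histogram", call. = FALSE)
  }
  weights <- match.arg(weights)
  if (!n_components %in% c(1, 2)) stop("`n_components` must be 1 or 2", call. = FALSE)
  npar <- if (n_components == 2) 6 else 3
  if (sum(hist$bins$count > 0) < 3 * npar) {
    stop("too few non-empty bins (need >= ", 3 * npar,
         ") to fit ", npar, " parameters", call. = FALSE)
  }
  mid <- hist$bins$mid
  obs <- hist$bins$density
  w <- if (weights == "poisson") {
    sd <- sqrt(pmax(hist$bins$count, 1)) / (hist$n * hist$bin_width_um)
    1 / sd
  } else {
    rep(1, length(obs))
  }
  lower <- if (n_components == 2) c(0, 0, 0, 0, 1e-4, 1e-4) else c(0, 0, 1e-4)
  resid_fn <- function(par) w * (dd_model(mid, par, n_components) - obs)

  par0 <- if (is.null(init)) {
    initial_guess(hist, n_components)
  } else {
    p <- as_mixture_vector(init)
    if (n_components == 2) unname(p[c("a1", "a2", "mu1", "mu2", "sigma1", "sigma2")])
    else unname(p[c("a1", "mu1", "sigma1")])
  }
  par0 <- pmax(par0, lower)

  run_fit <- function(start) {
    tryCatch(
      minpack.lm::nls.lm(start, lower = lower, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
  }
  best <- run_fit(par0)
  attempts <- 0
  perturb <- function(par) {
    p <- par * exp(stats::rnorm(length(par), 0, 0.3))
    pmax(p, lower)
  }
  while ((is.null(best) || !(best$info %in% 1:4)) && attempts < max_restarts) {
    attempts <- attempts + 1
    cand <- run_fit(perturb(par0))
    if (is.null(best) ||
        (!is.null(cand) && sum(cand$fvec^2) < sum(best$fvec^2))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("least-squares fit failed to evaluate", call. = FALSE)
  converged <- best$info %in% 1:4
  par <- best$par

  # sort components by mu ascending (2-component case)
  perm <- seq_len(npar)
  if (n_components == 2 && par[3] > par[4]) {
    perm <- c(2, 1, 4, 3, 6, 5)
    par <- par[perm]
  }
  resid <- resid_fn(if (n_components == 2) par else par)
  ss <- sum(resid^2)

  # covariance via the numerically evaluated Jacobian at the solution
  J <- tryCatch(
    pracma::jacobian(function(p) w * dd_model(mid, p, n_components), par),
    error = function(e) NULL)
  dof <- length(mid) - npar
  covar <- NULL
  if (!is.null(J) && dof > 0) {
    covar <- tryCatch(sum(resid^2) / dof * solve(crossprod(J)),
                      error = function(e) NULL)
  }
  free_names <- if (n_components == 2) {
    c("a1", "a2", "mu1", "mu2", "sigma1", "sigma2")
  } else {
    c("a1", "mu1", "sigma1")
  }
  if (is.null(covar)) {
    covar <- matrix(NA_real_, npar, npar)
  }
  dimnames(covar) <- list(free_names, free_names)

  params <- structure(par_to_mixture(par, n_components),
                      class = c("mixture_params", "numeric"))
  fit <- structure(
    list(params = params, covariance = covar, ci95 = NULL,
         residual_ss = ss, converged = converged, degenerate = NA,
         offending = NULL, n_components = n_components, n = hist$n,
         bin_width_um = hist$bin_width_um, weights = weights,
         histogram = hist),
    class = "dd_fit"
  )
  assess_fit(confidence_intervals(fit))
}

#' Attach 95% confidence intervals to a fit
#'
#' Per-parameter half-widths `1.96 * sqrt(diag(covariance))`. Non-finite
#' covariance entries yield infinite intervals (and, through
#' [assess_fit()], a degenerate flag).
#'
#' @param fit A `dd_fit`.
#' @return The fit with its `ci95` element populated.
#' @export
confidence_intervals <- function(fit) {
  stopifnot(inherits(fit, "dd_fit"))
  v <- diag(fit$covariance)
  half <- ifelse(is.finite(v) & v >= 0, 1.96 * sqrt(v), Inf)
  names(half) <- colnames(fit$covariance)
  fit$ci95 <- half
  fit
}

#' Apply the degenerate-fit rule
#'
#' A fit is degenerate when any active parameter's 95% confidence
#' half-width exceeds the magnitude of its estimate — parameter
#' uncertainties greater than the parameter estimates themselves. The
#' offending parameters are listed in the returned fit.
#'
#' @param fit A `dd_fit` with confidence intervals computed.
#' @return The fit with `degenerate` and `offending` populated.
#' @export
assess_fit <- function(fit) {
  stopifnot(inherits(fit, "dd_fit"))
  if (is.null(fit$ci95)) fit <- confidence_intervals(fit)
  free_names <- names(fit$ci95)
  est <- as_mixture_vector(fit$params)[free_names]
  bad <- !is.finite(fit$ci95) | fit$ci95 > abs(est)
  fit$degenerate <- any(bad)
  fit$offending <- tibble::tibble(
    term = free_names[bad],
    estimate = unname(est[bad]),
    ci95_half_width = unname(fit$ci95[bad])
  )
  fit
}

#' @export
print.dd_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<dd_fit> %d-component distance-distribution fit (n = %d)\n",
              x$n_components, x$n))
  cat(sprintf("  mu1 = %.4g um (+/- %.3g), sigma1 = %.4g um, a1 = %.3g\n",
              p["mu1"], x$ci95["mu1"], p["sigma1"], p["a1"]))
  if (x$n_components == 2) {
    cat(sprintf("  mu2 = %.4g um (+/- %.3g), sigma2 = %.4g um, a2 = %.3g\n",
                p["mu2"], x$ci95["mu2"], p["sigma2"], p["a2"]))
  }
  cat(sprintf("  residual SS %.4g; converged: %s; degenerate: %s\n",
              x$residual_ss, x$converged, x$degenerate))
  invisible(x)
}

#' Tidy a distance-distribution fit
#'
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.dd_fit <- function(x, ...) {
  free_names <- names(x$ci95)
  est <- as_mixture_vector(x$params)[free_names]
  se <- x$ci95 / 1.96
  tibble::tibble(
    term = free_names, estimate = unname(est), std.error = unname(se),
    conf.low = unname(est - x$ci95), conf.high = unname(est + x$ci95)
  )
}

#' One-row summary of a distance-distribution fit
#'
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.dd_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_components = x$n_components, residual_ss = x$residual_ss,
    converged = x$converged, degenerate = x$degenerate,
    bin_width_um = x$bin_width_um
  )
}

#' Plot a fitted distance distribution over its histogram
#'
#' @param object A `dd_fit`.
#' @param n_curve Points on the fitted curve.
#' @param ... Unused.
#' @return A ggplot showing the histogram, the total fitted density and the
#'   individual components.
#' @export
autoplot.dd_fit <- function(object, n_curve = 400, ...) {
  bins <- object$histogram$bins
  r <- seq(0, max(bins$bin_right), length.out = n_curve)
  p <- object$params
  curves <- dplyr::bind_rows(
    tibble::tibble(r = r, density = dd_density(r, p), part = "fit"),
    tibble::tibble(r = r, density = dd_component(r, p["a1"], p["mu1"], p["sigma1"]),
                   part = "component 1"),
    if (object$n_components == 2)
      tibble::tibble(r = r, density = dd_component(r, p["a2"], p["mu2"], p["sigma2"]),
                     part = "component 2")
  )
  autoplot.distance_histogram(object$histogram) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$r, .data$density,
                                    colour = .data$part),
                       inherit.aes = FALSE, linewidth = 0.7) +
    ggplot2::labs(colour = NULL)
}

#' Write a fit report to JSON
#'
#' @param fit A `dd_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(params = as.list(as_mixture_vector(fit$params)),
         ci95 = as.list(fit$ci95),
         residual_ss = fit$residual_ss, converged = fit$converged,
         degenerate = fit$degenerate, n = fit$n,
         n_components = fit$n_components, bin_width_um = fit$bin_width_um),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
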
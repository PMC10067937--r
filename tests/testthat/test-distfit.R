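test_that("the distance density has the right limits and normalisation", {
  # leading factor r makes the density vanish at the origin
  expect_equal(dd_density(0, mixture_params()), 0)
  # Rayleigh limit at mu = 0, sigma = 1, r = 1: exp(-1/2)
  ray <- mixture_params(a1 = 1, a2 = 0, mu1 = 0, sigma1 = 1)
  expect_equal(dd_density(1, ray), exp(-0.5), tolerance = 1e-12)
  expect_error(dd_density(-0.1, ray), ">= 0")

  # integral equals a1 + a2 for random valid parameter sets
  set.seed(11)
  for (k in 1:20) {
    p <- random_mixture()
    integral <- stats::integrate(function(r) dd_density(r, p), 0, Inf,
                                 rel.tol = 1e-10)$value
    expect_equal(integral, unname(p["a1"] + p["a2"]), tolerance = 1e-6)
  }
})

test_that("a mu -> 0 component converges pointwise to the Rayleigh density", {
  sigma <- 0.03
  p <- mixture_params(a1 = 1, a2 = 0, mu1 = 1e-8, sigma1 = sigma)
  r <- seq(0, 5 * sigma, length.out = 200)
  rayleigh <- (r / sigma^2) * exp(-r^2 / (2 * sigma^2))
  expect_lt(max(abs(dd_density(r, p) - rayleigh)), 1e-9)
})

test_that("large Bessel arguments evaluate stably", {
  # r mu / sigma^2 ~ 4e4: naive exp * besselI overflows, scaled form must not
  p <- mixture_params(a1 = 1, a2 = 0, mu1 = 0.4, sigma1 = 0.002)
  v <- dd_density(seq(0.3, 0.5, length.out = 100), p)
  expect_true(all(is.finite(v)))
  # integrate across the narrow peak explicitly (mass lives in [0.3, 0.5])
  expect_equal(stats::integrate(function(r) dd_density(r, p),
                                0.3, 0.5, rel.tol = 1e-10)$value,
               1, tolerance = 1e-6)
})

make_exact_histogram <- function(params, bin_width = 0.005, rmax = 0.45,
                                 n = 10000) {
  edges <- seq(0, rmax, by = bin_width)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- dd_density(mid, params)
  structure(
    list(bins = tibble::tibble(
      bin_left = edges[-length(edges)], bin_right = edges[-1], mid = mid,
      count = pmax(round(dens * n * bin_width), ifelse(dens > 1e-8, 1, 0)),
      density = dens),
      n = n, bin_width_um = bin_width),
    class = "distance_histogram")
}

test_that("fitting a noise-free tabulated density recovers all parameters", {
  truth <- mixture_params(a1 = 0.7, a2 = 0.3, mu1 = 0.034, mu2 = 0.169,
                          sigma1 = 0.010, sigma2 = 0.040)
  h <- make_exact_histogram(truth)
  fit <- fit_distance_model(h, n_components = 2)
  expect_true(fit$converged)
  rel <- abs(as.numeric(fit$params) - as.numeric(truth)) / as.numeric(truth)
  expect_lt(max(rel), 1e-4)
  expect_false(fit$degenerate)
  # component ordering is mu-ascending by construction
  expect_lte(fit$params[["mu1"]], fit$params[["mu2"]])

  # single-component exact curve
  ray <- mixture_params(a1 = 1, a2 = 0, mu1 = 0.05, sigma1 = 0.02)
  h1 <- make_exact_histogram(ray, rmax = 0.25)
  fit1 <- fit_distance_model(h1, n_components = 1)
  expect_lt(abs(fit1$params[["mu1"]] - 0.05) / 0.05, 1e-4)
})

test_that("the returned fit is at least as good as a coarse grid search", {
  truth <- mixture_params()
  s <- sample_displacement_distances(truth, n = 8000, seed = 42)
  h <- build_histogram(s$distance_um, bin_width_um = 0.01)
  fit <- fit_distance_model(h, n_components = 2, weights = "none")

  mid <- h$bins$mid; obs <- h$bins$density
  basis <- function(mu, sg) {
    x <- mid * mu / sg^2
    (mid / sg^2) * exp(-(mid - mu)^2 / (2 * sg^2)) *
      besselI(x, 0, expon.scaled = TRUE)
  }
  best_ss <- Inf
  for (mu1 in seq(0.02, 0.06, by = 0.01))
    for (sg1 in c(0.008, 0.012, 0.02))
      for (mu2 in seq(0.1, 0.25, by = 0.03))
        for (sg2 in c(0.03, 0.05, 0.08)) {
          X <- cbind(basis(mu1, sg1), basis(mu2, sg2))
          a <- tryCatch(stats::coef(stats::lm.fit(X, obs)),
                        error = function(e) NULL)
          if (is.null(a) || anyNA(a)) next
          a <- pmax(a, 0)
          ss <- sum((X %*% a - obs)^2)
          if (ss < best_ss) best_ss <- ss
        }
  expect_lte(fit$residual_ss, best_ss)
})

test_that("confidence intervals follow 1.96 * sqrt(diag(cov))", {
  truth <- mixture_params()
  h <- make_exact_histogram(truth)
  fit <- fit_distance_model(h, n_components = 2)

  fit$covariance[] <- 0
  fit <- confidence_intervals(fit)
  expect_true(all(fit$ci95 == 0))

  fit$covariance[] <- 0
  fit$covariance["mu1", "mu1"] <- 1e-4
  fit <- confidence_intervals(fit)
  expect_equal(unname(fit$ci95["mu1"]), 1.96 * 0.01)

  fit$covariance["mu2", "mu2"] <- NA
  fit <- assess_fit(confidence_intervals(fit))
  expect_true(is.infinite(fit$ci95[["mu2"]]))
  expect_true(fit$degenerate)
  expect_true("mu2" %in% fit$offending$term)
})

test_that("the degeneracy rule compares CI half-widths with estimates", {
  truth <- mixture_params()
  h <- make_exact_histogram(truth)
  fit <- fit_distance_model(h, n_components = 2)

  # mu1 = 0.034 with half-width 0.010: informative
  fit$covariance[] <- 0
  fit$covariance["mu1", "mu1"] <- (0.010 / 1.96)^2
  fit <- assess_fit(confidence_intervals(fit))
  expect_false(fit$degenerate)

  # mu2 half-width 0.20 against an estimate of 0.169: degenerate
  fit$covariance["mu2", "mu2"] <- (0.20 / 1.96)^2
  fit <- assess_fit(confidence_intervals(fit))
  expect_true(fit$degenerate)
  expect_equal(fit$offending$term, "mu2")
})

test_that("covariance-based CI widths agree with the bootstrap within 2x", {
  truth <- mixture_params()
  s <- sample_displacement_distances(truth, n = 5000, seed = 42)
  h <- build_histogram(s$distance_um, bin_width_um = 0.01)
  fit <- fit_distance_model(h, n_components = 2)
  ci_mu1 <- fit$ci95[["mu1"]]

  set.seed(42)
  boot <- replicate(150, {
    d <- sample(s$distance_um, replace = TRUE)
    hb <- build_histogram(d, bin_width_um = 0.01)
    fb <- tryCatch(fit_distance_model(hb, n_components = 2, init = truth),
                   error = function(e) NULL)
    if (is.null(fb)) NA_real_ else fb$params[["mu1"]]
  })
  boot_ci <- 1.96 * stats::sd(boot, na.rm = TRUE)
  expect_gt(ci_mu1 / boot_ci, 0.5)
  expect_lt(ci_mu1 / boot_ci, 2)
})

test_that("more data does not worsen the characteristic-distance estimate", {
  truth <- mixture_params()
  err_at <- function(n) {
    vapply(1:6, function(sd) {
      s <- sample_displacement_distances(truth, n = n, seed = 100 + sd)
      h <- build_histogram(s$distance_um, bin_width_um = 0.01)
      fit <- fit_distance_model(h, n_components = 2)
      abs(fit$params[["mu1"]] - truth[["mu1"]])
    }, numeric(1))
  }
  expect_lte(median(err_at(1e5)), median(err_at(1e3)))
})

test_that("fit objects expose tidy, glance and a JSON report", {
  h <- make_exact_histogram(mixture_params())
  fit <- fit_distance_model(h, n_components = 2)
  td <- tidy(fit)
  expect_setequal(td$term, c("a1", "a2", "mu1", "mu2", "sigma1", "sigma2"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_components, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$params$mu1, fit$params[["mu1"]])
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
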
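test_that("joint survival: boundary, independence and formula oracle", {
  p <- amh_design("D1")
  expect_equal(amh_survival(0, 0, p), 1.0)

  # independence reduction at phi = 0
  p0 <- amh_params(1.3, 0.7, 2.1, 1.4, 0)
  expect_equal(amh_survival(0.6, 1.1, p0),
               exp(-0.7 * 0.6^1.3) * exp(-1.4 * 1.1^2.1))

  # direct arithmetic oracle, D1 parameters at t1 = t2 = 0.5
  S1 <- exp(-1 * 0.5^2)
  S2 <- exp(-1 * 0.5^3)
  oracle <- S1 * S2 / (1 - 0.5 * (1 - S1) * (1 - S2))
  expect_equal(amh_survival(0.5, 0.5, p), oracle, tolerance = 1e-12)

  # marginal identities S(t, 0) = S1(t), S(0, t) = S2(t) over random params
  set.seed(401)
  for (k in 1:20) {
    pr <- random_params()
    t <- runif(1, 0.05, 3)
    expect_equal(amh_survival(t, 0, pr), exp(-pr[["beta1"]] * t^pr[["alpha1"]]),
                 tolerance = 1e-12)
    expect_equal(amh_survival(0, t, pr), exp(-pr[["beta2"]] * t^pr[["alpha2"]]),
                 tolerance = 1e-12)
  }

  expect_error(amh_params(2, 1, 3, 1, 1), "phi")
  expect_error(amh_params(-2, 1, 3, 1, 0), "alpha1")
})

test_that("joint density: independence product, finite differences, mass one", {
  # phi = 0: product of Weibull densities
  p0 <- amh_params(2, 1, 3, 1, 0)
  f1 <- function(t) 1 * 2 * t^1 * exp(-t^2)
  f2 <- function(t) 1 * 3 * t^2 * exp(-t^3)
  expect_equal(amh_density(0.7, 1.2, p0), f1(0.7) * f2(1.2), tolerance = 1e-12)

  # mixed-partial finite-difference oracle, D2 params at (1.0, 0.8)
  p2 <- amh_design("D2")
  expect_equal(amh_density(1.0, 0.8, p2), fd_density(1.0, 0.8, p2),
               tolerance = 1e-4)

  # integrates to one over the positive quadrant (D4, strong dependence)
  p4 <- amh_design("D4")
  mass <- pracma::integral2(function(x, y) amh_density(x, y, p4),
                            1e-8, 10, 1e-8, 10, reltol = 1e-8)$Q
  expect_equal(mass, 1, tolerance = 1e-3)

  # nonnegative on a grid for random params including phi near both ends
  set.seed(402)
  grid <- expand.grid(t1 = c(0.05, 0.3, 1, 2.5), t2 = c(0.05, 0.3, 1, 2.5))
  for (k in 1:15) {
    pr <- random_params()
    vals <- amh_density(grid$t1, grid$t2, pr)
    expect_true(all(is.finite(vals) & vals >= 0))
  }
})

test_that("partial survival derivatives match finite differences and limits", {
  p <- amh_design("D1")
  # phi = 0 reduction: f1(t1) S2(t2)
  p0 <- amh_params(2, 1, 3, 1, 0)
  expect_equal(amh_partial(0.7, 0.9, p0, margin = 1),
               2 * 0.7 * exp(-0.7^2) * exp(-0.9^3), tolerance = 1e-12)

  expect_equal(amh_partial(0.7, 0.9, p, margin = 2),
               fd_partial(0.7, 0.9, p, 2), tolerance = 1e-4)
  expect_equal(amh_partial(0.7, 0.9, p, margin = 1),
               fd_partial(0.7, 0.9, p, 1), tolerance = 1e-4)

  # t2 -> 0: margin-1 partial tends to the marginal density f1(t1)
  expect_equal(amh_partial(0.7, 1e-9, p, margin = 1),
               2 * 0.7 * exp(-0.7^2), tolerance = 1e-6)

  expect_error(amh_partial(1, 1, p, margin = 3), "margin")
})

test_that("log-likelihood: exponential toy value and phi = 0 decomposition", {
  d <- tibble::tibble(time1 = c(1, 2), status1 = c(1, 0),
                      time2 = c(0.5, 1.5), status2 = c(1, 0))
  expect_equal(amh_loglik(d, amh_params(1, 1, 1, 1, 0)), -5.0, tolerance = 1e-12)

  # phi = 0 equals the sum of two univariate censored Weibull log-likelihoods
  set.seed(403)
  dat <- amh_simulate(60, "D1", censor_pct = 20)
  for (pars in list(c(2, 1, 3, 1), c(1.4, 0.6, 2.2, 1.7))) {
    expect_equal(
      amh_loglik(dat, c(pars, 0)),
      weibull_cens_loglik(dat$time1, dat$status1, pars[1], pars[2]) +
        weibull_cens_loglik(dat$time2, dat$status2, pars[3], pars[4]),
      tolerance = 1e-10
    )
  }
})

test_that("log-likelihood factors by censoring pattern", {
  # each subject contributes density / partial / joint survival according
  # to (status1, status2); checked against the R-level formulas
  d <- toy_mixed_data()
  for (p in list(amh_design("D1"), amh_design("D2"), amh_design("D4"))) {
    oracle <- sum(purrr::pmap_dbl(d, function(time1, status1, time2, status2) {
      if (status1 == 1 && status2 == 1) log(amh_density(time1, time2, p))
      else if (status1 == 1) log(amh_partial(time1, time2, p, 1))
      else if (status2 == 1) log(amh_partial(time1, time2, p, 2))
      else log(amh_survival(time1, time2, p))
    }))
    expect_equal(amh_loglik(d, p), oracle, tolerance = 1e-10)
  }

  # all-uncensored: sum of log joint densities
  set.seed(404)
  du <- amh_simulate(30, "D2")
  p2 <- amh_design("D2")
  expect_equal(amh_loglik(du, p2),
               sum(log(amh_density(du$time1, du$time2, p2))), tolerance = 1e-10)
})

test_that("log prior: Gamma/uniform components and support", {
  # alpha = beta = 1 under Gamma(1, 1) contributes -1 each; phi = 0 under
  # U(-1, 1) contributes log(1/2)
  h1 <- amh_hyperparams(a11 = 1, a12 = 1, a21 = 1, a22 = 1,
                        b11 = 1, b12 = 1, b21 = 1, b22 = 1)
  expect_equal(amh_logprior(amh_params(1, 1, 1, 1, 0), h1),
               4 * (-1) + log(0.5), tolerance = 1e-12)
  # vague defaults: each Gamma(0.01, 0.01) has mean 1 and variance 100
  h <- amh_hyperparams()
  expect_equal(h[["a11"]] / h[["a12"]], 1)
  expect_equal(h[["a11"]] / h[["a12"]]^2, 100)
})

test_that("shape conditional kernel matches log-posterior differences", {
  set.seed(405)
  dat <- amh_simulate(25, "D1", censor_pct = 10)
  st <- amh_design("D1")
  for (margin in 1:2) {
    a1 <- 1.4; a2 <- 2.7
    lk <- amh_log_kappa(c(a1, a2), margin, dat, st)
    lp <- vapply(c(a1, a2), function(a) {
      p <- as.numeric(unclass(st))
      p[if (margin == 1) 1 else 3] <- a
      amh_loglik(dat, p) + amh_logprior(p)
    }, numeric(1))
    expect_equal(lk[1] - lk[2], lp[1] - lp[2], tolerance = 1e-10)
  }
  expect_error(amh_log_kappa(-1, 1, dat, st), "alpha")
})

test_that("shape kernel with an all-censored margin matches the closed form", {
  # r1 = 0: kappa(alpha) = alpha^(a11-1) exp(-a12 alpha - beta1 sum t^alpha) Psi
  d <- tibble::tibble(time1 = c(0.6, 1.2, 0.9), status1 = c(0, 0, 0),
                      time2 = c(0.4, 0.8, 1.5), status2 = c(1, 1, 0))
  st <- amh_params(1.5, 1, 2, 1, 0.4)
  h <- amh_hyperparams()
  for (alpha in c(0.5, 1.7)) {
    F1 <- 1 - exp(-1 * d$time1^alpha)
    F2 <- 1 - exp(-1 * d$time2^2)
    D <- 1 - 0.4 * F1 * F2
    psi <- sum(ifelse(d$status2 == 1, log(1 - 0.4 * F1) - 2 * log(D), -log(D)))
    oracle <- (h[["a11"]] - 1) * log(alpha) - h[["a12"]] * alpha -
      1 * sum(d$time1^alpha) + psi
    expect_equal(amh_log_kappa(alpha, 1, d, st, h), oracle, tolerance = 1e-10)
  }
})
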
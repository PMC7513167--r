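test_that("thinning bookkeeping, determinism and summary identities", {
  set.seed(601)
  dat <- amh_simulate(30, "D1")
  ctl <- amh_control(L = 110, B = 10, J = 10)
  f <- amh_fit(dat, "A2", control = ctl, seed = 5)
  expect_equal(nrow(f$draws), 10)               # S = floor((L - B)/J)
  expect_equal(f$draws$iter, seq(20, 110, by = 10))
  expect_equal(unname(f$estimates),
               unname(colMeans(f$draws[c("alpha1", "beta1", "alpha2", "beta2", "phi")])))
  expect_true(all(f$draws$phi > -1 & f$draws$phi < 1))

  g <- amh_fit(dat, "A2", control = ctl, seed = 5)
  expect_identical(f$draws, g$draws)            # bit-for-bit under a seed

  f3 <- amh_fit(dat, "A3", control = ctl, seed = 5)
  expect_equal(unname(f3$acceptance[c("alpha1", "alpha2")]), c(1, 1))
})

test_that("scale update is an exact Gibbs draw when phi is zero", {
  set.seed(602)
  dat <- amh_simulate(40, amh_params(2, 1, 3, 1, 0), censor_pct = 15)
  st <- as.numeric(unclass(amh_params(2, 1, 3, 1, 0)))
  h <- amh_hyperparams()
  r1 <- sum(dat$status1)
  gshape <- h[["b11"]] + r1
  grate <- h[["b12"]] + sum(dat$time1^2)
  n_up <- 3000
  vals <- numeric(n_up)
  acc <- logical(n_up)
  p <- st
  for (i in seq_len(n_up)) {
    s <- update_beta(dat, p, 1)
    vals[i] <- s$value; acc[i] <- s$accepted
    p[2] <- s$value
  }
  expect_true(all(acc))                          # eta ratio identically 1
  gm <- gshape / grate
  gsd <- sqrt(gshape) / grate
  expect_lt(abs(mean(vals) - gm), 4 * gsd / sqrt(n_up))
  expect_lt(abs(sd(vals) - gsd) / gsd, 0.15)
})

test_that("each shape sampler targets the conditional posterior (quadrature oracle)", {
  set.seed(603)
  dat <- amh_simulate(40, amh_params(2, 1, 3, 1, 0))
  st <- amh_params(1.5, 1, 3, 1, 0)
  grid <- seq(0.02, 8, by = 0.002)
  lk <- amh_log_kappa(grid, 1, dat, st)
  w <- exp(lk - max(lk))
  qmean <- sum(grid * w) / sum(w)

  run1d <- function(method, nsteps, seed) {
    set.seed(seed)
    a <- 1.5
    out <- numeric(nsteps)
    p <- as.numeric(unclass(st))
    for (i in seq_len(nsteps)) {
      p[1] <- a
      a <- update_alpha(dat, p, 1, method)$value
      out[i] <- a
    }
    out
  }
  for (spec in list(list("rwm", 20000), list("slice", 20000), list("imh", 60000))) {
    x <- run1d(spec[[1]], spec[[2]], 7)
    mcse <- sd(x) * sqrt(max(mcmc_iat(x), 1) / length(x))
    expect_lt(abs(mean(x) - qmean), 3 * mcse)
  }
})

test_that("random-walk shape update never leaves the support", {
  set.seed(604)
  dat <- amh_simulate(15, "D1")
  p <- as.numeric(unclass(amh_params(0.05, 1, 3, 1, 0.5)))
  for (i in 1:300) {
    s <- update_alpha(dat, p, 1, "rwm", sigma2 = 25)  # proposals mostly negative
    expect_gt(s$value, 0)
    p[1] <- s$value
  }
})

test_that("slice sampler reproduces a known truncated-normal target", {
  set.seed(605)
  x <- amhsurv:::slice_chain_gauss_cpp(100000, 2, 2, 1, 0.05, TRUE)
  xt <- x[seq(1, length(x), by = 4)]
  Ftn <- function(q) (pnorm(q - 2) - pnorm(-2)) / (1 - pnorm(-2))
  D <- suppressWarnings(ks.test(xt, Ftn)$statistic)
  expect_lt(D, 1.63 / sqrt(length(xt)))          # 1% KS critical value

  # verbatim stepping mode carries only an O(lambda) edge effect
  set.seed(606)
  xp <- amhsurv:::slice_chain_gauss_cpp(40000, 2, 2, 1, 0.05, FALSE)
  mu_true <- 2 + dnorm(-2) / (1 - pnorm(-2))
  expect_lt(abs(mean(xp) - mu_true), 0.02)
})

test_that("grid sampler for phi is uniform under a flat likelihood", {
  set.seed(607)
  ph <- amhsurv:::grid_phi_chain_flat_cpp(200000, 0.05)
  pht <- ph[seq(1, length(ph), by = 400)]        # near-independent draws
  expected <- length(pht) / 20
  cnt <- table(cut(pht, breaks = seq(-1, 1, by = 0.1)))
  chi <- sum((cnt - expected)^2 / expected)
  expect_lt(chi, qchisq(0.99, df = 19))
  expect_true(all(ph > -1 & ph < 1))
})

test_that("grid sampler for phi matches deterministic 1-D posterior quadrature", {
  set.seed(608)
  d0 <- amh_simulate(100, amh_params(2, 1, 3, 1, 0))
  v <- amhsurv:::surv_vectors(d0)
  truthv <- c(2, 1, 3, 1, 0)
  set.seed(609)
  ph <- amhsurv:::grid_phi_chain_model_cpp(60000, v$t1, v$d1, v$t2, v$d2, truthv)
  grid <- seq(-0.9995, 0.9995, by = 0.001)
  ll <- vapply(grid, function(g) amh_loglik(d0, c(2, 1, 3, 1, g)), numeric(1))
  wts <- exp(ll - max(ll))
  post_mean <- sum(grid * wts) / sum(wts)
  mcse <- sd(ph) * sqrt(max(mcmc_iat(ph), 1) / length(ph))
  expect_lt(abs(mean(ph) - post_mean), 3 * mcse)
})

test_that("the three algorithms agree on shared data within Monte Carlo error", {
  set.seed(610)
  dat <- amh_simulate(100, "D1")
  f1 <- amh_fit(dat, "A1", control = amh_control(L = 150000, B = 10000, J = 10), seed = 11)
  f2 <- amh_fit(dat, "A2", control = amh_control(L = 20000, B = 2000, J = 5), seed = 12)
  f3 <- amh_fit(dat, "A3", control = amh_control(L = 20000, B = 2000, J = 5), seed = 13)
  mcse <- function(f) {
    vapply(c("alpha1", "beta1", "alpha2", "beta2", "phi"), function(tm) {
      x <- f$draws[[tm]]
      sd(x) * sqrt(max(mcmc_iat(x), 1) / length(x))
    }, numeric(1))
  }
  pairs <- list(list(f1, f2), list(f1, f3), list(f2, f3))
  for (pr in pairs) {
    z <- abs(pr[[1]]$estimates - pr[[2]]$estimates) /
      sqrt(mcse(pr[[1]])^2 + mcse(pr[[2]])^2)
    expect_lt(max(z), 3)
  }
  # the independence sampler pays for its vague proposal in acceptance rate
  expect_lt(f1$acceptance[["alpha1"]], f2$acceptance[["alpha1"]])
})

test_that("chains started at the truth of a large dataset stay put", {
  set.seed(611)
  dat <- amh_simulate(400, "D1")
  truth <- amh_design("D1")
  f <- amh_fit(dat, "A2", control = amh_control(L = 3000, B = 500, J = 5),
               init = truth, seed = 7)
  for (tm in c("alpha1", "beta1", "alpha2", "beta2", "phi")) {
    x <- f$draws[[tm]]
    expect_lt(abs(mean(x) - truth[[tm]]), 3 * sd(x))
  }
})

test_that("fit preconditions and configuration are validated", {
  all_cens <- tibble::tibble(time1 = c(1, 2), status1 = c(0, 0),
                             time2 = c(1, 2), status2 = c(0, 0))
  expect_error(amh_fit(all_cens, "A2"), "event")
  set.seed(612)
  dat <- amh_simulate(10, "D1")
  expect_error(amh_control(L = 100, B = 100), "B < L")
  expect_error(amh_control(L = 100, B = 95, J = 10), "kept")
  expect_error(amh_fit(dat, "A9"), "arg")
  expect_error(amh_fit(dat, "A2", control = list(L = 100)), "amh_control")
})

test_that("posterior summaries handle degenerate and uniform chains", {
  fake <- structure(list(
    draws = tibble::tibble(chain = 1, iter = 1:100,
                           alpha1 = 2, beta1 = 1, alpha2 = 3, beta2 = 1,
                           phi = 0.5),
    n_chains = 1
  ), class = "amh_fit")
  s <- suppressWarnings(posterior_summary(fake))
  expect_equal(s$estimate, c(2, 1, 3, 1, 0.5))
  expect_equal(s$conf.low, s$conf.high)

  fake$draws$alpha1 <- seq_len(100) / 100
  s2 <- suppressWarnings(posterior_summary(fake))
  expect_equal(s2$conf.low[1], quantile(fake$draws$alpha1, 0.025, names = FALSE))
})

test_that("multi-chain fits expose Gelman-Rubin diagnostics", {
  set.seed(613)
  dat <- amh_simulate(60, "D1")
  f <- amh_fit(dat, "A3", control = amh_control(L = 2200, B = 200, J = 5),
               n_chains = 2, seed = 9)
  expect_equal(sort(unique(f$draws$chain)), c(1, 2))
  dg <- diagnose(f)
  expect_true(all(is.finite(dg$psrf)))
  expect_true(all(dg$psrf < 1.2))
  gl <- glance(f)
  expect_equal(gl$n_chains, 2)
  expect_true(is.finite(gl$max_psrf))
})
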
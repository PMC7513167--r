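# shared oracles and fixtures, all generated in code

toy_mixed_data <- function() {
  tibble::tibble(
    time1 = c(1.0, 2.0, 0.8, 1.3),
    status1 = c(1, 0, 1, 0),
    time2 = c(0.5, 1.5, 2.1, 0.4),
    status2 = c(1, 0, 0, 1)
  )
}

# univariate right-censored Weibull log-likelihood (rate-type scale),
# closed form: sum delta [log(alpha beta) + (alpha-1) log t] - beta sum t^alpha
weibull_cens_loglik <- function(time, status, alpha, beta) {
  sum(status * (log(alpha) + log(beta) + (alpha - 1) * log(time))) -
    beta * sum(time^alpha)
}

# central mixed second finite difference of the joint survival function
fd_density <- function(t1, t2, params, h = 1e-4) {
  (amh_survival(t1 + h, t2 + h, params) - amh_survival(t1 + h, t2 - h, params) -
     amh_survival(t1 - h, t2 + h, params) + amh_survival(t1 - h, t2 - h, params)) /
    (4 * h^2)
}

fd_partial <- function(t1, t2, params, margin, h = 1e-6) {
  if (margin == 1) {
    -(amh_survival(t1 + h, t2, params) - amh_survival(t1 - h, t2, params)) / (2 * h)
  } else {
    -(amh_survival(t1, t2 + h, params) - amh_survival(t1, t2 - h, params)) / (2 * h)
  }
}

amh_copula <- function(u, v, phi) u * v / (1 - phi * (1 - u) * (1 - v))

# random valid parameter vectors for property loops
random_params <- function() {
  amh_params(runif(1, 0.3, 4), runif(1, 0.2, 3),
             runif(1, 0.3, 4), runif(1, 0.2, 3),
             runif(1, -1, 0.999))
}
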
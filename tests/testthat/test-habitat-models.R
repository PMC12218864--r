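# minimal prepared-data lists, bypassing the table layer
occ_data <- function(S = 3, J = 4, seed = 1, gp = FALSE) {
  set.seed(seed)
  y <- matrix(rbinom(S * J, 1, 0.4), S, J)
  list(
    X = cbind(opuntia = rnorm(S)),
    season = rep(1L, S), seasons = 1L,
    y = y, temp = matrix(rnorm(S * J), S, J),
    cam = rep(1L, S), n_cam = 1L,
    coords = if (gp) cbind(runif(S, 0, 1000), runif(S, 0, 1000)) else NULL,
    jitter = 1e-6, rho_scale = 1000
  )
}

test_that("log_posterior equals likelihood-plus-prior computed by hand", {
  data <- occ_data(S = 3, J = 4, seed = 2)
  spec <- model_spec("occupancy", gp = FALSE)
  params <- c(
    alpha_s1 = 0.3, beta_opuntia_s1 = 0.8,
    a0_cam = -0.2, a_cam1 = -0.5, gamma_temp = 0.25
  )
  psi <- plogis(0.3 + 0.8 * data$X[, 1])
  p <- plogis(-0.5 + 0.25 * data$temp)
  manual <- occupancy_loglik(data$y, psi, p) +
    dnorm(0.3, 0, 1.5, log = TRUE) + dnorm(0.8, 0, 1, log = TRUE) +
    dnorm(-0.2, 0, 1.5, log = TRUE) + dnorm(-0.5, -0.2, 1, log = TRUE) +
    dnorm(0.25, 0, 1, log = TRUE)
  expect_equal(log_posterior(spec, params, data), manual, tolerance = 1e-10)
})

test_that("with no observed data the posterior reduces to the prior", {
  data <- occ_data(S = 2, J = 3, seed = 3)
  data$y[] <- NA # cameras never active
  spec <- model_spec("occupancy", gp = FALSE)
  params <- c(
    alpha_s1 = -0.4, beta_opuntia_s1 = 1.1,
    a0_cam = 0.2, a_cam1 = 0.9, gamma_temp = -0.3
  )
  prior <- dnorm(-0.4, 0, 1.5, log = TRUE) + dnorm(1.1, 0, 1, log = TRUE) +
    dnorm(0.2, 0, 1.5, log = TRUE) + dnorm(0.9, 0.2, 1, log = TRUE) +
    dnorm(-0.3, 0, 1, log = TRUE)
  expect_equal(log_posterior(spec, params, data), prior, tolerance = 1e-10)
})

test_that("duplicating a site doubles its likelihood contribution", {
  set.seed(4)
  base <- list(
    X = cbind(opuntia = 0.7), season = 1L, seasons = 1L,
    y = matrix(c(2L, 0L, 3L), 1, 3), jitter = 1e-6
  )
  dup <- list(
    X = cbind(opuntia = c(0.7, 0.7)), season = c(1L, 1L), seasons = 1L,
    y = matrix(rep(c(2L, 0L, 3L), each = 2), 2, 3), jitter = 1e-6
  )
  spec <- model_spec("count", gp = FALSE)
  params <- c(alpha_s1 = -0.5, beta_opuntia_s1 = 0.4, log_phi = 0.1)
  prior <- dnorm(-0.5, 0, 1.5, TRUE) + dnorm(0.4, 0, 1, TRUE) + dnorm(0.1, 0, 1.5, TRUE)
  ll1 <- log_posterior(spec, params, base) - prior
  ll2 <- log_posterior(spec, params, dup) - prior
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("log-posterior stays finite at extreme logits", {
  data <- occ_data(S = 4, J = 5, seed = 5)
  spec <- model_spec("occupancy", gp = FALSE)
  for (sgn in c(-1, 1)) {
    params <- c(
      alpha_s1 = sgn * 35, beta_opuntia_s1 = 0,
      a0_cam = 0, a_cam1 = sgn * 35, gamma_temp = 0
    )
    lp <- log_posterior(spec, params, data)
    expect_false(is.nan(lp))
    # -Inf only allowed when the data are impossible under the parameters;
    # here some detections exist, so psi -> 0 legitimately gives -Inf
    if (sgn > 0) expect_true(is.finite(lp))
  }
})

test_that("the sampler's fast occupancy path matches occupancy_loglik", {
  data <- occ_data(S = 6, J = 8, seed = 6, gp = TRUE)
  data$y[2, 3] <- NA
  spec <- model_spec("occupancy", gp = TRUE)
  model <- opuntiacam:::build_habitat_model(spec, data)
  set.seed(7)
  for (i in 1:10) {
    par <- setNames(rnorm(length(model$par_names), 0, 0.8), model$par_names)
    # reproduce psi and p by hand
    eta <- exp(par["log_eta"])
    rho <- exp(par["log_rho"])
    L <- t(chol(gp_covariance(data$coords, eta, rho, data$jitter)))
    f <- drop(L %*% par[paste0("u", 1:6)])
    psi <- plogis(par["alpha_s1"] + par["beta_opuntia_s1"] * data$X[, 1] + f)
    p <- plogis(par["a_cam1"] + par["gamma_temp"] * data$temp)
    expect_equal(model$loglik(par), occupancy_loglik(data$y, psi, p),
      tolerance = 1e-10
    )
  }
})

test_that("missing parameters and dimension problems are named", {
  data <- occ_data()
  spec <- model_spec("occupancy", gp = FALSE)
  expect_error(
    log_posterior(spec, c(alpha_s1 = 0), data),
    "missing parameter"
  )
})

test_that("posterior sampling is seed-reproducible end to end", {
  data <- occ_data(S = 5, J = 6, seed = 8)
  spec <- model_spec("occupancy", gp = FALSE)
  a <- suppressWarnings(sample_posterior(spec, data, chains = 2, warmup = 100, iters = 80, seed = 5))
  b <- suppressWarnings(sample_posterior(spec, data, chains = 2, warmup = 100, iters = 80, seed = 5))
  expect_identical(a$draws, b$draws)
})

test_that("negative-binomial posterior agrees with an independent JAGS fit", {
  skip_if_not_installed("rjags")
  set.seed(9)
  S <- 30
  J <- 10
  x <- rnorm(S)
  mu <- exp(-0.5 + 0.6 * x)
  y <- matrix(rnbinom(S * J, size = 1.2, mu = rep(mu, J)), S, J)
  data <- list(
    X = cbind(opuntia = x), season = rep(1L, S), seasons = 1L,
    y = y, jitter = 1e-6
  )
  spec <- model_spec("count", gp = FALSE)
  ours <- suppressWarnings( # borderline Rhat on the intercept is immaterial here
    sample_posterior(spec, data, chains = 2, warmup = 1500, iters = 2500, seed = 10)
  )
  m <- pool_draws(ours)

  jm <- rjags::jags.model(
    textConnection("
      model {
        for (i in 1:S) { for (j in 1:J) {
          y[i,j] ~ dnegbin(pr[i], phi)
        }}
        for (i in 1:S) {
          pr[i] <- phi / (phi + mu[i])
          log(mu[i]) <- alpha + beta * x[i]
        }
        alpha ~ dnorm(0, 1 / 2.25)
        beta ~ dnorm(0, 1)
        lphi ~ dnorm(0, 1 / 2.25)
        phi <- exp(lphi)
      }"),
    data = list(S = S, J = J, y = y, x = x), n.chains = 2, quiet = TRUE,
    inits = list(
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
      list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 2)
    )
  )
  update(jm, 1500)
  js <- rjags::coda.samples(jm, c("alpha", "beta", "lphi"), n.iter = 2500)
  jmat <- as.matrix(js)
  expect_lt(abs(mean(m[, "beta_opuntia_s1"]) - mean(jmat[, "beta"])), 0.05)
  expect_lt(abs(mean(m[, "alpha_s1"]) - mean(jmat[, "alpha"])), 0.05)
  expect_lt(abs(sd(m[, "beta_opuntia_s1"]) - sd(jmat[, "beta"])), 0.03)
})

test_that("table preparation drops unsampled squares and keeps lunar raw", {
  st <- tiny_study(seed = 22, n_squares = 5, days = 8)
  sites <- st$sites
  sites$square_opuntia_vol_m3_per_m[1:2] <- NA # one unsampled square
  obs <- st$observations[st$observations$species == "impala", ]
  spec <- model_spec("night", exposure_scale = "square", gp = FALSE)
  expect_message(
    data <- prepare_habitat_data(spec, obs, sites),
    "unsampled"
  )
  expect_equal(length(data$site_ids), 8)
  # standardized design matrix, raw lunar fractions
  expect_lt(max(abs(colMeans(data$X))), 1e-10)
  expect_true(all(data$lunar >= 0 & data$lunar <= 1, na.rm = TRUE))
  sc <- attr(data, "scaling")
  expect_false("lunar_frac" %in% sc$variable)
})

test_that("non-convergence raises a classed warning", {
  data <- occ_data(S = 4, J = 5, seed = 11)
  spec <- model_spec("occupancy", gp = FALSE)
  # no warmup, huge initial spread: split chains cannot agree
  expect_warning(
    sample_posterior(spec, data, chains = 2, warmup = 0, iters = 30, seed = 12),
    class = "opuntiacam_convergence"
  )
})
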
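## The package's MCMC engine.
##
## Posteriors are sampled by blocked MCMC: fixed-effect blocks move by
## adaptive multivariate random-walk Metropolis (empirical proposal
## covariance scaled by 2.38^2/d, adapted during warmup only, so the
## post-warmup kernel is fixed and valid), and Gaussian-process coefficient
## blocks move by elliptical slice sampling, which is rejection-free and
## tuning-free for parameters with a standard-normal prior (the non-centred
## GP field). Chains are independent and reproducible given a seed.
##
## A model is a plain list:
##   par_names  character vector naming the flat parameter vector
##   blocks     list of list(type = "rw" | "ess", idx = <positions>)
##   init       function() -> numeric start values (uses the chain RNG)
##   loglik     function(par) -> scalar log-likelihood
##   logprior   function(par) -> log prior density of all parameters EXCEPT
##              "ess" blocks, whose standard-normal prior is implicit in the
##              elliptical slice update.

# one elliptical slice update of u (prior N(0, I)) against loglik_fn
ess_update <- function(u, loglik_fn, ll_cur) {
  nu <- rnorm(length(u))
  log_y <- ll_cur + log(runif(1))
  theta <- runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  repeat {
    prop <- u * cos(theta) + nu * sin(theta)
    ll <- loglik_fn(prop)
    if (is.finite(ll) && ll > log_y) {
      return(list(u = prop, ll = ll))
    }
    if (theta < 0) lo <- theta else hi <- theta
    if (hi - lo < 1e-12) {
      return(list(u = u, ll = ll_cur)) # bracket collapsed; keep state
    }
    theta <- runif(1, lo, hi)
  }
}

run_mcmc_chain <- function(model, warmup, iters, chain_seed) {
  set.seed(chain_seed)
  par <- model$init()
  P <- length(par)
  stopifnot(P == length(model$par_names))
  ll <- model$loglik(par)
  lp <- model$logprior(par)
  tries <- 0
  while (!is.finite(ll + lp) && tries < 50) {
    par <- model$init()
    ll <- model$loglik(par)
    lp <- model$logprior(par)
    tries <- tries + 1
  }
  if (!is.finite(ll + lp)) stopf("could not find a finite starting point")

  blocks <- model$blocks
  nb <- length(blocks)
  # adaptive RW state per block
  rw <- lapply(blocks, function(b) {
    d <- length(b$idx)
    list(
      d = d, S = diag(0.1, d), mu = par[b$idx],
      covm = diag(d), n = 0L, acc = 0L, tot = 0L
    )
  })
  out <- matrix(NA_real_, iters, P, dimnames = list(NULL, model$par_names))
  total <- warmup + iters
  for (it in seq_len(total)) {
    for (k in seq_len(nb)) {
      b <- blocks[[k]]
      if (b$type == "ess") {
        # two slice updates per iteration: slice moves are cheap relative to
        # the random-walk blocks and the field's mixing feeds every other
        # parameter's effective sample size
        for (sweep in 1:2) {
          res <- ess_update(
            par[b$idx],
            function(u) {
              p2 <- par
              p2[b$idx] <- u
              model$loglik(p2)
            },
            ll
          )
          par[b$idx] <- res$u
          ll <- res$ll
        }
      } else {
        # higher-dimensional blocks get several sweeps per iteration: each
        # costs one likelihood evaluation and roughly offsets the slower
        # random-walk mixing as dimension grows
        for (sweep in seq_len(max(1L, ceiling(length(b$idx) / 3)))) {
          st <- rw[[k]]
          prop <- par
          prop[b$idx] <- par[b$idx] + drop(st$S %*% rnorm(st$d))
          llp <- model$loglik(prop)
          lpp <- model$logprior(prop)
          rw[[k]]$tot <- st$tot + 1L
          if (is.finite(llp + lpp) &&
            log(runif(1)) < (llp + lpp) - (ll + lp)) {
            par <- prop
            ll <- llp
            lp <- lpp
            rw[[k]]$acc <- st$acc + 1L
          }
          if (it <= warmup) { # adapt empirical covariance during warmup only
            st <- rw[[k]]
            st$n <- st$n + 1L
            dlt <- par[b$idx] - st$mu
            st$mu <- st$mu + dlt / st$n
            st$covm <- st$covm + (tcrossprod(dlt) * (st$n - 1) / st$n - st$covm) / st$n
            if (st$n > 50L) {
              st$S <- t(chol(2.38^2 / st$d * st$covm + 1e-8 * diag(st$d)))
            }
            rw[[k]] <- st
          }
        }
      }
    }
    if (it > warmup) out[it - warmup, ] <- par
  }
  acc <- vapply(seq_len(nb), function(k) {
    if (blocks[[k]]$type == "ess") NA_real_ else rw[[k]]$acc / max(1L, rw[[k]]$tot)
  }, 0)
  list(draws = out, acceptance = acc)
}

#' Run the package MCMC engine
#'
#' Low-level interface used by [sample_posterior()] and
#' [fit_distance_model()]; see the package vignette for the sampler design.
#'
#' @param model a model list (see `R/mcmc.R` for the interface contract).
#' @param chains number of chains (>= 2 recommended for diagnostics).
#' @param warmup,iters warmup and retained iterations per chain.
#' @param seed integer seed; chains get independent derived seeds.
#' @return A `posterior_draws` object: draws array `(chain, iteration,
#'   parameter)`, sampler metadata and per-block acceptance rates.
#' @export
run_mcmc <- function(model, chains = 4, warmup = 1000, iters = 1000, seed = 1) {
  check_number(chains, "chains", lower = 1)
  check_number(iters, "iters", lower = 1)
  check_number(warmup, "warmup", lower = 0)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max %/% 2, chains)
  res <- lapply(chain_seeds, function(cs) run_mcmc_chain(model, warmup, iters, cs))
  P <- length(model$par_names)
  draws <- array(
    NA_real_,
    dim = c(chains, iters, P),
    dimnames = list(NULL, NULL, model$par_names)
  )
  for (c in seq_len(chains)) draws[c, , ] <- res[[c]]$draws
  acc <- do.call(rbind, lapply(res, `[[`, "acceptance"))
  structure(
    list(
      draws = draws, warmup = warmup, iters = iters, seed = seed,
      acceptance = acc, par_names = model$par_names
    ),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "<posterior_draws: %d chains x %d iterations x %d parameters (warmup %d, seed %d)>\n",
    d[1], d[2], d[3], x$warmup, x$seed
  ))
  cat(
    "parameters:",
    paste(head(x$par_names, 8), collapse = ", "),
    if (d[3] > 8) sprintf("... (%d more)", d[3] - 8) else "", "\n"
  )
  invisible(x)
}

#' Pool posterior draws across chains
#'
#' @param x a `posterior_draws` object.
#' @return A matrix `(chains * iterations) x parameters`.
#' @export
pool_draws <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(m) <- x$par_names
  m
}

#' Tidy posterior draws
#'
#' @param x a `posterior_draws`.
#' @param ... unused.
#' @return Tibble with posterior mean, sd, central 90% interval,
#'   rank-normalized split-Rhat and bulk ESS per parameter.
#' @export
tidy.posterior_draws <- function(x, ...) {
  m <- pool_draws(x)
  tibble::tibble(
    parameter = x$par_names,
    estimate = colMeans(m),
    std.error = apply(m, 2, sd),
    q5 = apply(m, 2, quantile, 0.05),
    q95 = apply(m, 2, quantile, 0.95),
    rhat = split_rhat(x),
    ess_bulk = ess_bulk(x)
  )
}

## ---- convergence diagnostics (rank-normalized split-Rhat / bulk ESS) ----

# x: iterations x chains matrix for one parameter
.split_chains <- function(x) {
  n <- nrow(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE], x[(n - h + 1L):n, , drop = FALSE])
}

.rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

.rhat_basic <- function(x) { # x: iters x chains
  n <- nrow(x)
  m <- ncol(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, var)
  W <- mean(s2)
  B <- n * var(mu)
  if (!is.finite(W)) return(NA_real_)
  if (W == 0) return(if (B > 0) Inf else NA_real_) # stuck, disagreeing chains
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_basic <- function(x) { # x: iters x chains, Geyer initial monotone
  n <- nrow(x)
  m <- ncol(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, var)
  W <- mean(s2)
  var_plus <- (n - 1) / n * W + var(mu)
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  # mean within-chain autocovariance per lag
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = n - 1L, type = "covariance", plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 0
  t <- 1L
  last <- Inf
  max_t <- length(rho) - 1L
  while (t + 1L <= max_t) {
    pair <- rho[t + 1L] + if (t + 2L <= length(rho)) rho[t + 2L] else 0
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, last)
    last <- pair
    tau <- tau + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n * log10(m * n)) # cap, as per the rank-normalized recipe
}

.per_parameter <- function(x, fn) {
  if (inherits(x, "posterior_draws")) {
    arr <- x$draws
  } else if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x
  } else if (is.matrix(x)) { # iterations x chains, single parameter
    arr <- array(t(x), dim = c(ncol(x), nrow(x), 1L), dimnames = list(NULL, NULL, "par"))
  } else {
    stopf("expected a posterior_draws object, a 3-d array or an iterations x chains matrix")
  }
  if (dim(arr)[1] < 2L) stopf("at least 2 chains are required for diagnostics")
  if (dim(arr)[2] < 4L) stopf("at least 4 draws per chain are required")
  out <- vapply(seq_len(dim(arr)[3]), function(p) {
    m <- t(arr[, , p, drop = TRUE]) # iters x chains
    if (dim(arr)[1] == 1L) m <- matrix(arr[1, , p], ncol = 1)
    sp <- .split_chains(m)
    if (all(!is.finite(sp)) || max(sp) - min(sp) == 0) return(NA_real_)
    fn(.rank_normalize(sp))
  }, 0)
  names(out) <- dimnames(arr)[[3]]
  out
}

#' Rank-normalized split-Rhat
#'
#' Chains are split in half, draws are replaced by their normal scores
#' (rank-normalization), and the classic potential-scale-reduction factor is
#' computed on the result. Values near 1 indicate mixing; constant chains
#' yield `NA` (diagnostic undefined).
#'
#' @param x a `posterior_draws`, a `(chain, iteration, parameter)` array, or
#'   an iterations-by-chains matrix for a single parameter.
#' @return Named numeric vector of Rhat values per parameter.
#' @export
split_rhat <- function(x) .per_parameter(x, .rhat_basic)

#' Bulk effective sample size
#'
#' Rank-normalized split-chain ESS using Geyer's initial monotone positive
#' sequence estimator of the autocorrelation time.
#'
#' @inheritParams split_rhat
#' @return Named numeric vector of ESS values per parameter.
#' @export
ess_bulk <- function(x) .per_parameter(x, .ess_basic)
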
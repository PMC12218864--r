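## Model likelihoods.
##
## Three observation models share the linear-predictor machinery: a
## single-season site-occupancy model with the latent occupancy state
## marginalized out, an NB2 negative-binomial model for daily detection
## counts, and a binomial model for the proportion of detections at night.

#' Standardize covariate columns
#'
#' Centres and scales (sample sd, `n - 1`) every numeric column except those
#' in `exclude`, recording the transformation so effect curves can be mapped
#' back to raw units. Lunar illumination is conventionally excluded (it is
#' already a 0-1 fraction).
#'
#' @param data a data frame.
#' @param exclude character vector of column names to leave untouched
#'   (non-numeric columns are always left untouched).
#' @return The data frame with standardized columns and an attribute
#'   `"scaling"`: a tibble `(variable, mean, sd)`. Retrieve it with
#'   `attr(x, "scaling")`.
#' @export
#' @examples
#' standardize_covariates(data.frame(a = 1:3, lunar = c(.1, .5, .9)), exclude = "lunar")
standardize_covariates <- function(data, exclude = "lunar_frac") {
  num <- names(data)[vapply(data, is.numeric, TRUE)]
  cols <- setdiff(num, exclude)
  scaling <- tibble::tibble(
    variable = cols,
    mean = vapply(cols, function(v) mean(data[[v]]), 0, USE.NAMES = FALSE),
    sd = vapply(cols, function(v) sd(data[[v]]), 0, USE.NAMES = FALSE)
  )
  zero <- scaling$variable[scaling$sd == 0 | !is.finite(scaling$sd)]
  if (length(zero)) {
    stopf("zero-variance column(s): %s", paste(zero, collapse = ", "))
  }
  for (v in cols) data[[v]] <- (data[[v]] - scaling$mean[scaling$variable == v]) /
      scaling$sd[scaling$variable == v]
  attr(data, "scaling") <- scaling
  data
}

#' Gaussian-process covariance matrix
#'
#' Exponentiated-quadratic kernel on planar coordinates:
#' `K_ij = eta^2 exp(-d_ij^2 / (2 rho^2))`, plus `jitter` on the diagonal so
#' the Cholesky factorization succeeds.
#'
#' @param coords numeric matrix `n x 2` of easting/northing in metres.
#' @param eta marginal standard deviation (>= 0).
#' @param rho length scale in metres (> 0).
#' @param jitter diagonal stabilizer (default `1e-6`).
#' @return Symmetric positive-definite `n x n` matrix.
#' @export
gp_covariance <- function(coords, eta, rho, jitter = 1e-6) {
  coords <- as.matrix(coords)
  if (anyNA(coords) || any(!is.finite(coords))) stopf("non-finite coordinates")
  check_number(eta, "eta", lower = 0)
  check_number(rho, "rho", lower = 0, strict_lower = TRUE)
  d2 <- unname(as.matrix(dist(coords))^2)
  K <- eta^2 * exp(-d2 / (2 * rho^2))
  diag(K) <- diag(K) + jitter
  K
}

# lower Cholesky of the GP covariance, with an explicit diagnostic if the
# jittered matrix is still not positive definite
gp_cholesky <- function(coords, eta, rho, jitter = 1e-6) {
  K <- gp_covariance(coords, eta, rho, jitter)
  L <- tryCatch(t(chol(K)), error = function(e) {
    stopf(
      "GP covariance not positive definite after jitter %g (eta=%g, rho=%g); %s",
      jitter, eta, rho, conditionMessage(e)
    )
  })
  L
}

#' Marginalized occupancy log-likelihood
#'
#' Single-season site-occupancy likelihood with the latent occupancy state
#' summed out. For a site with at least one detection the contribution is
#' `log(psi) + sum_j log Bern(y_j | p_j)`; for an all-zero history it is
#' `log(psi * prod_j (1 - p_j) + (1 - psi))`, evaluated with log-sum-exp.
#' `NA` entries of `y` mark camera-inactive days and are skipped.
#'
#' @param y detection matrix, sites x days, values 0/1/`NA`.
#' @param psi per-site occupancy probabilities in (0, 1).
#' @param p detection probabilities: a sites-x-days matrix or a per-site
#'   vector (recycled across days). Must be non-`NA` wherever `y` is
#'   observed.
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' occupancy_loglik(matrix(1), psi = 0.6, p = matrix(0.3)) # log(0.6 * 0.3)
occupancy_loglik <- function(y, psi, p) {
  y <- as.matrix(y)
  S <- nrow(y)
  if (length(psi) != S) stopf("`psi` must have one entry per site (row of `y`)")
  check_number(psi, "psi", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  if (is.null(dim(p))) p <- matrix(p, S, ncol(y))
  if (!all(dim(p) == dim(y))) stopf("`p` must match the dimensions of `y`")
  obs <- !is.na(y)
  if (any(obs & is.na(p))) stopf("observed detection on a day with missing detection probability")
  if (any(p[obs] <= 0 | p[obs] >= 1)) stopf("`p` must lie strictly in (0, 1) on observed days")
  lp1 <- matrix(0, S, ncol(y))
  lp0 <- matrix(0, S, ncol(y))
  lp1[obs] <- ifelse(y[obs] == 1, log(p[obs]), log1p(-p[obs]))
  lp0[obs] <- log1p(-p[obs])
  detected <- rowSums(y == 1, na.rm = TRUE) > 0
  l_hist <- rowSums(lp1) # log P(history | z = 1)
  l_zero <- rowSums(lp0) # log P(all-zero history | z = 1)
  out <- numeric(S)
  out[detected] <- log(psi[detected]) + l_hist[detected]
  nd <- !detected
  out[nd] <- log_sum_exp2(log(psi[nd]) + l_zero[nd], log1p(-psi[nd]))
  sum(out)
}

#' NB2 negative-binomial log-likelihood
#'
#' Mean `mu`, dispersion `phi` (variance `mu + mu^2/phi`); the Poisson is
#' recovered as `phi -> Inf`. Evaluated through the gamma-function form of
#' the pmf.
#'
#' @param counts non-negative integer counts (`NA` allowed, skipped).
#' @param mu positive means (scalar or per observation).
#' @param phi positive dispersion.
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' nb_loglik(0, mu = 1, phi = 1) # log(1/2)
nb_loglik <- function(counts, mu, phi) {
  ok <- !is.na(counts)
  counts <- counts[ok]
  if (length(mu) > 1) mu <- mu[ok]
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("`counts` must be non-negative integers")
  }
  check_number(mu, "mu", lower = 0, strict_lower = TRUE)
  check_number(phi, "phi", lower = 0, strict_lower = TRUE)
  sum(dnbinom(counts, size = phi, mu = mu, log = TRUE))
}

#' Binomial night-activity log-likelihood
#'
#' `k ~ Binomial(n, plogis(linear_predictor))` per site-day; rows with
#' `n = 0` contribute exactly zero. `NA` pairs are skipped.
#'
#' @param k night detection counts.
#' @param n total detection counts (`k <= n`).
#' @param linear_predictor logit-scale predictor, same length.
#' @return Scalar log-likelihood.
#' @export
#' @examples
#' night_loglik(2, 5, 0) # log(choose(5,2) / 32)
night_loglik <- function(k, n, linear_predictor) {
  ok <- !is.na(k) & !is.na(n)
  k <- k[ok]
  n <- n[ok]
  if (length(linear_predictor) > 1) linear_predictor <- linear_predictor[ok]
  if (any(k < 0) || any(n < 0)) stopf("counts must be non-negative")
  if (any(k > n)) stopf("night counts exceed totals (k > n)")
  pr <- plogis(clamp_logit(linear_predictor))
  sum(dbinom(k, n, pr, log = TRUE))
}
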
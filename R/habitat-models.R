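## Bayesian habitat-use models.
##
## Three models share one machinery: a marginalized site-occupancy model
## (daily detection/non-detection, camera-model intercepts and daily mean
## temperature in the detection sub-model), an NB2 negative-binomial model
## for total daily detections, and a binomial model for the proportion of
## detections at night (with an Opuntia x lunar-illumination interaction).
## Every model carries season-specific intercepts and slopes and an optional
## Gaussian-process spatial random effect (non-centred), and is sampled by
## the package MCMC engine ([run_mcmc()]).

#' Describe a habitat-use model
#'
#' @param response one of `"occupancy"`, `"count"`, `"night"`.
#' @param exposure_scale `"site"` (site-level Opuntia percent cover) or
#'   `"square"` (grid-square Opuntia volume per metre of transect).
#' @param covariates adjustment covariates (columns of the site table);
#'   default is the back-door set selected on [habitat_dag()].
#' @param native_plants also adjust for the native plant community (grass,
#'   shrub, forb, succulent cover and tree count): the "direct effect"
#'   variant.
#' @param gp include the spatial Gaussian process.
#' @param lunar_interaction include lunar illumination and its interaction
#'   with Opuntia (night model only).
#' @return A `model_spec` list.
#' @export
model_spec <- function(response = c("occupancy", "count", "night"),
                       exposure_scale = c("site", "square"),
                       covariates = c("livestock_prop", "dist_river_m", "dist_road_m"),
                       native_plants = FALSE,
                       gp = TRUE,
                       lunar_interaction = TRUE) {
  response <- match.arg(response)
  exposure_scale <- match.arg(exposure_scale)
  check_flag(native_plants, "native_plants")
  check_flag(gp, "gp")
  if (native_plants) {
    covariates <- union(covariates, c(
      "grass_pct", "shrub_pct", "forb_pct", "succulent_pct", "tree_count"
    ))
  }
  structure(
    list(
      response = response, exposure_scale = exposure_scale,
      covariates = covariates, native_plants = native_plants,
      gp = gp, lunar_interaction = lunar_interaction
    ),
    class = "model_spec"
  )
}

# default warmup lengths by response
default_warmup <- function(response) if (response == "count") 7000 else 4000

## ---- internal: model construction over prepared data ----
##
## `data` is a list with (depending on response):
##   X        sites x covariates matrix, standardized, first column "opuntia"
##   season   integer season index per site (1-based into `seasons`)
##   seasons  sorted unique season labels
##   coords   sites x 2 matrix (m), if gp
##   y        detection matrix (occupancy), counts (count), or k/n (night)
##   temp     sites x days standardized temperature (occupancy)
##   cam      integer camera-model index per site (occupancy)
##   n_cam    number of camera models
##   lunar    sites x days lunar fraction (night)
##   jitter   GP jitter (default 1e-6)

build_habitat_model <- function(spec, data) {
  X <- as.matrix(data$X)
  S <- nrow(X)
  n_season <- length(data$seasons)
  season <- data$season
  covs <- colnames(X)
  jitter <- data$jitter %||% 1e-6

  nm_alpha <- paste0("alpha_s", data$seasons)
  nm_beta <- as.vector(outer(covs, data$seasons, function(c, s) paste0("beta_", c, "_s", s)))
  nms <- c(nm_alpha, nm_beta)
  if (spec$response == "occupancy") {
    nms <- c(nms, "a0_cam", paste0("a_cam", seq_len(data$n_cam)), "gamma_temp")
  }
  if (spec$response == "count") nms <- c(nms, "log_phi")
  if (spec$response == "night" && spec$lunar_interaction) {
    nms <- c(nms, "beta_lunar", "beta_opuntia_x_lunar")
  }
  n_fixed <- length(nms)
  if (spec$gp) nms <- c(nms, paste0("u", seq_len(S)), "log_eta", "log_rho")

  ix <- function(x) match(x, nms)
  i_alpha <- ix(nm_alpha)
  i_beta <- matrix(ix(nm_beta), ncol = n_season) # covariate x season
  i_u <- if (spec$gp) ix(paste0("u", seq_len(S))) else integer()
  i_hyp <- if (spec$gp) ix(c("log_eta", "log_rho")) else integer()

  # season-expanded linear predictor for the state model
  state_linpred <- function(par, f) {
    eta <- par[i_alpha][season] + f
    for (s in seq_len(n_season)) {
      in_s <- season == s
      if (any(in_s)) eta[in_s] <- eta[in_s] + X[in_s, , drop = FALSE] %*% par[i_beta[, s]]
    }
    eta
  }

  chol_cache <- new.env(parent = emptyenv())
  d2 <- if (spec$gp) as.matrix(dist(data$coords))^2 else NULL
  gp_field <- function(par) {
    if (!spec$gp) return(rep(0, S))
    eta <- exp(par[i_hyp[1]])
    rho <- exp(par[i_hyp[2]])
    key <- c(eta, rho)
    if (is.null(chol_cache$key) || !identical(chol_cache$key, key)) {
      K <- eta^2 * exp(-d2 / (2 * rho^2))
      diag(K) <- diag(K) + jitter
      chol_cache$L <- tryCatch(t(chol(K)), error = function(e) {
        stopf(
          "GP covariance not positive definite after jitter %g (eta=%g, rho=%g)",
          jitter, eta, rho
        )
      })
      chol_cache$key <- key
    }
    drop(chol_cache$L %*% par[i_u])
  }

  loglik <- switch(spec$response,
    occupancy = {
      i_acam <- ix(paste0("a_cam", seq_len(data$n_cam)))
      i_gT <- ix("gamma_temp")
      # precomputed masks make the per-evaluation cost a handful of
      # vectorized ops; this is algebraically the same marginalized
      # likelihood as occupancy_loglik() (equality is tested)
      obs <- !is.na(data$y)
      y1 <- !is.na(data$y) & data$y == 1
      y0 <- obs & !y1
      detected <- rowSums(y1) > 0
      # log sigmoid, stable in both tails: min(x,0) - log1p(exp(-|x|))
      log_sigmoid <- function(x) pmin(x, 0) - log1p(exp(-abs(x)))
      # detection terms depend only on (a_cam, gamma_temp): cache them so
      # the frequent GP-field updates skip the site-by-day matrix work
      det_cache <- new.env(parent = emptyenv())
      det_terms <- function(par) {
        key <- par[c(i_acam, i_gT)]
        if (is.null(det_cache$key) || !identical(det_cache$key, key)) {
          lp <- par[i_acam][data$cam] + par[i_gT] * data$temp
          l1p <- log1p(exp(-abs(lp)))
          log_p <- pmin(lp, 0) - l1p
          log_1mp <- pmin(-lp, 0) - l1p
          det_cache$l_hist <- rowSums(log_p * y1) + rowSums(log_1mp * y0)
          det_cache$l_zero <- rowSums(log_1mp * obs)
          det_cache$key <- key
        }
        det_cache
      }
      function(par) {
        lin <- state_linpred(par, gp_field(par))
        dt <- det_terms(par)
        log_psi <- log_sigmoid(lin)
        log_1mpsi <- log_sigmoid(-lin)
        sum(log_psi[detected] + dt$l_hist[detected]) +
          sum(log_sum_exp2(
            log_psi[!detected] + dt$l_zero[!detected],
            log_1mpsi[!detected]
          ))
      }
    },
    count = {
      i_phi <- ix("log_phi")
      function(par) {
        mu_site <- exp(pmin(state_linpred(par, gp_field(par)), 30))
        mu <- matrix(mu_site, S, ncol(data$y))
        nb_loglik(as.vector(data$y), as.vector(mu), exp(par[i_phi]))
      }
    },
    night = {
      i_bl <- if (spec$lunar_interaction) ix("beta_lunar") else integer()
      i_bol <- if (spec$lunar_interaction) ix("beta_opuntia_x_lunar") else integer()
      function(par) {
        eta_site <- state_linpred(par, gp_field(par))
        lp <- matrix(eta_site, S, ncol(data$n))
        if (spec$lunar_interaction) {
          lp <- lp + par[i_bl] * data$lunar +
            par[i_bol] * (X[, "opuntia"] * data$lunar)
        }
        night_loglik(as.vector(data$k), as.vector(data$n), as.vector(lp))
      }
    }
  )

  logprior <- function(par) {
    lp <- sum(dnorm(par[i_alpha], 0, 1.5, log = TRUE)) +
      sum(dnorm(par[i_beta], 0, 1, log = TRUE))
    if (spec$response == "occupancy") {
      a0 <- par[ix("a0_cam")]
      lp <- lp + dnorm(a0, 0, 1.5, log = TRUE) +
        sum(dnorm(par[ix(paste0("a_cam", seq_len(data$n_cam)))], a0, 1, log = TRUE)) +
        dnorm(par[ix("gamma_temp")], 0, 1, log = TRUE)
    }
    if (spec$response == "count") {
      lp <- lp + dnorm(par[ix("log_phi")], 0, 1.5, log = TRUE)
    }
    if (spec$response == "night" && spec$lunar_interaction) {
      lp <- lp + dnorm(par[ix("beta_lunar")], 0, 1, log = TRUE) +
        dnorm(par[ix("beta_opuntia_x_lunar")], 0, 1, log = TRUE)
    }
    if (spec$gp) {
      # eta ~ half-N(1), rho ~ half-N(half the study extent); log-scale jacobian
      eta <- exp(par[i_hyp[1]])
      rho <- exp(par[i_hyp[2]])
      rho_scale <- data$rho_scale %||% (max(dist(data$coords)) / 2)
      lp <- lp + dnorm(eta, 0, 1, log = TRUE) + log(2) + par[i_hyp[1]] +
        dnorm(rho, 0, rho_scale, log = TRUE) + log(2) + par[i_hyp[2]]
    }
    lp
  }

  blocks <- list(list(type = "rw", idx = seq_len(n_fixed)))
  if (spec$gp) {
    blocks <- c(blocks, list(
      list(type = "ess", idx = i_u),
      list(type = "rw", idx = i_hyp)
    ))
  }

  init <- function() {
    par <- setNames(numeric(length(nms)), nms)
    par[seq_len(n_fixed)] <- rnorm(n_fixed, 0, 0.3)
    if (spec$response == "count") par[ix("log_phi")] <- rnorm(1, 0, 0.3)
    if (spec$gp) {
      par[i_u] <- rnorm(S)
      par[i_hyp] <- c(log(0.5), log(stats::quantile(dist(data$coords), 0.25)))
    }
    par
  }

  list(
    par_names = nms, blocks = blocks, init = init,
    loglik = loglik, logprior = logprior,
    n_fixed = n_fixed, i_u = i_u
  )
}

#' Joint log-posterior density
#'
#' Log-likelihood plus log-priors for a habitat model, at a named parameter
#' vector (or list). Priors: intercepts Normal(0, 1.5); slopes Normal(0, 1);
#' camera intercepts hierarchical Normal(a0, 1) with a0 ~ Normal(0, 1.5);
#' dispersion via log(phi) ~ Normal(0, 1.5); GP amplitude half-Normal(1) and
#' length scale half-Normal(half the study extent); the non-centred GP
#' coefficients `u` are standard normal.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector or named list of parameter values;
#'   names must follow the layout produced by [sample_posterior()]
#'   (`alpha_s1`, `beta_<cov>_s<season>`, `u1...`, `log_eta`, ...).
#' @param data prepared data list (see [sample_posterior()]).
#' @return Scalar log-posterior density (unnormalized).
#' @export
log_posterior <- function(spec, params, data) {
  model <- build_habitat_model(spec, data)
  if (is.list(params)) params <- unlist(params)
  missing <- setdiff(model$par_names, names(params))
  if (length(missing)) {
    stopf("missing parameter(s): %s", paste(head(missing, 5), collapse = ", "))
  }
  par <- params[model$par_names]
  lp <- model$loglik(par) + model$logprior(par)
  if (length(model$i_u)) lp <- lp + sum(dnorm(par[model$i_u], log = TRUE))
  unname(lp)
}

#' Sample a habitat-model posterior
#'
#' Runs the package MCMC engine on a prepared data list: adaptive
#' random-walk Metropolis for the fixed effects, elliptical slice sampling
#' for the GP field, adaptive random walk for the GP hyperparameters.
#' Convergence is checked with rank-normalized split-Rhat; any fixed-effect
#' Rhat above 1.01 raises a warning (never a silent success).
#'
#' @inheritParams log_posterior
#' @param chains,iters MCMC settings (defaults 4 chains, 2000 iterations).
#' @param warmup warmup iterations; default 4000 (7000 for the count model).
#' @param seed integer seed.
#' @return A `posterior_draws` object.
#' @export
sample_posterior <- function(spec, data, chains = 4, warmup = NULL,
                             iters = 2000, seed = 1) {
  warmup <- warmup %||% default_warmup(spec$response)
  model <- build_habitat_model(spec, data)
  draws <- run_mcmc(model, chains = chains, warmup = warmup, iters = iters, seed = seed)
  fixed <- model$par_names[seq_len(model$n_fixed)]
  rh <- if (chains >= 2) split_rhat(draws)[fixed] else NA_real_
  if (any(rh > 1.01, na.rm = TRUE)) {
    warn(
      sprintf(
        "possible non-convergence: split-Rhat > 1.01 for %s",
        paste(names(rh)[which(rh > 1.01)], collapse = ", ")
      ),
      class = "opuntiacam_convergence"
    )
  }
  draws
}

## ---- data preparation from the tabular formats ----

# site x day matrix of `value` ordered by site_id / date
.obs_matrix <- function(observations, value, site_ids) {
  wide <- observations |>
    dplyr::select("site_id", "date", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "date", values_from = dplyr::all_of(value)) |>
    dplyr::arrange(.data$site_id)
  wide <- wide[match(site_ids, wide$site_id), ]
  as.matrix(wide[, -1, drop = FALSE])
}

prepare_habitat_data <- function(spec, observations, sites, jitter = 1e-6) {
  exposure_col <- if (spec$exposure_scale == "site") {
    "opuntia_cover_pct"
  } else {
    "square_opuntia_vol_m3_per_m"
  }
  needed <- c("site_id", "season", exposure_col, spec$covariates)
  missing <- setdiff(needed, names(sites))
  if (length(missing)) stopf("`sites` lacks column(s): %s", paste(missing, collapse = ", "))
  sites <- dplyr::arrange(sites, .data$site_id)
  keep <- !is.na(sites[[exposure_col]])
  if (!all(keep)) {
    message(sprintf(
      "dropping %d site(s) without %s (unsampled squares)", sum(!keep), exposure_col
    ))
    sites <- sites[keep, ]
  }
  observations <- observations[observations$site_id %in% sites$site_id, ]

  covfr <- sites[, c(exposure_col, spec$covariates)]
  names(covfr)[1] <- "opuntia"
  covfr <- standardize_covariates(covfr)
  scaling <- attr(covfr, "scaling")

  seasons <- sort(unique(sites$season))
  data <- list(
    X = as.matrix(covfr),
    season = match(sites$season, seasons),
    seasons = seasons,
    site_ids = sites$site_id,
    jitter = jitter
  )
  if (spec$gp) data$coords <- as.matrix(sites[, c("easting_m", "northing_m")])

  if (spec$response == "occupancy") {
    data$y <- .obs_matrix(observations, "detected", sites$site_id)
    temp <- .obs_matrix(observations, "temp_c", sites$site_id)
    tmu <- mean(temp, na.rm = TRUE)
    tsd <- sd(as.vector(temp), na.rm = TRUE)
    data$temp <- (temp - tmu) / tsd
    data$temp[is.na(data$temp)] <- 0 # inactive days; masked by NA in y
    scaling <- dplyr::bind_rows(scaling, tibble::tibble(variable = "temp_c", mean = tmu, sd = tsd))
    cams <- sort(unique(sites$camera_model))
    data$cam <- match(sites$camera_model, cams)
    data$n_cam <- length(cams)
    data$camera_models <- cams
  } else if (spec$response == "count") {
    data$y <- .obs_matrix(observations, "count", sites$site_id)
  } else {
    data$n <- .obs_matrix(observations, "count", sites$site_id)
    data$k <- .obs_matrix(observations, "night_count", sites$site_id)
    lun <- .obs_matrix(observations, "lunar_frac", sites$site_id)
    lun[is.na(lun)] <- 0
    data$lunar <- lun # never standardized
  }
  attr(data, "scaling") <- scaling
  data
}

#' Fit a habitat-use model to study tables
#'
#' High-level interface: prepares matrices from the `sites` and
#' `observations` tables (standardizing covariates, excluding lunar
#' illumination), then samples the posterior.
#'
#' @param observations per site x day observation table (columns `site_id`,
#'   `date`, `detected`, `count`, `night_count`, `temp_c`, `lunar_frac`).
#' @param sites site table (see [simulate_site_covariates()] for the schema).
#' @param spec a [model_spec()]; or use the `response`/`exposure_scale`
#'   shortcuts.
#' @inheritParams sample_posterior
#' @inheritParams model_spec
#' @param ... passed to [model_spec()] when `spec` is not supplied.
#' @return A `habitat_fit` object with [tidy.habitat_fit()] and
#'   [glance.habitat_fit()] methods.
#' @export
fit_habitat_model <- function(observations, sites,
                              response = c("occupancy", "count", "night"),
                              exposure_scale = c("site", "square"),
                              spec = NULL, chains = 4, warmup = NULL,
                              iters = 2000, seed = 1, ...) {
  spec <- spec %||% model_spec(
    response = match.arg(response),
    exposure_scale = match.arg(exposure_scale), ...
  )
  data <- prepare_habitat_data(spec, observations, sites)
  draws <- sample_posterior(spec, data, chains = chains, warmup = warmup, iters = iters, seed = seed)
  structure(
    list(
      spec = spec, draws = draws, data = data,
      scaling = attr(data, "scaling"),
      seasons = data$seasons, site_ids = data$site_ids
    ),
    class = "habitat_fit"
  )
}

#' @rdname fit_habitat_model
#' @export
fit_occupancy <- function(observations, sites, ...) {
  fit_habitat_model(observations, sites, response = "occupancy", ...)
}

#' @rdname fit_habitat_model
#' @export
fit_daily_counts <- function(observations, sites, ...) {
  fit_habitat_model(observations, sites, response = "count", ...)
}

#' @rdname fit_habitat_model
#' @export
fit_night_activity <- function(observations, sites, ...) {
  fit_habitat_model(observations, sites, response = "night", ...)
}

#' @export
print.habitat_fit <- function(x, ...) {
  cat(sprintf(
    "<habitat_fit: %s model, %s-scale exposure, %d sites, %d seasons>\n",
    x$spec$response, x$spec$exposure_scale, length(x$site_ids), length(x$seasons)
  ))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy a habitat-model fit
#'
#' @param x a `habitat_fit`.
#' @param include_gp include the per-site GP coefficients.
#' @param ... unused.
#' @return Tibble of posterior summaries (mean, sd, central 90% interval,
#'   split-Rhat, bulk ESS) per parameter.
#' @export
tidy.habitat_fit <- function(x, include_gp = FALSE, ...) {
  out <- tidy(x$draws)
  if (!include_gp) out <- out[!grepl("^u[0-9]+$", out$parameter), ]
  out
}

#' @export
glance.habitat_fit <- function(x, ...) {
  td <- tidy(x, include_gp = FALSE)
  d <- dim(x$draws$draws)
  tibble::tibble(
    response = x$spec$response,
    exposure_scale = x$spec$exposure_scale,
    n_sites = length(x$site_ids),
    chains = d[1], iters = d[2], warmup = x$draws$warmup,
    max_rhat = max(td$rhat, na.rm = TRUE),
    min_ess = min(td$ess_bulk, na.rm = TRUE),
    mean_accept = mean(x$draws$acceptance, na.rm = TRUE)
  )
}
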
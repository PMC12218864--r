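## Line-transect distance sampling of Opuntia stands.
##
## Stands are counted in perpendicular-distance bins along transects, in
## three height classes (S < 1 m, M 1-2 m, L > 2 m). Detection falls off
## with distance as a half-normal, counts per bin are Poisson-thinned
## multinomial cells, and posterior stand abundances convert to volumes via
## hemisphere-based per-stand constants.

#' Per-stand Opuntia volume constants (m^3)
#'
#' Representative per-stand volumes for the three size classes, derived from
#' hemispheres of height 0.5, 1.5 and 2.5 m. The stored values are the
#' published constants used throughout the pipeline; note that uniform
#' 3-decimal rounding of `hemisphere_volume()` reproduces the large-class
#' constant exactly, while the small and medium constants match at 2
#' decimals (0.26, 7.07).
#'
#' @return Named numeric vector `c(S = 0.260, M = 7.070, L = 32.725)`.
#' @seealso [hemisphere_volume()]
#' @export
opuntia_volume_constants <- function() {
  c(S = 0.260, M = 7.070, L = 32.725)
}

#' Hemisphere volume
#'
#' `(2/3) * pi * r^3`, the geometric model behind the per-stand volume
#' constants (a stand of height `h` is treated as a hemisphere of radius `h`).
#'
#' @param r hemisphere radius (= stand height), metres.
#' @return Volume in m^3.
#' @export
#' @examples
#' hemisphere_volume(2.5) # ~32.725
hemisphere_volume <- function(r) {
  check_number(r, "r", lower = 0)
  (2 / 3) * pi * r^3
}

#' Half-normal detection function
#'
#' @param x perpendicular distance (m), non-negative.
#' @param sigma detection scale (m), positive.
#' @return Detection probability `exp(-x^2 / (2 sigma^2))`.
#' @export
#' @examples
#' halfnormal_g(0, 4) # 1
#' halfnormal_g(4, 4) # exp(-1/2)
halfnormal_g <- function(x, sigma) {
  check_number(x, "x", lower = 0)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  exp(-x^2 / (2 * sigma^2))
}

.check_breaks <- function(breaks) {
  if (length(breaks) < 2 || anyNA(breaks) || breaks[1] != 0 ||
    any(diff(breaks) <= 0)) {
    stopf("`breaks` must be strictly increasing and start at 0")
  }
  breaks
}

#' Per-bin detection probabilities under half-normal detection
#'
#' For stands uniform on `[0, B]` (`B = max(breaks)`), the probability a
#' stand falls in bin `c` *and* is detected is
#' `(1/B) * integral over the bin of exp(-x^2/(2 sigma^2)) dx`, evaluated in
#' closed form through the Gaussian CDF. An extra `undetected` cell brings
#' the probabilities to a full multinomial.
#'
#' @param breaks distance-bin breaks (m), strictly increasing from 0.
#' @param sigma half-normal scale (m), positive.
#' @return A list: `cell_probs` (one per bin), `p_detect` (their sum) and
#'   `undetected` (`1 - p_detect`).
#' @export
#' @examples
#' bin_detection_probs(0:10, sigma = 4)
bin_detection_probs <- function(breaks, sigma) {
  .check_breaks(breaks)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  B <- max(breaks)
  # integral of exp(-x^2/2s^2) from a to b = s*sqrt(2*pi)*(pnorm(b/s)-pnorm(a/s))
  ints <- sigma * sqrt(2 * pi) *
    (pnorm(breaks[-1] / sigma) - pnorm(breaks[-length(breaks)] / sigma))
  cells <- ints / B
  list(cell_probs = cells, p_detect = sum(cells), undetected = 1 - sum(cells))
}

#' Poisson-multinomial distance-sampling log-likelihood
#'
#' The factorized form of the model: independent `y_c ~ Poisson(lambda *
#' pi_c)` per distance cell, which is marginally identical to drawing a
#' Poisson(`lambda`) number of stands and thinning them multinomially into
#' cells. `counts` may be a vector (one transect) or a matrix with one row
#' per transect sharing `lambda` and `sigma`.
#'
#' @param counts integer counts per distance bin (vector or matrix, columns
#'   = bins matching `breaks`).
#' @param breaks distance-bin breaks (m).
#' @param lambda expected number of stands in `[0, B]` per transect, >= 0.
#' @param sigma half-normal detection scale (m).
#' @return Scalar log-likelihood; `-Inf` (not an error) when a count falls
#'   in a zero-probability cell.
#' @export
ds_log_likelihood <- function(counts, breaks, lambda, sigma) {
  check_number(lambda, "lambda", lower = 0)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (ncol(counts) != length(breaks) - 1L) {
    stopf("`counts` must have one column per distance bin")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("`counts` must be non-negative integers")
  }
  pi_c <- bin_detection_probs(breaks, sigma)$cell_probs
  mu <- rep(lambda * pi_c, each = nrow(counts))
  ll <- dpois(as.vector(counts), mu, log = TRUE)
  # dpois(k>0, 0) is -Inf already; keep it a value, not an exception
  sum(ll)
}

#' Volume from stand counts
#'
#' Linear combination of the three per-stand constants; counts may be
#' posterior expectations, hence real-valued.
#'
#' @param n_small,n_medium,n_large stand counts (>= 0).
#' @return Volume in m^3.
#' @export
#' @examples
#' volume_from_counts(0, 0, 1) # 32.725
volume_from_counts <- function(n_small, n_medium, n_large) {
  check_number(n_small, "n_small", lower = 0)
  check_number(n_medium, "n_medium", lower = 0)
  check_number(n_large, "n_large", lower = 0)
  k <- opuntia_volume_constants()
  k[["S"]] * n_small + k[["M"]] * n_medium + k[["L"]] * n_large
}

#' Per-metre and whole-square volume metrics
#'
#' Divides a square's volume estimate by its transect length, then scales by
#' the 500 m square edge to obtain the total-square volume.
#'
#' @param volume estimated volume along the transect strip (m^3).
#' @param transect_length transect length (m), positive.
#' @param square_edge square edge length (m), default 500.
#' @return A tibble with `vol_per_m` (m^3/m) and `total_vol_m3`.
#' @export
#' @examples
#' square_volume_metrics(65.45, 500)
square_volume_metrics <- function(volume, transect_length, square_edge = 500) {
  check_number(volume, "volume", lower = 0)
  check_number(transect_length, "transect_length", lower = 0, strict_lower = TRUE)
  tibble::tibble(
    vol_per_m = volume / transect_length,
    total_vol_m3 = volume / transect_length * square_edge
  )
}

#' Fit the distance-sampling model
#'
#' Bayesian fit of the Poisson-multinomial half-normal model to binned
#' transect counts, one detection scale and one expected stand count per
#' size class (classes are fitted independently unless `shared_sigma`).
#' Sampling uses the package MCMC engine on `(log sigma, log lambda)` with
#' weakly regularising priors (`sigma ~ half-Normal(5)`,
#' `log lambda ~ Normal(0, 2)`).
#'
#' @param transects tibble with columns `square_id`, `size_class`,
#'   `bin_lo_m`, `bin_hi_m`, `count`, `transect_length_m` (as written by
#'   [simulate_transects()]).
#' @param shared_sigma fit a single detection scale across size classes.
#' @param chains,warmup,iters,seed MCMC settings.
#' @return A `ds_fit` object; see [tidy.ds_fit()] for posterior summaries
#'   and [square_opuntia_volumes()] for the volume pipeline.
#' @export
fit_distance_model <- function(transects, shared_sigma = FALSE, chains = 4,
                               warmup = 1000, iters = 1000, seed = 1) {
  needed <- c("square_id", "size_class", "bin_lo_m", "bin_hi_m", "count")
  if (!all(needed %in% names(transects))) {
    stopf("`transects` must have columns %s", paste(needed, collapse = ", "))
  }
  classes <- sort(unique(transects$size_class))
  zero <- vapply(classes, function(cl) {
    sum(transects$count[transects$size_class == cl]) == 0
  }, TRUE)
  if (any(zero)) {
    stopf(
      "size class(es) with zero detections: %s; sigma is unidentifiable there",
      paste(classes[zero], collapse = ", ")
    )
  }
  breaks <- sort(unique(c(transects$bin_lo_m, transects$bin_hi_m)))
  .check_breaks(breaks)

  class_data <- lapply(classes, function(cl) {
    sub <- dplyr::arrange(
      transects[transects$size_class == cl, ],
      .data$square_id, .data$bin_lo_m
    )
    # squares x bins count matrix
    tab <- tidyr::pivot_wider(
      sub[, c("square_id", "bin_lo_m", "count")],
      names_from = "bin_lo_m", values_from = "count", values_fill = 0L
    )
    ord <- order(as.numeric(names(tab)[-1]))
    as.matrix(tab[, -1, drop = FALSE])[, ord, drop = FALSE]
  })
  names(class_data) <- classes

  fit_one <- function(counts, seed_k) {
    model <- list(
      par_names = c("log_sigma", "log_lambda"),
      blocks = list(list(type = "rw", idx = 1:2)),
      init = function() c(log(max(breaks) / 3), log(max(1, mean(rowSums(counts))))),
      loglik = function(par) {
        ds_log_likelihood(counts, breaks, exp(par[2]), exp(par[1]))
      },
      logprior = function(par) {
        # sigma ~ half-N(5) with log-scale jacobian; log lambda ~ N(0,2)
        dnorm(exp(par[1]), 0, 5, log = TRUE) + log(2) + par[1] +
          dnorm(par[2], 0, 2, log = TRUE)
      }
    )
    run_mcmc(model, chains = chains, warmup = warmup, iters = iters, seed = seed_k)
  }

  fit_shared <- function() {
    nc <- length(classes)
    model <- list(
      par_names = c("log_sigma", paste0("log_lambda_", classes)),
      blocks = list(list(type = "rw", idx = seq_len(nc + 1L))),
      init = function() {
        c(
          log(max(breaks) / 3),
          vapply(class_data, function(m) log(max(1, mean(rowSums(m)))), 0)
        )
      },
      loglik = function(par) {
        sum(vapply(seq_len(nc), function(k) {
          ds_log_likelihood(class_data[[k]], breaks, exp(par[1 + k]), exp(par[1]))
        }, 0))
      },
      logprior = function(par) {
        dnorm(exp(par[1]), 0, 5, log = TRUE) + log(2) + par[1] +
          sum(dnorm(par[-1], 0, 2, log = TRUE))
      }
    )
    run_mcmc(model, chains = chains, warmup = warmup, iters = iters, seed = seed)
  }

  if (shared_sigma) {
    shared <- fit_shared()
    # per-class views share the sigma column so downstream summaries are
    # uniform across the two modes
    draws <- lapply(classes, function(cl) {
      d <- shared
      keep <- c("log_sigma", paste0("log_lambda_", cl))
      d$draws <- d$draws[, , keep, drop = FALSE]
      dimnames(d$draws)[[3]] <- c("log_sigma", "log_lambda")
      d$par_names <- c("log_sigma", "log_lambda")
      d
    })
    names(draws) <- classes
  } else {
    draws <- vector("list", length(classes))
    names(draws) <- classes
    for (k in seq_along(classes)) {
      draws[[k]] <- fit_one(class_data[[k]], seed + k - 1L)
    }
  }
  structure(
    list(
      draws = draws, breaks = breaks, classes = classes,
      counts = class_data, transects = transects, seed = seed,
      shared_sigma = shared_sigma
    ),
    class = "ds_fit"
  )
}

#' @export
print.ds_fit <- function(x, ...) {
  cat(sprintf(
    "<ds_fit: %d size classes, %d distance bins, %d squares>\n",
    length(x$classes), length(x$breaks) - 1L, nrow(x$counts[[1]])
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a distance-sampling fit
#'
#' @param x a `ds_fit`.
#' @param ... unused.
#' @return Tibble with posterior mean, sd and central 90% interval of
#'   `sigma_m` and `lambda` per size class.
#' @export
tidy.ds_fit <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    m <- pool_draws(x$draws[[cl]])
    sig <- exp(m[, "log_sigma"])
    lam <- exp(m[, "log_lambda"])
    tibble::tibble(
      size_class = cl,
      parameter = c("sigma_m", "lambda"),
      estimate = c(mean(sig), mean(lam)),
      std.error = c(sd(sig), sd(lam)),
      q5 = c(quantile(sig, 0.05), quantile(lam, 0.05)),
      q95 = c(quantile(sig, 0.95), quantile(lam, 0.95))
    )
  })
}

#' @export
glance.ds_fit <- function(x, ...) {
  rh <- purrr::map_dbl(x$draws, function(d) max(split_rhat(d), na.rm = TRUE))
  tibble::tibble(
    n_squares = nrow(x$counts[[1]]), n_classes = length(x$classes),
    chains = dim(x$draws[[1]]$draws)[1], iters = dim(x$draws[[1]]$draws)[2],
    max_rhat = max(rh)
  )
}

#' Posterior Opuntia volumes per square
#'
#' Combines per-class posterior expected abundances with per-square bin
#' counts into the volume pipeline: per-class expected stands per square ->
#' hemisphere-constant volume -> volume per metre of transect -> total
#' square volume (x 500 m).
#'
#' Per-square abundance is estimated as the posterior mean of
#' `n_detected / p_detect` per square (detected stands corrected for
#' detectability), with lambda draws informing `p_detect` through sigma.
#'
#' @param fit a `ds_fit`.
#' @return Tibble with one row per square: expected stands per class,
#'   `vol_m3`, `vol_per_m`, `total_vol_m3` plus 90% interval columns.
#' @export
square_opuntia_volumes <- function(fit) {
  squares <- rownames(fit$counts[[1]]) %||%
    sort(unique(fit$transects$square_id))
  lens <- fit$transects |>
    dplyr::distinct(.data$square_id, .data$transect_length_m) |>
    dplyr::arrange(.data$square_id)
  n_sq <- nrow(fit$counts[[1]])
  # posterior draws of per-square abundance per class: N_hat = y_det / p_det
  vol_draws <- 0
  n_hat <- list()
  for (cl in fit$classes) {
    m <- pool_draws(fit$draws[[cl]])
    sig <- exp(m[, "log_sigma"])
    pdet <- vapply(sig, function(s) bin_detection_probs(fit$breaks, s)$p_detect, 0)
    ydet <- rowSums(fit$counts[[cl]])
    # draws x squares
    n_hat[[cl]] <- outer(1 / pdet, ydet)
    vol_draws <- vol_draws + opuntia_volume_constants()[[cl]] * n_hat[[cl]]
  }
  out <- tibble::tibble(
    square_id = sort(unique(fit$transects$square_id)),
    transect_length_m = lens$transect_length_m
  )
  for (cl in fit$classes) {
    out[[paste0("lambda_", cl)]] <- colMeans(n_hat[[cl]])
  }
  out$vol_m3 <- colMeans(vol_draws)
  out$vol_m3_q5 <- apply(vol_draws, 2, quantile, 0.05)
  out$vol_m3_q95 <- apply(vol_draws, 2, quantile, 0.95)
  vm <- square_volume_metrics(out$vol_m3, out$transect_length_m)
  out$vol_per_m <- vm$vol_per_m
  out$total_vol_m3 <- vm$total_vol_m3
  out
}
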
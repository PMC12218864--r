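## Posterior effect summaries: P(+ve effect), nested compatibility
## intervals, and marginal effect curves on the response scale.

# pooled draws of one parameter from a fit / posterior_draws / numeric vector
posterior_vector <- function(x, parameter = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    return(x)
  }
  if (inherits(x, "habitat_fit")) x <- x$draws
  if (inherits(x, "posterior_draws")) {
    if (is.null(parameter)) stopf("`parameter` is required")
    if (!parameter %in% x$par_names) {
      stopf(
        "unknown parameter `%s`; available: %s", parameter,
        paste(head(setdiff(x$par_names, grep("^u[0-9]+$", x$par_names, value = TRUE)), 12), collapse = ", ")
      )
    }
    return(pool_draws(x)[, parameter])
  }
  stopf("cannot extract draws from a %s", class(x)[1])
}

#' Posterior probability of a positive effect
#'
#' Fraction of pooled post-warmup draws strictly above zero; exact zeros
#' count as not positive. A value of 0.5 means positive and negative effects
#' are equally probable.
#'
#' @param x a `habitat_fit`, `posterior_draws`, or numeric draw vector.
#' @param parameter parameter name (when `x` holds draws of several).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' p_positive(c(-1, 2, 3, 4)) # 0.75
p_positive <- function(x, parameter = NULL) {
  mean(posterior_vector(x, parameter) > 0)
}

#' Nested compatibility intervals
#'
#' Central posterior intervals at several levels; the shared quantile
#' function guarantees nesting (the 50% interval lies inside the 60%, and so
#' on up to 95%).
#'
#' @inheritParams p_positive
#' @param levels interval levels in percent, within (0, 100).
#' @return Tibble `level`, `lower`, `upper`, sorted by decreasing level.
#' @export
compatibility_intervals <- function(x, parameter = NULL,
                                    levels = c(95, 89, 80, 70, 60, 50)) {
  check_number(levels, "levels", 0, 100, strict_lower = TRUE, strict_upper = TRUE)
  draws <- posterior_vector(x, parameter)
  levels <- sort(levels, decreasing = TRUE)
  if (length(draws) < 40 / (100 - max(levels))) {
    warn("few draws for the most extreme quantile; intervals will be noisy")
  }
  tibble::tibble(
    level = levels,
    lower = quantile(draws, (100 - levels) / 200, names = FALSE),
    upper = quantile(draws, 1 - (100 - levels) / 200, names = FALSE)
  )
}

#' Marginal effect of Opuntia on the response scale
#'
#' Conditional-at-means effect curve: for each raw exposure value on the
#' grid, the exposure is standardized with the fit's scaling record, all
#' other covariates sit at their standardized mean (0), the GP term at 0 and
#' detection nuisances at their reference, and every posterior draw is
#' pushed through the inverse link (logistic for occupancy and night
#' activity, exponential for counts).
#'
#' @param fit a `habitat_fit`.
#' @param exposure_grid raw-scale exposure values (site percent cover or
#'   square volume per metre); defaults to 25 points over the observed
#'   range. Values outside the observed range trigger an extrapolation
#'   warning but are still computed.
#' @param season season label to condition on (default: first season).
#' @param levels compatibility-interval levels for the ribbon quantiles.
#' @return Tibble: `exposure`, `season`, `median`, and `lo`/`hi` columns per
#'   level, with class `marginal_effect_curve` for [autoplot()].
#' @export
marginal_effect_curve <- function(fit, exposure_grid = NULL,
                                  season = NULL,
                                  levels = c(95, 89, 80, 70, 60, 50)) {
  stopifnot(inherits(fit, "habitat_fit"))
  sc <- fit$scaling[fit$scaling$variable == "opuntia", ]
  obs_range <- sc$mean + c(-1, 1) * 3 * sc$sd # generous observed span
  raw_obs <- fit$data$X[, "opuntia"] * sc$sd + sc$mean
  exposure_grid <- exposure_grid %||%
    seq(min(raw_obs), max(raw_obs), length.out = 25)
  if (any(exposure_grid < min(raw_obs)) || any(exposure_grid > max(raw_obs))) {
    warn("exposure grid extends beyond the observed exposure range (extrapolation)")
  }
  season <- season %||% fit$seasons[1]
  if (!season %in% fit$seasons) stopf("season %s not in the fit", season)
  m <- pool_draws(fit$draws)
  a <- m[, paste0("alpha_s", season)]
  b <- m[, paste0("beta_opuntia_s", season)]
  inv_link <- if (fit$spec$response == "count") exp else plogis
  z <- (exposure_grid - sc$mean) / sc$sd
  qs <- sort(c((100 - levels) / 200, 0.5, 1 - (100 - levels) / 200))
  out <- purrr::map_dfr(seq_along(z), function(i) {
    resp <- inv_link(a + b * z[i])
    qq <- quantile(resp, qs, names = FALSE)
    row <- tibble::tibble(exposure = exposure_grid[i], season = season, median = qq[qs == 0.5])
    for (L in levels) {
      row[[sprintf("lo%d", L)]] <- qq[qs == (100 - L) / 200]
      row[[sprintf("hi%d", L)]] <- qq[qs == 1 - (100 - L) / 200]
    }
    row
  })
  class(out) <- c("marginal_effect_curve", class(out))
  attr(out, "response") <- fit$spec$response
  attr(out, "levels") <- sort(levels, decreasing = TRUE)
  out
}

#' Summarise one fitted effect cell
#'
#' One row of the effect matrix: species, season, exposure scale, model type
#' and the posterior probability that the seasonal Opuntia slope is
#' positive.
#'
#' @param fit a `habitat_fit`.
#' @param species species label for the row.
#' @return Tibble with one row per season in the fit.
#' @export
summarise_effects <- function(fit, species) {
  purrr::map_dfr(fit$seasons, function(s) {
    par <- paste0("beta_opuntia_s", s)
    ci <- compatibility_intervals(fit, par)
    tibble::tibble(
      species = species, season = s,
      scale = fit$spec$exposure_scale, model = fit$spec$response,
      p_positive = p_positive(fit, par),
      q2.5 = ci$lower[ci$level == 95], q97.5 = ci$upper[ci$level == 95]
    )
  })
}

#' Species-by-condition matrix of P(+ve effect)
#'
#' Arranges per-cell summaries into the wide reporting matrix: one row per
#' species (in [focal_species()] order where applicable), one column per
#' (season, exposure scale, model type) combination. Missing cells stay
#' `NA`; duplicated cells are an error.
#'
#' @param summaries tibble with columns `species`, `season`, `scale`,
#'   `model`, `p_positive` (rows = cells), e.g. bound
#'   [summarise_effects()] outputs.
#' @return Wide tibble, one row per species, `p_positive` spread across
#'   `<model>_<scale>_s<season>` columns.
#' @export
effect_matrix <- function(summaries) {
  if (!nrow(summaries)) {
    return(tibble::tibble(species = character()))
  }
  dup <- summaries |>
    dplyr::count(.data$species, .data$season, .data$scale, .data$model) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stopf(
      "duplicate effect cell(s): %s",
      paste(dup$species, dup$model, dup$scale, dup$season, collapse = "; ")
    )
  }
  wide <- summaries |>
    dplyr::mutate(cell = sprintf("%s_%s_s%d", .data$model, .data$scale, .data$season)) |>
    dplyr::select("species", "cell", "p_positive") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "p_positive")
  ord <- match(wide$species, focal_species())
  wide[order(ifelse(is.na(ord), Inf, ord), wide$species), ]
}

#' Plot a marginal effect curve
#'
#' Nested compatibility-interval ribbons (widest and lightest at 95%) around
#' the posterior median response.
#'
#' @param object a [marginal_effect_curve()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.marginal_effect_curve <- function(object, ...) {
  levels <- attr(object, "levels")
  resp <- attr(object, "response")
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$exposure))
  for (i in seq_along(levels)) {
    L <- levels[i]
    g <- g + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data[[sprintf("lo%d", L)]],
        ymax = .data[[sprintf("hi%d", L)]]
      ),
      fill = "steelblue", alpha = 0.8 / length(levels)
    )
  }
  g + ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.8) +
    ggplot2::labs(
      x = "Opuntia exposure (raw scale)",
      y = switch(resp,
        occupancy = "occupancy probability",
        count = "expected detections per day",
        night = "proportion of detections at night"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the P(+ve effect) matrix
#'
#' @param summaries long summaries as taken by [effect_matrix()].
#' @return A ggplot tile map, species by condition, filled by P(+ve effect)
#'   (0.5 = sign undetermined).
#' @export
plot_effect_matrix <- function(summaries) {
  df <- summaries |>
    dplyr::mutate(
      cell = sprintf("%s\n%s s%d", .data$model, .data$scale, .data$season),
      species = factor(.data$species, levels = rev(union(focal_species(), .data$species)))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$species, fill = .data$p_positive)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p_positive)), size = 3) +
    ggplot2::scale_fill_gradient2(
      low = "#b2182b", mid = "white", high = "#2166ac",
      midpoint = 0.5, limits = c(0, 1), name = "P(+ve effect)"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
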
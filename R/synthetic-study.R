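## Synthetic camera-trap studies with known ground truth.
##
## The generator reproduces the study design end to end: paired sites inside
## 500 x 500 m grid squares (one visibly high-Opuntia site, one lower-cover
## site 50-70 m away), two deployment seasons, daily detection / count /
## night-count observations driven by the same three models the package
## fits (with a shared spatial GP field), line-transect distance-sampling
## counts of Opuntia stands in three size classes, and per-image volunteer
## vote vectors with a configurable confusion structure. Everything is
## deterministic given a seed, and the latent truth is returned so each
## downstream stage can be verified by parameter recovery.

#' Ground-truth generative parameters
#'
#' Constructor with the package's default study conditions. Slopes act on
#' internally standardized covariates (mean 0, sd 1 over the generated
#' sites), matching how the models are fitted; lunar illumination stays on
#' its raw 0-1 scale.
#'
#' @param covariates covariates (beyond Opuntia) entering the state models.
#' @param alpha_psi,alpha_n,alpha_k intercepts per season (logit / log /
#'   logit scale) for occupancy, counts and night activity.
#' @param beta_psi,beta_n,beta_k named slope vectors (applied to both
#'   seasons) or covariate-by-season matrices; names must cover `"opuntia"`
#'   and `covariates`.
#' @param a_cam detection intercepts per camera model (logit scale).
#' @param gamma_temp detection slope on standardized daily temperature.
#' @param phi NB2 dispersion (> 0).
#' @param beta_lunar,beta_opuntia_x_lunar night-model lunar slope and the
#'   Opuntia-by-lunar interaction.
#' @param eta,rho,jitter GP amplitude (>= 0), length scale in metres (> 0)
#'   and diagonal jitter.
#' @param sigma half-normal detection scales (m) per Opuntia size class.
#' @param density expected Opuntia stands per square per size class.
#' @param transect_length_m transect length per square (m).
#' @param confusion volunteer confusion matrix (rows = true label, columns =
#'   voted label, rows sum to 1); default 0.9 on the diagonal with the
#'   remaining 0.1 voted "empty".
#' @param expert_fraction fraction of images also classified by an expert.
#' @param species labels used for the confusion matrix (plus `"empty"`).
#' @return A validated `true_parameters` list.
#' @export
true_parameters <- function(
    covariates = c("livestock_prop", "dist_river_m", "dist_road_m"),
    alpha_psi = c(0, 0),
    beta_psi = c(opuntia = 0.5, livestock_prop = -0.3, dist_river_m = -0.2, dist_road_m = 0.1),
    a_cam = c(modelA = -1, modelB = -0.7),
    gamma_temp = 0.3,
    alpha_n = c(-1.5, -1.5),
    beta_n = c(opuntia = 0.4, livestock_prop = -0.2, dist_river_m = -0.2, dist_road_m = 0.1),
    phi = 1,
    alpha_k = c(0, 0),
    beta_k = c(opuntia = 0.3, livestock_prop = 0, dist_river_m = 0, dist_road_m = 0),
    beta_lunar = -0.5,
    beta_opuntia_x_lunar = -0.3,
    eta = 0.5, rho = 1000, jitter = 1e-6,
    sigma = c(S = 2, M = 4, L = 6),
    density = c(S = 40, M = 25, L = 10),
    transect_length_m = 500,
    confusion = NULL,
    expert_fraction = 0.144,
    species = focal_species()) {
  as_beta <- function(b) {
    if (is.matrix(b)) b else cbind(s1 = b, s2 = b)
  }
  if (is.null(confusion)) {
    labels <- c(species, "empty")
    confusion <- matrix(0, length(labels), length(labels),
      dimnames = list(labels, labels)
    )
    for (sp in species) {
      confusion[sp, sp] <- 0.9
      confusion[sp, "empty"] <- 0.1
    }
    confusion["empty", "empty"] <- 0.95
    confusion["empty", species] <- 0.05 / length(species)
  }
  p <- structure(
    list(
      covariates = covariates,
      alpha_psi = alpha_psi, beta_psi = as_beta(beta_psi),
      a_cam = a_cam, gamma_temp = gamma_temp,
      alpha_n = alpha_n, beta_n = as_beta(beta_n), phi = phi,
      alpha_k = alpha_k, beta_k = as_beta(beta_k),
      beta_lunar = beta_lunar, beta_opuntia_x_lunar = beta_opuntia_x_lunar,
      eta = eta, rho = rho, jitter = jitter,
      sigma = sigma, density = density, transect_length_m = transect_length_m,
      confusion = confusion, expert_fraction = expert_fraction,
      species = species
    ),
    class = "true_parameters"
  )
  validate_true_parameters(p)
}

#' @rdname true_parameters
#' @param params object to validate.
#' @export
validate_true_parameters <- function(params) {
  check_number(params$phi, "phi", 0, strict_lower = TRUE)
  check_number(params$rho, "rho", 0, strict_lower = TRUE)
  check_number(params$eta, "eta", 0)
  check_number(params$sigma, "sigma", 0)
  check_number(params$density, "density", 0)
  check_number(params$expert_fraction, "expert_fraction", 0, 1)
  cm <- params$confusion
  if (is.null(dim(cm)) || any(cm < 0) || any(cm > 1) ||
    any(abs(rowSums(cm) - 1) > 1e-8)) {
    stopf("confusion matrix rows must be probabilities summing to 1")
  }
  for (nm in c("beta_psi", "beta_n", "beta_k")) {
    need <- c("opuntia", params$covariates)
    if (!all(need %in% rownames(params[[nm]]))) {
      stopf("`%s` must have named rows covering: %s", nm, paste(need, collapse = ", "))
    }
  }
  params
}

#' Generate a paired-site study design
#'
#' Lays grid squares of side `square_edge` on a planar grid and places two
#' camera sites in each: the first uniformly inside the square (with a
#' margin so the pair stays inside), the second at a uniform random bearing
#' and a uniform 50-70 m distance. Season 1 squares are deployed first
#' (January-April), season 2 squares later (October-November).
#'
#' @param n_squares_s1,n_squares_s2 number of squares per season (>= 0,
#'   total >= 1). The original study covered 46 + 14 squares; cameras always
#'   come in pairs here, so site counts are exactly `2 * n_squares`.
#' @param days survey days per deployment (>= 1; survey length is a free
#'   design parameter).
#' @param seed integer seed.
#' @param square_edge square side (m).
#' @param pair_offset distance range (m) between the paired sites.
#' @param camera_models camera model labels assigned randomly to sites.
#' @param bin_breaks distance-sampling bin breaks (m), increasing from 0.
#' @param start_dates deployment start date per season.
#' @return A `study_design` list with `sites` and `squares` tibbles.
#' @export
#' @examples
#' d <- generate_design(2, 1, days = 10, seed = 1)
#' d$sites
generate_design <- function(n_squares_s1 = 46, n_squares_s2 = 14, days = 90,
                            seed = 1, square_edge = 500,
                            pair_offset = c(50, 70),
                            camera_models = c("modelA", "modelB"),
                            bin_breaks = 0:10,
                            start_dates = as.Date(c("2021-01-15", "2021-10-15"))) {
  check_number(n_squares_s1, "n_squares_s1", lower = 0)
  check_number(n_squares_s2, "n_squares_s2", lower = 0)
  if (n_squares_s1 + n_squares_s2 < 1) stopf("at least one square is required")
  check_number(days, "days", lower = 1)
  if (square_edge <= 2 * max(pair_offset)) {
    stopf("square edge must exceed twice the maximum pair offset")
  }
  set.seed(seed)
  n_sq <- n_squares_s1 + n_squares_s2
  ncol_grid <- ceiling(sqrt(n_sq))
  margin <- max(pair_offset)
  squares <- tibble::tibble(
    square_id = sprintf("sq%03d", seq_len(n_sq)),
    season = rep(c(1L, 2L), c(n_squares_s1, n_squares_s2)),
    ll_east = ((seq_len(n_sq) - 1L) %% ncol_grid) * square_edge,
    ll_north = ((seq_len(n_sq) - 1L) %/% ncol_grid) * square_edge
  )
  e1 <- squares$ll_east + runif(n_sq, margin, square_edge - margin)
  n1 <- squares$ll_north + runif(n_sq, margin, square_edge - margin)
  d <- runif(n_sq, pair_offset[1], pair_offset[2])
  b <- runif(n_sq, 0, 2 * pi)
  sites <- tibble::tibble(
    site_id = sprintf("%s_%s", rep(squares$square_id, each = 2), rep(c("a", "b"), n_sq)),
    square_id = rep(squares$square_id, each = 2),
    season = rep(squares$season, each = 2),
    pair_rank = rep(1:2, n_sq),
    easting_m = as.vector(rbind(e1, e1 + d * sin(b))),
    northing_m = as.vector(rbind(n1, n1 + d * cos(b))),
    camera_model = sample(camera_models, 2L * n_sq, replace = TRUE),
    deploy_start = rep(start_dates[squares$season], each = 2),
    deploy_days = as.integer(days)
  )
  structure(
    list(
      squares = squares, sites = sites, days = as.integer(days),
      square_edge = square_edge, pair_offset = pair_offset,
      camera_models = camera_models, bin_breaks = bin_breaks,
      seed = seed
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design: %d squares (%d season-1, %d season-2), %d sites, %d days>\n",
    nrow(x$squares), sum(x$squares$season == 1), sum(x$squares$season == 2),
    nrow(x$sites), x$days
  ))
  invisible(x)
}

#' Simulate site-level habitat covariates
#'
#' Adds percentage covers (not constrained to sum to 100), tree counts,
#' distances to river/road, livestock use and the square-level Opuntia
#' volume to a design's site table. Within each pair, the first site's
#' Opuntia cover is strictly greater than the second's (the second is
#' resampled until lower, as in the field protocol), and the square-level
#' volume is positively correlated (configurable `volume_cover_r`) with the
#' square's mean site cover.
#'
#' @param design a [generate_design()] object.
#' @param params a [true_parameters()] object (unused by default fields, but
#'   kept in the signature so covariate generation can later depend on
#'   truth).
#' @param seed integer seed.
#' @param volume_cover_r correlation between square-level log volume and
#'   mean site cover (0 = independent).
#' @return The `sites` tibble with covariate columns appended.
#' @export
simulate_site_covariates <- function(design, params = true_parameters(), seed = 1,
                                     volume_cover_r = 0.7) {
  check_number(volume_cover_r, "volume_cover_r", -1, 1)
  set.seed(seed)
  sites <- design$sites
  n_sq <- nrow(design$squares)
  cover1 <- runif(n_sq, 10, 90)
  cover2 <- runif(n_sq, 0, 100)
  repeat {
    bad <- cover2 >= cover1
    if (!any(bad)) break
    cover2[bad] <- runif(sum(bad), 0, 100)
  }
  sites$opuntia_cover_pct <- as.vector(rbind(cover1, cover2))
  mean_cover <- (cover1 + cover2) / 2
  zc <- as.vector(scale(mean_cover))
  if (n_sq == 1L) zc <- 0
  zv <- volume_cover_r * zc + sqrt(1 - volume_cover_r^2) * rnorm(n_sq)
  vol <- exp(-2 + 0.8 * zv) # m^3 per metre of transect, median ~0.14
  sites$square_opuntia_vol_m3_per_m <- rep(vol, each = 2)
  n <- nrow(sites)
  sites$grass_pct <- 100 * rbeta(n, 2, 2)
  sites$shrub_pct <- 100 * rbeta(n, 2, 4)
  sites$forb_pct <- 100 * rbeta(n, 1.5, 6)
  sites$succulent_pct <- 100 * rbeta(n, 1.2, 8)
  sites$tree_count <- rpois(n, 5)
  # pair members share landscape position, so distances are square-level
  sites$dist_river_m <- rep(runif(n_sq, 0, 3000), each = 2)
  sites$dist_road_m <- rep(runif(n_sq, 0, 2000), each = 2)
  sites$livestock_prop <- rbeta(n, 1, 4)
  sites
}

# standardized covariate matrix (opuntia first) used by the generator;
# mirrors prepare_habitat_data so generated slopes match fitted slopes
.generator_X <- function(sites, params) {
  covfr <- sites[, c("opuntia_cover_pct", params$covariates)]
  names(covfr)[1] <- "opuntia"
  as.matrix(standardize_covariates(covfr))
}

#' Simulate daily observations and latent truth
#'
#' Draws the spatial GP field, latent occupancy states, daily detections,
#' NB2 daily counts and binomial night counts from the generative model, one
#' row per site x day. Daily mean temperature follows a sinusoidal annual
#' cycle with Gaussian noise; lunar illumination comes from
#' [lunar_fraction()] at local midnight.
#'
#' @param sites site table from [simulate_site_covariates()].
#' @param params a [true_parameters()].
#' @param seed integer seed.
#' @param env optional environment table (`site_id`, `date`, `temp_c`,
#'   `lunar_frac`) to reuse across species; generated when `NULL`.
#'   Temperature and moonlight are properties of the site and night, so a
#'   multi-species study shares one environment table.
#' @return A list: `observations` tibble (`site_id`, `date`, `detected`,
#'   `count`, `night_count`, `temp_c`, `lunar_frac`), `env` (the environment
#'   table used) and `truth` (GP field `f`, occupancy states `z`,
#'   probabilities and means).
#' @export
simulate_observations <- function(sites, params = true_parameters(), seed = 1,
                                  env = NULL) {
  validate_true_parameters(params)
  set.seed(seed)
  S <- nrow(sites)
  X <- .generator_X(sites, params)
  covs <- colnames(X)
  season <- sites$season
  coords <- as.matrix(sites[, c("easting_m", "northing_m")])

  f <- if (params$eta > 0) {
    L <- gp_cholesky(coords, params$eta, params$rho, params$jitter)
    drop(L %*% rnorm(S))
  } else {
    rep(0, S)
  }

  lin <- function(alpha, beta) {
    clamp_logit(alpha[season] + rowSums(X * t(beta[covs, season])) + f)
  }
  psi <- plogis(lin(params$alpha_psi, params$beta_psi))
  z <- rbinom(S, 1, psi)
  mu <- exp(pmin(lin(params$alpha_n, params$beta_n), 30))

  days <- sites$deploy_days
  if (length(unique(days)) != 1L) stopf("all sites must share `deploy_days`")
  J <- days[1]
  dates <- lapply(seq_len(S), function(i) sites$deploy_start[i] + seq_len(J) - 1L)

  if (is.null(env)) {
    all_dates <- sort(unique(as.Date(unlist(dates), origin = "1970-01-01")))
    lunar_by_date <- setNames(lunar_fraction_daily(all_dates), as.character(all_dates))
    env <- purrr::map_dfr(seq_len(S), function(i) {
      dts <- dates[[i]]
      doy <- as.integer(format(dts, "%j"))
      tibble::tibble(
        site_id = sites$site_id[i], date = dts,
        temp_c = 24 + 4 * sin(2 * pi * (doy - 105) / 365) + rnorm(J, 0, 2),
        lunar_frac = unname(lunar_by_date[as.character(dts)])
      )
    })
  }

  cam_logit <- params$a_cam[sites$camera_model]
  if (anyNA(cam_logit)) stopf("`a_cam` must name every camera model in `sites`")

  obs <- purrr::map_dfr(seq_len(S), function(i) {
    dts <- dates[[i]]
    ei <- env[env$site_id == sites$site_id[i], ]
    ei <- ei[match(dts, ei$date), ]
    temp <- ei$temp_c
    lun <- ei$lunar_frac
    temp_z <- (temp - 24) / 2.9 # approximate population standardization
    p <- plogis(clamp_logit(cam_logit[i] + params$gamma_temp * temp_z))
    y <- rbinom(J, 1, z[i] * p)
    n <- rnbinom(J, size = params$phi, mu = mu[i])
    lp_k <- clamp_logit(
      params$alpha_k[season[i]] +
        sum(X[i, ] * params$beta_k[covs, season[i]]) + f[i] +
        params$beta_lunar * lun +
        params$beta_opuntia_x_lunar * X[i, "opuntia"] * lun
    )
    k <- rbinom(J, n, plogis(lp_k))
    tibble::tibble(
      site_id = sites$site_id[i], date = dts,
      detected = y, count = n, night_count = k,
      temp_c = temp, lunar_frac = lun
    )
  })
  list(
    observations = obs,
    env = env,
    truth = list(
      f = f, z = z, psi = psi, mu = mu,
      X = X, params = params
    )
  )
}

#' Simulate distance-sampling transect counts
#'
#' Per square and size class: the true number of stands in the surveyed
#' strip is Poisson(`density`); each stand sits at a uniform perpendicular
#' distance in `[0, B]` and is detected with half-normal probability; the
#' detected stands are counted per distance bin.
#'
#' @param design a [generate_design()].
#' @param params a [true_parameters()].
#' @param seed integer seed.
#' @return Tibble: `square_id`, `size_class`, `bin_lo_m`, `bin_hi_m`,
#'   `count`, `transect_length_m`, plus attribute `"truth"` with the true
#'   abundances.
#' @export
simulate_transects <- function(design, params = true_parameters(), seed = 1) {
  validate_true_parameters(params)
  breaks <- .check_breaks(design$bin_breaks)
  set.seed(seed)
  B <- max(breaks)
  grid <- tidyr::expand_grid(
    square_id = design$squares$square_id,
    size_class = names(params$sigma)
  )
  truth <- integer(nrow(grid))
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cl <- grid$size_class[g]
    N <- rpois(1, params$density[[cl]])
    truth[g] <<- N
    counts <- integer(length(breaks) - 1L)
    if (N > 0 && params$sigma[[cl]] > 0) {
      x <- runif(N, 0, B)
      det <- runif(N) < halfnormal_g(x, params$sigma[[cl]])
      if (any(det)) {
        counts <- as.integer(table(cut(x[det], breaks, include.lowest = TRUE)))
      }
    }
    tibble::tibble(
      square_id = grid$square_id[g], size_class = cl,
      bin_lo_m = breaks[-length(breaks)], bin_hi_m = breaks[-1],
      count = counts, transect_length_m = params$transect_length_m
    )
  })
  attr(rows, "truth") <- tibble::tibble(grid, n_true = truth)
  rows
}

#' Simulate volunteer classification votes
#'
#' Each image receives `n_volunteers` independent votes drawn from the
#' confusion-matrix row of its true label; a configurable fraction of images
#' also receives an (always correct) expert label.
#'
#' @param true_labels character vector of true labels per image, or a tibble
#'   with columns `image_id` and `true_species`.
#' @param params a [true_parameters()] (provides the confusion matrix and
#'   default expert fraction).
#' @param n_volunteers votes per image (>= 1; the study retired images at
#'   12).
#' @param seed integer seed.
#' @param expert_fraction overrides `params$expert_fraction`.
#' @return Long tibble: `image_id`, `volunteer_id`, `label`, `expert_label`
#'   (`NA` where no expert saw the image).
#' @export
simulate_votes <- function(true_labels, params = true_parameters(),
                           n_volunteers = 12, seed = 1,
                           expert_fraction = NULL) {
  validate_true_parameters(params)
  check_number(n_volunteers, "n_volunteers", lower = 1)
  expert_fraction <- expert_fraction %||% params$expert_fraction
  if (is.data.frame(true_labels)) {
    ids <- true_labels$image_id
    labs <- true_labels$true_species
  } else {
    ids <- sprintf("img%06d", seq_along(true_labels))
    labs <- true_labels
  }
  cm <- params$confusion
  unknown <- setdiff(unique(labs), rownames(cm))
  if (length(unknown)) stopf("labels not in confusion matrix: %s", paste(unknown, collapse = ", "))
  set.seed(seed)
  n_img <- length(ids)
  # one multinomial draw stream per true label (vectorized across images)
  votes <- tibble::tibble(
    image_id = rep(ids, each = n_volunteers),
    true_label = rep(labs, each = n_volunteers),
    volunteer_id = rep(sprintf("vol%02d", seq_len(n_volunteers)), n_img),
    label = NA_character_
  )
  for (tl in unique(labs)) {
    rows <- votes$true_label == tl
    votes$label[rows] <- sample(colnames(cm), sum(rows),
      replace = TRUE, prob = cm[tl, ]
    )
  }
  votes$true_label <- NULL
  experts <- tibble::tibble(
    image_id = ids,
    expert_label = ifelse(runif(n_img) < expert_fraction, labs, NA_character_)
  )
  dplyr::left_join(votes, experts, by = "image_id")
}

#' Simulate a complete synthetic study
#'
#' Composes the full generator: design, site covariates, per-species daily
#' observations (species share the generative parameters but use independent
#' randomness), distance-sampling transects, per-detection images with
#' day/night timestamps, and volunteer votes for every image.
#'
#' @param design a [generate_design()]; built from `...` when `NULL`.
#' @param params a [true_parameters()].
#' @param species character vector of species to simulate.
#' @param seed integer seed (all stage seeds derive from it).
#' @param vote_images maximum number of images to put through the volunteer
#'   vote simulator (kept moderate because votes are the bulkiest table).
#' @param ... passed to [generate_design()] when `design` is `NULL`.
#' @return A `synthetic_study` list: `design`, `sites`, `observations` (with
#'   a `species` column), `transects`, `images`, `votes`, `truth` (per
#'   species).
#' @export
simulate_study <- function(design = NULL, params = true_parameters(),
                           species = c("impala", "olive_baboon", "leopard"),
                           seed = 1, vote_images = 2000, ...) {
  design <- design %||% generate_design(..., seed = seed)
  sites <- simulate_site_covariates(design, params, seed = seed + 1L)
  obs <- list()
  truth <- list()
  env <- NULL
  for (si in seq_along(species)) {
    res <- simulate_observations(sites, params, seed = seed + 10L + si, env = env)
    env <- res$env # one shared environment (temperature, moonlight)
    obs[[species[si]]] <- dplyr::mutate(res$observations, species = species[si], .before = 1)
    truth[[species[si]]] <- res$truth
  }
  observations <- dplyr::bind_rows(obs)
  transects <- simulate_transects(design, params, seed = seed + 2L)
  images <- .images_from_counts(observations, seed = seed + 3L)
  if (nrow(images) > vote_images) {
    set.seed(seed + 4L)
    images <- images[sort(sample.int(nrow(images), vote_images)), ]
  }
  votes <- if (nrow(images)) {
    simulate_votes(
      tibble::tibble(image_id = images$image_id, true_species = images$species),
      params,
      seed = seed + 5L
    )
  } else {
    tibble::tibble(
      image_id = character(), volunteer_id = character(),
      label = character(), expert_label = character()
    )
  }
  structure(
    list(
      design = design, sites = sites, observations = observations,
      transects = transects, images = images, votes = votes,
      truth = truth, params = params, seed = seed
    ),
    class = "synthetic_study"
  )
}

# one image per detection event; timestamps placed safely inside the day or
# night window (tropical dawn ~06:20, dusk ~18:45 local)
.images_from_counts <- function(observations, seed = 1, tz_offset_hours = 3) {
  set.seed(seed)
  with_counts <- observations[!is.na(observations$count) & observations$count > 0, ]
  if (!nrow(with_counts)) {
    return(tibble::tibble(
      image_id = character(), site_id = character(), species = character(),
      timestamp = as.POSIXct(character(), tz = "UTC")
    ))
  }
  rows <- with_counts[rep(seq_len(nrow(with_counts)), with_counts$count), ]
  at_night <- unlist(purrr::map2(with_counts$count, with_counts$night_count, function(n, k) {
    sample(c(rep(TRUE, k), rep(FALSE, n - k)))
  }))
  local_hour <- ifelse(
    at_night,
    sample(c(runif(nrow(rows), 20.5, 23.9), runif(nrow(rows), 0.2, 5.2)), nrow(rows)),
    runif(nrow(rows), 8, 17)
  )
  ts <- as.POSIXct(paste(rows$date, "00:00:00"), tz = "UTC") +
    local_hour * 3600 - tz_offset_hours * 3600
  tibble::tibble(
    image_id = sprintf("img%06d", seq_len(nrow(rows))),
    site_id = rows$site_id,
    species = rows$species %||% "unknown",
    timestamp = ts
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study: %d sites, %d species, %d obs rows, %d images, %d vote rows>\n",
    nrow(x$sites), length(unique(x$observations$species)),
    nrow(x$observations), nrow(x$images), nrow(x$votes)
  ))
  invisible(x)
}

#' Write a synthetic study to CSV + JSON
#'
#' Emits `sites.csv`, `observations.csv`, `transects.csv`, `votes.csv` and
#' `truth.json` into `dir`.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$sites, file.path(dir, "sites.csv"))
  readr::write_csv(study$observations, file.path(dir, "observations.csv"))
  readr::write_csv(study$transects, file.path(dir, "transects.csv"))
  readr::write_csv(study$votes, file.path(dir, "votes.csv"))
  readr::write_csv(study$images, file.path(dir, "images.csv"))
  truth <- lapply(study$truth, function(t) {
    list(z = t$z, f = t$f, psi = t$psi, mu = t$mu)
  })
  pj <- unclass(study$params)
  pj$confusion <- as.data.frame(pj$confusion)
  jsonlite::write_json(
    list(params = pj, latent = truth, seed = study$seed),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
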
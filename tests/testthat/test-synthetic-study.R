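test_that("design emits two sites per square with the paired-site geometry", {
  d <- generate_design(46, 14, days = 90, seed = 1)
  expect_equal(nrow(d$sites), 2 * (46 + 14)) # 92 + 28 (study had 101 + 27)
  expect_equal(sum(d$sites$season == 1), 92)
  expect_equal(sum(d$sites$season == 2), 28)
  # pair distances within [50, 70]
  pd <- d$sites |>
    dplyr::group_by(square_id) |>
    dplyr::summarise(d = sqrt(diff(easting_m)^2 + diff(northing_m)^2))
  expect_true(all(pd$d >= 50 & pd$d <= 70))
  # both sites inside their square
  sq <- d$squares[match(d$sites$square_id, d$squares$square_id), ]
  expect_true(all(d$sites$easting_m >= sq$ll_east &
    d$sites$easting_m <= sq$ll_east + 500))
  expect_true(all(d$sites$northing_m >= sq$ll_north &
    d$sites$northing_m <= sq$ll_north + 500))
})

test_that("minimal design and argument validation", {
  d <- generate_design(1, 0, days = 1, seed = 99)
  expect_equal(nrow(d$sites), 2)
  dist <- sqrt(diff(d$sites$easting_m)^2 + diff(d$sites$northing_m)^2)
  expect_true(dist >= 50 && dist <= 70)
  expect_error(generate_design(0, 0, days = 1), "at least one square")
  expect_error(generate_design(2, 0, days = 0), "lie in")
  expect_error(generate_design(-1, 0, days = 5), "lie in")
  expect_error(generate_design(2, 0, days = 5, square_edge = 120), "pair offset")
})

test_that("designs are deterministic given the seed", {
  a <- generate_design(5, 2, days = 10, seed = 3)
  b <- generate_design(5, 2, days = 10, seed = 3)
  c <- generate_design(5, 2, days = 10, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a$sites$easting_m, c$sites$easting_m))
})

test_that("site covariates respect supports and the pair ordering", {
  d <- generate_design(500, 0, days = 1, seed = 5)
  s <- simulate_site_covariates(d, seed = 6, volume_cover_r = 0)
  pairs <- matrix(s$opuntia_cover_pct, nrow = 2)
  expect_true(all(pairs[1, ] > pairs[2, ])) # site 1 strictly higher cover
  pct <- unlist(s[, c("opuntia_cover_pct", "grass_pct", "shrub_pct", "forb_pct", "succulent_pct")])
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(all(s$tree_count >= 0))
  expect_true(all(s$dist_river_m >= 0 & s$dist_road_m >= 0))
  expect_true(all(s$livestock_prop >= 0 & s$livestock_prop <= 1))
  # r = 0: square volume independent of mean site cover (Monte-Carlo bound)
  sq_cover <- colMeans(pairs)
  sq_vol <- s$square_opuntia_vol_m3_per_m[seq(1, nrow(s), by = 2)]
  expect_lt(abs(cor(sq_cover, log(sq_vol))), 3 / sqrt(500))
  # positive correlation when requested
  s2 <- simulate_site_covariates(d, seed = 6, volume_cover_r = 0.7)
  sq_vol2 <- s2$square_opuntia_vol_m3_per_m[seq(1, nrow(s2), by = 2)]
  expect_gt(cor(colMeans(matrix(s2$opuntia_cover_pct, 2)), log(sq_vol2)), 0.4)
})

test_that("degenerate probabilities give all-ones detection histories", {
  d <- generate_design(5, 0, days = 8, seed = 7)
  s <- simulate_site_covariates(d, seed = 8)
  params <- true_parameters(
    alpha_psi = c(35, 35),
    beta_psi = c(opuntia = 0, livestock_prop = 0, dist_river_m = 0, dist_road_m = 0),
    a_cam = c(modelA = 35, modelB = 35), gamma_temp = 0, eta = 0
  )
  sim <- simulate_observations(s, params, seed = 9)
  expect_true(all(sim$observations$detected == 1))
  expect_true(all(sim$truth$z == 1))
})

test_that("null model yields a single homogeneous detection rate", {
  d <- generate_design(100, 0, days = 50, seed = 10)
  s <- simulate_site_covariates(d, seed = 11)
  params <- true_parameters(
    alpha_psi = c(35, 35), # every site occupied
    beta_psi = c(opuntia = 0, livestock_prop = 0, dist_river_m = 0, dist_road_m = 0),
    a_cam = c(modelA = -0.5, modelB = -0.5), gamma_temp = 0, eta = 0
  )
  sim <- simulate_observations(s, params, seed = 12)
  per_site <- sim$observations |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(det = sum(detected), n = dplyr::n())
  # chi-square homogeneity across 200 sites x 50 days
  tab <- cbind(per_site$det, per_site$n - per_site$det)
  pval <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(pval, 0.001)
})

test_that("night counts never exceed daily totals and moments match truth", {
  d <- generate_design(60, 0, days = 40, seed = 13)
  s <- simulate_site_covariates(d, seed = 14)
  params <- true_parameters(
    beta_n = c(opuntia = 0, livestock_prop = 0, dist_river_m = 0, dist_road_m = 0),
    beta_k = c(opuntia = 0, livestock_prop = 0, dist_river_m = 0, dist_road_m = 0),
    beta_lunar = 0, beta_opuntia_x_lunar = 0, eta = 0,
    alpha_n = c(-1, -1), alpha_k = c(0.4, 0.4), phi = 1.5
  )
  sim <- simulate_observations(s, params, seed = 15)
  o <- sim$observations
  expect_true(all(o$night_count <= o$count))
  # method-of-moments recovery at null slopes: mean counts ~ exp(-1)
  n_obs <- nrow(o)
  mu <- exp(-1)
  se_mu <- sqrt((mu + mu^2 / 1.5) / n_obs)
  expect_lt(abs(mean(o$count) - mu), 3 * se_mu)
  # night proportion ~ plogis(0.4)
  tot <- sum(o$count)
  pi0 <- plogis(0.4)
  expect_lt(abs(sum(o$night_count) / tot - pi0), 3 * sqrt(pi0 * (1 - pi0) / tot) + 0.02)
  # NB dispersion: var/mean relationship gives phi back within a wide band
  vm <- var(o$count) / mean(o$count)
  phi_hat <- mean(o$count) / (vm - 1)
  expect_gt(phi_hat, 0.8)
  expect_lt(phi_hat, 2.8)
})

test_that("identity confusion gives unanimous correct votes", {
  labels <- c(focal_species(), "empty")
  ident <- diag(length(labels))
  dimnames(ident) <- list(labels, labels)
  params <- true_parameters(confusion = ident)
  votes <- simulate_votes(c("impala", "leopard", "empty"), params,
    n_volunteers = 12, seed = 16, expert_fraction = 0
  )
  expect_equal(nrow(votes), 36)
  tallies <- votes |> dplyr::count(image_id, label)
  expect_true(all(tallies$n == 12)) # unanimous
  cons <- consensus_classify(votes)
  expect_true(all(cons$entropy == 0))
})

test_that("vote simulation matches the binomial tail for consensus", {
  params <- true_parameters() # 0.9 correct / 0.1 empty rows
  n_img <- 2000
  votes <- simulate_votes(rep("impala", n_img), params,
    n_volunteers = 12, seed = 17, expert_fraction = 0
  )
  cons <- consensus_classify(votes)
  hit <- mean(purrr::map_lgl(cons$species, ~ "impala" %in% .x))
  # P(>= 8 of 12 correct votes): entropy never bites with two labels
  # (max entropy ln 2 < 1), so consensus rate is the pure binomial tail
  p_theory <- pbinom(7, 12, 0.9, lower.tail = FALSE)
  se <- sqrt(p_theory * (1 - p_theory) / n_img)
  expect_lt(abs(hit - p_theory), 3 * se)
})

test_that("a full synthetic study is deterministic and schema-clean", {
  a <- tiny_study(seed = 20)
  b <- tiny_study(seed = 20)
  expect_identical(a$sites, b$sites)
  expect_identical(a$observations, b$observations)
  expect_identical(a$votes, b$votes)
  expect_equal(unique(a$votes |> dplyr::count(image_id, volunteer_id) |> dplyr::pull(n)), 1)
  dir <- withr::local_tempdir()
  write_study(a, dir)
  v <- validate_tables(list(
    sites = file.path(dir, "sites.csv"),
    observations = file.path(dir, "observations.csv"),
    transects = file.path(dir, "transects.csv"),
    votes = file.path(dir, "votes.csv")
  ))
  expect_equal(nrow(v), 0)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_true(all(unlist(truth$latent$impala$z) %in% c(0, 1)))
})

test_that("malformed generative parameters are rejected", {
  expect_error(true_parameters(phi = 0), "lie in")
  expect_error(true_parameters(rho = -1), "lie in")
  cm <- matrix(c(0.5, 0.2, 0.4, 0.8), 2,
    dimnames = list(c("a", "empty"), c("a", "empty"))
  )
  expect_error(true_parameters(confusion = cm, species = "a"), "summing to 1")
})
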
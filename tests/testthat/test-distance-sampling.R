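test_that("half-normal detection has unit intercept and known shape", {
  expect_equal(halfnormal_g(0, 3), 1)
  expect_equal(halfnormal_g(4, 4), exp(-0.5))
  grid <- seq(0, 20, by = 0.5)
  expect_true(all(diff(halfnormal_g(grid, 5)) < 0))
  expect_error(halfnormal_g(-1, 2), "lie in")
  expect_error(halfnormal_g(1, 0), "lie in")
})

test_that("bin detection probabilities agree with adaptive quadrature", {
  for (sigma in c(0.5, 2, 4, 10)) {
    for (breaks in list(0:10, c(0, 2, 5, 10), seq(0, 20, by = 4))) {
      bp <- bin_detection_probs(breaks, sigma)
      B <- max(breaks)
      quad <- vapply(seq_len(length(breaks) - 1), function(c) {
        stats::integrate(function(x) exp(-x^2 / (2 * sigma^2)) / B,
          breaks[c], breaks[c + 1],
          rel.tol = 1e-12
        )$value
      }, 0)
      expect_lt(max(abs(bp$cell_probs - quad)), 1e-8)
      expect_lt(abs(sum(bp$cell_probs) + bp$undetected - 1), 1e-12)
    }
  }
})

test_that("perfect detection limit: cells proportional to bin widths", {
  breaks <- c(0, 1, 3, 6, 10)
  bp <- bin_detection_probs(breaks, sigma = 1e6)
  expect_equal(bp$cell_probs, diff(breaks) / max(breaks), tolerance = 1e-9)
  expect_equal(bp$p_detect, 1, tolerance = 1e-9)
})

test_that("Poisson-multinomial likelihood equals explicit marginalization", {
  breaks <- 0:5
  y <- c(4, 3, 1, 1, 0)
  for (lambda in c(2, 10, 25)) {
    for (sigma in c(1, 2.5)) {
      expect_equal(
        ds_log_likelihood(y, breaks, lambda, sigma),
        oracle_ds_loglik(y, breaks, lambda, sigma, nmax = 500),
        tolerance = 1e-8
      )
    }
  }
})

test_that("distance likelihood edge cases", {
  breaks <- 0:4
  expect_equal(ds_log_likelihood(rep(0, 4), breaks, 0, 2), 0)
  # counts in a zero-probability cell: -Inf, not an exception
  expect_identical(ds_log_likelihood(c(0, 0, 0, 3), breaks, 0, 2), -Inf)
  # invariance to relabelling bins together with their counts
  y <- c(5, 2, 1, 0)
  ll <- ds_log_likelihood(y, breaks, 8, 2)
  # swapping equal-width bins 2 and 3 with their counts changes nothing
  # beyond the cell probabilities moving with the counts:
  pi_c <- bin_detection_probs(breaks, 2)$cell_probs
  perm <- c(1, 3, 2, 4)
  ll_perm <- sum(dpois(y[perm], 8 * pi_c[perm], log = TRUE))
  expect_equal(ll, ll_perm, tolerance = 1e-12)
  expect_error(ds_log_likelihood(c(1.5, 0, 0, 0), breaks, 1, 1), "integers")
})

test_that("likelihood is concave in log lambda at fixed sigma", {
  breaks <- 0:8
  y <- c(6, 5, 3, 2, 1, 0, 0, 1)
  ll <- vapply(
    seq(log(1), log(100), length.out = 60),
    function(ll) ds_log_likelihood(y, breaks, exp(ll), 3), 0
  )
  expect_true(all(diff(diff(ll)) < 1e-8))
})

test_that("hemisphere volumes reproduce the stored per-stand constants", {
  k <- opuntia_volume_constants()
  expect_equal(round(hemisphere_volume(2.5), 3), k[["L"]]) # 32.725
  expect_equal(round(hemisphere_volume(1.5), 2), round(k[["M"]], 2)) # 7.07
  expect_equal(round(hemisphere_volume(0.5), 2), round(k[["S"]], 2)) # 0.26
})

test_that("volume arithmetic and square metrics", {
  expect_equal(volume_from_counts(0, 0, 1), 32.725)
  expect_equal(volume_from_counts(0, 0, 0), 0)
  expect_equal(volume_from_counts(1, 1, 1), 0.260 + 7.070 + 32.725)
  expect_error(volume_from_counts(-1, 0, 0), "lie in")
  m <- square_volume_metrics(65.45, 500)
  expect_equal(m$vol_per_m, 0.1309)
  expect_equal(m$total_vol_m3, 65.45)
  expect_equal(square_volume_metrics(0, 100)$vol_per_m, 0)
  expect_equal(
    square_volume_metrics(10, 200)$vol_per_m,
    square_volume_metrics(10, 100)$vol_per_m / 2
  )
  expect_error(square_volume_metrics(1, 0), "lie in")
})

test_that("simulated transects hit the perfect-detection and empty limits", {
  des <- generate_design(10, 0, days = 1, seed = 3)
  p_perfect <- true_parameters(sigma = c(S = 1e6, M = 1e6, L = 1e6))
  tr <- simulate_transects(des, p_perfect, seed = 4)
  truth <- attr(tr, "truth")
  got <- tr |>
    dplyr::group_by(square_id, size_class) |>
    dplyr::summarise(n = sum(count), .groups = "drop") |>
    dplyr::arrange(square_id, size_class)
  truth <- dplyr::arrange(truth, square_id, size_class)
  expect_equal(got$n, truth$n_true)

  p_zero <- true_parameters(density = c(S = 0, M = 0, L = 0))
  tr0 <- simulate_transects(des, p_zero, seed = 5)
  expect_true(all(tr0$count == 0))
})

test_that("empirical bin proportions match quadrature within 3 SE", {
  # one square, very high density ~ 1e5 stands
  des <- generate_design(1, 0, days = 1, seed = 1)
  params <- true_parameters(
    density = c(S = 1e5, M = 1, L = 1),
    sigma = c(S = 3, M = 3, L = 3)
  )
  tr <- simulate_transects(des, params, seed = 9)
  ncl <- tr[tr$size_class == "S", ]
  n_true <- attr(tr, "truth")
  N <- n_true$n_true[n_true$size_class == "S"]
  bp <- bin_detection_probs(0:10, 3)
  for (c in seq_len(10)) {
    p <- bp$cell_probs[c]
    se <- sqrt(p * (1 - p) / N)
    expect_lt(abs(ncl$count[c] / N - p), 3 * se + 1e-12)
  }
})

test_that("zero-count size classes give a clean error before sampling", {
  des <- generate_design(5, 0, days = 1, seed = 2)
  params <- true_parameters(density = c(S = 30, M = 30, L = 0))
  tr <- simulate_transects(des, params, seed = 2)
  expect_error(fit_distance_model(tr), "unidentifiable")
})

test_that("distance fit recovers truth on a small simulation", {
  des <- generate_design(40, 0, days = 1, seed = 21)
  params <- true_parameters(
    sigma = c(S = 4, M = 4, L = 4),
    density = c(S = 30, M = 30, L = 30)
  )
  tr <- simulate_transects(des, params, seed = 22)
  fit <- fit_distance_model(tr[tr$size_class == "S", ],
    chains = 2, warmup = 400, iters = 400, seed = 23
  )
  td <- tidy(fit)
  sig <- td[td$parameter == "sigma_m", ]
  lam <- td[td$parameter == "lambda", ]
  expect_true(sig$q5 < 4 * 1.35 && sig$q95 > 4 / 1.35)
  expect_true(lam$q5 < 30 * 1.35 && lam$q95 > 30 / 1.35)
  vols <- square_opuntia_volumes(fit)
  expect_equal(nrow(vols), 40)
  expect_true(all(vols$vol_per_m >= 0))
  expect_equal(vols$total_vol_m3, vols$vol_per_m * 500)
})
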
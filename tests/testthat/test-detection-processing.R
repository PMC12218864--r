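test_that("detector-score filtering respects inclusive thresholds", {
  rec <- tibble::tibble(
    image_id = sprintf("i%d", 1:5),
    animal_score = c(0.98, 0.979, 0.999, 0.5, 0.99),
    human_score = c(0, 0, 0.10, 0.5, 0.09),
    vehicle_score = 0,
    confirmed_human = c(NA, NA, TRUE, FALSE, NA)
  )
  out <- filter_detector_scores(rec)
  expect_equal(out$status, c("retained", "not_retained", "dropped", "not_retained", "retained"))
  expect_equal(out$needs_screening, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_error(
    filter_detector_scores(dplyr::mutate(rec, animal_score = animal_score * 2)),
    "lie in"
  )
})

test_that("Shannon entropy closed forms and properties", {
  expect_equal(shannon_entropy(c(12)), 0)
  expect_equal(shannon_entropy(c(6, 6)), log(2))
  expect_equal(shannon_entropy(c(4, 4, 4)), log(3))
  expect_equal(shannon_entropy(c(6, 6), base = 2), 1)
  # permutation invariance and the log(#labels) bound
  set.seed(2)
  for (i in 1:20) {
    counts <- rpois(sample(2:6, 1), 4) + 1
    H <- shannon_entropy(counts)
    expect_equal(H, shannon_entropy(sample(counts)))
    expect_gte(H, 0)
    expect_lte(H, log(length(counts)) + 1e-12)
  }
  expect_error(shannon_entropy(c(0, 0)), "empty")
})

make_votes <- function(labels, image_id = "img1", expert = NA_character_) {
  tibble::tibble(
    image_id = image_id,
    volunteer_id = sprintf("v%02d", seq_along(labels)),
    label = labels,
    expert_label = expert
  )
}

test_that("consensus thresholds, entropy discard and expert override", {
  # 8 of 12 for elephant: 0.667 >= 0.66, entropy 0.637 <= 1 -> present
  v <- make_votes(c(rep("elephant", 8), rep("empty", 4)))
  out <- consensus_classify(v)
  expect_identical(out$species[[1]], "elephant")
  expect_identical(out$status, "consensus")
  expect_equal(out$entropy, -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3)), tolerance = 1e-12)

  # 7 of 12 misses the threshold
  v7 <- make_votes(c(rep("elephant", 7), rep("empty", 5)))
  out7 <- consensus_classify(v7)
  expect_length(out7$species[[1]], 0)
  expect_identical(out7$status, "no_consensus")

  # 4/4/4 three-way split: entropy log(3) > 1 -> discarded
  v3 <- make_votes(rep(c("impala", "dikdik", "empty"), each = 4))
  out3 <- consensus_classify(v3)
  expect_identical(out3$status, "discarded_entropy")
  expect_length(out3$species[[1]], 0)
  expect_equal(out3$entropy, log(3), tolerance = 1e-12)

  # expert override beats both rules
  ve <- make_votes(rep(c("impala", "dikdik", "empty"), each = 4), expert = "leopard")
  oute <- consensus_classify(ve)
  expect_identical(oute$status, "expert")
  expect_identical(oute$species[[1]], "leopard")

  expect_error(consensus_classify(v, species_threshold = 0), "0, 1")
  expect_error(consensus_classify(v, species_threshold = 1.2), "0, 1")
})

test_that("adding a supporting vote never removes a species", {
  set.seed(3)
  labels <- c("impala", "dikdik", "empty")
  for (i in 1:30) {
    base <- sample(labels, 12, replace = TRUE, prob = c(0.7, 0.2, 0.1))
    before <- consensus_classify(make_votes(base))
    after <- consensus_classify(make_votes(c(base, "impala")))
    if ("impala" %in% before$species[[1]] && after$status != "discarded_entropy") {
      expect_true("impala" %in% after$species[[1]])
    }
  }
})

test_that("statuses partition the uploaded images", {
  st <- tiny_study(seed = 31)
  cons <- consensus_classify(st$votes)
  expect_equal(nrow(cons), length(unique(st$votes$image_id)))
  expect_true(all(cons$status %in% c("consensus", "no_consensus", "discarded_entropy", "expert")))
  expect_equal(sum(table(cons$status)), nrow(cons))
  expect_true(all(cons$n_volunteers == 12))
})

test_that("identity confusion recovers the truth for every image", {
  labels <- c(focal_species(), "empty")
  ident <- diag(length(labels))
  dimnames(ident) <- list(labels, labels)
  truth <- sample(c("impala", "leopard", "buffalo"), 50, replace = TRUE)
  votes <- simulate_votes(truth, true_parameters(confusion = ident),
    seed = 4, expert_fraction = 0
  )
  cons <- consensus_classify(votes) |> dplyr::arrange(image_id)
  expect_true(all(cons$status == "consensus"))
  expect_identical(unlist(cons$species), truth[order(sprintf("img%06d", seq_along(truth)))])
})

test_that("sensitivity and specificity definitions", {
  # consensus identical to expert -> perfect scores
  cons <- tibble::tibble(
    image_id = sprintf("i%d", 1:6),
    species = list("impala", character(), "leopard", character(), "impala", character()),
    status = "consensus", entropy = 0, n_volunteers = 12
  )
  expert <- tibble::tibble(
    image_id = cons$image_id,
    expert_species = cons$species
  )
  acc <- classification_accuracy(cons, expert)
  expect_true(all(acc$sensitivity == 1))
  expect_true(all(acc$specificity == 1))

  # counting arithmetic: TP=97, FN=3, TN=998, FP=2
  n <- 1100
  truth <- c(rep(TRUE, 100), rep(FALSE, 1000))
  called <- c(rep(TRUE, 97), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 998))
  cons2 <- tibble::tibble(
    image_id = sprintf("i%d", 1:n),
    species = purrr::map(called, ~ if (.x) "impala" else character()),
    status = "consensus", entropy = 0, n_volunteers = 12
  )
  expert2 <- tibble::tibble(
    image_id = cons2$image_id,
    expert_species = purrr::map(truth, ~ if (.x) "impala" else character())
  )
  acc2 <- classification_accuracy(cons2, expert2, species = "impala")
  expect_equal(acc2$sensitivity, 0.97)
  expect_equal(acc2$specificity, 0.998)

  # a species with no expert positives: sensitivity missing, specificity valid
  acc3 <- classification_accuracy(cons2, expert2, species = "leopard")
  expect_true(is.na(acc3$sensitivity))
  expect_equal(acc3$specificity, 1)

  # expert-status images are excluded from the audit
  cons_exp <- dplyr::mutate(cons2, status = "expert")
  acc4 <- classification_accuracy(cons_exp, expert2, species = "impala")
  expect_equal(acc4$tp + acc4$fn + acc4$fp + acc4$tn, 0)
})

test_that("detection histories count days, nights and inactive periods", {
  deployments <- tibble::tibble(
    site_id = "s1", deploy_start = as.Date("2021-02-01"), deploy_days = 10L
  )
  # three detections on Feb 3 (local), one of them at night (22:00 local)
  det <- tibble::tibble(
    image_id = c("a", "b", "c"),
    site_id = "s1",
    timestamp = as.POSIXct(
      c("2021-02-03 07:00:00", "2021-02-03 12:00:00", "2021-02-03 19:00:00"),
      tz = "UTC"
    ), # 10:00, 15:00, 22:00 local
    species = "impala"
  )
  hist <- build_detection_histories(det, deployments, "impala")
  expect_equal(nrow(hist), 10)
  day3 <- hist[hist$date == as.Date("2021-02-03"), ]
  expect_equal(day3$count, 3)
  expect_equal(day3$night_count, 1)
  expect_equal(day3$detected, 1)
  expect_true(all(hist$count[hist$date != as.Date("2021-02-03")] == 0))

  # no detections at all: ten zero rows
  empty <- build_detection_histories(det[0, ], deployments, "impala")
  expect_equal(nrow(empty), 10)
  expect_true(all(empty$detected == 0))

  # a detection outside the deployment is an error naming the record
  late <- dplyr::mutate(det, timestamp = timestamp + 40 * 86400)
  expect_error(build_detection_histories(late, deployments, "impala"), "outside deployment")
})

test_that("a detection at exactly dawn is classified as day", {
  deployments <- tibble::tibble(
    site_id = "s1", deploy_start = as.Date("2021-02-01"), deploy_days = 3L
  )
  dawn <- sun_times(as.Date("2021-02-02"), 0.3, 36.9)$dawn
  det <- tibble::tibble(
    image_id = "a", site_id = "s1", timestamp = dawn, species = "impala"
  )
  hist <- build_detection_histories(det, deployments, "impala")
  row <- hist[hist$count > 0, ]
  expect_equal(row$night_count, 0)
})
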
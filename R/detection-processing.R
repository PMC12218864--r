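## From raw detector scores and volunteer votes to detection histories.
##
## Images pass a detector-score filter (animal score >= 0.98 auto-retained;
## human/vehicle score >= 0.10 flagged for manual screening and dropped when
## confirmed), then volunteer votes are aggregated: a species is declared
## present when at least 66% of the image's volunteers voted for it, images
## whose vote distribution has Shannon entropy above 1 are discarded, and an
## expert label overrides everything.

#' Filter detector scores
#'
#' @param records tibble with columns `image_id`, `animal_score`,
#'   `human_score`, `vehicle_score` in `[0, 1]`, and optionally
#'   `confirmed_human` (logical result of manual screening).
#' @param animal_thr animal-score retention threshold (inclusive).
#' @param human_thr human/vehicle screening threshold (inclusive).
#' @return The records with `needs_screening` (flagged for manual review)
#'   and `status` in `retained` / `dropped` / `not_retained`. Flagged
#'   records with `confirmed_human = TRUE` are `dropped`; flagged records
#'   confirmed clean follow the animal-score rule.
#' @export
filter_detector_scores <- function(records, animal_thr = 0.98, human_thr = 0.10) {
  for (col in c("animal_score", "human_score", "vehicle_score")) {
    if (!col %in% names(records)) stopf("`records` lacks column `%s`", col)
    check_number(records[[col]], col, 0, 1)
  }
  confirmed <- records$confirmed_human %||% rep(NA, nrow(records))
  records |>
    dplyr::mutate(
      needs_screening = .data$human_score >= human_thr | .data$vehicle_score >= human_thr,
      status = dplyr::case_when(
        needs_screening & !is.na(confirmed) & confirmed ~ "dropped",
        .data$animal_score >= animal_thr ~ "retained",
        TRUE ~ "not_retained"
      )
    )
}

#' Shannon entropy of a vote distribution
#'
#' `H = -sum(q * log(q))` over labels with positive counts, where `q` are
#' vote proportions. Natural log by default; pass `base = 2` for bits.
#'
#' @param counts non-negative vote counts (named or not); total must be > 0.
#' @param base logarithm base (default `exp(1)`, nats).
#' @return Entropy `H >= 0`.
#' @export
#' @examples
#' shannon_entropy(c(6, 6)) # log(2)
shannon_entropy <- function(counts, base = exp(1)) {
  check_number(counts, "counts", lower = 0)
  total <- sum(counts)
  if (total == 0) stopf("entropy is undefined for an empty vote distribution")
  q <- counts[counts > 0] / total
  -sum(q * log(q, base = base))
}

#' Consensus classification of volunteer votes
#'
#' Per image: a species is declared present iff at least
#' `species_threshold` of the image's volunteers voted for it (inclusive);
#' an image whose vote distribution has entropy above `entropy_max` is
#' discarded regardless; an expert label, where present, overrides both
#' rules. `"empty"` votes count toward the denominator and the entropy but
#' never yield a species.
#'
#' @param votes long tibble: `image_id`, `volunteer_id`, `label`, optional
#'   `expert_label` (NA where absent).
#' @param species_threshold consensus threshold in (0, 1]; default 0.66.
#' @param entropy_max entropy discard threshold (strictly above discards).
#' @param base entropy log base.
#' @return Tibble per image: `species` (list column, possibly empty),
#'   `status` in `consensus` / `no_consensus` / `discarded_entropy` /
#'   `expert`, `entropy`, `n_volunteers`.
#' @export
consensus_classify <- function(votes, species_threshold = 0.66,
                               entropy_max = 1.0, base = exp(1)) {
  if (species_threshold <= 0 || species_threshold > 1) {
    stopf("`species_threshold` must lie in (0, 1]")
  }
  if (!all(c("image_id", "volunteer_id", "label") %in% names(votes))) {
    stopf("`votes` needs columns image_id, volunteer_id, label")
  }
  if (!"expert_label" %in% names(votes)) votes$expert_label <- NA_character_

  per_image <- votes |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(n_volunteers = dplyr::n_distinct(.data$volunteer_id))
  tallies <- votes |>
    dplyr::count(.data$image_id, .data$label) |>
    dplyr::left_join(per_image, by = "image_id")
  entropies <- tallies |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(entropy = {
      q <- .data$n / sum(.data$n)
      -sum(q * log(q, base = base))
    })
  hits <- tallies |>
    dplyr::filter(.data$n / .data$n_volunteers >= species_threshold) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      any_hit = dplyr::n() > 0,
      hit_species = list(sort(setdiff(.data$label, "empty")))
    )
  experts <- votes |>
    dplyr::filter(!is.na(.data$expert_label)) |>
    dplyr::distinct(.data$image_id, .data$expert_label) |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(expert_species = list(sort(setdiff(.data$expert_label, "empty"))))

  out <- per_image |>
    dplyr::left_join(entropies, by = "image_id") |>
    dplyr::left_join(hits, by = "image_id") |>
    dplyr::left_join(experts, by = "image_id")
  is_expert <- !purrr::map_lgl(out$expert_species, is.null)
  any_hit <- !is.na(out$any_hit) & out$any_hit
  discard <- out$entropy > entropy_max
  status <- dplyr::case_when(
    is_expert ~ "expert",
    discard ~ "discarded_entropy",
    any_hit ~ "consensus",
    TRUE ~ "no_consensus"
  )
  species <- purrr::pmap(
    list(status, out$hit_species, out$expert_species),
    function(st, hs, es) {
      switch(st,
        expert = es,
        consensus = hs,
        character()
      )
    }
  )
  tibble::tibble(
    image_id = out$image_id, species = species, status = status,
    entropy = out$entropy, n_volunteers = out$n_volunteers
  )
}

#' Sensitivity and specificity of consensus classifications
#'
#' Image-level presence/absence agreement between consensus and expert
#' labels, per species, over the expert-labelled subset. Images whose
#' consensus *is* the expert label (status `expert`) are excluded — the
#' audit never compares the expert with itself.
#'
#' @param consensus output of [consensus_classify()].
#' @param expert tibble `image_id`, `expert_species` (list column or
#'   character).
#' @param species species to evaluate (default: all expert species).
#' @return Tibble per species: TP/FP/TN/FN counts, `sensitivity`
#'   (`NA` when the species has no expert positives), `specificity`.
#' @export
classification_accuracy <- function(consensus, expert, species = NULL) {
  if (!nrow(expert)) stopf("expert subset is empty")
  if (!is.list(expert$expert_species)) {
    expert$expert_species <- as.list(expert$expert_species)
  }
  eval_set <- consensus |>
    dplyr::filter(.data$status != "expert") |>
    dplyr::inner_join(expert, by = "image_id")
  species <- species %||% sort(unique(unlist(expert$expert_species)))
  species <- setdiff(species, "empty")
  purrr::map_dfr(species, function(sp) {
    truth <- purrr::map_lgl(eval_set$expert_species, ~ sp %in% .x)
    called <- purrr::map_lgl(eval_set$species, ~ sp %in% .x)
    tp <- sum(truth & called)
    fn <- sum(truth & !called)
    fp <- sum(!truth & called)
    tn <- sum(!truth & !called)
    tibble::tibble(
      species = sp, tp = tp, fp = fp, tn = tn, fn = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  })
}

#' Build per-species detection histories
#'
#' Converts consensus detections into the site x day observation table one
#' species at a time: `detected` is 1 on days with at least one detection,
#' `count` is the number of detection events, `night_count` those strictly
#' after dusk / before dawn ([is_night()]); days outside a site's deployment
#' are `NA`. Days are binned on the local civil date.
#'
#' @param detections tibble `image_id`, `site_id`, `timestamp`, `species`
#'   (character or list column).
#' @param deployments tibble `site_id`, `deploy_start` (Date),
#'   `deploy_days`.
#' @param species single species to build histories for.
#' @param lat,lon reference coordinates for the day/night boundary (defaults
#'   to the study area; dawn/dusk vary by under 2 minutes across it).
#' @param tz_offset_hours local civil-day offset from UTC.
#' @return Observation tibble: `site_id`, `date`, `detected`, `count`,
#'   `night_count`.
#' @export
build_detection_histories <- function(detections, deployments, species,
                                      lat = 0.3, lon = 36.9,
                                      tz_offset_hours = 3) {
  if (is.list(detections$species)) {
    keep <- purrr::map_lgl(detections$species, ~ species %in% .x)
  } else {
    keep <- detections$species == species
  }
  det <- detections[keep, ]
  # referential check: every detection inside its deployment window
  if (nrow(det)) {
    dep <- deployments[match(det$site_id, deployments$site_id), ]
    if (anyNA(dep$site_id)) {
      stopf("detections at unknown site(s): %s", paste(
        unique(det$site_id[is.na(dep$site_id)]),
        collapse = ", "
      ))
    }
    ldate <- as.Date(det$timestamp + tz_offset_hours * 3600)
    out_of_window <- ldate < dep$deploy_start |
      ldate > dep$deploy_start + dep$deploy_days - 1L
    if (any(out_of_window)) {
      stopf(
        "detection outside deployment: image %s at %s on %s",
        det$image_id[out_of_window][1], det$site_id[out_of_window][1],
        format(ldate[out_of_window][1])
      )
    }
    det$date <- ldate
    det$night <- is_night(det$timestamp, lat, lon, tz_offset_hours = tz_offset_hours)
  }
  grid <- deployments |>
    dplyr::rowwise() |>
    dplyr::reframe(
      site_id = .data$site_id,
      date = .data$deploy_start + seq_len(.data$deploy_days) - 1L
    )
  daily <- if (nrow(det)) {
    det |>
      dplyr::count(.data$site_id, .data$date, wt = NULL, name = "count") |>
      dplyr::left_join(
        det |> dplyr::filter(.data$night) |> dplyr::count(.data$site_id, .data$date, name = "night_count"),
        by = c("site_id", "date")
      )
  } else {
    tibble::tibble(
      site_id = character(), date = as.Date(character()),
      count = integer(), night_count = integer()
    )
  }
  grid |>
    dplyr::left_join(daily, by = c("site_id", "date")) |>
    dplyr::mutate(
      count = dplyr::coalesce(.data$count, 0L),
      night_count = dplyr::coalesce(.data$night_count, 0L),
      detected = as.integer(.data$count > 0)
    ) |>
    dplyr::select("site_id", "date", "detected", "count", "night_count")
}

#' Proportion of active days with livestock detections
#'
#' The site-level livestock covariate: the share of deployment days on which
#' at least one livestock image was consensus-classified.
#'
#' @inheritParams build_detection_histories
#' @param livestock_label label counted as livestock.
#' @return Tibble `site_id`, `livestock_prop`.
#' @export
livestock_proportion <- function(detections, deployments,
                                 livestock_label = "livestock",
                                 tz_offset_hours = 3) {
  hist <- build_detection_histories(
    detections, deployments, livestock_label,
    tz_offset_hours = tz_offset_hours
  )
  hist |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(livestock_prop = mean(.data$detected, na.rm = TRUE))
}
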
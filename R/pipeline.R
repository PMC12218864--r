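## End-to-end orchestration with a manifest and content-hash caching.
##
## Stage order: simulate -> consensus -> histories; transects -> square
## volumes; DAG -> covariate sets; fits -> effect report. Each stage records
## its input file hashes in `manifest.json`; a rerun with unchanged inputs
## and parameters skips the stage.

#' Pipeline configuration
#'
#' @param out_dir run directory (created if needed).
#' @param seed master seed; all stage seeds derive from it.
#' @param species species to simulate and fit.
#' @param n_squares_s1,n_squares_s2,days study dimensions for the simulate
#'   stage.
#' @param models model types to fit (`"occupancy"`, `"count"`, `"night"`).
#' @param exposure_scale exposure scale for the fits.
#' @param chains,warmup,iters sampler settings for the fit stage (kept small
#'   by default: the pipeline smoke-scale run is a correctness check, not an
#'   inference run).
#' @param consensus_threshold,entropy_max consensus stage settings.
#' @param stages stages to run, in order.
#' @param gp fit the spatial GP in the fit stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            species = c("impala", "olive_baboon", "leopard"),
                            n_squares_s1 = 20, n_squares_s2 = 0, days = 30,
                            models = "count",
                            exposure_scale = "site",
                            chains = 2, warmup = 400, iters = 400,
                            consensus_threshold = 0.66, entropy_max = 1.0,
                            gp = FALSE,
                            stages = c(
                              "simulate", "consensus", "histories",
                              "distance", "adjust", "fit", "report"
                            )) {
  structure(
    list(
      out_dir = out_dir, seed = seed, species = species,
      n_squares_s1 = n_squares_s1, n_squares_s2 = n_squares_s2, days = days,
      models = models, exposure_scale = exposure_scale,
      chains = chains, warmup = warmup, iters = iters,
      consensus_threshold = consensus_threshold, entropy_max = entropy_max,
      gp = gp, stages = stages
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @param ... overrides applied after reading.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

.hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  h <- tools::md5sum(paths)
  setNames(as.vector(h), basename(paths))
}

.stage_fresh <- function(manifest, stage, inputs, params_hash, outputs) {
  rec <- manifest[[stage]]
  if (is.null(rec) || !identical(rec$status, "ok")) {
    return(FALSE)
  }
  if (!identical(rec$params_hash, params_hash)) {
    return(FALSE)
  }
  in_now <- .hash_files(inputs)
  if (!identical(as.list(in_now), rec$inputs)) {
    return(FALSE)
  }
  all(file.exists(outputs))
}

#' Run the pipeline
#'
#' Executes the configured stages in dependency order, writing all artefacts
#' and `manifest.json` (stage status, seeds, input hashes, wall time) into
#' the run directory. Stages whose inputs and parameters are unchanged since
#' the recorded run are skipped; a stage failure halts downstream stages and
#' is recorded in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (list), invisibly; artefacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(config$out_dir, ...)
  manifest_path <- pth("manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list()
  }

  run_stage <- function(stage, inputs, outputs, params, fn) {
    params_hash <- paste(deparse(params), collapse = "")
    if (.stage_fresh(manifest, stage, inputs, params_hash, outputs)) {
      message(sprintf("[%s] up to date, skipped", stage))
      manifest[[stage]]$skipped <<- TRUE
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    message(sprintf("[%s] running (seed %d)", stage, config$seed))
    ok <- TRUE
    err <- NULL
    tryCatch(fn(), error = function(e) {
      ok <<- FALSE
      err <<- conditionMessage(e)
    })
    manifest[[stage]] <<- list(
      status = if (ok) "ok" else "failed",
      error = err,
      seed = config$seed,
      params_hash = params_hash,
      inputs = as.list(.hash_files(inputs)),
      outputs = as.list(.hash_files(outputs)),
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      skipped = FALSE
    )
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, null = "null")
    if (!ok) stopf("stage `%s` failed: %s; downstream stages halted", stage, err)
  }

  want <- function(s) s %in% config$stages

  if (want("simulate")) {
    run_stage(
      "simulate",
      inputs = character(),
      outputs = pth(c(
        "sites.csv", "observations.csv", "transects.csv",
        "votes.csv", "images.csv", "truth.json"
      )),
      params = config[c("seed", "species", "n_squares_s1", "n_squares_s2", "days")],
      fn = function() {
        study <- simulate_study(
          params = true_parameters(),
          species = config$species, seed = config$seed,
          n_squares_s1 = config$n_squares_s1,
          n_squares_s2 = config$n_squares_s2, days = config$days
        )
        write_study(study, config$out_dir)
      }
    )
  }

  if (want("consensus")) {
    run_stage(
      "consensus",
      inputs = pth(c("votes.csv", "images.csv")),
      outputs = pth("detections.csv"),
      params = config[c("consensus_threshold", "entropy_max")],
      fn = function() {
        votes <- readr::read_csv(pth("votes.csv"), show_col_types = FALSE)
        images <- readr::read_csv(pth("images.csv"), show_col_types = FALSE)
        cons <- consensus_classify(
          votes,
          species_threshold = config$consensus_threshold,
          entropy_max = config$entropy_max
        )
        detections <- cons |>
          tidyr::unnest_longer("species", values_to = "species") |>
          dplyr::inner_join(
            images[, c("image_id", "site_id", "timestamp")],
            by = "image_id"
          ) |>
          dplyr::select("image_id", "site_id", "timestamp", "species", "status")
        readr::write_csv(detections, pth("detections.csv"))
      }
    )
  }

  if (want("histories")) {
    run_stage(
      "histories",
      inputs = pth(c("detections.csv", "sites.csv", "observations.csv")),
      outputs = pth("observations_consensus.csv"),
      params = list(config$species),
      fn = function() {
        detections <- readr::read_csv(pth("detections.csv"), show_col_types = FALSE)
        sites <- readr::read_csv(pth("sites.csv"), show_col_types = FALSE)
        env <- readr::read_csv(pth("observations.csv"), show_col_types = FALSE) |>
          dplyr::distinct(.data$site_id, .data$date, .data$temp_c, .data$lunar_frac)
        hist <- purrr::map_dfr(config$species, function(sp) {
          build_detection_histories(detections, sites, sp) |>
            dplyr::mutate(species = sp, .before = 1)
        })
        hist |>
          dplyr::left_join(env, by = c("site_id", "date")) |>
          readr::write_csv(pth("observations_consensus.csv"))
      }
    )
  }

  if (want("distance")) {
    run_stage(
      "distance",
      inputs = pth("transects.csv"),
      outputs = pth("square_opuntia.csv"),
      params = config["seed"],
      fn = function() {
        transects <- readr::read_csv(pth("transects.csv"), show_col_types = FALSE)
        fit <- fit_distance_model(
          transects,
          chains = 2, warmup = 400, iters = 400,
          seed = config$seed
        )
        readr::write_csv(square_opuntia_volumes(fit), pth("square_opuntia.csv"))
      }
    )
  }

  if (want("adjust")) {
    run_stage(
      "adjust",
      inputs = character(),
      outputs = pth("adjustment_sets.json"),
      params = list(),
      fn = function() {
        sets <- total_effect_sets(habitat_dag())
        jsonlite::write_json(sets, pth("adjustment_sets.json"))
      }
    )
  }

  if (want("fit")) {
    run_stage(
      "fit",
      inputs = pth(c("observations_consensus.csv", "sites.csv")),
      outputs = pth("fit_summaries.csv"),
      params = config[c("models", "exposure_scale", "chains", "warmup", "iters", "seed", "gp")],
      fn = function() {
        obs <- readr::read_csv(pth("observations_consensus.csv"), show_col_types = FALSE)
        sites <- readr::read_csv(pth("sites.csv"), show_col_types = FALSE)
        combos <- tidyr::expand_grid(species = config$species, model = config$models)
        summaries <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
          sp <- combos$species[i]
          fit <- fit_habitat_model(
            obs[obs$species == sp, ], sites,
            response = combos$model[i],
            exposure_scale = config$exposure_scale,
            gp = config$gp,
            chains = config$chains, warmup = config$warmup,
            iters = config$iters, seed = config$seed + i
          )
          dplyr::mutate(summarise_effects(fit, sp), .before = 1)
        })
        readr::write_csv(summaries, pth("fit_summaries.csv"))
      }
    )
  }

  if (want("report")) {
    run_stage(
      "report",
      inputs = pth("fit_summaries.csv"),
      outputs = pth("effects.csv"),
      params = list(),
      fn = function() {
        summaries <- readr::read_csv(pth("fit_summaries.csv"), show_col_types = FALSE)
        readr::write_csv(summaries, pth("effects.csv"))
        readr::write_csv(effect_matrix(summaries), pth("effect_matrix.csv"))
      }
    )
  }

  invisible(manifest)
}

## ---- table validation ----

.violation <- function(table, check, message) {
  tibble::tibble(table = table, check = check, message = message)
}

#' Validate pipeline tables
#'
#' Schema, range and referential-integrity checks over the CSV artefacts.
#' Reports violations as a tibble; it never raises.
#'
#' @param paths named list/vector of file paths; recognised names are
#'   `sites`, `observations`, `transects`, `votes`.
#' @return Tibble of violations (`table`, `check`, `message`); zero rows
#'   when everything is clean.
#' @export
validate_tables <- function(paths) {
  v <- list()
  add <- function(x) v[[length(v) + 1]] <<- x
  tabs <- list()
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      add(.violation(nm, "exists", sprintf("file not found: %s", paths[[nm]])))
    } else {
      tabs[[nm]] <- readr::read_csv(paths[[nm]], show_col_types = FALSE)
    }
  }
  need <- list(
    sites = c(
      "site_id", "square_id", "season", "easting_m", "northing_m",
      "camera_model", "opuntia_cover_pct"
    ),
    observations = c("site_id", "date", "detected", "count", "night_count"),
    transects = c("square_id", "size_class", "bin_lo_m", "bin_hi_m", "count"),
    votes = c("image_id", "volunteer_id", "label")
  )
  for (nm in names(tabs)) {
    if (!is.null(need[[nm]])) {
      missing <- setdiff(need[[nm]], names(tabs[[nm]]))
      if (length(missing)) {
        add(.violation(nm, "schema", sprintf("missing column(s): %s", paste(missing, collapse = ", "))))
      }
    }
  }
  s <- tabs$sites
  o <- tabs$observations
  t <- tabs$transects
  if (!is.null(s)) {
    if (!all(s$season %in% c(1, 2))) add(.violation("sites", "range", "season outside {1, 2}"))
    if (any(s$opuntia_cover_pct < 0 | s$opuntia_cover_pct > 100, na.rm = TRUE)) {
      add(.violation("sites", "range", "opuntia_cover_pct outside [0, 100]"))
    }
    if ("livestock_prop" %in% names(s) &&
      any(s$livestock_prop < 0 | s$livestock_prop > 1, na.rm = TRUE)) {
      add(.violation("sites", "range", "livestock_prop outside [0, 1]"))
    }
  }
  if (!is.null(o)) {
    bad_k <- which(o$night_count > o$count)
    for (r in head(bad_k, 5)) {
      add(.violation(
        "observations", "range",
        sprintf("row %d: night_count > count (site %s, %s)", r, o$site_id[r], o$date[r])
      ))
    }
    if (any(o$detected %in% c(0, 1) == FALSE & !is.na(o$detected))) {
      add(.violation("observations", "range", "detected outside {0, 1, NA}"))
    }
    if (!is.null(s)) {
      orphans <- setdiff(unique(o$site_id), s$site_id)
      if (length(orphans)) {
        add(.violation(
          "observations", "referential",
          sprintf("unknown site_id(s): %s", paste(head(orphans, 5), collapse = ", "))
        ))
      }
    }
  }
  if (!is.null(t)) {
    if (any(t$count < 0)) add(.violation("transects", "range", "negative counts"))
    if (any(t$bin_hi_m <= t$bin_lo_m)) add(.violation("transects", "range", "bin_hi_m <= bin_lo_m"))
    if (!is.null(s)) {
      orphans <- setdiff(unique(t$square_id), s$square_id)
      if (length(orphans)) {
        add(.violation(
          "transects", "referential",
          sprintf("unknown square_id(s): %s", paste(head(orphans, 5), collapse = ", "))
        ))
      }
    }
  }
  if (length(v)) dplyr::bind_rows(v) else .violation(character(), character(), character())[0, ]
}
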
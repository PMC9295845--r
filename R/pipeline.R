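#' End-to-end pipeline: simulate, train, detect, stage, compare
#'
#' Runs the whole workflow on a synthetic recording: draw a ground-truth
#' state sequence and trajectory, harvest labelled patches and train the
#' mouse classifier (or load one), detect the mouse frame by frame without
#' materialising the video, convert windowed feature differences to a
#' per-second activity trace, stage sleep/wake with the immobility and
#' merging rules, epoch the result, and score it against the reference
#' hypnogram emitted by the simulator. Deterministic under a fixed seed.
#'
#' @param config Named list (or path to a YAML file) with any of:
#'   `seed` (integer), `duration_s`, `scenario` (arguments to
#'   [cage_scenario()]), `model` (arguments to [state_model()]),
#'   `staging` (arguments to [staging_params()]), `vision` (arguments to
#'   [vision_params()]; `expected_area_px` defaults from the scenario's
#'   mouse radius), `classifier_path` (load instead of train),
#'   `n_patches_per_class`, `out_dir` (write results when given).
#' @return A `pipeline_result` list: `truth`, `classifier`, `detections`,
#'   `activity`, `hypnogram_s` (per-second), `hypnogram` (epoch-level),
#'   `reference`, `agreement`, and a provenance `manifest` (parameter
#'   values, seed, package version, config digest).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  duration_s <- config$duration_s %||% 3600

  scenario <- do.call(cage_scenario, config$scenario %||% list())
  model <- do.call(state_model, config$model %||% list())
  sparams <- do.call(staging_params, config$staging %||% list())
  vargs <- config$vision %||% list()
  if (is.null(vargs$expected_area_px)) {
    vargs$expected_area_px <- round(pi * 1.4 * 0.75 * scenario$mouse_radius_px^2)
  }
  vparams <- do.call(vision_params, vargs)

  truth <- simulate_state_sequence(model, duration_s, seed = seed)
  truth <- add_trajectory(truth, scenario, seed = seed + 1L)

  if (!is.null(config$classifier_path)) {
    if (!file.exists(config$classifier_path)) {
      abort(sprintf("classifier stage: file not found: %s",
                    config$classifier_path))
    }
    classifier <- read_classifier(config$classifier_path)
  } else {
    patches <- harvest_training_patches(
      truth, scenario,
      n_per_class = config$n_patches_per_class %||% 150,
      seed = seed + 2L)
    classifier <- train_classifier(
      patches, train_config(patch_size_px = 64, seed = seed + 3L))
  }

  detections <- detect_scenario(truth, scenario, classifier, vparams)
  activity <- activity_from_detections(detections, sparams)
  hyp_s <- stage_sleep_wake(activity, sparams)
  hyp <- epoch_hypnogram(hyp_s, sparams$epoch_s)
  reference <- emit_reference_hypnogram(truth, epoch_s = sparams$epoch_s)
  n <- min(nrow(hyp), nrow(reference))
  agreement <- compare_staging(truncate_hypnogram(hyp, n),
                               truncate_hypnogram(reference, n))

  manifest <- list(
    package = "cagesleep",
    version = as.character(utils::packageVersion("cagesleep")),
    seed = seed,
    duration_s = duration_s,
    scenario = config$scenario %||% list(),
    model = config$model %||% list(),
    staging = unclass(sparams),
    vision = unclass(vparams),
    config_digest = rlang::hash(config)
  )

  result <- structure(
    list(truth = truth, classifier = classifier, detections = detections,
         activity = activity, hypnogram_s = hyp_s, hypnogram = hyp,
         reference = reference, agreement = agreement, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

truncate_hypnogram <- function(h, n) {
  hypnogram(h$label[seq_len(n)], attr(h, "epoch_s"),
            attr(h, "start_time_s"), attr(h, "zeitgeber_offset_s"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %g s recording, seed %d\n",
              x$manifest$duration_s, x$manifest$seed))
  print(x$agreement)
  invisible(x)
}

#' Write a pipeline result bundle to a directory
#'
#' Hypnogram and detection CSVs, the agreement summary and the provenance
#' manifest (JSON, including the config digest), plus the ground-truth
#' states and twitch list.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hypnogram(result$hypnogram, file.path(dir, "hypnogram_epochs.csv"))
  write_hypnogram(result$hypnogram_s, file.path(dir, "hypnogram_seconds.csv"))
  write_hypnogram(result$reference, file.path(dir, "reference_epochs.csv"))
  write_detections(result$detections, file.path(dir, "detections.csv"))
  write_ground_truth(result$truth, file.path(dir, "truth"))
  jsonlite::write_json(glance(result$agreement),
                       file.path(dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
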
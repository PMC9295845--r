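#' Sleep/wake bout model for the cage simulator
#'
#' Describes the semi-Markov state process the simulator draws from:
#' alternating wake and sleep bouts with shifted-gamma durations, plus brief
#' movement "twitches" injected into sleep as a Poisson process. Twitches are
#' the events the movement-merging filter exists for: short movements during
#' sleep that a naive immobility rule would misread as waking.
#'
#' Bout durations are drawn from a gamma distribution with shape
#' `bout_shape`, shifted right by `bout_min_s`, and scaled so the mean equals
#' the requested bout mean. The shift guarantees both sub-40 s and longer
#' immobility runs occur, exercising the sleep-rule boundary.
#'
#' @param mean_wake_bout_s,mean_sleep_bout_s Mean bout durations in seconds;
#'   must exceed `bout_min_s`. Defaults (360 s wake, 480 s sleep) give the
#'   consolidated multi-minute bouts typical of adult mice.
#' @param bout_shape Gamma shape parameter for bout durations.
#' @param bout_min_s Minimum bout duration in seconds (the gamma shift).
#' @param twitch_rate_per_min Poisson rate of twitches per minute of sleep.
#' @param twitch_duration_s Length-2 numeric, min and max twitch duration in
#'   seconds (drawn uniformly).
#' @param twitch_amp_px Peak centroid excursion during a twitch, pixels.
#' @param wake_speed_px_s Locomotion speed while awake, pixels per second.
#' @param sleep_jitter_px Bound on the residual centroid excursion while
#'   asleep, pixels: breathing-scale movement, rendered as a slow smooth
#'   oscillation that never exceeds this amplitude.
#' @return A `state_model` list.
#' @seealso [simulate_state_sequence()]
#' @export
state_model <- function(mean_wake_bout_s = 360,
                        mean_sleep_bout_s = 480,
                        bout_shape = 2,
                        bout_min_s = 20,
                        twitch_rate_per_min = 0.3,
                        twitch_duration_s = c(5, 12),
                        twitch_amp_px = 8,
                        wake_speed_px_s = 40,
                        sleep_jitter_px = 1) {
  if (mean_wake_bout_s <= bout_min_s || mean_sleep_bout_s <= bout_min_s) {
    abort("mean bout durations must exceed `bout_min_s`")
  }
  if (twitch_rate_per_min < 0) abort("`twitch_rate_per_min` must be >= 0")
  if (length(twitch_duration_s) != 2 || any(twitch_duration_s < 0) ||
      twitch_duration_s[1] > twitch_duration_s[2]) {
    abort("`twitch_duration_s` must be an increasing pair of non-negative values")
  }
  structure(
    list(
      mean_wake_bout_s = mean_wake_bout_s,
      mean_sleep_bout_s = mean_sleep_bout_s,
      bout_shape = bout_shape,
      bout_min_s = bout_min_s,
      twitch_rate_per_min = twitch_rate_per_min,
      twitch_duration_s = as.numeric(twitch_duration_s),
      twitch_amp_px = twitch_amp_px,
      wake_speed_px_s = wake_speed_px_s,
      sleep_jitter_px = sleep_jitter_px
    ),
    class = "state_model"
  )
}

#' Cage scenario: arena, camera, light cycle, distractors
#'
#' Rendering-side configuration of the simulator. The defaults mirror a common
#' infrared home-cage setup: a 704 x 576 camera at 25 frames/s over a single
#' cage, 12 h light / 12 h dark. Frames are 8-bit grayscale; the light-phase
#' background renders bright (gray 180) with a darker mouse (gray 120), the
#' dark (infrared-lit) phase renders a dark background (gray 40) with the
#' mouse brighter than its surround, so detection must handle both polarities.
#'
#' @param width_px,height_px Arena (frame) size in pixels.
#' @param fps Frames per second.
#' @param light_cycle Data frame with columns `start_s`, `end_s`, `phase`
#'   (`"light"` or `"dark"`) tiling the recording; `NULL` means all light.
#' @param mouse_radius_px Nominal mouse body radius in pixels; the rendered
#'   blob is an ellipse with semi-axes about 1.4 and 0.75 times this value.
#'   Arena dimensions must be at least 4 x this radius.
#' @param distractors Data frame of static confounds (food pellets, water gel,
#'   shadows) with columns `shape` (`"disk"`, `"rect"` or `"shadow"`), `row`,
#'   `col`, `size`, `gray`; `NULL` for none, `"default"` for a representative
#'   trio.
#' @param bg_gray_light,bg_gray_dark,mouse_gray 8-bit gray levels.
#' @param noise_sd Pixel noise standard deviation in gray levels.
#' @return A `cage_scenario` list.
#' @export
cage_scenario <- function(width_px = 704, height_px = 576, fps = 25,
                          light_cycle = NULL,
                          mouse_radius_px = 30,
                          distractors = "default",
                          bg_gray_light = 180, bg_gray_dark = 40,
                          mouse_gray = 120, noise_sd = 1.5) {
  if (fps <= 0) abort("`fps` must be > 0")
  if (min(width_px, height_px) < 4 * mouse_radius_px) {
    abort("arena dimensions must be at least 4 x `mouse_radius_px`")
  }
  if (is.character(distractors) && identical(distractors, "default")) {
    r <- mouse_radius_px
    distractors <- tibble(
      shape = c("disk", "rect", "shadow"),
      row   = c(round(height_px * 0.2), round(height_px * 0.8), round(height_px * 0.5)),
      col   = c(round(width_px * 0.85), round(width_px * 0.15), round(width_px * 0.92)),
      size  = c(round(r * 0.8), round(r * 0.9), round(r * 1.6)),
      gray  = c(220, 90, NA_real_)  # shadow gray is phase-relative
    )
  }
  if (!is.null(light_cycle)) {
    light_cycle <- as_tibble(light_cycle)
    stopifnot(all(c("start_s", "end_s", "phase") %in% names(light_cycle)))
  }
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      fps = fps, light_cycle = light_cycle,
      mouse_radius_px = mouse_radius_px,
      distractors = if (is.null(distractors)) NULL else as_tibble(distractors),
      bg_gray_light = bg_gray_light, bg_gray_dark = bg_gray_dark,
      mouse_gray = mouse_gray, noise_sd = noise_sd
    ),
    class = "cage_scenario"
  )
}

#' Frame-level detection parameters
#'
#' Controls candidate extraction: Gaussian smoothing, the union of an adaptive
#' (local-mean) and a global (Otsu) threshold on the median-centred absolute
#' deviation image, and a minimum component area. The thresholding techniques
#' are standard; the specific constants here are engineering defaults exposed
#' for tuning. All coordinates in this package are 1-based with inclusive
#' bounding boxes, matching R indexing.
#'
#' @param sigma_px Gaussian smoothing sigma, pixels.
#' @param block_px Adaptive-threshold block size (odd), pixels.
#' @param offset_gray Adaptive-threshold offset, gray levels: a pixel is
#'   foreground when its deviation exceeds the local mean by this much. Also
#'   the floor applied to the Otsu threshold so pure-noise frames yield no
#'   foreground.
#' @param min_area_frac Minimum component area as a fraction of
#'   `expected_area_px`.
#' @param expected_area_px Expected mouse area in pixels; defaults to the
#'   rendered ellipse area for a 30 px radius mouse. When the mouse is
#'   undetected, features are carried forward from the last valid frame; how
#'   long such carried frames still count as staging evidence is the
#'   `max_gap_s` rule in [staging_params()].
#' @return A `vision_params` list.
#' @export
vision_params <- function(sigma_px = 2, block_px = 51, offset_gray = 5,
                          min_area_frac = 0.25,
                          expected_area_px = round(pi * 1.4 * 0.75 * 30^2)) {
  if (block_px %% 2 == 0) abort("`block_px` must be odd")
  structure(
    list(sigma_px = sigma_px, block_px = as.integer(block_px),
         offset_gray = offset_gray, min_area_frac = min_area_frac,
         expected_area_px = expected_area_px),
    class = "vision_params"
  )
}

#' Staging parameters: activity thresholds and sleep rules
#'
#' The defaults are the published operating point of the video staging
#' method: a frame is active when any within-window difference satisfies
#' `P > 0.1` (prediction score), `G > 3` gray levels, `A > 5` px centroid
#' displacement, or the normalised combination `(G/255 + M + P)/3 > 0.5`
#' (M = 1 - mask IoU); sleep is at least 40 s of continuous immobility; wake
#' interruptions of at most 15 s between two sleep bouts are relabelled
#' sleep; hypnograms are scored in 20 s epochs.
#'
#' @param sample_period_s Seconds between analysed time points (the activity
#'   trace resolution).
#' @param window_half_width Window half-width m, in samples: frame t is
#'   compared with frames at t +/- 1..m sample periods.
#' @param thr_P,thr_G,thr_A,thr_combined Activity thresholds (score units,
#'   gray levels, pixels, and the normalised mean respectively).
#' @param immobility_min_s Minimum continuous immobility scored as sleep, s.
#' @param merge_filter_s Maximum wake-run length merged into flanking sleep, s.
#' @param epoch_s Epoch length for hypnogram scoring, s.
#' @param max_gap_s Detection-gap rule: carried-forward (undetected) frames
#'   count as inactive evidence only while the gap since the last real
#'   detection is at most this long; beyond it they are excluded from
#'   staging.
#' @return A `staging_params` list.
#' @export
staging_params <- function(sample_period_s = 1, window_half_width = 2,
                           thr_P = 0.1, thr_G = 3, thr_A = 5,
                           thr_combined = 0.5,
                           immobility_min_s = 40, merge_filter_s = 15,
                           epoch_s = 20, max_gap_s = 2) {
  if (any(c(thr_P, thr_G, thr_A, thr_combined) <= 0)) {
    abort("activity thresholds must be > 0")
  }
  if (merge_filter_s >= immobility_min_s) {
    abort("`merge_filter_s` must be smaller than `immobility_min_s`")
  }
  structure(
    list(sample_period_s = sample_period_s,
         window_half_width = as.integer(window_half_width),
         thr_P = thr_P, thr_G = thr_G, thr_A = thr_A,
         thr_combined = thr_combined,
         immobility_min_s = immobility_min_s,
         merge_filter_s = merge_filter_s, epoch_s = epoch_s,
         max_gap_s = max_gap_s),
    class = "staging_params"
  )
}

#' Classifier training configuration
#'
#' Training protocol for the mouse-versus-background patch classifier: a
#' random 80/20 train/validation split, cross-entropy loss, and (for the
#' iterative backbone) stochastic gradient steps at a fixed learning rate of
#' 0.001 for 50 epochs. The `"logistic"` backbone fits by iteratively
#' reweighted least squares, so `learning_rate` and `epochs` are recorded in
#' the report but do not alter that fit; they drive the `"mlp"` backbone's
#' optimiser budget.
#'
#' @param split_fraction Training share of the labelled patches.
#' @param learning_rate Fixed learning rate for iterative backbones.
#' @param epochs Training epochs.
#' @param patch_size_px Side of the square patch fed to the classifier;
#'   candidate crops are resized to this before feature extraction.
#' @param backbone `"logistic"` (default) or `"mlp"` (single hidden layer).
#' @param hidden_units Hidden units for the `"mlp"` backbone.
#' @param seed Integer seed controlling the split and initialisation.
#' @return A `train_config` list.
#' @export
train_config <- function(split_fraction = 0.8, learning_rate = 0.001,
                         epochs = 50, patch_size_px = 64,
                         backbone = c("logistic", "mlp"),
                         hidden_units = 8, seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("`split_fraction` must be in (0, 1)")
  }
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  backbone <- match.arg(backbone)
  structure(
    list(split_fraction = split_fraction, loss = "cross-entropy",
         optimizer = "sgd", learning_rate = learning_rate,
         epochs = as.integer(epochs), patch_size_px = as.integer(patch_size_px),
         backbone = backbone, hidden_units = as.integer(hidden_units),
         seed = as.integer(seed)),
    class = "train_config"
  )
}
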
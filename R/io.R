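#' Read and write hypnogram CSV files
#'
#' The on-disk form is a plain CSV with columns
#' `epoch_index,start_s,label`; the epoch length is recovered from the
#' `start_s` spacing on read (single-epoch files need `epoch_s`).
#'
#' @param h A [hypnogram()].
#' @param path File path.
#' @param epoch_s Epoch length override when it cannot be inferred.
#' @return `write_hypnogram`: invisibly, `path`; `read_hypnogram`: a
#'   [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  write.csv(
    data.frame(epoch_index = h$epoch, start_s = h$start_s, label = h$label),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, epoch_s = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epoch_index", "start_s", "label") %in% names(d)))
  if (is.null(epoch_s)) {
    if (nrow(d) < 2) abort("cannot infer `epoch_s` from a single epoch; supply it")
    epoch_s <- d$start_s[2] - d$start_s[1]
  }
  hypnogram(d$label, epoch_s, start_time_s = if (nrow(d)) d$start_s[1] else 0)
}

#' Write simulator ground truth to disk
#'
#' The per-second state sequence goes to `<stem>_states.csv`
#' (`second,state`), the twitch list to `<stem>_twitches.json`.
#'
#' @param truth A `cage_truth`.
#' @param stem Path stem (no extension).
#' @return Invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, stem) {
  p1 <- paste0(stem, "_states.csv")
  p2 <- paste0(stem, "_twitches.json")
  write.csv(truth$states, p1, row.names = FALSE)
  jsonlite::write_json(truth$twitches, p2, digits = NA)
  invisible(c(p1, p2))
}

#' Read a per-second activity CSV
#'
#' Columns `second,active` (active as 0/1 or logical); the bare-trace entry
#' point for staging data produced outside this package.
#'
#' @param path File path.
#' @return An `activity_trace` tibble.
#' @export
read_activity <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("second", "active") %in% names(d)))
  structure(tibble(second = d$second, active = as.logical(d$active)),
            class = c("activity_trace", class(tibble())))
}

#' Read a per-epoch spectral table CSV
#'
#' Columns `epoch,bin_1..bin_30[,emg][,state]`, the supported entry point
#' for EEG-derived analytics.
#'
#' @param path File path.
#' @return A spectral tibble.
#' @export
read_spectral_epochs <- function(path) {
  check_spectra(read.csv(path, stringsAsFactors = FALSE))
}

#' Write and read a cage scenario as YAML
#'
#' @param scenario A [cage_scenario()].
#' @param path YAML file path.
#' @return `write_scenario`: invisibly `path`; `read_scenario`: a
#'   [cage_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  x$light_cycle <- if (is.null(x$light_cycle)) NULL else as.data.frame(x$light_cycle)
  x$distractors <- if (is.null(x$distractors)) NULL else as.data.frame(x$distractors)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  to_tbl <- function(v) if (is.null(v)) NULL else as_tibble(as.data.frame(v))
  cage_scenario(
    width_px = x$width_px, height_px = x$height_px, fps = x$fps,
    light_cycle = to_tbl(x$light_cycle),
    mouse_radius_px = x$mouse_radius_px,
    distractors = to_tbl(x$distractors),
    bg_gray_light = x$bg_gray_light, bg_gray_dark = x$bg_gray_dark,
    mouse_gray = x$mouse_gray, noise_sd = x$noise_sd
  )
}
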
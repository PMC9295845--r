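#' Construct a hypnogram
#'
#' A hypnogram is a tibble of consecutive fixed-length epochs, each carrying a
#' single vigilance-state label: `"Sleep"`/`"Wake"` for two-state video
#' staging, or `"Wake"`/`"NREM"`/`"REM"` for three-state EEG/EMG-style
#' scoring. Per-second traces are hypnograms with `epoch_s = 1`.
#'
#' @param labels Character vector of state labels.
#' @param epoch_s Epoch length in seconds.
#' @param start_time_s Recording time of the first epoch's start.
#' @param zeitgeber_offset_s Seconds from lights-on (ZT0) to `start_time_s`.
#' @return A `hypnogram` tibble with columns `epoch`, `start_s`, `label`.
#' @export
hypnogram <- function(labels, epoch_s, start_time_s = 0,
                      zeitgeber_offset_s = 0) {
  two <- c("Sleep", "Wake")
  three <- c("Wake", "NREM", "REM")
  labels <- as.character(labels)
  alphabet <- if (all(labels %in% two)) two else if (all(labels %in% three)) three else
    abort("labels must be drawn from {Sleep, Wake} or {Wake, NREM, REM}")
  out <- tibble(
    epoch = seq_along(labels),
    start_s = start_time_s + (seq_along(labels) - 1) * epoch_s,
    label = labels
  )
  structure(out,
            class = c("hypnogram", class(tibble())),
            epoch_s = epoch_s,
            start_time_s = start_time_s,
            zeitgeber_offset_s = zeitgeber_offset_s,
            alphabet = alphabet)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s (%s)\n",
              nrow(x), attr(x, "epoch_s"),
              paste(attr(x, "alphabet"), collapse = "/")))
  NextMethod()
}

#' Epoch length of a hypnogram
#' @param h A [hypnogram()].
#' @return Epoch length in seconds.
#' @export
epoch_length <- function(h) attr(h, "epoch_s")

#' Run-length bout table of a hypnogram
#'
#' A bout is a maximal run of consecutive epochs sharing a label.
#'
#' @param h A [hypnogram()].
#' @return Tibble with one row per bout: `state`, `start_s`, `duration_s`,
#'   `n_epochs`.
#' @export
bouts <- function(h) {
  r <- rle(h$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble(
    state = r$values,
    start_s = h$start_s[starts],
    duration_s = r$lengths * attr(h, "epoch_s"),
    n_epochs = r$lengths
  )
}

#' Number of bouts of a given state
#' @param h A [hypnogram()].
#' @param state State label to count bouts of.
#' @return Integer bout count.
#' @export
n_bouts <- function(h, state = "Sleep") {
  sum(bouts(h)$state == state)
}

#' Collapse a three-state hypnogram to Sleep/Wake
#'
#' NREM and REM are both sleep from the video method's point of view (it
#' cannot separate them), so comparisons against EEG-style references first
#' collapse NREM and REM into `"Sleep"`.
#'
#' @param h A [hypnogram()].
#' @return A two-state `hypnogram`.
#' @export
collapse_to_sleep_wake <- function(h) {
  lab <- ifelse(h$label %in% c("NREM", "REM"), "Sleep", h$label)
  hypnogram(lab, attr(h, "epoch_s"), attr(h, "start_time_s"),
            attr(h, "zeitgeber_offset_s"))
}

# Preserve attributes when dplyr/tidyr verbs would strip the subclass: metrics
# only ever consume label/epoch columns plus epoch_s, so reconstruct manually
# where needed rather than implementing the full dplyr extension protocol.
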
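#' Epoch-by-epoch staging agreement
#'
#' Confusion of a test hypnogram against a reference at equal epoch length
#' and count, with Sleep as the positive class: sensitivity is the fraction
#' of reference sleep epochs recovered (the quantity hurt when small
#' movements during sleep are misjudged as waking), specificity the fraction
#' of reference wake epochs recovered. Three-state references are collapsed
#' (NREM and REM both count as Sleep). Bout counts come from run-length
#' encoding of each hypnogram.
#'
#' @param test,reference [hypnogram()] objects.
#' @return A `staging_agreement` object; [tidy()] gives the confusion table,
#'   [glance()] the one-row metric summary.
#' @export
compare_staging <- function(test, reference) {
  test <- collapse_to_sleep_wake(test)
  reference <- collapse_to_sleep_wake(reference)
  if (attr(test, "epoch_s") != attr(reference, "epoch_s")) {
    abort(sprintf("epoch lengths differ: test %g s, reference %g s",
                  attr(test, "epoch_s"), attr(reference, "epoch_s")))
  }
  if (nrow(test) != nrow(reference)) {
    abort(sprintf("epoch counts differ: test %d, reference %d",
                  nrow(test), nrow(reference)))
  }
  tp <- sum(test$label == "Sleep" & reference$label == "Sleep")
  tn <- sum(test$label == "Wake" & reference$label == "Wake")
  fp <- sum(test$label == "Sleep" & reference$label == "Wake")
  fn <- sum(test$label == "Wake" & reference$label == "Sleep")
  n <- nrow(test)
  out <- structure(
    list(tp = tp, tn = tn, fp = fp, fn = fn, n_epochs = n,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         accuracy = (tp + tn) / n,
         bout_count_test = n_bouts(test, "Sleep"),
         bout_count_reference = n_bouts(reference, "Sleep"),
         epoch_s = attr(test, "epoch_s")),
    class = "staging_agreement"
  )
  # formula identities asserted on every construction
  stopifnot(tp + tn + fp + fn == n,
            is.na(out$sensitivity) || abs(out$sensitivity - tp / (tp + fn)) < 1e-12,
            is.na(out$specificity) || abs(out$specificity - tn / (tn + fp)) < 1e-12,
            abs(out$accuracy - (tp + tn) / n) < 1e-12)
  out
}

#' @export
print.staging_agreement <- function(x, ...) {
  cat(sprintf(
    paste0("<staging_agreement> %d epochs x %g s\n",
           "  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
           "  sleep bouts: test %d, reference %d\n"),
    x$n_epochs, x$epoch_s, x$sensitivity, x$specificity, x$accuracy,
    x$bout_count_test, x$bout_count_reference))
  invisible(x)
}

#' @method tidy staging_agreement
#' @export
tidy.staging_agreement <- function(x, ...) {
  tibble(
    test = c("Sleep", "Sleep", "Wake", "Wake"),
    reference = c("Sleep", "Wake", "Sleep", "Wake"),
    n = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' @method glance staging_agreement
#' @export
glance.staging_agreement <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy, n_epochs = x$n_epochs,
         bout_count_test = x$bout_count_test,
         bout_count_reference = x$bout_count_reference)
}

#' Hourly and daily sleep-time summaries
#'
#' Minutes of each state per zeitgeber hour (ZT0 = lights-on), with
#' multi-day recordings averaged per ZT hour, plus per-day totals.
#'
#' @param h A [hypnogram()].
#' @param zeitgeber_offset_s Seconds from lights-on to the start of the
#'   recording; defaults to the hypnogram's own anchor, and must be present
#'   one way or the other.
#' @return A `sleep_summary` list of two tibbles: `hourly` (`zt_hour`,
#'   `state`, `minutes`, averaged over days) and `daily` (`day`, `state`,
#'   `minutes`).
#' @export
sleep_time_summary <- function(h, zeitgeber_offset_s = NULL) {
  if (is.null(zeitgeber_offset_s)) {
    zeitgeber_offset_s <- attr(h, "zeitgeber_offset_s")
  }
  if (is.null(zeitgeber_offset_s)) {
    abort("no zeitgeber anchor: supply `zeitgeber_offset_s`")
  }
  ep_min <- attr(h, "epoch_s") / 60
  zt_s <- h$start_s + zeitgeber_offset_s
  d <- tibble(
    day = floor(zt_s / 86400) + 1,
    zt_hour = floor((zt_s %% 86400) / 3600),
    state = h$label
  )
  per_day_hour <- d %>%
    dplyr::count(.data$day, .data$zt_hour, .data$state) %>%
    mutate(minutes = .data$n * ep_min) %>%
    # a state absent from an observed hour is 0 minutes, and must enter the
    # across-day average as 0, not as a missing row
    tidyr::complete(tidyr::nesting(day, zt_hour), state = unique(d$state),
                    fill = list(n = 0L, minutes = 0))
  hourly <- per_day_hour %>%
    group_by(.data$zt_hour, .data$state) %>%
    summarise(minutes = mean(.data$minutes), .groups = "drop")
  daily <- d %>%
    dplyr::count(.data$day, .data$state) %>%
    tidyr::complete(day = unique(d$day), state = unique(d$state),
                    fill = list(n = 0L)) %>%
    mutate(minutes = .data$n * ep_min) %>%
    dplyr::select(-"n")
  structure(list(hourly = hourly, daily = daily), class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat("<sleep_summary>\nhourly (ZT, averaged over days):\n")
  print(x$hourly, n = 6)
  cat("daily totals:\n")
  print(x$daily, n = 6)
  invisible(x)
}

# --- EEG band-power analytics ----------------------------------------------

spectral_bins <- function() paste0("bin_", 1:30)

check_spectra <- function(spectra) {
  spectra <- as_tibble(spectra)
  missing <- setdiff(c("epoch", spectral_bins()), names(spectra))
  if (length(missing)) {
    abort(paste("spectral table lacks columns:", paste(missing, collapse = ", ")))
  }
  spectra
}

#' Hourly relative NREM delta power
#'
#' For each NREM epoch, the delta ratio is the summed power of the 1-4 Hz
#' bins divided by the summed power of the 1-30 Hz bins (both inclusive, on
#' the 1 Hz bin grid, so four bins over thirty). Ratios are then averaged
#' over all NREM epochs of each zeitgeber hour, pooling days; hours with no
#' NREM give a missing value, and epochs with zero total power are excluded
#' with a note.
#'
#' @param spectra Tibble with `epoch` and `bin_1` ... `bin_30` (power per
#'   1 Hz bin, arbitrary units), aligned to `h` by epoch index.
#' @param h A [hypnogram()]; in a two-state hypnogram "Sleep" counts as NREM.
#' @return Tibble `zt_hour`, `delta_ratio`, `n_epochs`.
#' @export
relative_delta_power <- function(spectra, h) {
  spectra <- check_spectra(spectra)
  stopifnot(nrow(spectra) == nrow(h))
  B <- as.matrix(spectra[, spectral_bins()])
  tot <- rowSums(B)
  delta <- rowSums(B[, paste0("bin_", 1:4), drop = FALSE])
  zero <- tot <= 0
  if (any(zero)) {
    inform(sprintf("%d epoch(s) with zero total power excluded", sum(zero)))
  }
  is_nrem <- h$label %in% c("NREM", "Sleep") & !zero
  zt_s <- h$start_s + (attr(h, "zeitgeber_offset_s") %||% 0)
  zt_hour_all <- floor((zt_s %% 86400) / 3600)
  tibble(zt_hour = zt_hour_all, nrem = is_nrem,
         ratio = ifelse(zero, NA_real_, delta / tot)) %>%
    group_by(.data$zt_hour) %>%
    summarise(
      delta_ratio = if (any(.data$nrem)) mean(.data$ratio[.data$nrem]) else NA_real_,
      n_epochs = sum(.data$nrem), .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' State-wise EEG power spectra
#'
#' For each vigilance state, the mean over that state's epochs of each 1 Hz
#' bin's power expressed as a percentage of the epoch's total 1-30 Hz power.
#' Percentages sum to 100 within each state. States with no epochs are
#' omitted with a note.
#'
#' @inheritParams relative_delta_power
#' @return Tibble `state`, `freq_hz` (1-30), `percent`.
#' @export
state_power_spectra <- function(spectra, h) {
  spectra <- check_spectra(spectra)
  stopifnot(nrow(spectra) == nrow(h))
  B <- as.matrix(spectra[, spectral_bins()])
  tot <- rowSums(B)
  keep <- tot > 0
  if (any(!keep)) {
    inform(sprintf("%d epoch(s) with zero total power excluded", sum(!keep)))
  }
  states <- unique(h$label)
  out <- purrr::map(states, function(s) {
    sel <- keep & h$label == s
    if (!any(sel)) {
      inform(sprintf("state %s has no epochs; omitted", s))
      return(NULL)
    }
    pct <- colMeans(100 * B[sel, , drop = FALSE] / tot[sel])
    tibble(state = s, freq_hz = 1:30, percent = unname(pct))
  })
  dplyr::bind_rows(out)
}

#' Detect direct wake-to-REM transitions
#'
#' Narcolepsy-like episodes: REM runs whose immediately preceding run is
#' Wake of at least `min_wake_s`. Transitions out of NREM are normal and not
#' counted.
#'
#' @param h A three-state [hypnogram()].
#' @param min_wake_s Minimum preceding wake-run duration, seconds; defaults
#'   to one epoch.
#' @return Tibble with one row per episode: `onset_epoch`, `onset_s`,
#'   `wake_run_s`.
#' @export
detect_wake_to_rem <- function(h, min_wake_s = NULL) {
  if (!"REM" %in% attr(h, "alphabet")) {
    abort("`detect_wake_to_rem()` needs a three-state hypnogram")
  }
  ep <- attr(h, "epoch_s")
  if (is.null(min_wake_s)) min_wake_s <- ep
  r <- rle(h$label)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  k <- which(r$values == "REM")
  k <- k[k > 1 & r$values[pmax(k - 1, 1)] == "Wake" &
           r$lengths[pmax(k - 1, 1)] * ep >= min_wake_s]
  tibble(onset_epoch = as.integer(starts[k]),
         onset_s = h$start_s[starts[k]],
         wake_run_s = r$lengths[k - 1] * ep)
}

#' Rule-based three-state stager from per-epoch band powers
#'
#' A deliberately simple per-epoch rule table over the delta ratio
#' (1-4 Hz / 1-30 Hz), theta ratio (6-9 Hz / 1-30 Hz) and an EMG amplitude
#' summary: high delta with low EMG is NREM; high theta with atonic EMG is
#' REM; everything else is Wake. Cutoffs are configurable; EMG cuts are
#' percentiles of the recording's own EMG distribution. This is a
#' convenience stager for synthetic and exploratory data, not a validated
#' clinical scorer. Without an `emg` column it falls back to two states
#' (Sleep when delta is high) with a warning.
#'
#' @param spectra Tibble with `epoch`, `bin_1` ... `bin_30` and `emg`.
#' @param delta_cut,theta_cut Ratio cutoffs.
#' @param emg_low_q,emg_atonia_q EMG percentile cutoffs for "low tonus" and
#'   "atonia".
#' @param epoch_s Epoch length of the output hypnogram, seconds.
#' @return A [hypnogram()] (three-state, or two-state on EMG fallback).
#' @export
rule_based_eeg_stager <- function(spectra, delta_cut = 0.4, theta_cut = 0.45,
                                  emg_low_q = 0.5, emg_atonia_q = 0.15,
                                  epoch_s = 20) {
  spectra <- check_spectra(spectra)
  B <- as.matrix(spectra[, spectral_bins()])
  tot <- rowSums(B)
  delta <- rowSums(B[, paste0("bin_", 1:4), drop = FALSE]) / pmax(tot, 1e-12)
  theta <- rowSums(B[, paste0("bin_", 6:9), drop = FALSE]) / pmax(tot, 1e-12)
  if (!"emg" %in% names(spectra) || all(is.na(spectra$emg))) {
    warn("no EMG summary; falling back to two-state delta-only staging")
    return(hypnogram(ifelse(delta > delta_cut, "Sleep", "Wake"), epoch_s))
  }
  emg <- spectra$emg
  emg_low <- stats::quantile(emg, emg_low_q, na.rm = TRUE)
  emg_atonia <- stats::quantile(emg, emg_atonia_q, na.rm = TRUE)
  lab <- rep("Wake", nrow(spectra))
  lab[delta > delta_cut & emg <= emg_low] <- "NREM"
  lab[lab == "Wake" & theta > theta_cut & emg <= emg_atonia] <- "REM"
  hypnogram(lab, epoch_s)
}

#' Simulate per-epoch EEG/EMG band powers for a hypnogram
#'
#' Synthetic spectral table matched to a state sequence, for exercising the
#' band-power analytics without real EEG: NREM epochs concentrate power in
#' the 1-4 Hz delta bins with low EMG, REM epochs in the 6-9 Hz theta bins
#' with near-zero EMG, wake epochs have a flat low-power spectrum with high,
#' variable EMG. Powers are gamma-distributed around those profiles.
#'
#' @param h A [hypnogram()].
#' @param seed Integer seed.
#' @return Tibble `epoch`, `bin_1` ... `bin_30`, `emg`, `state`.
#' @export
simulate_spectral_epochs <- function(h, seed = 1L) {
  set.seed(seed)
  n <- nrow(h)
  freq <- 1:30
  profile_for <- function(state) {
    base <- 1.5 / (1 + 0.12 * freq)          # 1/f-ish floor
    switch(state,
      NREM = { p <- base; p[1:4] <- p[1:4] + 9; p },
      Sleep = { p <- base; p[1:4] <- p[1:4] + 9; p },
      REM = { p <- base; p[6:9] <- p[6:9] + 7; p },
      Wake = base + 0.3
    )
  }
  emg_for <- function(state) {
    switch(state,
      NREM = rgamma(1, 4, rate = 40),        # ~0.1, low tonus
      Sleep = rgamma(1, 4, rate = 40),
      REM = rgamma(1, 2, rate = 200),        # ~0.01, atonia
      Wake = rgamma(1, 6, rate = 8)          # ~0.75, high and variable
    )
  }
  M <- matrix(0, n, 30, dimnames = list(NULL, spectral_bins()))
  emg <- numeric(n)
  for (i in seq_len(n)) {
    pr <- profile_for(h$label[i])
    M[i, ] <- rgamma(30, shape = 8, rate = 8 / pr)
    emg[i] <- emg_for(h$label[i])
  }
  dplyr::bind_cols(tibble(epoch = seq_len(n)), as_tibble(M),
                   tibble(emg = emg, state = h$label))
}
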
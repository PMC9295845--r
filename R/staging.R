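#' Windowed frame-difference features at one sample
#'
#' For sample `t`, compares the detection at `t` with detections at
#' `t +/- 1..m` sample periods and returns one row per available offset:
#' `P` (absolute prediction-score difference), `M` (mask difference,
#' `1 - IoU` of the two pixel masks), `A` (Euclidean centroid displacement in
#' pixels) and `G` (absolute mean-gray difference in gray levels). Offsets
#' falling outside the recording are truncated; offsets whose pair involves a
#' carried-forward frame beyond the detection-gap rule are skipped.
#'
#' @param detections Detection tibble from [detect_frames()] /
#'   [detect_scenario()].
#' @param t 1-based row index of the centre sample.
#' @param params A [staging_params()]; the sample period is interpreted in
#'   the detection tibble's own time base.
#' @return Tibble with columns `offset` (signed, in samples), `P`, `M`, `A`,
#'   `G`. All values are non-negative; `M` lies in `[0, 1]`.
#' @export
compute_feature_diffs <- function(detections, t, params = staging_params()) {
  n <- nrow(detections)
  stopifnot(t >= 1, t <= n)
  fps_det <- detection_rate(detections)
  step <- max(1L, round(params$sample_period_s * fps_det))
  offs <- c(-(params$window_half_width:1), 1:params$window_half_width)
  rows <- t + offs * step
  ok <- rows >= 1 & rows <= n
  offs <- offs[ok]; rows <- rows[ok]
  usable <- detection_usable(detections, params)
  keep <- usable[t] & usable[rows]
  offs <- offs[keep]; rows <- rows[keep]
  if (!length(offs)) {
    return(tibble(offset = integer(0), P = numeric(0), M = numeric(0),
                  A = numeric(0), G = numeric(0)))
  }
  P <- abs(detections$score[rows] - detections$score[t])
  G <- abs(detections$gray[rows] - detections$gray[t])
  A <- sqrt((detections$row[rows] - detections$row[t])^2 +
              (detections$col[rows] - detections$col[t])^2)
  M <- vapply(rows, function(r) {
    mask_difference(detections$pixels[[t]], detections$pixels[[r]])
  }, numeric(1))
  tibble(offset = offs, P = P, M = M, A = A, G = G)
}

# 1 - IoU over sorted 1-based linear pixel indices
mask_difference <- function(a, b) {
  if (is.null(a) || is.null(b) || !length(a) || !length(b)) return(1)
  inter <- cpp_intersect_size(a, b)
  1 - inter / (length(a) + length(b) - inter)
}

# frames with a usable feature vector: real detections, or carried-forward
# ones within the gap rule
detection_usable <- function(detections, params) {
  detections$present | (detections$carried &
                          is.finite(detections$gap_s) &
                          detections$gap_s <= params$max_gap_s)
}

# median sampling rate of a detection tibble (frames per second)
detection_rate <- function(detections) {
  if (nrow(detections) < 2) return(1)
  1 / median(diff(detections$time_s))
}

#' Judge whether the mouse is active at a sample
#'
#' Active if any within-window difference satisfies `P > thr_P`, or
#' `G > thr_G`, or `A > thr_A`, or the normalised combination
#' `(G/255 + M + P)/3 > thr_combined`. `P` and `M` are already in `[0, 1]`;
#' `G` is divided by 255 for the combination only — the individual `G` and
#' `A` thresholds apply to raw gray levels and pixels.
#'
#' @param diffs Feature-difference tibble from [compute_feature_diffs()].
#' @param params A [staging_params()].
#' @return Logical. An empty `diffs` yields `FALSE` (immobile) with attribute
#'   `low_confidence = TRUE`.
#' @export
judge_active <- function(diffs, params = staging_params()) {
  if (nrow(diffs) == 0) {
    return(structure(FALSE, low_confidence = TRUE))
  }
  any(diffs$P > params$thr_P |
        diffs$G > params$thr_G |
        diffs$A > params$thr_A |
        (diffs$G / 255 + diffs$M + diffs$P) / 3 > params$thr_combined)
}

#' Per-second activity trace from frame detections
#'
#' Applies the windowed difference features and the activity judgement to
#' every usable sampled frame, then reduces to one value per second by OR
#' over that second's frames. Seconds with no usable frame get `NA` and are
#' excluded from immobility evidence downstream (counted as wake).
#'
#' The bulk path short-circuits the mask-difference term: under the default
#' thresholds the combined clause can only fire when `P` or `G` already
#' fired, so `1 - IoU` is computed only for sample pairs where it could
#' change the verdict.
#'
#' @param detections Detection tibble.
#' @param params A [staging_params()].
#' @return Tibble `second` (0-based), `active` (logical, `NA` when no usable
#'   evidence), class `activity_trace`.
#' @export
activity_from_detections <- function(detections, params = staging_params()) {
  n <- nrow(detections)
  fps_det <- detection_rate(detections)
  step <- max(1L, round(params$sample_period_s * fps_det))
  usable <- detection_usable(detections, params)

  sc <- detections$score; gr <- detections$gray
  rr <- detections$row; cc <- detections$col
  fired <- rep(FALSE, n)       # any offset fired so far
  seen <- rep(FALSE, n)        # any usable offset existed
  for (o in c(-(params$window_half_width:1), 1:params$window_half_width)) {
    k <- o * step
    src <- which(detections$present)    # judgements made at real frames only
    dst <- src + k
    ok <- dst >= 1 & dst <= n
    src <- src[ok]; dst <- dst[ok]
    pairu <- usable[dst]
    src <- src[pairu]; dst <- dst[pairu]
    if (!length(src)) next
    seen[src] <- TRUE
    P <- abs(sc[dst] - sc[src])
    G <- abs(gr[dst] - gr[src])
    A <- sqrt((rr[dst] - rr[src])^2 + (cc[dst] - cc[src])^2)
    hit <- P > params$thr_P | G > params$thr_G | A > params$thr_A
    # combined clause needs M only when it could still push the mean over
    need_m <- which(!hit & (P + G / 255 + 1) / 3 > params$thr_combined)
    if (length(need_m)) {
      M <- vapply(need_m, function(j) {
        mask_difference(detections$pixels[[src[j]]],
                        detections$pixels[[dst[j]]])
      }, numeric(1))
      hit[need_m] <- (G[need_m] / 255 + M + P[need_m]) / 3 > params$thr_combined
    }
    fired[src[hit]] <- TRUE
  }
  # real frames: judged; carried frames within the gap rule: forced inactive
  # evidence; beyond the gap rule: no evidence at all
  active_frame <- rep(NA, n)
  active_frame[detections$present & seen] <- fired[detections$present & seen]
  active_frame[detections$present & !seen] <- FALSE  # isolated frame, no window
  active_frame[!detections$present & usable] <- FALSE

  secs <- floor(detections$time_s)
  grp <- split(active_frame, secs)
  out <- tibble(
    second = as.numeric(names(grp)),
    active = vapply(grp, function(v) {
      if (all(is.na(v))) NA else any(v, na.rm = TRUE)
    }, logical(1))
  )
  out <- out[order(out$second), ]
  n_na <- sum(is.na(out$active))
  if (n_na > 0) {
    inform(sprintf("%d second(s) without usable detections excluded from immobility evidence", n_na))
  }
  structure(out, class = c("activity_trace", class(tibble())))
}

#' Stage sleep and wake from an activity trace
#'
#' The immobility rule: every maximal run of inactive samples lasting at
#' least `immobility_min_s` is labelled Sleep, everything else Wake; then the
#' movement-merging filter ([merge_brief_movements()]) relabels brief wake
#' interruptions between two sleep bouts. `NA` activity (no usable video
#' evidence) never counts as immobility.
#'
#' @param activity Tibble with `second` and logical `active` (an
#'   `activity_trace`, or any per-second table, e.g. read from CSV).
#' @param params A [staging_params()].
#' @return A per-second [hypnogram()] (epoch length = the trace's sample
#'   period).
#' @export
stage_sleep_wake <- function(activity, params = staging_params()) {
  act <- activity$active
  period <- params$sample_period_s
  n <- length(act)
  if (n * period < params$immobility_min_s) {
    warn("trace shorter than the immobility threshold; staging everything Wake")
    return(hypnogram(rep("Wake", n), period,
                     start_time_s = if (n) activity$second[1] else 0))
  }
  immobile <- !is.na(act) & !act
  r <- rle(immobile)
  lab_runs <- ifelse(r$values & r$lengths * period >= params$immobility_min_s,
                     "Sleep", "Wake")
  labels <- inverse.rle(list(lengths = r$lengths, values = lab_runs))
  h <- hypnogram(labels, period, start_time_s = activity$second[1])
  merge_brief_movements(h, params$merge_filter_s)
}

#' Movement-merging filter
#'
#' Relabels every Wake run of duration at most `merge_filter_s` that is
#' flanked by Sleep on both sides as Sleep, re-scanning until a fixed point
#' so chains such as Sleep-Wake(10 s)-Sleep-Wake(10 s)-Sleep merge fully.
#' `merge_filter_s = 0` is the identity.
#'
#' @param h A two-state per-second (or per-sample) [hypnogram()].
#' @param merge_filter_s Maximum merged wake-run duration, seconds.
#' @return The filtered [hypnogram()].
#' @export
merge_brief_movements <- function(h, merge_filter_s) {
  stopifnot(identical(attr(h, "alphabet"), c("Sleep", "Wake")))
  period <- attr(h, "epoch_s")
  labels <- h$label
  repeat {
    r <- rle(labels)
    k <- length(r$values)
    if (k < 3) break
    mergeable <- which(
      r$values == "Wake" &
        r$lengths * period <= merge_filter_s &
        seq_len(k) > 1 & seq_len(k) < k
    )
    mergeable <- mergeable[r$values[mergeable - 1] == "Sleep" &
                             r$values[mergeable + 1] == "Sleep"]
    if (!length(mergeable)) break
    r$values[mergeable] <- "Sleep"
    labels <- inverse.rle(r)
  }
  hypnogram(labels, period, attr(h, "start_time_s"),
            attr(h, "zeitgeber_offset_s"))
}

#' Epoch a per-second hypnogram
#'
#' Majority label per fixed-length epoch; exact ties go to Wake (the
#' conservative choice: never inflate sleep), and a trailing partial epoch is
#' dropped with a note.
#'
#' @param h A two-state per-second [hypnogram()].
#' @param epoch_s Epoch length in seconds.
#' @return An epoch-level [hypnogram()].
#' @export
epoch_hypnogram <- function(h, epoch_s) {
  stopifnot(epoch_s > 0, identical(attr(h, "alphabet"), c("Sleep", "Wake")))
  if (attr(h, "epoch_s") != 1) {
    abort("`epoch_hypnogram()` expects a per-second (epoch_s = 1) hypnogram")
  }
  out <- epoch_by_majority(h$label, epoch_s)
  attr(out, "start_time_s") <- attr(h, "start_time_s")
  attr(out, "zeitgeber_offset_s") <- attr(h, "zeitgeber_offset_s")
  out$start_s <- out$start_s + attr(h, "start_time_s")
  out
}

#' Sweep the movement-merging threshold
#'
#' Stages the same activity trace at each merge threshold, epochs the result
#' to the reference's epoch length, and tabulates epoch agreement and sleep
#' bout counts against the reference hypnogram. Used to choose the operating
#' point: small thresholds leave sleep fragmented by twitches, large ones
#' swallow real awakenings.
#'
#' @param activity Per-second activity tibble.
#' @param reference Reference [hypnogram()] (epoch-level; three-state
#'   references are collapsed to Sleep/Wake).
#' @param thresholds Merge thresholds to test, seconds.
#' @param params A [staging_params()] (its `merge_filter_s` is overridden by
#'   each threshold in turn).
#' @return Tibble of class `staging_sweep`: one row per threshold with the
#'   epoch-level agreement (`sensitivity`, `specificity`, `accuracy`),
#'   `bout_count` (sleep bouts in the staged per-second hypnogram, where
#'   sub-epoch fragmentation by twitches is still visible),
#'   `bout_count_epoch` and `bout_count_reference` (both at epoch level),
#'   and `total_sleep_min`.
#' @export
sweep_merge_threshold <- function(activity, reference,
                                  thresholds = c(0, 5, 10, 15, 20, 25, 30),
                                  params = staging_params()) {
  ref2 <- collapse_to_sleep_wake(reference)
  rows <- purrr::map(thresholds, function(th) {
    p <- params; p$merge_filter_s <- th
    h <- stage_sleep_wake(activity, p)
    he <- epoch_hypnogram(h, attr(ref2, "epoch_s"))
    agr <- compare_staging(he, ref2)
    g <- glance(agr)
    tibble(threshold_s = th,
           sensitivity = g$sensitivity, specificity = g$specificity,
           accuracy = g$accuracy,
           bout_count = n_bouts(h, "Sleep"),
           bout_count_epoch = g$bout_count_test,
           bout_count_reference = g$bout_count_reference,
           total_sleep_min = sum(h$label == "Sleep") *
             attr(h, "epoch_s") / 60)
  })
  structure(dplyr::bind_rows(rows),
            class = c("staging_sweep", class(tibble())))
}
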
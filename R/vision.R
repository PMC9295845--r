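#' Extract candidate mouse regions from a frame
#'
#' Stage-one detection: the frame is Gaussian-smoothed, converted to a
#' median-centred absolute-deviation image (so the mouse is found whether it
#' is darker or brighter than the background), and thresholded two ways — an
#' adaptive local-mean threshold and a global Otsu threshold (floored at the
#' adaptive offset so noise-only frames produce no foreground). The union of
#' the two foregrounds is labelled into 8-connected components; components at
#' or above the minimum area each become one candidate. More than one
#' candidate is allowed — food, water gel and shadows can all trigger — and
#' the classifier decides later which one is the mouse.
#'
#' Coordinates are 1-based (R convention) with inclusive bounding boxes.
#'
#' @param frame Numeric matrix, gray values 0-255.
#' @param params A [vision_params()].
#' @return Tibble with one row per candidate: `area`, centroid `row`/`col`
#'   (sub-pixel), mean `gray` over the original frame inside the mask,
#'   bounding box `rmin`/`rmax`/`cmin`/`cmax`, `pixels` (list-column of
#'   1-based linear mask indices, sorted) and `score` (`NA` until scored).
#'   Zero rows when nothing qualifies; a degenerate or empty frame yields an
#'   empty tibble, not an error.
#' @export
extract_roi_candidates <- function(frame, params = vision_params()) {
  empty <- tibble(
    area = integer(0), row = numeric(0), col = numeric(0), gray = numeric(0),
    rmin = integer(0), rmax = integer(0), cmin = integer(0), cmax = integer(0),
    pixels = list(), score = numeric(0)
  )
  if (!is.matrix(frame) || length(frame) == 0) return(empty)
  st <- roi_candidates_core(frame, params)
  if (is.null(st)) return(empty)
  tibble(
    area = st$area, row = st$row, col = st$col, gray = st$gray,
    rmin = st$rmin, rmax = st$rmax, cmin = st$cmin, cmax = st$cmax,
    pixels = st$pixels, score = NA_real_
  )
}

# Hot-path candidate extraction: plain list of vectors (no tibble), NULL when
# nothing qualifies. extract_roi_candidates() is the tibble wrapper.
roi_candidates_core <- function(frame, params) {
  cpp_roi_candidates(frame, params$sigma_px, (params$block_px - 1L) %/% 2L,
                     params$offset_gray,
                     params$min_area_frac * params$expected_area_px)
}

#' Select the mouse among candidate regions
#'
#' Every candidate crop is scored by the patch classifier; the candidate with
#' the highest confidence is designated the mouse and the rest are treated as
#' background. Ties are broken by larger area, then by lower row index (both
#' noted when they occur). With no candidates the detection is absent and
#' flagged.
#'
#' @param candidates Candidate tibble from [extract_roi_candidates()].
#' @param classifier A trained [train_classifier()] model, or any plain
#'   function mapping a cropped patch matrix to a score in `[0, 1]`.
#' @param frame The frame the candidates came from (for patch crops).
#' @return One-row tibble: `present`, `row`, `col`, `area`, `gray`, `score`,
#'   `pixels` (list-column; `NULL` mask when absent).
#' @export
select_mouse <- function(candidates, classifier, frame) {
  if (nrow(candidates) == 0) {
    return(tibble(present = FALSE, row = NA_real_, col = NA_real_,
                  area = NA_integer_, gray = NA_real_, score = NA_real_,
                  pixels = list(NULL)))
  }
  scores <- score_candidates(classifier, frame, candidates)
  best <- pick_best_candidate(scores, candidates$area, candidates$row)
  tibble(present = TRUE,
         row = candidates$row[best], col = candidates$col[best],
         area = candidates$area[best], gray = candidates$gray[best],
         score = scores[best], pixels = candidates$pixels[best])
}

# arg-max with documented tie rule: score, then larger area, then lower row
pick_best_candidate <- function(scores, areas, rows) {
  top <- which(scores == max(scores))
  if (length(top) > 1) {
    inform("candidate score tie; breaking by larger area then lower row",
           .frequency = "once", .frequency_id = "cagesleep_score_tie")
    top <- top[areas[top] == max(areas[top])]
    if (length(top) > 1) top <- top[which.min(rows[top])]
  }
  top[1]
}

# Feature-matrix scoring of all candidates of one frame (single predict call
# for model classifiers; direct application for function classifiers)
score_candidates <- function(classifier, frame, candidates) {
  crops <- lapply(seq_len(nrow(candidates)),
                  function(k) crop_candidate(frame, candidates[k, ]))
  if (is.function(classifier)) {
    return(vapply(crops, classifier, numeric(1)))
  }
  X <- do.call(rbind,
               lapply(crops, patch_features, size = classifier$patch_size))
  predict_scores(classifier, X)
}

# Square crop around a candidate bounding box with a small margin, clipped to
# the frame. `crop_candidate` takes a one-row candidate tibble; `crop_patch`
# is the plain-argument hot path.
crop_candidate <- function(frame, cand) {
  crop_patch(frame, cand$row, cand$col, cand$rmin, cand$rmax,
             cand$cmin, cand$cmax)
}

crop_patch <- function(frame, row, col, rmin, rmax, cmin, cmax) {
  side <- max(rmax - rmin, cmax - cmin) + 1
  half <- ceiling(side * 0.65)
  r0 <- max(1, round(row) - half); r1 <- min(nrow(frame), round(row) + half)
  c0 <- max(1, round(col) - half); c1 <- min(ncol(frame), round(col) + half)
  frame[r0:r1, c0:c1, drop = FALSE]
}

#' Detect the mouse across a recording, frame by frame
#'
#' Runs candidate extraction and mouse selection over every frame of a
#' rendered stack (or a subset of frames of a scenario, rendered on the fly
#' in chunks so long recordings never materialise in memory; see
#' [detect_scenario()]). When a frame has no acceptable candidate, the last
#' valid detection is carried forward and the frame flagged; staging later
#' counts carried frames as inactive evidence only while the gap is short
#' (the `max_gap_s` rule in [staging_params()]) and excludes longer gaps.
#'
#' @param stack A `frame_stack` from [render_video()].
#' @param classifier A trained patch classifier.
#' @param params A [vision_params()].
#' @return Detection tibble: `frame`, `time_s`, `present`, `carried`,
#'   `gap_s`, `row`, `col`, `area`, `gray`, `score`, `pixels` (list-column).
#' @export
detect_frames <- function(stack, classifier, params = vision_params()) {
  n <- dim(stack$frames)[3]
  detect_loop(function(i) stack$frames[, , i], stack$times, n,
              classifier, params)
}

#' Detect over a simulated scenario without materialising the video
#'
#' Renders frames at the scenario's fps in chunks and feeds them through the
#' same per-frame detection as [detect_frames()]. This is the streaming path
#' the full pipeline uses for multi-hour recordings.
#'
#' @inheritParams detect_frames
#' @param truth A `cage_truth` (trajectory added if absent).
#' @param scenario A [cage_scenario()].
#' @return Detection tibble as in [detect_frames()].
#' @export
detect_scenario <- function(truth, scenario, classifier,
                            params = vision_params()) {
  if (is.null(truth$trajectory)) truth <- add_trajectory(truth, scenario)
  check_trajectory_bounds(truth, scenario)
  rc <- render_context(truth, scenario)
  detect_loop(function(i) render_frame_ctx(rc, i), truth$trajectory$time_s,
              nrow(truth$trajectory), classifier, params)
}

# Shared per-frame loop over a frame source, using the tibble-free candidate
# core; semantics identical to extract_roi_candidates() + select_mouse().
detect_loop <- function(get_frame, times, n, classifier, params) {
  det <- detection_accumulator(n)
  for (i in seq_len(n)) {
    fr <- get_frame(i)
    st <- roi_candidates_core(fr, params)
    if (is.null(st)) {
      detection_push_absent(det, i, times[i])
      next
    }
    X <- do.call(rbind, lapply(seq_along(st$area), function(k) {
      patch_features(
        crop_patch(fr, st$row[k], st$col[k], st$rmin[k], st$rmax[k],
                   st$cmin[k], st$cmax[k]),
        classifier$patch_size)
    }))
    scores <- predict_scores(classifier, X)
    best <- pick_best_candidate(scores, st$area, st$row)
    detection_push_present(det, i, times[i], st, best, scores[best])
  }
  detection_finish(det)
}

# --- flat accumulator for per-frame detections ------------------------------
# An environment mutated in place: a list would be copied on every
# modification, turning a long recording into quadratic memcpy.

detection_accumulator <- function(n) {
  det <- new.env(parent = emptyenv())
  det$n <- n
  det$frame <- integer(n); det$time_s <- numeric(n)
  det$present <- logical(n); det$carried <- logical(n); det$gap_s <- numeric(n)
  det$row <- numeric(n); det$col <- numeric(n)
  det$area <- rep(NA_integer_, n); det$gray <- numeric(n)
  det$score <- numeric(n); det$pixels <- vector("list", n)
  det$last_valid <- NULL; det$n_missing <- 0L
  det
}

detection_push_present <- function(det, i, time_s, st, k, score) {
  det$frame[i] <- i; det$time_s[i] <- time_s
  det$present[i] <- TRUE; det$carried[i] <- FALSE; det$gap_s[i] <- 0
  det$row[i] <- st$row[k]; det$col[i] <- st$col[k]; det$area[i] <- st$area[k]
  det$gray[i] <- st$gray[k]; det$score[i] <- score
  det$pixels[[i]] <- st$pixels[[k]]
  det$last_valid <- i
  invisible(det)
}

detection_push_absent <- function(det, i, time_s) {
  det$frame[i] <- i; det$time_s[i] <- time_s
  det$n_missing <- det$n_missing + 1L
  det$present[i] <- FALSE; det$carried[i] <- TRUE
  if (!is.null(det$last_valid)) {
    j <- det$last_valid
    det$gap_s[i] <- time_s - det$time_s[j]
    det$row[i] <- det$row[j]; det$col[i] <- det$col[j]
    det$area[i] <- det$area[j]; det$gray[i] <- det$gray[j]
    det$score[i] <- det$score[j]; det$pixels[[i]] <- det$pixels[[j]]
  } else {
    det$row[i] <- NA_real_; det$col[i] <- NA_real_
    det$gray[i] <- NA_real_; det$score[i] <- NA_real_
    det$gap_s[i] <- Inf
  }
  invisible(det)
}

detection_finish <- function(det) {
  if (det$n_missing > 0) {
    inform(sprintf("%d of %d frames had no detection (features carried forward)",
                   det$n_missing, det$n))
  }
  tibble(frame = det$frame, time_s = det$time_s, present = det$present,
         carried = det$carried, gap_s = det$gap_s, row = det$row,
         col = det$col, area = det$area, gray = det$gray, score = det$score,
         pixels = det$pixels)
}

#' Write per-frame detections to CSV
#'
#' Mask pixel lists are not serialised; the CSV carries the scalar features
#' (`frame,time_s,present,carried,row,col,area,gray,score`).
#'
#' @param detections Detection tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_detections <- function(detections, path) {
  out <- detections[, c("frame", "time_s", "present", "carried",
                        "row", "col", "area", "gray", "score")]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
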
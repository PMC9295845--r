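#' Render a ground truth into a stack of cage frames
#'
#' Produces 8-bit-scale grayscale frames (numeric matrices with values in
#' 0-255): a phase-dependent background with static distractors (a bright
#' food-pellet disk, a dark water-gel rectangle, a soft shadow gradient), the
#' mouse as a deformable ellipse oriented along its direction of motion, and
#' pixel noise drawn from a small pre-generated bank that is circularly
#' shifted per frame. During the light phase the background is bright and the
#' mouse darker; during the dark (infrared-lit) phase the background is dark
#' and the mouse brighter.
#'
#' @param truth A `cage_truth` with a trajectory (see [add_trajectory()]); if
#'   the trajectory is absent it is added here using the truth's seed.
#' @param scenario A [cage_scenario()].
#' @param frames Integer vector of frame indices to render; `NULL` renders
#'   all frames. `integer(0)` gives an empty stack.
#' @return A `frame_stack`: list with `frames` (height x width x n array),
#'   `times` (seconds) and `fps`.
#' @export
render_video <- function(truth, scenario, frames = NULL) {
  stopifnot(inherits(truth, "cage_truth"), inherits(scenario, "cage_scenario"))
  if (is.null(truth$trajectory)) truth <- add_trajectory(truth, scenario)
  n_all <- nrow(truth$trajectory)
  if (is.null(frames)) frames <- seq_len(n_all)
  if (length(frames) && (min(frames) < 1 || max(frames) > n_all)) {
    abort("`frames` out of range for this truth's trajectory")
  }
  check_trajectory_bounds(truth, scenario)
  rc <- render_context(truth, scenario)
  arr <- array(0, c(scenario$height_px, scenario$width_px, length(frames)))
  for (j in seq_along(frames)) arr[, , j] <- render_frame_ctx(rc, frames[j])
  structure(
    list(frames = arr, times = truth$trajectory$time_s[frames],
         fps = scenario$fps),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames, %d x %d px, %g fps\n",
              d[3], d[1], d[2], x$fps))
  invisible(x)
}

#' Render a single frame
#'
#' @inheritParams render_video
#' @param frame 1-based frame index.
#' @return A height x width numeric matrix, gray values in 0-255.
#' @export
render_frame <- function(truth, scenario, frame) {
  if (is.null(truth$trajectory)) truth <- add_trajectory(truth, scenario)
  render_frame_ctx(render_context(truth, scenario), frame)
}

check_trajectory_bounds <- function(truth, scenario) {
  tr <- truth$trajectory
  if (any(tr$row < 1 | tr$row > scenario$height_px |
          tr$col < 1 | tr$col > scenario$width_px)) {
    abort("trajectory leaves the arena; cannot render")
  }
  invisible(TRUE)
}

# Precomputed per-recording rendering state: one background per phase, a
# deterministic noise bank, per-frame phase and sleep/wake lookups.
render_context <- function(truth, scenario) {
  bg <- list(light = build_background(scenario, "light"),
             dark = build_background(scenario, "dark"))
  # noise bank: 16 pre-drawn fields cycled per frame (its own stream, so
  # frame content is reproducible regardless of which frames are rendered).
  # 16 is coprime to the 1-2 s window offsets used downstream, so compared
  # frames never share a noise field.
  n_noise <- 16L
  noise <- NULL
  if (scenario$noise_sd > 0) {
    set.seed(truth$seed + 2L)
    noise <- lapply(seq_len(n_noise), function(i) {
      matrix(rnorm(scenario$height_px * scenario$width_px, 0,
                   scenario$noise_sd),
             scenario$height_px, scenario$width_px)
    })
  }
  tr <- truth$trajectory
  phase <- phase_at(scenario, tr$time_s)
  asleep <- truth$states$state[pmin(floor(tr$time_s), truth$duration_s - 1) + 1] == "Sleep"
  # clamping to [0,255] is only needed when grays + noise could overflow
  grays <- c(unlist(bg), scenario$mouse_gray)
  margin <- 6.5 * scenario$noise_sd
  clamp <- min(grays) - margin < 0 || max(grays) + margin > 255
  list(scenario = scenario, tr = tr, bg = bg, noise = noise,
       n_noise = n_noise, phase = phase, asleep = asleep, clamp = clamp,
       breath_amp = if (truth$model$sleep_jitter_px > 0) 0.04 else 0,
       npx = scenario$height_px * scenario$width_px)
}

render_frame_ctx <- function(rc, i) {
  sc <- rc$scenario
  f <- rc$bg[[rc$phase[i]]]
  if (!is.null(rc$noise)) {
    f <- f + rc$noise[[(i - 1L) %% rc$n_noise + 1L]]
  }
  # mouse ellipse: semi-axes breathe slowly; rounder (curled) when asleep.
  # Breathing deformation is part of the sleep micro-movement model, so a
  # zero sleep_jitter_px freezes it too (a perfectly still mouse renders
  # pixel-identically).
  tr <- rc$tr
  r <- sc$mouse_radius_px
  br <- 1 + rc$breath_amp * sin(2 * pi * tr$time_s[i] / 3)
  if (rc$asleep[i]) { a <- 1.15 * r * br; b2 <- 0.90 * r / br }
  else { a <- 1.40 * r * br; b2 <- 0.75 * r / br }
  f <- fill_ellipse(f, tr$row[i], tr$col[i], a, b2, tr$angle[i], sc$mouse_gray)
  if (rc$clamp) { f[f < 0] <- 0; f[f > 255] <- 255 }
  f
}

phase_at <- function(scenario, time_s) {
  if (is.null(scenario$light_cycle)) return(rep("light", length(time_s)))
  lc <- scenario$light_cycle
  idx <- findInterval(time_s, lc$start_s)
  idx[idx < 1] <- 1
  as.character(lc$phase[idx])
}

build_background <- function(scenario, phase) {
  g0 <- if (phase == "light") scenario$bg_gray_light else scenario$bg_gray_dark
  f <- matrix(g0, scenario$height_px, scenario$width_px)
  d <- scenario$distractors
  if (is.null(d)) return(f)
  for (k in seq_len(nrow(d))) {
    if (d$shape[k] == "disk") {
      f <- fill_ellipse(f, d$row[k], d$col[k], d$size[k], d$size[k], 0, d$gray[k])
    } else if (d$shape[k] == "rect") {
      r0 <- max(1, round(d$row[k] - d$size[k] / 2))
      r1 <- min(scenario$height_px, round(d$row[k] + d$size[k] / 2))
      c0 <- max(1, round(d$col[k] - d$size[k] / 2))
      c1 <- min(scenario$width_px, round(d$col[k] + d$size[k] / 2))
      f[r0:r1, c0:c1] <- d$gray[k]
    } else if (d$shape[k] == "shadow") {
      # soft radial darkening, scaled to the phase background
      s <- d$size[k]
      rows <- seq_len(scenario$height_px); cols <- seq_len(scenario$width_px)
      dist2 <- outer((rows - d$row[k])^2, (cols - d$col[k])^2, "+")
      depth <- if (phase == "light") 35 else 15
      f <- f - depth * exp(-dist2 / (2 * s^2))
    }
  }
  f
}

# Fill an ellipse (semi-axes a along `angle`, b across) centred at
# (row0, col0); only the bounding box is touched.
fill_ellipse <- function(f, row0, col0, a, b, angle, gray) {
  nr <- nrow(f); nc <- ncol(f)
  ext <- max(a, b)
  r0 <- max(1, floor(row0 - ext)); r1 <- min(nr, ceiling(row0 + ext))
  c0 <- max(1, floor(col0 - ext)); c1 <- min(nc, ceiling(col0 + ext))
  if (r0 > r1 || c0 > c1) return(f)
  dr <- (r0:r1) - row0
  dc <- (c0:c1) - col0
  sa <- sin(angle); ca <- cos(angle)
  p <- outer(dr * sa, dc * ca, "+")   # along-axis component
  q <- outer(-dr * ca, dc * sa, "+")  # across-axis component
  inside <- (p / a)^2 + (q / b)^2 <= 1
  sub <- f[r0:r1, c0:c1, drop = FALSE]
  sub[inside] <- gray
  f[r0:r1, c0:c1] <- sub
  f
}

#' Write a frame stack to disk as PNG images
#'
#' One zero-padded `frame_%06d.png` per frame. Requires the `png` package.
#'
#' @param stack A `frame_stack`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_frame_stack <- function(stack, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("writing PNG frames requires the `png` package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(stack$frames)[3]
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf("frame_%06d.png", i))
    png::writePNG(stack$frames[, , i] / 255, paths[i])
  }
  invisible(paths)
}
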
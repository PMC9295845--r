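#' Simulate a ground-truth sleep/wake state sequence
#'
#' Draws alternating wake and sleep bouts from the model's shifted-gamma
#' duration distribution until `duration_s` is tiled (the final bout is
#' truncated), then injects twitch events into sleep bouts as a Poisson
#' process with the model's rate. Twitches are brief movements during sleep;
#' they never extend outside the sleep bout that contains them, and their
#' count is faithful to the Poisson draw (overlapping excursions are allowed
#' and superpose at render time).
#'
#' @param model A [state_model()].
#' @param duration_s Recording length in seconds (>= 60).
#' @param seed Integer seed; fixed seed gives a bit-identical truth object.
#' @return A `cage_truth` list: `states` (tibble `second`, `state`, one row
#'   per second, `second` is the 0-based bin start), `bouts` (tibble
#'   `state`, `start_s`, `end_s`), `twitches` (tibble `start_s`, `end_s`),
#'   plus the model, duration and seed. The per-frame trajectory is added by
#'   [add_trajectory()].
#' @export
simulate_state_sequence <- function(model, duration_s, seed = 1L) {
  stopifnot(inherits(model, "state_model"))
  if (duration_s < 60) abort("`duration_s` must be >= 60 s")
  set.seed(seed)

  draw_bout <- function(state) {
    mean_s <- if (state == "Wake") model$mean_wake_bout_s else model$mean_sleep_bout_s
    scale <- (mean_s - model$bout_min_s) / model$bout_shape
    model$bout_min_s + rgamma(1, shape = model$bout_shape, scale = scale)
  }

  state <- "Wake"                      # recordings start with handling arousal
  starts <- numeric(0); ends <- numeric(0); labs <- character(0)
  t <- 0
  while (t < duration_s) {
    len <- draw_bout(state)
    end <- min(t + len, duration_s)
    starts <- c(starts, t); ends <- c(ends, end); labs <- c(labs, state)
    t <- end
    state <- if (state == "Wake") "Sleep" else "Wake"
  }
  bout_tbl <- tibble(state = labs, start_s = starts, end_s = ends)

  # per-second labels: second i covers [i, i+1); label by its containing bout
  sec <- 0:(duration_s - 1)
  idx <- findInterval(sec, starts)
  states <- tibble(second = sec, state = labs[idx])

  # twitches: Poisson count per sleep bout, uniform starts and durations
  tw_start <- numeric(0); tw_end <- numeric(0)
  if (model$twitch_rate_per_min > 0) {
    sleep_bouts <- bout_tbl[bout_tbl$state == "Sleep", ]
    for (b in seq_len(nrow(sleep_bouts))) {
      b0 <- sleep_bouts$start_s[b]; b1 <- sleep_bouts$end_s[b]
      n <- rpois(1, model$twitch_rate_per_min * (b1 - b0) / 60)
      if (n == 0) next
      dur <- runif(n, model$twitch_duration_s[1], model$twitch_duration_s[2])
      s0 <- b0 + runif(n, 0, pmax(0, (b1 - b0) - dur))
      s1 <- pmin(s0 + dur, b1)
      o <- order(s0)
      tw_start <- c(tw_start, s0[o]); tw_end <- c(tw_end, s1[o])
    }
  }

  structure(
    list(states = states, bouts = bout_tbl,
         twitches = tibble(start_s = tw_start, end_s = tw_end),
         trajectory = NULL, model = model,
         duration_s = duration_s, seed = as.integer(seed)),
    class = "cage_truth"
  )
}

#' @export
print.cage_truth <- function(x, ...) {
  cat(sprintf(
    "<cage_truth> %g s, %d bouts (%d sleep), %d twitches, trajectory %s\n",
    x$duration_s, nrow(x$bouts), sum(x$bouts$state == "Sleep"),
    nrow(x$twitches),
    if (is.null(x$trajectory)) "absent" else
      sprintf("present (%d frames)", nrow(x$trajectory))))
  invisible(x)
}

#' Add a per-frame centroid trajectory to a ground truth
#'
#' Wake bouts are a waypoint walk at the model's speed: the mouse heads to a
#' uniformly drawn target inside the arena (respecting a body-size margin)
#' and picks a new target on arrival. Sleep bouts hold the last position with
#' Gaussian jitter of the model's `sleep_jitter_px`; during twitches a smooth
#' out-and-back excursion of peak amplitude `twitch_amp_px` is superposed in
#' a random direction. Orientation follows the direction of motion and is
#' frozen during sleep.
#'
#' @param truth A `cage_truth` from [simulate_state_sequence()].
#' @param scenario A [cage_scenario()] (arena size and fps).
#' @param seed Seed for the trajectory draw; defaults to the truth's seed + 1.
#' @return The truth with a `trajectory` tibble (`frame`, `time_s`, `row`,
#'   `col`, `angle`) and the scenario's fps recorded.
#' @export
add_trajectory <- function(truth, scenario, seed = NULL) {
  stopifnot(inherits(truth, "cage_truth"), inherits(scenario, "cage_scenario"))
  set.seed(if (is.null(seed)) truth$seed + 1L else as.integer(seed))
  fps <- scenario$fps
  n <- round(truth$duration_s * fps)
  tt <- (seq_len(n) - 1) / fps
  margin <- 1.5 * scenario$mouse_radius_px + 2
  rlo <- margin; rhi <- scenario$height_px - margin
  clo <- margin; chi <- scenario$width_px - margin
  model <- truth$model

  row <- numeric(n); col <- numeric(n); ang <- numeric(n)
  pos <- c(runif(1, rlo, rhi), runif(1, clo, chi))
  target <- c(runif(1, rlo, rhi), runif(1, clo, chi))
  cur_ang <- atan2(target[1] - pos[1], target[2] - pos[2])
  step <- model$wake_speed_px_s / fps

  # per-frame state lookup
  st <- truth$bouts$state[findInterval(tt, truth$bouts$start_s)]
  i <- 1
  while (i <= n) {
    if (st[i] == "Wake") {
      d <- target - pos
      dist <- sqrt(sum(d^2))
      if (dist < step) {
        target <- c(runif(1, rlo, rhi), runif(1, clo, chi))
        d <- target - pos; dist <- sqrt(sum(d^2))
      }
      pos <- pos + d / dist * step
      cur_ang <- atan2(d[1], d[2])
      row[i] <- pos[1]; col[i] <- pos[2]; ang[i] <- cur_ang
      i <- i + 1
    } else {
      # whole sleep bout at once: rest position + breathing-scale movement.
      # The jitter is a smooth bounded oscillation (|offset| <= sleep_jitter_px):
      # breathing shifts the body slowly, it is not white noise at frame rate.
      j <- i
      while (j <= n && st[j] == "Sleep") j <- j + 1
      len <- j - i
      tloc <- tt[i:(j - 1)] - tt[i]
      per <- runif(2, 2.5, 4.5); ph <- runif(2, 0, 2 * pi)
      jit_r <- model$sleep_jitter_px * sin(2 * pi * tloc / per[1] + ph[1])
      jit_c <- model$sleep_jitter_px * sin(2 * pi * tloc / per[2] + ph[2])
      row[i:(j - 1)] <- pmin(pmax(pos[1] + jit_r, rlo), rhi)
      col[i:(j - 1)] <- pmin(pmax(pos[2] + jit_c, clo), chi)
      ang[i:(j - 1)] <- cur_ang
      i <- j
    }
  }

  # superpose twitch excursions
  if (nrow(truth$twitches) > 0) {
    for (k in seq_len(nrow(truth$twitches))) {
      t0 <- truth$twitches$start_s[k]; t1 <- truth$twitches$end_s[k]
      sel <- which(tt >= t0 & tt < t1)
      if (!length(sel)) next
      phase <- (tt[sel] - t0) / (t1 - t0)
      amp <- model$twitch_amp_px * sin(pi * phase)
      th <- runif(1, 0, 2 * pi)
      row[sel] <- pmin(pmax(row[sel] + amp * sin(th), rlo), rhi)
      col[sel] <- pmin(pmax(col[sel] + amp * cos(th), clo), chi)
    }
  }

  truth$trajectory <- tibble(frame = seq_len(n), time_s = tt,
                             row = row, col = col, angle = ang)
  truth$fps <- fps
  truth
}

#' Reference hypnogram from simulator ground truth
#'
#' Scores the per-second truth into fixed epochs by majority state (ties go
#' to Wake; a trailing partial epoch is dropped). Optionally relabels a
#' fraction of sleep epochs as REM in contiguous runs, either at sleep-bout
#' tails (the physiological position: REM follows NREM) or at sleep-bout
#' heads immediately after wake (the narcolepsy-like scenario, producing
#' direct wake-to-REM transitions).
#'
#' @param truth A `cage_truth`.
#' @param epoch_s Epoch length in seconds.
#' @param three_state Relabel some sleep as REM to produce a
#'   Wake/NREM/REM hypnogram?
#' @param rem_fraction Target fraction of sleep epochs relabelled REM.
#' @param rem_placement `"tail"` (normal) or `"post_wake"` (narcolepsy-like).
#' @return A [hypnogram()]; when `rem_placement = "post_wake"` the attribute
#'   `wake_to_rem_onsets` records the epoch indices of the injected direct
#'   wake-to-REM transitions.
#' @export
emit_reference_hypnogram <- function(truth, epoch_s = 20, three_state = FALSE,
                                     rem_fraction = 0.1,
                                     rem_placement = c("tail", "post_wake")) {
  stopifnot(inherits(truth, "cage_truth"))
  if (rem_fraction < 0 || rem_fraction > 1) {
    abort("`rem_fraction` must be in [0, 1]")
  }
  rem_placement <- match.arg(rem_placement)
  sec_labels <- ifelse(truth$states$state == "Sleep", "Sleep", "Wake")
  h <- epoch_by_majority(sec_labels, epoch_s)
  if (!three_state || rem_fraction == 0) return(h)

  lab <- ifelse(h$label == "Sleep", "NREM", "Wake")
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- as.integer(ends - r$lengths + 1L)
  sleep_runs <- which(r$values == "NREM")
  target <- round(rem_fraction * sum(lab == "NREM"))
  onsets <- integer(0)
  remaining <- target
  for (k in sleep_runs) {
    if (remaining <= 0) break
    len <- r$lengths[k]
    if (len < 2) next                       # keep at least one NREM epoch
    take <- min(remaining, max(1L, floor(len * rem_fraction)), len - 1L)
    if (rem_placement == "tail") {
      idx <- (ends[k] - take + 1):ends[k]
    } else {
      if (starts[k] == 1) next              # no preceding wake run to transition from
      idx <- starts[k]:(starts[k] + take - 1)
      onsets <- c(onsets, starts[k])
    }
    lab[idx] <- "REM"
    remaining <- remaining - take
  }
  out <- hypnogram(lab, epoch_s)
  attr(out, "wake_to_rem_onsets") <- onsets
  out
}

# Majority label per epoch over a per-second label vector; ties -> Wake,
# trailing partial epoch dropped (with a note when one exists).
epoch_by_majority <- function(sec_labels, epoch_s) {
  n_full <- length(sec_labels) %/% epoch_s
  dropped <- length(sec_labels) - n_full * epoch_s
  if (dropped > 0) {
    inform(sprintf("dropping trailing partial epoch (%d s)", dropped))
  }
  if (n_full == 0) return(hypnogram(character(0), epoch_s))
  m <- matrix(sec_labels[seq_len(n_full * epoch_s)] == "Sleep",
              nrow = epoch_s)
  sleep_frac <- colMeans(m)
  hypnogram(ifelse(sleep_frac > 0.5, "Sleep", "Wake"), epoch_s)
}
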
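# Shared fixtures and independent oracles. Everything is generated in code;
# the oracles deliberately use naive explicit loops so they share no code
# path with the implementations they check.

# small, fast rendering scenario used across tests
test_scenario <- function(...) {
  cage_scenario(width_px = 160, height_px = 128, fps = 5,
                mouse_radius_px = 12, distractors = NULL, ...)
}

test_vision_params <- function(radius = 12) {
  vision_params(expected_area_px = round(pi * 1.4 * 0.75 * radius^2))
}

as_activity <- function(active, start_second = 0) {
  structure(tibble::tibble(second = start_second + seq_along(active) - 1,
                           active = active),
            class = c("activity_trace", class(tibble::tibble())))
}

# brute-force run-length staging oracle: explicit scan for immobility runs,
# then repeated scans for the merging filter until nothing changes
oracle_stage <- function(active, min_s = 40, merge_s = 15) {
  n <- length(active)
  lab <- rep("Wake", n)
  i <- 1
  while (i <= n) {
    if (!active[i]) {
      j <- i
      while (j <= n && !active[j]) j <- j + 1
      if ((j - i) >= min_s) lab[i:(j - 1)] <- "Sleep"
      i <- j
    } else {
      i <- i + 1
    }
  }
  repeat {
    changed <- FALSE
    i <- 1
    while (i <= n) {
      if (lab[i] == "Wake") {
        j <- i
        while (j <= n && lab[j] == "Wake") j <- j + 1
        if (i > 1 && j <= n && (j - i) <= merge_s &&
            lab[i - 1] == "Sleep" && lab[j] == "Sleep") {
          lab[i:(j - 1)] <- "Sleep"
          changed <- TRUE
        }
        i <- j
      } else {
        i <- i + 1
      }
    }
    if (!changed) break
  }
  lab
}

# random binary activity traces with block structure (geometric run lengths)
# so immobility runs straddle the 40 s rule and gaps straddle the merge rule
random_trace <- function(n = 300, p_flip = 0.05) {
  v <- logical(n)
  cur <- runif(1) < 0.5
  for (i in seq_len(n)) {
    if (runif(1) < p_flip) cur <- !cur
    v[i] <- cur
  }
  v
}

# BFS flood-fill connected-component oracle (8-connectivity)
oracle_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) {
    for (r0 in seq_len(nr)) {
      if (!mask[r0, c0] || lab[r0, c0] > 0) next
      nxt <- nxt + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] && lab[r, c] == 0) {
            lab[r, c] <- nxt
            queue[[length(queue) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# one-row detection tibble for hand-built feature-difference tests
fake_detection <- function(time_s, row, col, gray = 120, score = 0.9,
                           pixels = 1:10, present = TRUE) {
  tibble::tibble(frame = NA_integer_, time_s = time_s, present = present,
                 carried = !present, gap_s = 0, row = row, col = col,
                 area = length(pixels), gray = gray, score = score,
                 pixels = list(as.integer(pixels)))
}

# labelled disk-vs-background patches: linearly separable classifier fixture
disk_patch_set <- function(n_per_class = 200, size = 40, seed = 1) {
  set.seed(seed)
  mk_disk <- function() {
    f <- matrix(180 + rnorm(size^2, 0, 2), size, size)
    r0 <- runif(1, size * 0.3, size * 0.7)
    c0 <- runif(1, size * 0.3, size * 0.7)
    rad <- runif(1, size * 0.15, size * 0.25)
    idx <- which(outer((1:size - r0)^2, (1:size - c0)^2, "+") <= rad^2)
    f[idx] <- 110 + rnorm(length(idx), 0, 2)
    f
  }
  mk_bg <- function() matrix(180 + rnorm(size^2, 0, 2), size, size)
  tibble::tibble(
    patch = c(replicate(n_per_class, mk_disk(), simplify = FALSE),
              replicate(n_per_class, mk_bg(), simplify = FALSE)),
    label = rep(c(1L, 0L), each = n_per_class)
  )
}

# cached small trained classifier + matching truth/scenario for vision tests
test_pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- test_scenario()
    truth <- add_trajectory(
      simulate_state_sequence(state_model(), 240, seed = 101), sc)
    patches <- harvest_training_patches(truth, sc, n_per_class = 80,
                                        params = test_vision_params(),
                                        seed = 7)
    cl <- train_classifier(patches, train_config(seed = 3))
    cache <<- list(scenario = sc, truth = truth, classifier = cl,
                   vparams = test_vision_params())
    cache
  }
})
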
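make_disk_frame <- function(nr = 128, nc = 160, bg = 180, disks = list()) {
  f <- matrix(bg, nr, nc)
  for (d in disks) {
    idx <- outer((1:nr - d$row)^2, (1:nc - d$col)^2, "+") <= d$radius^2
    f[idx] <- d$gray
  }
  f
}

test_that("uniform and degenerate frames yield no candidates", {
  p <- test_vision_params()
  expect_equal(nrow(extract_roi_candidates(matrix(128, 100, 100), p)), 0)
  expect_equal(nrow(extract_roi_candidates(matrix(numeric(0), 0, 0), p)), 0)
  # pure noise should not produce spurious blobs either
  set.seed(1)
  noisy <- matrix(128 + rnorm(128 * 160, 0, 1.5), 128, 160)
  expect_equal(nrow(extract_roi_candidates(noisy, p)), 0)
})

test_that("a single disk is recovered with area within 10 percent", {
  p <- test_vision_params()
  f <- make_disk_frame(disks = list(list(row = 60, col = 80, radius = 20,
                                         gray = 120)))
  cands <- extract_roi_candidates(f, p)
  expect_equal(nrow(cands), 1)
  analytic <- pi * 20^2
  expect_lt(abs(cands$area - analytic) / analytic, 0.10)
  expect_equal(cands$row, 60, tolerance = 0.5)
  expect_equal(cands$col, 80, tolerance = 0.5)
  # centroid inside bounding box, area equals mask popcount
  expect_true(cands$rmin <= cands$row && cands$row <= cands$rmax)
  expect_equal(length(cands$pixels[[1]]), cands$area)
})

test_that("a disk plus two distractor blobs gives three candidates", {
  p <- test_vision_params()
  f <- make_disk_frame(disks = list(
    list(row = 40, col = 40, radius = 14, gray = 120),
    list(row = 90, col = 120, radius = 12, gray = 230),
    list(row = 30, col = 120, radius = 13, gray = 90)))
  expect_equal(nrow(extract_roi_candidates(f, p)), 3)
})

test_that("extraction is idempotent on the same frame", {
  fx <- test_pipeline_fixture()
  f <- render_frame(fx$truth, fx$scenario, 42)
  a <- extract_roi_candidates(f, fx$vparams)
  b <- extract_roi_candidates(f, fx$vparams)
  expect_identical(a, b)
})

test_that("component labelling agrees with a BFS flood-fill oracle", {
  set.seed(42)
  for (rep in 1:20) {
    mask <- matrix(runif(30 * 40) < 0.25, 30, 40)
    got <- cagesleep:::cpp_label(mask)
    want <- oracle_label(mask)
    # same partition: component pixel sets must match exactly
    expect_equal(max(got), max(want))
    gs <- unname(split(which(got > 0), got[got > 0]))
    ws <- unname(split(which(want > 0), want[want > 0]))
    expect_setequal(lapply(gs, sort), lapply(ws, sort))
  }
})

test_that("the selector takes the arg-max score with documented tie rules", {
  p <- test_vision_params()
  f <- make_disk_frame(disks = list(
    list(row = 40, col = 40, radius = 10, gray = 120),
    list(row = 90, col = 120, radius = 16, gray = 120)))
  cands <- extract_roi_candidates(f, p)
  expect_equal(nrow(cands), 2)
  # function classifier: score by proximity to the first disk
  by_position <- function(patch) if (mean(patch < 150) < 0.4) 0.8 else 0.2
  scores <- c(0.2, 0.8, 0.5)
  pick <- cagesleep:::pick_best_candidate(scores, c(1, 1, 1), c(1, 2, 3))
  expect_equal(pick, 2)
  # equal scores: larger area wins
  expect_equal(
    suppressMessages(cagesleep:::pick_best_candidate(c(0.5, 0.5), c(100, 400),
                                                     c(5, 9))), 2)
  # equal scores and areas: lower row index wins
  expect_equal(
    suppressMessages(cagesleep:::pick_best_candidate(c(0.5, 0.5), c(100, 100),
                                                     c(9, 5))), 2)
  # single candidate wins outright through select_mouse
  one <- cands[1, ]
  sel <- select_mouse(one, function(patch) 0.9, f)
  expect_true(sel$present)
  expect_equal(sel$row, one$row)
  expect_equal(sel$score, 0.9)
})

test_that("no candidates gives an absent, flagged detection", {
  sel <- select_mouse(extract_roi_candidates(matrix(100, 64, 64),
                                             test_vision_params()),
                      function(patch) 1, matrix(100, 64, 64))
  expect_false(sel$present)
  expect_true(is.na(sel$row))
})

test_that("detection tracks the true trajectory within 2 px RMS on a clean clip", {
  sc <- test_scenario()  # no distractors
  truth <- add_trajectory(simulate_state_sequence(state_model(), 60, seed = 21), sc)
  fx <- test_pipeline_fixture()
  det <- suppressMessages(
    detect_scenario(truth, sc, fx$classifier, fx$vparams))
  expect_true(all(det$present))
  err <- sqrt((det$row - truth$trajectory$row)^2 +
                (det$col - truth$trajectory$col)^2)
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("missing detections carry features forward and are flagged", {
  fx <- test_pipeline_fixture()
  sc <- fx$scenario
  truth <- add_trajectory(simulate_state_sequence(state_model(), 60, seed = 22), sc)
  st <- render_video(truth, sc, frames = 1:20)
  # blank out some frames so nothing is detectable there
  st$frames[, , 8:9] <- 128
  det <- suppressMessages(detect_frames(st, fx$classifier, fx$vparams))
  expect_false(any(det$present[8:9]))
  expect_true(all(det$carried[8:9]))
  expect_equal(det$row[8], det$row[7])
  expect_equal(det$gap_s[9], st$times[9] - st$times[7])
  expect_true(all(det$present[c(1:7, 10:20)]))
})

test_that("detections round-trip to CSV", {
  fx <- test_pipeline_fixture()
  truth <- add_trajectory(simulate_state_sequence(state_model(), 60, seed = 23),
                          fx$scenario)
  st <- render_video(truth, fx$scenario, frames = 1:5)
  det <- detect_frames(st, fx$classifier, fx$vparams)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 5)
  expect_equal(back$row, det$row, tolerance = 1e-6)
})
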
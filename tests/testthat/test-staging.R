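test_that("feature differences are zero for identical detections", {
  det <- dplyr::bind_rows(
    fake_detection(0, 50, 60), fake_detection(1, 50, 60),
    fake_detection(2, 50, 60), fake_detection(3, 50, 60),
    fake_detection(4, 50, 60))
  d <- compute_feature_diffs(det, 3, staging_params())
  expect_equal(nrow(d), 4)
  expect_true(all(d$P == 0 & d$M == 0 & d$A == 0 & d$G == 0))
  expect_false(judge_active(d, staging_params()))
})

test_that("disjoint masks give M = 1 and a (3,4) shift gives A = 5", {
  det <- dplyr::bind_rows(
    fake_detection(0, 50, 60, pixels = 1:10),
    fake_detection(1, 53, 64, pixels = 11:20))
  d <- compute_feature_diffs(det, 1, staging_params(window_half_width = 1))
  expect_equal(d$M, 1)
  expect_equal(d$A, 5)
  # partial overlap: 1 - IoU
  det2 <- dplyr::bind_rows(
    fake_detection(0, 0, 0, pixels = 1:10),
    fake_detection(1, 0, 0, pixels = 6:15))
  d2 <- compute_feature_diffs(det2, 1, staging_params(window_half_width = 1))
  expect_equal(d2$M, 1 - 5 / 15)
})

test_that("the activity judgement applies the published threshold clauses", {
  p <- staging_params()
  mk <- function(P = 0, M = 0, A = 0, G = 0) {
    tibble::tibble(offset = 1L, P = P, M = M, A = A, G = G)
  }
  expect_false(judge_active(mk(), p))
  expect_true(judge_active(mk(A = 6), p))          # A > 5 px
  expect_false(judge_active(mk(A = 5), p))         # strict inequality
  expect_true(judge_active(mk(G = 3.5), p))        # G > 3 gray levels
  expect_true(judge_active(mk(P = 0.11), p))       # P > 0.1
  # combined clause: (G/255 + M + P)/3 > 0.5 with sub-threshold components
  expect_true(judge_active(mk(P = 0.09, M = 0.95, G = 2.9,
                              A = 0), staging_params(thr_combined = 0.35)))
  # spec example: P=0.05, G=2, A=4, combined mean ~0.2 -> inactive
  expect_false(judge_active(mk(P = 0.05, M = 0.5, A = 4, G = 2), p))
  # empty differences: inactive with a low-confidence flag
  empty <- mk()[0, ]
  out <- judge_active(empty, p)
  expect_false(as.logical(out))
  expect_true(attr(out, "low_confidence"))
})

test_that("the 40 s immobility rule is strict and the merge rule is <= 15 s", {
  p <- staging_params()
  h39 <- stage_sleep_wake(as_activity(c(rep(TRUE, 30), rep(FALSE, 39),
                                        rep(TRUE, 30))), p)
  expect_true(all(h39$label == "Wake"))
  h40 <- stage_sleep_wake(as_activity(c(rep(TRUE, 30), rep(FALSE, 40),
                                        rep(TRUE, 30))), p)
  expect_equal(sum(h40$label == "Sleep"), 40)
  expect_equal(bouts(h40)$state, c("Wake", "Sleep", "Wake"))
  # all-inactive trace is one long sleep bout
  hall <- stage_sleep_wake(as_activity(rep(FALSE, 3600)), p)
  expect_equal(bouts(hall)$duration_s, 3600)
  # merge examples
  m10 <- stage_sleep_wake(as_activity(c(rep(FALSE, 60), rep(TRUE, 10),
                                        rep(FALSE, 60))), p)
  expect_equal(bouts(m10)$duration_s, 130)
  m16 <- stage_sleep_wake(as_activity(c(rep(FALSE, 60), rep(TRUE, 16),
                                        rep(FALSE, 60))), p)
  expect_equal(nrow(bouts(m16)), 3)
})

test_that("merging iterates to a fixed point and zero threshold is identity", {
  h <- hypnogram(c(rep("Sleep", 50), rep("Wake", 10), rep("Sleep", 50),
                   rep("Wake", 10), rep("Sleep", 50)), 1)
  merged <- merge_brief_movements(h, 15)
  expect_true(all(merged$label == "Sleep"))
  expect_identical(merge_brief_movements(h, 0)$label, h$label)
  # wake at the trace edge is never merged (no flanking sleep)
  edge <- hypnogram(c(rep("Wake", 5), rep("Sleep", 60)), 1)
  expect_identical(merge_brief_movements(edge, 15)$label, edge$label)
})

test_that("short traces stage all wake with a warning", {
  expect_warning(h <- stage_sleep_wake(as_activity(rep(FALSE, 20)),
                                       staging_params()), "shorter")
  expect_true(all(h$label == "Wake"))
})

test_that("epoching uses majority with ties to Wake and drops partials", {
  p <- staging_params()
  hs <- hypnogram(rep(c("Sleep", "Wake"), c(11, 9)), 1)
  expect_equal(epoch_hypnogram(hs, 20)$label, "Sleep")
  tie <- hypnogram(rep(c("Sleep", "Wake"), c(10, 10)), 1)
  expect_equal(epoch_hypnogram(tie, 20)$label, "Wake")
  all_sleep <- hypnogram(rep("Sleep", 100), 1)
  expect_true(all(epoch_hypnogram(all_sleep, 20)$label == "Sleep"))
  # 72 h at 20 s -> 12,960 epochs
  h72 <- hypnogram(rep("Wake", 259200), 1)
  expect_equal(nrow(epoch_hypnogram(h72, 20)), 12960)
})

test_that("sleep and wake durations are conserved through merging", {
  set.seed(77)
  p <- staging_params()
  for (rep in 1:20) {
    tr <- random_trace(500)
    h <- stage_sleep_wake(as_activity(tr), p)
    expect_equal(nrow(h), 500)
    expect_equal(sum(h$label == "Sleep") + sum(h$label == "Wake"), 500)
  }
})

test_that("staging plus merging matches the brute-force oracle exactly", {
  set.seed(123)
  p <- staging_params()
  for (rep in 1:200) {
    tr <- random_trace(400, p_flip = runif(1, 0.01, 0.15))
    h <- stage_sleep_wake(as_activity(tr), p)
    expect_identical(h$label, oracle_stage(tr, 40, 15))
  }
})

test_that("sleep time and bout counts are monotone in the merge threshold", {
  set.seed(99)
  th <- c(0, 5, 10, 15, 20, 25, 30)
  for (rep in 1:25) {
    tr <- random_trace(600, p_flip = runif(1, 0.02, 0.1))
    sleep_s <- integer(0); nb <- integer(0)
    for (t in th) {
      p <- staging_params(merge_filter_s = t)
      h <- stage_sleep_wake(as_activity(tr), p)
      sleep_s <- c(sleep_s, sum(h$label == "Sleep"))
      nb <- c(nb, n_bouts(h, "Sleep"))
    }
    expect_true(all(diff(sleep_s) >= 0))
    expect_true(all(diff(nb) <= 0))
  }
})

test_that("the threshold sweep tabulates agreement and fine bout counts", {
  lab <- rep(TRUE, 1200)
  for (s in c(100, 500, 900)) lab[s:(s + 200)] <- FALSE
  for (tw in c(150, 560, 950)) lab[tw:(tw + 8)] <- TRUE
  act <- as_activity(lab)
  ref <- suppressMessages(
    epoch_hypnogram(stage_sleep_wake(act, staging_params()), 20))
  sw <- sweep_merge_threshold(act, ref)
  expect_equal(sw$threshold_s, c(0, 5, 10, 15, 20, 25, 30))
  # twitch gaps fragment the fine staging below the 10 s threshold only
  expect_gt(sw$bout_count[1], sw$bout_count[4])
  expect_true(all(diff(sw$bout_count) <= 0))
  expect_true(all(diff(sw$total_sleep_min) >= 0))
  # twitch-free trace: identical metrics at every threshold
  calm <- rep(TRUE, 600); calm[100:300] <- FALSE
  act2 <- as_activity(calm)
  ref2 <- suppressMessages(
    epoch_hypnogram(stage_sleep_wake(act2, staging_params()), 20))
  sw2 <- sweep_merge_threshold(act2, ref2)
  expect_equal(length(unique(sw2$accuracy)), 1)
  expect_equal(length(unique(sw2$bout_count)), 1)
})

test_that("carried-forward frames count as inactive and long gaps are excluded", {
  p <- staging_params(window_half_width = 1)
  base <- purrr::map(0:9, function(t) fake_detection(t, 50 + 10 * t, 60))
  det <- dplyr::bind_rows(base)
  det$present[4:5] <- FALSE; det$carried[4:5] <- TRUE
  det$gap_s[4] <- 1; det$gap_s[5] <- 2
  act <- suppressMessages(activity_from_detections(det, p))
  # moving detections around the gap are still active
  expect_true(any(act$active, na.rm = TRUE))
  # a long gap removes all evidence for those seconds
  det$gap_s[4] <- 5; det$gap_s[5] <- 6
  act2 <- suppressMessages(activity_from_detections(det, p))
  expect_true(all(is.na(act2$active[4:5])))
})
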
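test_that("agreement metrics satisfy their defining identities", {
  a <- hypnogram(rep(c("Sleep", "Wake"), 50), 20)
  same <- compare_staging(a, a)
  g <- glance(same)
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 1)
  expect_equal(g$accuracy, 1)
  flip <- hypnogram(rep(c("Wake", "Sleep"), 50), 20)
  expect_equal(glance(compare_staging(flip, a))$accuracy, 0)
  # hand-built confusion: 100 epochs, 40 true sleep, 10 sleep epochs missed
  ref <- hypnogram(rep(c("Sleep", "Wake"), c(40, 60)), 20)
  test <- hypnogram(rep(c("Sleep", "Wake", "Wake"), c(30, 10, 60)), 20)
  agr <- compare_staging(test, ref)
  expect_equal(agr$tp, 30); expect_equal(agr$fn, 10)
  expect_equal(agr$sensitivity, 0.75)
  expect_equal(agr$accuracy, 0.90)
  expect_equal(sum(tidy(agr)$n), 100)
})

test_that("swapping test and reference preserves accuracy and swaps the rates", {
  set.seed(5)
  a <- hypnogram(sample(c("Sleep", "Wake"), 200, TRUE), 20)
  b <- hypnogram(sample(c("Sleep", "Wake"), 200, TRUE), 20)
  ab <- glance(compare_staging(a, b))
  ba <- glance(compare_staging(b, a))
  expect_equal(ab$accuracy, ba$accuracy)
  # swapping roles transposes the confusion matrix: FP and FN exchange
  expect_equal(compare_staging(a, b)$fp, compare_staging(b, a)$fn)
})

test_that("misaligned hypnograms fail loudly with both lengths named", {
  a <- hypnogram(rep("Sleep", 10), 20)
  b <- hypnogram(rep("Sleep", 12), 20)
  expect_error(compare_staging(a, b), "10.*12")
  expect_error(compare_staging(a, hypnogram(rep("Sleep", 10), 10)),
               "epoch lengths")
})

test_that("three-state references collapse NREM and REM into sleep", {
  ref3 <- hypnogram(c("Wake", "NREM", "REM", "NREM"), 20)
  test <- hypnogram(c("Wake", "Sleep", "Sleep", "Sleep"), 20)
  expect_equal(glance(compare_staging(test, ref3))$accuracy, 1)
})

test_that("hourly summaries tally minutes per zeitgeber hour", {
  all_wake <- hypnogram(rep("Wake", 4320), 20)   # one day
  s <- sleep_time_summary(all_wake)
  expect_true(all(s$hourly$minutes[s$hourly$state == "Sleep"] == 0))
  expect_true(all(s$hourly$minutes[s$hourly$state == "Wake"] == 60))
  alt <- hypnogram(rep(c("Sleep", "Wake"), 2160), 20)
  sa <- sleep_time_summary(alt)
  expect_true(all(sa$hourly$minutes == 30))
  expect_equal(sa$daily$minutes[sa$daily$state == "Sleep"], 720)
  # simulator truth: per-hour tally matches the ground truth exactly
  tr <- simulate_state_sequence(state_model(), 7200, seed = 12)
  h <- hypnogram(tr$states$state, 1)
  st <- sleep_time_summary(h)
  for (hr in 0:1) {
    want <- sum(tr$states$state[(hr * 3600 + 1):((hr + 1) * 3600)] == "Sleep") / 60
    got <- st$hourly$minutes[st$hourly$zt_hour == hr &
                               st$hourly$state == "Sleep"]
    expect_equal(got, want)
  }
  # multi-day recordings average per ZT hour
  two_days <- hypnogram(rep(c("Sleep", "Wake"), c(4320, 4320)), 20)
  s2 <- sleep_time_summary(two_days)
  expect_true(all(s2$hourly$minutes == 30))
  # daily totals carry explicit zero rows for absent states
  expect_equal(nrow(s2$daily), 4)
  expect_equal(s2$daily$minutes[s2$daily$day == 2 &
                                  s2$daily$state == "Sleep"], 0)
})

test_that("delta ratio is band power over total power, NREM epochs only", {
  h <- hypnogram(rep(c("NREM", "Wake"), c(6, 6)), 20)
  sp <- simulate_spectral_epochs(h, seed = 2)
  # flat spectrum: ratio is exactly 4 bins of 30
  flat <- sp; flat[, paste0("bin_", 1:30)] <- 1
  rd <- relative_delta_power(flat, h)
  expect_equal(rd$delta_ratio[1], 4 / 30)
  expect_equal(rd$n_epochs[1], 6)
  # all power in delta: ratio 1
  delta_only <- sp
  delta_only[, paste0("bin_", 5:30)] <- 0
  expect_equal(relative_delta_power(delta_only, h)$delta_ratio[1], 1)
  # no NREM in the hour: missing value
  hw <- hypnogram(rep("Wake", 12), 20)
  expect_true(is.na(relative_delta_power(sp, hw)$delta_ratio[1]))
  # zero-power epochs are excluded with a note
  z <- sp; z[1, paste0("bin_", 1:30)] <- 0
  expect_message(relative_delta_power(z, h), "zero total power")
  # ratios always bounded
  r <- suppressMessages(relative_delta_power(sp, h))
  expect_true(all(r$delta_ratio >= 0 & r$delta_ratio <= 1, na.rm = TRUE))
})

test_that("state spectra are percentages that sum to 100 per state", {
  h <- hypnogram(c("NREM", "NREM", "REM", "Wake"), 20)
  sp <- simulate_spectral_epochs(h, seed = 3)
  out <- state_power_spectra(sp, h)
  sums <- tapply(out$percent, out$state, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # single epoch with all power in one bin
  one <- hypnogram("NREM", 20)
  spo <- simulate_spectral_epochs(one, 1)
  spo[, paste0("bin_", 1:30)] <- 0; spo$bin_7 <- 5
  po <- state_power_spectra(spo, one)
  expect_equal(po$percent[po$freq_hz == 7], 100)
  expect_equal(sum(po$percent), 100)
  # two epochs: output is the mean of per-epoch percentages
  two <- hypnogram(c("NREM", "NREM"), 20)
  spt <- simulate_spectral_epochs(two, 1)
  B <- as.matrix(spt[, paste0("bin_", 1:30)])
  want <- colMeans(100 * B / rowSums(B))
  got <- state_power_spectra(spt, two)
  expect_equal(got$percent, unname(want))
  # absent state is omitted with a note
  expect_message(state_power_spectra(spo, one), NA)
})

test_that("wake-to-REM detection counts only direct transitions", {
  h <- hypnogram(c("Wake", "Wake", "REM", "REM", "Wake", "NREM", "REM"), 20)
  ep <- detect_wake_to_rem(h)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset_epoch, 3)
  expect_equal(ep$wake_run_s, 40)
  # no REM at all
  h0 <- hypnogram(c("Wake", "NREM", "NREM", "Wake"), 20)
  expect_equal(nrow(detect_wake_to_rem(h0)), 0)
  # REM at the very start has no preceding run and is not counted
  h1 <- hypnogram(c("REM", "Wake", "NREM"), 20)
  expect_equal(nrow(detect_wake_to_rem(h1)), 0)
  # minimum wake duration filters short interruptions
  h2 <- hypnogram(c("NREM", "Wake", "REM"), 20)
  expect_equal(nrow(detect_wake_to_rem(h2, min_wake_s = 40)), 0)
  expect_equal(nrow(detect_wake_to_rem(h2, min_wake_s = 20)), 1)
  # two-state input is an error
  expect_error(detect_wake_to_rem(hypnogram(c("Sleep", "Wake"), 20)),
               "three-state")
})

test_that("the rule-based stager follows its rule table", {
  mk_epoch <- function(delta = 0.1, theta = 0.1, emg = 1) {
    p <- rep((1 - delta - theta) / 24, 30)
    p[1:4] <- delta / 4; p[6:9] <- theta / 4
    out <- as.list(p); names(out) <- paste0("bin_", 1:30)
    tibble::as_tibble(c(list(epoch = 1L), out, list(emg = emg)))
  }
  sp <- dplyr::bind_rows(
    mk_epoch(delta = 0.8, emg = 0.05),             # high delta, low EMG
    mk_epoch(theta = 0.7, emg = 0.001),            # high theta, atonia
    mk_epoch(delta = 0.1, theta = 0.1, emg = 2),   # active wake
    mk_epoch(delta = 0.5, emg = 3))                # high delta but high EMG
  sp$epoch <- 1:4
  h <- rule_based_eeg_stager(sp, emg_low_q = 0.5, emg_atonia_q = 0.3)
  expect_equal(h$label, c("NREM", "REM", "Wake", "Wake"))
  # EMG-free tables fall back to two states with a warning
  expect_warning(h2 <- rule_based_eeg_stager(sp[, setdiff(names(sp), "emg")]),
                 "EMG")
  expect_identical(attr(h2, "alphabet"), c("Sleep", "Wake"))
})

test_that("the stager recovers a synthetic hypnogram from its band powers", {
  set.seed(21)
  lab <- rep(c("Wake", "NREM", "REM", "NREM", "Wake"), c(30, 40, 10, 30, 40))
  h <- hypnogram(lab, 20)
  sp <- simulate_spectral_epochs(h, seed = 14)
  staged <- rule_based_eeg_stager(sp)
  expect_gt(mean(staged$label == lab), 0.9)
})
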
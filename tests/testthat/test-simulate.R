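test_that("state sequence tiles the duration exactly and twitches stay inside sleep", {
  m <- state_model(mean_wake_bout_s = 300, mean_sleep_bout_s = 300)
  for (seed in 1:5) {
    tr <- simulate_state_sequence(m, 3600, seed = seed)
    expect_equal(sum(tr$bouts$end_s - tr$bouts$start_s), 3600)
    expect_equal(tr$bouts$start_s[-1], tr$bouts$end_s[-nrow(tr$bouts)])
    expect_equal(nrow(tr$states), 3600)
    sleep <- tr$bouts[tr$bouts$state == "Sleep", ]
    for (k in seq_len(nrow(tr$twitches))) {
      expect_true(any(sleep$start_s <= tr$twitches$start_s[k] &
                        sleep$end_s >= tr$twitches$end_s[k]))
    }
  }
})

test_that("zero twitch rate gives no twitches and short durations are rejected", {
  m0 <- state_model(twitch_rate_per_min = 0)
  tr <- simulate_state_sequence(m0, 1800, seed = 2)
  expect_equal(nrow(tr$twitches), 0)
  expect_error(simulate_state_sequence(state_model(), 30), ">= 60")
  expect_error(state_model(mean_sleep_bout_s = 10), "exceed")
  expect_error(state_model(twitch_rate_per_min = -1), ">= 0")
})

test_that("fixed seed reproduces the ground truth bit-identically", {
  m <- state_model()
  a <- simulate_state_sequence(m, 1200, seed = 33)
  b <- simulate_state_sequence(m, 1200, seed = 33)
  expect_identical(a, b)
  sc <- test_scenario()
  expect_identical(add_trajectory(a, sc)$trajectory,
                   add_trajectory(b, sc)$trajectory)
})

test_that("twitch counts follow the Poisson expectation at rate 2/min", {
  m <- state_model(twitch_rate_per_min = 2)
  counts <- numeric(100); expected <- numeric(100)
  for (seed in 1:100) {
    tr <- simulate_state_sequence(m, 1800, seed = seed)
    counts[seed] <- nrow(tr$twitches)
    sleep_min <- sum(with(tr$bouts, (end_s - start_s)[state == "Sleep"])) / 60
    expected[seed] <- 2 * sleep_min
  }
  se <- sqrt(sum(expected)) / 100
  expect_lt(abs(mean(counts) - mean(expected)), 3 * se)
})

test_that("empirical bout means match the model within 5 percent", {
  m <- state_model(mean_wake_bout_s = 300, mean_sleep_bout_s = 300,
                   twitch_rate_per_min = 0)
  tr <- simulate_state_sequence(m, 400000, seed = 5)
  b <- tr$bouts[-nrow(tr$bouts), ]  # last bout is truncated
  expect_gt(nrow(b), 200)
  for (s in c("Wake", "Sleep")) {
    len <- with(b, (end_s - start_s)[state == s])
    expect_lt(abs(mean(len) - 300) / 300, 0.05)
    expect_gte(min(len), 20)  # shifted gamma minimum
  }
})

test_that("reference hypnogram epochs by majority and drops partial epochs", {
  m <- state_model()
  tr <- simulate_state_sequence(m, 3600, seed = 4)
  h <- emit_reference_hypnogram(tr, 20)
  expect_equal(nrow(h), 180)
  expect_identical(attr(h, "alphabet"), c("Sleep", "Wake"))
  # majority check against a direct per-second tally
  for (e in c(1, 50, 180)) {
    secs <- tr$states$state[((e - 1) * 20 + 1):(e * 20)]
    expect_equal(h$label[e],
                 if (mean(secs == "Sleep") > 0.5) "Sleep" else "Wake")
  }
  expect_message(emit_reference_hypnogram(tr, 7), "partial epoch")
  expect_equal(nrow(suppressMessages(emit_reference_hypnogram(tr, 7))),
               3600 %/% 7)
})

test_that("three-state relabelling respects rem_fraction and placement", {
  m <- state_model()
  tr <- simulate_state_sequence(m, 7200, seed = 8)
  expect_error(emit_reference_hypnogram(tr, 20, TRUE, rem_fraction = 1.5),
               "rem_fraction")
  h2 <- emit_reference_hypnogram(tr, 20, three_state = TRUE, rem_fraction = 0)
  expect_identical(attr(h2, "alphabet"), c("Sleep", "Wake"))
  h3 <- emit_reference_hypnogram(tr, 20, three_state = TRUE,
                                 rem_fraction = 0.15)
  expect_identical(attr(h3, "alphabet"), c("Wake", "NREM", "REM"))
  expect_gt(sum(h3$label == "REM"), 0)
  # tail placement: REM always follows NREM, never wake
  prev <- h3$label[which(h3$label == "REM") - 1]
  expect_true(all(prev %in% c("NREM", "REM")))
})
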
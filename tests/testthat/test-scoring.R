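test_that("ongoing scoring discards orientation trials and tallies the rest", {
  sides <- rep(c("left", "right"), 15)
  ## all correct at a fixed 800 ms
  s <- ongoingStream(sides, sides, rep(800, 30))
  sc <- scoreOngoing(s, discardFirst = 10L)
  expect_equal(sc$n_trials, 20)
  expect_equal(sc$accuracy_pct, 100)
  expect_equal(sc$mean_rt_ms, 800)

  expect_error(scoreOngoing(s[s$t_ms < 10 * 2000, ], 10L), "discard")
})

test_that("ongoing scoring equals a hand-enumerated tally on a mixed stream", {
  sides <- c("left", "right", "left", "left", "right", "right")
  resp  <- c("left", "left", NA, "left", "right", "left")
  rts   <- c(500, 700, NA, 900, 1100, 1300)
  s <- ongoingStream(sides, resp, rts)
  sc <- scoreOngoing(s, discardFirst = 0L)
  ## by hand: correct = trials 1, 4, 5 (no-response trial 3 is incorrect)
  expect_equal(sc$accuracy_pct, 100 * 3 / 6)
  expect_equal(sc$mean_rt_ms, mean(c(500, 900, 1100)))
  expect_equal(sc$n_trials, 6)
})

test_that("event-PM credit window spans the target and the following trial", {
  sides <- c("left", "left", NA, "left", "left", NA, "left", "left")
  tgt <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  rows <- list()
  for (i in seq_along(sides)) {
    rows[[length(rows) + 1L]] <- streamRow((i - 1) * 2000, "stimulus_on",
                                           target = tgt[i],
                                           side = sides[i])
    if (!tgt[i])
      rows[[length(rows) + 1L]] <- streamRow((i - 1) * 2000 + 600, sides[i])
  }
  base <- do.call(rbind, rows)

  ## press inside the target trial: credited
  s1 <- buildStream(base, streamRow(2 * 2000 + 500, "spacebar"),
                    streamRow(5 * 2000 + 500, "spacebar"))
  expect_equal(scoreEventPM(s1)$pm$accuracy_pct, 100)
  expect_equal(scoreEventPM(s1)$pm$mean_rt_ms, 500)

  ## press during the following trial: still credited (late response)
  s2 <- buildStream(base, streamRow(3 * 2000 + 500, "spacebar"),
                    streamRow(5 * 2000 + 500, "spacebar"))
  expect_equal(scoreEventPM(s2)$pm$accuracy_pct, 100)

  ## press two trials later: outside the window, target missed
  s3 <- buildStream(base, streamRow(4 * 2000 + 500, "spacebar"),
                    streamRow(5 * 2000 + 500, "spacebar"))
  expect_equal(scoreEventPM(s3)$pm$accuracy_pct, 50)

  ## ongoing trials are scored over non-targets only
  expect_equal(scoreEventPM(s1)$ogpm$n_trials, 6)
  expect_error(scoreEventPM(base[!base$is_pm_target, ]), "target")
})

test_that("event-PM accuracy equals an independent window matcher", {
  set.seed(404)
  for (rep in 1:5) {
    hit <- runif(15) < 0.6
    stream <- generateTrialStream("PM_phase_event",
                                  list(pmHitRate = 0, rtSdLog = 0.1),
                                  seed = rep)
    ## inject presses for chosen targets only, 400 ms after onset
    stim <- stream[stream$kind == "stimulus_on", ]
    tOnsets <- stim$t_ms[stim$is_pm_target]
    press <- do.call(rbind, lapply(tOnsets[hit], function(t0)
      streamRow(t0 + 400, "spacebar")))
    s <- buildStream(stream, press)
    expect_equal(scoreEventPM(s)$pm$accuracy_pct, 100 * mean(hit))
  }
})

test_that("time-based scoring: intervals, press ratio and clock checks", {
  mk <- function(pressS, durS = 300, checks = numeric(0)) {
    rows <- list(streamRow(0, "stimulus_on"),
                 streamRow(durS * 1000, "stimulus_on"))
    for (p in pressS)
      rows[[length(rows) + 1L]] <- streamRow(p * 1000, "spacebar")
    for (cc in checks) {
      rows[[length(rows) + 1L]] <- streamRow(cc * 1000, "clock_open")
      rows[[length(rows) + 1L]] <- streamRow(cc * 1000 + 800, "clock_close")
    }
    do.call(buildStream, rows)
  }
  ideal <- scoreTimePM(mk(c(30, 60, 90), durS = 90))
  expect_equal(ideal$mean_interpress_s, 30)

  ## irregular pressing with the same mean: the mean alone cannot tell
  irr <- scoreTimePM(mk(c(10, 55, 70), durS = 70))
  expect_equal(irr$mean_interpress_s, 30)

  five <- scoreTimePM(mk(c(30, 90, 150, 210, 270)))
  expect_equal(five$press_ratio_pct, 50)  # 5 presses of an ideal 10
  expect_equal(five$press_count, 5)

  single <- scoreTimePM(mk(30))
  expect_true(is.na(single$mean_interpress_s))  # undefined, not zero

  checked <- scoreTimePM(mk(c(30, 60), checks = c(5, 20, 40)))
  expect_equal(checked$clock_checks, 3)
})

test_that("time-estimation totals: ideal, scaled and degenerate performers", {
  ideal1 <- scoreTimeEstimation(generateTrialStream("TE1"), "TE1")
  expect_equal(ideal1$total_s, 100)
  expect_equal(ideal1$trial_durations_s, c(10, 20, 30, 40))
  expect_false(ideal1$partial)

  ideal2 <- scoreTimeEstimation(generateTrialStream("TE2"), "TE2")
  expect_equal(ideal2$total_s, 100)

  fast <- scoreTimeEstimation(
    generateTrialStream("TE1", list(paceFactor = 1.5)), "TE1")
  expect_equal(fast$total_s, 150)

  immediate <- scoreTimeEstimation(
    generateTrialStream("TE2", list(paceFactor = 1e-4)), "TE2")
  expect_lt(immediate$total_s, 0.1)

  ## a trial without a final press is missing, and the total is partial
  s <- generateTrialStream("TE1")
  s <- s[-max(which(s$kind == "spacebar")), ]
  part <- scoreTimeEstimation(s, "TE1")
  expect_true(part$partial)
  expect_true(anyNA(part$trial_durations_s))
})

test_that("TE totals scale linearly with a uniform pace distortion", {
  for (f in c(0.5, 0.8, 1.3)) {
    got <- scoreTimeEstimation(
      generateTrialStream("TE2", list(paceFactor = f)), "TE2")
    expect_equal(got$total_s, 100 * f, tolerance = 1e-9)
  }
})

test_that("the fixed event schedule yields the printed design arithmetic", {
  sm <- eventScheduleSummary()
  expect_identical(sm$n_og_trials, 242L)
  expect_identical(sm$n_targets, 15L)
  expect_equal(sm$target_frequency_pct, 5.9)

  stream <- generateTrialStream("PM_phase_event", seed = 8)
  expect_silent(validateEventSchedule(stream))
  stim <- stream[stream$kind == "stimulus_on", ]
  expect_equal(sum(stim$is_pm_target), 15)
  expect_equal(sum(!stim$is_pm_target), 242)

  ## a stream without the scheduled targets is caught
  expect_error(validateEventSchedule(
    generateTrialStream("OGonly", seed = 1)), "targets")
})
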
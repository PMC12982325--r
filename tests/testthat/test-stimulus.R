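test_that("visual-angle geometry matches the closed form and its limits", {
  # 2 * 1.8 * tan(1.035 deg) = 0.06505 m -> 6.5 cm
  expect_equal(round(100 * visualAngleToDiameter(1.8, 2.07), 1), 6.5)
  # independent evaluation: 2 * 1.0 * tan(0.0180654 rad)
  expect_equal(visualAngleToDiameter(1.0, 2.07), 2 * tan(0.03613 / 2),
               tolerance = 1e-4)
  expect_identical(visualAngleToDiameter(0, 45), 0)
  # linear in depth at fixed angle
  d <- runif(5, 0.1, 3)
  expect_equal(visualAngleToDiameter(2 * d, 2.07),
               2 * visualAngleToDiameter(d, 2.07), tolerance = 1e-12)
  expect_error(visualAngleToDiameter(-1, 2.07), "depth")
  expect_error(visualAngleToDiameter(Inf, 2.07), "depth")
  expect_error(visualAngleToDiameter(1, 0), "angle")
  expect_error(visualAngleToDiameter(1, 180), "angle")
})

test_that("admissible frequencies follow the refresh/n rule exactly", {
  one <- admissibleFrequencies(90, 8, 8)
  expect_equal(one$frequency, 11.25)
  expect_equal(one$frames_per_cycle, 8L)

  grid <- admissibleFrequencies(90, 5, 12)
  expect_true(all(c(18, 11.25, 7.5) %in% grid$frequency))
  expect_equal(grid$frequency[grid$frames_per_cycle == 5], 18)
  expect_equal(grid$frequency[grid$frames_per_cycle == 12], 7.5)
  # rational identity with zero floating error
  expect_identical(grid$frequency * grid$frames_per_cycle, rep(90, nrow(grid)))

  expect_equal(admissibleFrequencies(90, 90, 90)$frequency, 1)
  expect_equal(nrow(admissibleFrequencies(90, 9, 8)), 0L)
  expect_error(admissibleFrequencies(0, 1, 5), "positive")
})

test_that("square wave renders whole on/off frames with exact duty cycle", {
  spec <- stimulusSpec(framesPerCycle = 8, refreshRate = 90, depth = 1.8)
  expect_equal(spec@frequency, 11.25)
  w <- squareWave(spec, duration = 8 / 90)
  expect_identical(w@samples, c(1, 1, 1, 1, 0, 0, 0, 0))

  expect_length(squareWave(spec, 0)@samples, 0L)

  w10 <- squareWave(spec, duration = 10 / 11.25)
  expect_identical(mean(w10@samples), 0.5)   # duty-cycle identity, exact
  expect_true(all(w10@samples %in% c(0, 1)))

  # non-frame-locked frequency rejected with the refresh/n rule named
  expect_error(stimulusSpec(frequency = 10.7, refreshRate = 90),
               "refreshRate / n")
  # fractional on-frames rejected
  expect_error(stimulusSpec(framesPerCycle = 8, dutyCycle = 0.3),
               "whole number")
})

test_that("blocked schedules reproduce the session structure and timing", {
  sched <- buildSchedule("MR", c(0.4, 1, 1.8), c(7.5, 11.25, 18), 10)
  expect_equal(nTrials(sched), 90L)
  expect_equal(totalDuration(sched), 810)   # 13.5 min
  tr <- trialInfo(sched)
  # per-cell repetition counts
  counts <- table(tr$depth, tr$frequency)
  expect_true(all(counts == 10))
  # strictly increasing, non-overlapping
  expect_true(all(diff(tr$cue_onset) > 0))
  expect_true(all(tr$cue_onset[-1] >= tr$rest_end[-90] - 1e-9))
  # blocked: first sub-block is one (depth, frequency) cell
  expect_equal(length(unique(tr$depth[1:30])), 1L)
  expect_equal(length(unique(tr$frequency[1:10])), 1L)
  # timing arithmetic: 1 + 5 + 3 s per trial
  expect_equal(tr$stim_onset - tr$cue_onset, rep(1, 90))
  expect_equal(tr$stim_offset - tr$stim_onset, rep(5, 90))
  expect_equal(tr$rest_end - tr$stim_offset, rep(3, 90))

  single <- buildSchedule("MR", 1, 11.25, 1)
  expect_equal(nTrials(single), 1L)
  expect_equal(totalDuration(single), 9)

  expect_error(buildSchedule("MR", 1, 11.25, 0), "repsPerCell")
})

test_that("randomised ordering keeps cell counts and timing grid", {
  sched <- buildSchedule("MR", c(0.4, 1.8), c(7.5, 18), 5,
                         ordering = "random", seed = 3)
  tr <- trialInfo(sched)
  expect_equal(nrow(tr), 20L)
  expect_true(all(table(tr$depth, tr$frequency) == 5))
  expect_true(all(diff(tr$stim_onset) == 9))
  # same seed reproduces the order
  tr2 <- trialInfo(buildSchedule("MR", c(0.4, 1.8), c(7.5, 18), 5,
                                 ordering = "random", seed = 3))
  expect_identical(tr$frequency, tr2$frequency)
})

test_that("schedules serialise to events TSV and JSON", {
  sched <- buildSchedule("VR", c(0.4, 1.8), c(7.5, 18), 2)
  tsv <- tempfile(fileext = ".tsv")
  writeScheduleTsv(sched, tsv)
  ev <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(ev), 8L)
  expect_named(ev, c("onset", "duration", "trial_type", "frequency",
                     "depth", "environment", "round"))
  expect_equal(ev$onset, trialInfo(sched)$stim_onset)
  expect_true(all(ev$duration == 5))

  js <- tempfile(fileext = ".json")
  writeScheduleJson(sched, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$trials), 8L)
  expect_equal(parsed$stim_duration, 5)
})
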
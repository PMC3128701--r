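smallSpec <- function(seed = 1L, ...) {
  g <- voxelGrid(c(12, 12, 12), 2)
  cohortSpec(nPatients = 8L, nControls = 12L, grid = g,
             lesionVolumeRange = c(0.1, 3), seed = seed, ...)
}

test_that("the same seed reproduces the cohort bit for bit", {
  a <- generateCohort(smallSpec(7L))
  b <- generateCohort(smallSpec(7L))
  expect_identical(lapply(a$masks, lesionIndices),
                   lapply(b$masks, lesionIndices))
  expect_identical(a$subjects, b$subjects)
  c2 <- generateCohort(smallSpec(8L))
  expect_false(identical(a$subjects$interpress_s,
                         c2$subjects$interpress_s))
})

test_that("subjects are stable when the cohort grows", {
  small <- generateCohort(smallSpec(5L))
  g <- voxelGrid(c(12, 12, 12), 2)
  big <- generateCohort(cohortSpec(nPatients = 12L, nControls = 12L,
                                   grid = g, lesionVolumeRange = c(0.1, 3),
                                   seed = 5L))
  for (i in 1:8)
    expect_identical(lesionIndices(big$masks[[i]]),
                     lesionIndices(small$masks[[i]]))
})

test_that("masks are valid, binary and in the requested volume range", {
  co <- generateCohort(smallSpec(3L))
  g <- co$masks[[1]]@grid
  for (m in co$masks) {
    idx <- lesionIndices(m)
    expect_true(length(idx) >= 1)
    expect_true(max(idx) <= prod(gridDims(g)))
    expect_identical(anyDuplicated(idx), 0L)
  }
})

test_that("carriers are exactly the patients overlapping the planted region", {
  g <- voxelGrid(c(12, 12, 12), 2)
  planted <- sphereRegion(g, c(8, 8, 6), 1.5)
  spec <- cohortSpec(nPatients = 10L, nControls = 15L, grid = g,
                     plantedRegion = planted, nCarriers = 4L,
                     lesionVolumeRange = c(0.1, 3), seed = 9L)
  co <- generateCohort(spec)
  byRule <- vapply(co$masks, function(m)
    sum(lesionIndices(m) %in% planted) >= 1L, logical(1))
  expect_setequal(co$groundTruth$carrierIds,
                  vapply(co$masks, subjectId, character(1))[byRule])
  expect_true(all(sprintf("P%03d", 1:4) %in% co$groundTruth$carrierIds))
  expect_equal(unname(co$groundTruth$trueEffects["interpress_s"]),
               48.1 - 32.9, tolerance = 1e-9)
})

test_that("a zero planted effect leaves carriers indistinguishable", {
  g <- voxelGrid(c(14, 14, 14), 2)
  planted <- sphereRegion(g, c(9, 9, 7), 1.5)
  nullModel <- list(interpress_s = list(mean = 32.9, sd = 9.6,
                                        carrierMean = 32.9, carrierSd = 9.6,
                                        range = c(5, 120)))
  ps <- vapply(1:200, function(s) {
    co <- generateCohort(cohortSpec(
      nPatients = 12L, nControls = 2L, grid = g, plantedRegion = planted,
      nCarriers = 5L, effectModel = nullModel,
      lesionVolumeRange = c(0.05, 0.5), seed = s))
    carr <- co$subjects$subject_id %in% co$groundTruth$carrierIds
    pat <- co$subjects$group == "patient"
    rankSumTest(co$subjects$interpress_s[carr & pat],
                co$subjects$interpress_s[!carr & pat])$p
  }, numeric(1))
  ks <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lt(ks, 0.12)  # uniform within Monte-Carlo + lattice slack
})

test_that("generated control scores follow the configured distribution", {
  g <- voxelGrid(c(8, 8, 8), 2)
  co <- generateCohort(cohortSpec(nPatients = 2L, nControls = 400L,
                                  grid = g, lesionVolumeRange = c(0.1, 1),
                                  seed = 31L))
  ctl <- co$subjects$interpress_s[co$subjects$group == "control"]
  expect_equal(mean(ctl), 32.9, tolerance = 0.06 * 32.9)
  expect_equal(sd(ctl), 9.6, tolerance = 0.15 * 9.6)
  expect_true(all(ctl >= 5 & ctl <= 120))
})

test_that("trial-stream generation is deterministic and well-formed", {
  a <- generateTrialStream("PM_phase_event", seed = 13)
  b <- generateTrialStream("PM_phase_event", seed = 13)
  expect_identical(a, b)
  expect_true(!is.unsorted(a$t_ms))

  tm <- generateTrialStream("PM_phase_time", list(clockChecks = 4L),
                            seed = 2)
  expect_equal(sum(tm$kind == "clock_open"), 4)
  expect_equal(scoreTimePM(tm)$mean_interpress_s, 30)  # zero jitter, bias
})

test_that("time-based scoring recovers the generator's parameters", {
  jitter <- 3
  tm <- generateTrialStream(
    "PM_phase_time",
    list(interpressJitter = jitter, sessionDurationS = 1200),
    seed = 17)
  sc <- scoreTimePM(tm)
  expect_gt(sc$press_count, 30)
  expect_lt(abs(sc$mean_interpress_s - 30),
            3 * jitter / sqrt(sc$press_count))

  biased <- generateTrialStream(
    "PM_phase_time",
    list(interpressBias = 18, interpressJitter = 2,
         sessionDurationS = 1200), seed = 18)
  sb <- scoreTimePM(biased)
  expect_lt(abs(sb$mean_interpress_s - 48), 2)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(smallSpec(nCarriers = 3L), "plantedRegion")
  expect_error(cohortSpec(plantedRegion = integer(0)), "non-empty")
  g <- voxelGrid(c(8, 8, 8), 2)
  expect_error(cohortSpec(grid = g, effectModel = list(
    m = list(mean = 1, sd = 0, carrierMean = 1, carrierSd = 1,
             range = c(0, 2)))), "positive")
})
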
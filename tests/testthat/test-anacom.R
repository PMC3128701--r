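patientTable <- function(patientScores, controlScores) {
  data.frame(
    subject_id = c(names(patientScores),
                   sprintf("C%02d", seq_along(controlScores))),
    group = rep(c("patient", "control"),
                c(length(patientScores), length(controlScores))),
    score = c(unname(patientScores), controlScores),
    stringsAsFactors = FALSE)
}

test_that("subregion testing mirrors the rank-sum kernel", {
  g <- tinyGrid(5L, 1)
  masks <- lapply(c("a", "b", "c"), function(id)
    lesionMask(id, g, c(3L, 4L)))
  sub <- partitionSubregions(masks, 3L)[[1]]

  r <- testSubregion(sub, c(a = 5, b = 6, c = 7), c(1, 2, 3, 4))
  expect_true(r$tested)
  expect_equal(r$U, 12)
  expect_equal(r$p, 2 / 35)
  expect_identical(r$nPatients, 3L)

  same <- testSubregion(sub, c(a = 1, b = 2, c = 3), c(1, 2, 3))
  expect_equal(same$p, 1, tolerance = 1e-12)

  ## a missing score drops the subregion below the minimum: skip, loudly
  expect_warning(
    sk <- testSubregion(sub, c(a = 5, b = 6, c = NA), c(1, 2, 3, 4)),
    "skipped.*c")
  expect_false(sk$tested)
})

test_that("the full map chains partition, tests and Holm coherently", {
  g <- tinyGrid(8L)
  ## deficit cluster shared by p1-p3; unrelated lesion for p4/p5
  core <- sphereRegion(g, c(2, 2, 2), 1.5)
  masks <- list(lesionMask("p1", g, core),
                lesionMask("p2", g, core),
                lesionMask("p3", g, c(core, 500L)),
                lesionMask("p4", g, sphereRegion(g, c(6, 6, 6), 1.5)),
                lesionMask("p5", g, sphereRegion(g, c(6, 6, 6), 1.5)))
  set.seed(88)
  controls <- rnorm(40, 30, 5)
  subj <- patientTable(c(p1 = 75, p2 = 80, p3 = 78, p4 = 30, p5 = 31),
                       controls)
  res <- runAnacom(masks, subj, "score", minOverlap = 3L)

  ## only the common core reaches 3 lesions and its patients are deviant
  expect_identical(res$holm$m, 1L)
  expect_identical(nrow(res$report), 1L)
  expect_lt(res$report$p_raw, 0.01)
  expect_identical(res$report$n_patients, 3L)

  ## every voxel of the significant subregion carries the subregion p
  sig <- which(res$statMap@significant)
  expect_setequal(sig, core)
  expect_true(all(res$statMap@p[sig] == res$report$p_raw))

  ## reported coordinates equal the centroid pushed through the affine
  ijk <- t(vapply(core, function(v) {
    v0 <- v - 1L
    d <- gridDims(g)
    c(v0 %% d[1], (v0 %/% d[1]) %% d[2], v0 %/% (d[1] * d[2]))
  }, numeric(3)))
  expected <- round(voxelToWorld(g, colMeans(ijk)))
  expect_identical(c(res$report$x, res$report$y, res$report$z),
                   as.integer(expected))

  ## size in mm^3 follows the voxel volume
  expect_equal(res$report$size_mm3, length(core) * 8)
})

test_that("patients without the measure keep their anatomy but not a vote", {
  g <- tinyGrid(6L)
  core <- c(10L, 11L)
  masks <- lapply(sprintf("p%d", 1:4), function(id) lesionMask(id, g, core))
  subj <- patientTable(c(p1 = 70, p2 = 72, p3 = 71, p4 = NA),
                       rnorm(20, 30, 5))
  res <- suppressWarnings(runAnacom(masks, subj, "score", minOverlap = 3L))
  expect_identical(res$holm$m, 1L)
  expect_identical(res$results[[1]]$nPatients, 3L)  # p4 excluded from test
  expect_setequal(res$subregions[[1]]@pattern, sprintf("p%d", 1:4))
})

test_that("an unreachable overlap yields an empty map with a warning", {
  g <- tinyGrid(5L, 1)
  masks <- list(lesionMask("a", g, 1:3), lesionMask("b", g, 2:4))
  subj <- patientTable(c(a = 1, b = 2), rnorm(10))
  expect_warning(res <- runAnacom(masks, subj, "score", minOverlap = 3L),
                 "minimum overlap")
  expect_identical(sum(!is.na(res$statMap@p)), 0L)
  expect_identical(nrow(res$report), 0L)
  expect_equal(attr(res$report, "H"), 0.05)
})

test_that("null cohorts produce no significant subregions", {
  g <- voxelGrid(c(12, 12, 12), 2)
  for (seed in c(3, 14)) {
    spec <- cohortSpec(nPatients = 15L, nControls = 30L, grid = g,
                       lesionVolumeRange = c(0.1, 3), seed = seed)
    co <- generateCohort(spec)
    res <- suppressWarnings(runAnacom(co$masks, co$subjects, "interpress_s"))
    expect_identical(nrow(res$report), 0L)
  }
})

test_that("a planted deficit region is recovered where the oracle can see it", {
  g <- voxelGrid(c(16, 16, 16), 2)
  planted <- sphereRegion(g, c(10, 10, 8), 2)
  spec <- cohortSpec(nPatients = 25L, nControls = 60L, grid = g,
                     plantedRegion = planted, nCarriers = 6L,
                     lesionVolumeRange = c(0.1, 8), seed = 42L)
  co <- generateCohort(spec)
  res <- suppressWarnings(runAnacom(co$masks, co$subjects, "interpress_s"))
  sig <- which(res$statMap@significant)

  ## direct oracle: rank-sum of the known carriers against controls
  gt <- co$groundTruth
  carrierScores <- co$subjects$interpress_s[
    co$subjects$subject_id %in% gt$carrierIds]
  ctl <- co$subjects$interpress_s[co$subjects$group == "control"]
  oracle <- rankSumTest(carrierScores, ctl)
  if (oracle$p <= res$holm$H)
    expect_gt(length(intersect(sig, planted)), 0)

  ## flagged voxels stay inside planted region and carrier lesions
  carrierVox <- unique(unlist(lapply(
    co$masks[vapply(co$masks, subjectId, character(1)) %in% gt$carrierIds],
    lesionIndices)))
  expect_length(setdiff(sig, union(planted, carrierVox)), 0)
})

test_that("region-vs-rest contrasts cover numeric, categorical and paired", {
  g <- tinyGrid(6L)
  region <- new("Subregion", pattern = "x", grid = g, indices = c(8L, 9L),
                sizeMm3 = 16, centroidMni = c(0, 0, 0))
  masks <- c(lapply(sprintf("p%d", 1:4), function(id)
    lesionMask(id, g, c(8L, 20L))),          # damaged in region
    lapply(sprintf("p%d", 5:8), function(id)
      lesionMask(id, g, c(40L, 41L))))       # spared
  subj <- data.frame(
    subject_id = sprintf("p%d", 1:8),
    group = "patient",
    score = c(2, 4, 6, 8, 2, 4, 6, 8),  # identical multisets
    rt_before = c(500, 600, 700, 800, 500, 600, 700, 800),
    rt_during = c(520, 640, 690, 850, 510, 610, 700, 790),
    sex = c("m", "f", "m", "f", "m", "f", "m", "f"),
    stringsAsFactors = FALSE)

  tab <- regionVsRest(region, masks, subj, measures = "score",
                      categorical = "sex",
                      paired = list(c("rt_before", "rt_during")))
  expect_equal(tab$p[tab$measure == "score"], 1, tolerance = 1e-12)
  expect_equal(tab$statistic[tab$type == "chi_square"], 0)
  expect_equal(tab$p[tab$type == "chi_square"], 1)
  expect_identical(tab$n_region[tab$measure == "score"], 4L)

  ## small-sample rank-sum agrees with enumeration
  subj2 <- subj
  subj2$score <- c(9, 10, 11, 12, 1, 2, 3, 4)
  tab2 <- regionVsRest(region, masks, subj2, measures = "score")
  expect_equal(tab2$p, enumRankSumP(c(9, 10, 11, 12), c(1, 2, 3, 4)),
               tolerance = 1e-12)

  ## degenerate group sizes are skipped with a warning, not dropped
  expect_warning(
    tab3 <- regionVsRest(region, masks[1:4], subj[1:4, ],
                         measures = "score"),
    "fewer than 2")
  expect_true(is.na(tab3$statistic))
})
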
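## Synthetic cohort generator: lesion masks (unions of randomised
## ellipsoids), behavioural scores with an optional planted
## lesion-deficit effect, and raw trial streams — all with known ground
## truth so every pipeline stage can be validated without patient data.

#' Specify a synthetic cohort
#'
#' Defaults emulate the scale of the study population the package targets:
#' 45 patients and 107 controls on an MNI-like 2 mm grid, lesion volumes
#' log-uniform over 1-100 cm^3 built from 1-3 axis-aligned ellipsoids per
#' patient, and a time-based inter-press measure with control scores
#' ~ Normal(32.9 s, 9.6 s) and carriers of the planted deficit at
#' Normal(48.1 s, 5.1 s). A `NULL` `plantedRegion` yields a null cohort:
#' every score is drawn from the control distribution.
#'
#' @param nPatients,nControls cohort sizes.
#' @param grid a [VolumeGrid-class]; small grids (<= 20^3) keep tests fast.
#' @param plantedRegion integer linear voxel indices of the deficit
#'   region, or NULL for a null cohort.
#' @param nCarriers number of patients whose lesion is guaranteed to cover
#'   the planted region (their lesion gets an ellipsoid seeded inside it).
#' @param effectModel named list (one entry per measure) of lists with
#'   `mean`, `sd`, `carrierMean`, `carrierSd`, `range` (truncation).
#' @param carrierMinVoxels minimum lesion overlap with the planted region
#'   (in voxels) for a patient to carry the deficit (default 1).
#' @param lesionVolumeRange per-patient total lesion volume range in
#'   cm^3, sampled log-uniformly.
#' @param ellipsoidsPerPatient range of ellipsoid counts per lesion.
#' @param seed integer; all cohort randomness derives from it via
#'   per-subject substreams, so subject k is identical whatever the
#'   cohort size.
#' @return a `cohortSpec` list (class `"cohortSpec"`).
#' @export
cohortSpec <- function(nPatients = 45L, nControls = 107L,
                       grid = voxelGrid(c(79L, 95L, 79L), 2),
                       plantedRegion = NULL, nCarriers = 0L,
                       effectModel = list(interpress_s = list(
                         mean = 32.9, sd = 9.6,
                         carrierMean = 48.1, carrierSd = 5.1,
                         range = c(5, 120))),
                       carrierMinVoxels = 1L,
                       lesionVolumeRange = c(1, 100),
                       ellipsoidsPerPatient = c(1L, 3L),
                       seed = 1L) {
  if (is.null(plantedRegion) && nCarriers > 0L)
    stop("nCarriers > 0 requires a plantedRegion", call. = FALSE)
  if (!is.null(plantedRegion) && !length(plantedRegion))
    stop("plantedRegion must be non-empty when given", call. = FALSE)
  for (em in effectModel) {
    if (em$sd <= 0 || em$carrierSd <= 0)
      stop("effect-model standard deviations must be positive",
           call. = FALSE)
  }
  stopifnot(nPatients >= 1L, nControls >= 1L)
  structure(list(nPatients = as.integer(nPatients),
                 nControls = as.integer(nControls), grid = grid,
                 plantedRegion = as.integer(plantedRegion),
                 nCarriers = as.integer(nCarriers),
                 effectModel = effectModel,
                 carrierMinVoxels = as.integer(carrierMinVoxels),
                 lesionVolumeRange = lesionVolumeRange,
                 ellipsoidsPerPatient = as.integer(ellipsoidsPerPatient),
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

#' A spherical region of voxels, for planting deficits
#'
#' @param grid a [VolumeGrid-class].
#' @param centre 0-based voxel index triple.
#' @param radius radius in voxels.
#' @return integer linear voxel indices.
#' @export
sphereRegion <- function(grid, centre, radius) {
  rng <- lapply(1:3, function(ax)
    max(0L, floor(centre[ax] - radius)):min(grid@dims[ax] - 1L,
                                            ceiling(centre[ax] + radius)))
  ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  d2 <- (ijk[, 1] - centre[1])^2 + (ijk[, 2] - centre[2])^2 +
        (ijk[, 3] - centre[3])^2
  sort(ijkToLinear(grid, ijk[d2 <= radius^2, , drop = FALSE]))
}

## deterministic per-subject substream seed (stays below 2^31)
subjectSeed <- function(baseSeed, index, stream = 0L) {
  (as.double(baseSeed) + 104729 * index + 15485863 * stream) %% 2147483629
}

ellipsoidIndices <- function(grid, centre, semi) {
  rng <- lapply(1:3, function(ax)
    max(0L, floor(centre[ax] - semi[ax])):min(grid@dims[ax] - 1L,
                                              ceiling(centre[ax] + semi[ax])))
  ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  d2 <- ((ijk[, 1] - centre[1]) / semi[1])^2 +
        ((ijk[, 2] - centre[2]) / semi[2])^2 +
        ((ijk[, 3] - centre[3]) / semi[3])^2
  ijkToLinear(grid, ijk[d2 <= 1, , drop = FALSE])
}

## semi-axes (voxels) for an ellipsoid of given volume (mm^3) with mild
## random anisotropy
semiAxesFor <- function(volMm3, voxelSize) {
  r <- (3 * volMm3 / (4 * pi))^(1 / 3)
  aniso <- exp(stats::runif(3, log(0.7), log(1.4)))
  aniso <- aniso / prod(aniso)^(1 / 3)
  pmax(r * aniso / voxelSize, 0.5)
}

generateLesion <- function(spec, patientIndex) {
  grid <- spec$grid
  set.seed(subjectSeed(spec$seed, patientIndex, 1L))
  k <- sample(seq(spec$ellipsoidsPerPatient[1],
                  spec$ellipsoidsPerPatient[2]), 1L)
  totalVol <- exp(stats::runif(1, log(spec$lesionVolumeRange[1] * 1000),
                               log(spec$lesionVolumeRange[2] * 1000)))
  vols <- totalVol * as.numeric(stats::rmultinom(1, 100, rep(1, k))) / 100
  vols <- pmax(vols, voxelVolume(grid))
  idx <- integer(0)
  margin <- 0.1
  lo <- margin * (grid@dims - 1L); hi <- (1 - margin) * (grid@dims - 1L)
  isCarrier <- patientIndex <= spec$nCarriers
  for (e in seq_len(k)) {
    if (e == 1L && isCarrier) {
      ## seed the first ellipsoid inside the planted region so the lesion
      ## is guaranteed to cover it
      pr <- linearToIjk(grid, spec$plantedRegion)
      centre <- pr[sample(nrow(pr), 1L), ]
    } else {
      centre <- stats::runif(3, lo, hi)
    }
    idx <- c(idx, ellipsoidIndices(grid, centre,
                                   semiAxesFor(vols[e], grid@voxelSize)))
  }
  if (isCarrier) {
    ## a designated carrier is lesioned across the whole planted region,
    ## mirroring a deficit region defined by its patients' common damage
    idx <- c(idx, spec$plantedRegion)
  }
  sort(unique(as.integer(idx)))
}

rnormTrunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2]))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic lesion-and-behaviour cohort
#'
#' Produces per-patient lesion masks, a subject table of behavioural
#' scores, and the ground truth (who carries the planted deficit, where
#' it is). Carriers are determined from the generated masks by the
#' carrier rule (lesion overlaps the planted region by at least
#' `carrierMinVoxels`); their scores for each measure are drawn from the
#' carrier distribution, all other subjects from the control
#' distribution, truncated to the measure's plausible range.
#'
#' @param spec a [cohortSpec()].
#' @return list with `masks` (list of [LesionMask-class]), `subjects`
#'   (data.frame: subject_id, group, one column per measure),
#'   `groundTruth` (list: `carrierIds`, `plantedRegion`, `trueEffects`).
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  pids <- sprintf("P%03d", seq_len(spec$nPatients))
  cids <- sprintf("C%03d", seq_len(spec$nControls))
  masks <- lapply(seq_len(spec$nPatients), function(i)
    lesionMask(pids[i], spec$grid, generateLesion(spec, i)))
  carriers <- if (length(spec$plantedRegion)) {
    pids[vapply(masks, function(m)
      sum(m@indices %in% spec$plantedRegion) >= spec$carrierMinVoxels,
      logical(1))]
  } else character(0)
  scores <- lapply(names(spec$effectModel), function(meas) {
    em <- spec$effectModel[[meas]]
    vapply(seq_len(spec$nPatients + spec$nControls), function(i) {
      set.seed(subjectSeed(spec$seed, i,
                           2L + match(meas, names(spec$effectModel))))
      id <- if (i <= spec$nPatients) pids[i] else cids[i - spec$nPatients]
      if (id %in% carriers)
        rnormTrunc(1, em$carrierMean, em$carrierSd, em$range)
      else rnormTrunc(1, em$mean, em$sd, em$range)
    }, numeric(1))
  })
  names(scores) <- names(spec$effectModel)
  subjects <- data.frame(
    subject_id = c(pids, cids),
    group = rep(c("patient", "control"),
                c(spec$nPatients, spec$nControls)),
    scores, stringsAsFactors = FALSE)
  trueEffects <- vapply(spec$effectModel, function(em)
    if (length(carriers)) em$carrierMean - em$mean else 0, numeric(1))
  list(masks = masks, subjects = subjects,
       groundTruth = list(carrierIds = carriers,
                          plantedRegion = spec$plantedRegion,
                          trueEffects = trueEffects))
}

#' Simulate a raw trial stream for one task session
#'
#' Event-based phases follow the fixed printed target schedule exactly
#' (15 targets, 242 ongoing trials). Time-based phases emit spacebar
#' presses at successive Normal(`targetInterval + interpressBias`,
#' `interpressJitter`) intervals plus clock checks. Time-estimation
#' sessions emit four trials of ten paced numerals each, with the
#' produced duration scaled by `paceFactor` (1 = error-free). Ongoing
#' and control tasks emit self-paced two-alternative trials with
#' log-normal reaction times capped at 3000 ms.
#'
#' @param task one of `"OGonly"`, `"PM_phase_event"`, `"PM_phase_time"`,
#'   `"TE1"`, `"TE2"`, `"SRT"`, `"PREP"`, `"DETECT"`, `"INHIB"`,
#'   `"INSTRUCT"`, `"SWITCH"`.
#' @param profile named list of performance parameters; unset entries
#'   take the defaults of an unimpaired performer:
#'   `ogAccuracy` (0.95), `rtMeanMs` (1000), `rtSdLog` (0.25),
#'   `pmHitRate` (1), `pmRtMeanMs` (900), `interpressBias` (0 s),
#'   `interpressJitter` (0 s), `targetInterval` (30 s),
#'   `sessionDurationS` (300), `clockChecks` (10), `paceFactor` (1),
#'   `nTrials` (30), `itiMs` (300).
#' @param seed integer seed.
#' @param sessionId session identifier string.
#' @return a trial-stream data.frame (see [readTrialStream()]).
#' @export
generateTrialStream <- function(task, profile = list(), seed = 1L,
                                sessionId = task) {
  defaults <- list(ogAccuracy = 0.95, rtMeanMs = 1000, rtSdLog = 0.25,
                   pmHitRate = 1, pmRtMeanMs = 900, interpressBias = 0,
                   interpressJitter = 0, targetInterval = 30,
                   sessionDurationS = 300, clockChecks = 10L,
                   paceFactor = 1, nTrials = 30L, itiMs = 300)
  p <- utils::modifyList(defaults, profile)
  set.seed(as.integer(seed) %% 2147483629)
  ev <- switch(task,
    PM_phase_event = eventPhaseEvents(p),
    PM_phase_time = timePhaseEvents(p),
    TE1 = teEvents(p, "TE1"),
    TE2 = teEvents(p, "TE2"),
    ongoingEvents(p))
  data.frame(session_id = sessionId, task = task, t_ms = ev$t_ms,
             kind = ev$kind, is_pm_target = ev$is_pm_target,
             correct_side = ev$correct_side, stringsAsFactors = FALSE)
}

drawRt <- function(p, n = 1L, meanMs = p$rtMeanMs) {
  pmin(stats::rlnorm(n, log(meanMs) - p$rtSdLog^2 / 2, p$rtSdLog), 3000)
}

emptyEvents <- function() {
  data.frame(t_ms = numeric(0), kind = character(0),
             is_pm_target = logical(0), correct_side = character(0),
             stringsAsFactors = FALSE)
}

addEvent <- function(ev, t, kind, target = FALSE, side = NA_character_) {
  rbind(ev, data.frame(t_ms = t, kind = kind, is_pm_target = target,
                       correct_side = side, stringsAsFactors = FALSE))
}

ongoingTrialSequence <- function(p, isTarget) {
  n <- length(isTarget)
  sides <- sample(rep(c("left", "right"), length.out = n))
  rows <- vector("list", 2L * n)
  t <- 0
  ri <- 0L
  for (i in seq_len(n)) {
    side <- if (isTarget[i]) NA_character_ else sides[i]
    ri <- ri + 1L
    rows[[ri]] <- data.frame(t_ms = t, kind = "stimulus_on",
                             is_pm_target = isTarget[i],
                             correct_side = side,
                             stringsAsFactors = FALSE)
    if (isTarget[i]) {
      if (stats::runif(1) < p$pmHitRate) {
        rt <- drawRt(p, meanMs = p$pmRtMeanMs)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(t_ms = t + rt, kind = "spacebar",
                                 is_pm_target = FALSE,
                                 correct_side = NA_character_,
                                 stringsAsFactors = FALSE)
        t <- t + rt + p$itiMs
      } else t <- t + 3000 + p$itiMs
    } else {
      rt <- drawRt(p)
      resp <- if (stats::runif(1) < p$ogAccuracy) side else
              setdiff(c("left", "right"), side)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(t_ms = t + rt, kind = resp,
                               is_pm_target = FALSE,
                               correct_side = NA_character_,
                               stringsAsFactors = FALSE)
      t <- t + rt + p$itiMs
    }
  }
  do.call(rbind, rows[seq_len(ri)])
}

ongoingEvents <- function(p) {
  ongoingTrialSequence(p, rep(FALSE, p$nTrials))
}

eventPhaseEvents <- function(p) {
  sched <- pmEventSchedule()
  isTarget <- unlist(lapply(sched, function(k) c(rep(FALSE, k), TRUE)))
  isTarget <- c(isTarget, FALSE, FALSE)  # two terminal ongoing trials
  ongoingTrialSequence(p, isTarget)
}

timePhaseEvents <- function(p) {
  durMs <- p$sessionDurationS * 1000
  ev <- data.frame(t_ms = 0, kind = "stimulus_on", is_pm_target = FALSE,
                   correct_side = NA_character_, stringsAsFactors = FALSE)
  t <- 0
  repeat {
    jit <- if (p$interpressJitter > 0)
      stats::rnorm(1, 0, p$interpressJitter) else 0
    gap <- p$targetInterval + p$interpressBias + jit
    t <- t + max(gap, 0.5) * 1000
    if (t > durMs) break
    ev <- addEvent(ev, t, "spacebar")
  }
  if (p$clockChecks > 0L) {
    opens <- sort(stats::runif(p$clockChecks, 0, durMs - 1500))
    for (o in opens) {
      ev <- addEvent(ev, o, "clock_open")
      ev <- addEvent(ev, o + 1000, "clock_close")
    }
  }
  ev <- addEvent(ev, durMs, "stimulus_on")  # session end marker
  ev[order(ev$t_ms), , drop = FALSE]
}

teEvents <- function(p, variant) {
  sched <- teIdealSchedule(variant)
  paceMs <- sched$pace_s * 1000
  ev <- emptyEvents()
  t <- 0
  for (trial in seq_len(4L)) {
    onsets <- t + paceMs * (0:9)
    for (o in onsets) ev <- addEvent(ev, o, "stimulus_on")
    last <- onsets[10]
    press <- last + sched$counts_remaining[trial] * paceMs * p$paceFactor
    ev <- addEvent(ev, press, "spacebar")
    t <- press + 2000
  }
  ev
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Masks as `<outDir>/masks/<subject_id>.nii.gz`, the subject table as
#' `<outDir>/subjects.csv`, and the ground truth as
#' `<outDir>/ground_truth.json`.
#'
#' @param spec a [cohortSpec()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the generated cohort list.
#' @export
writeSyntheticCohort <- function(spec, outDir) {
  cohort <- generateCohort(spec)
  maskDir <- file.path(outDir, "masks")
  dir.create(maskDir, recursive = TRUE, showWarnings = FALSE)
  for (m in cohort$masks)
    writeMask(m, file.path(maskDir, paste0(m@subjectId, ".nii.gz")))
  utils::write.csv(cohort$subjects, file.path(outDir, "subjects.csv"),
                   row.names = FALSE)
  gt <- cohort$groundTruth
  jsonlite::write_json(
    list(carrier_ids = gt$carrierIds,
         planted_region_voxels = gt$plantedRegion,
         true_effects = as.list(gt$trueEffects)),
    file.path(outDir, "ground_truth.json"), auto_unbox = FALSE,
    digits = NA)
  invisible(cohort)
}
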
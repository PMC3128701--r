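## The mapping procedure: superimpose binary lesion masks into an overlap
## map, group lesioned voxels into subregions by identical coverage
## pattern, test each sufficiently covered subregion's patients against
## the control sample with a rank-sum test, and control the family-wise
## error over each map with the Holm step-down procedure.

#' Build the maximum overlap map of a lesion cohort
#'
#' For every voxel of the shared grid, counts the number of patients whose
#' lesion covers it.
#'
#' @param masks non-empty list of [LesionMask-class] on one grid.
#' @return an [OverlapMap-class].
#' @export
buildOverlapMap <- function(masks) {
  checkMaskList(masks)
  grid <- masks[[1]]@grid
  counts <- integer(prod(grid@dims))
  for (m in masks) counts[m@indices] <- counts[m@indices] + 1L
  dim(counts) <- grid@dims
  new("OverlapMap", grid = grid, counts = counts,
      subjectIds = vapply(masks, subjectId, character(1)))
}

checkMaskList <- function(masks) {
  if (!length(masks)) stop("empty mask list", call. = FALSE)
  grid <- masks[[1]]@grid
  for (m in masks) stopIfGridMismatch(m@grid, grid)
  ids <- vapply(masks, subjectId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject ids in mask list: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Partition covered voxels into coverage-pattern subregions
#'
#' Voxels covered by at least `minOverlap` lesions are grouped by the
#' exact set of subjects whose lesions contain them. Each distinct set
#' (coverage pattern) yields one [Subregion-class]; voxels sharing a
#' pattern form one subregion even if spatially disconnected, since the
#' pattern — not contiguity — determines which patients are compared to
#' controls.
#'
#' @param masks non-empty list of [LesionMask-class] on one grid.
#' @param minOverlap minimum number of covering lesions for a voxel to be
#'   eligible for testing (default 3).
#' @return list of [Subregion-class], ordered by decreasing pattern size
#'   then pattern key; empty list if no voxel reaches `minOverlap`.
#' @export
partitionSubregions <- function(masks, minOverlap = 3L) {
  checkMaskList(masks)
  if (minOverlap < 1L) stop("minOverlap must be >= 1", call. = FALSE)
  grid <- masks[[1]]@grid
  om <- buildOverlapMap(masks)
  cand <- which(om@counts >= minOverlap)
  if (!length(cand)) return(list())
  pos <- integer(prod(grid@dims))
  pos[cand] <- seq_along(cand)
  key <- character(length(cand))
  for (i in seq_along(masks)) {
    sel <- pos[masks[[i]]@indices]
    sel <- sel[sel > 0L]
    key[sel] <- paste0(key[sel], i, ",")
  }
  groups <- split(cand, key)
  ids <- vapply(masks, subjectId, character(1))
  subs <- lapply(names(groups), function(k) {
    memberIdx <- as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
    vox <- groups[[k]]
    ijk <- linearToIjk(grid, vox)
    centroid <- voxelToWorld(grid, colMeans(ijk))
    new("Subregion", pattern = ids[memberIdx], grid = grid,
        indices = as.integer(vox),
        sizeMm3 = length(vox) * voxelVolume(grid),
        centroidMni = as.numeric(centroid))
  })
  ord <- order(-vapply(subs, function(s) length(s@pattern), integer(1)),
               names(groups))
  subs[ord]
}

#' Split a subregion into 26-connected components
#'
#' Reporting aid only: the statistics always operate on whole
#' coverage-pattern subregions. Two voxels are connected when they differ
#' by at most one step along every axis.
#'
#' @param sub a [Subregion-class].
#' @return list of [Subregion-class], one per connected component.
#' @export
connectedComponents <- function(sub) {
  ijk <- linearToIjk(sub@grid, sub@indices)
  n <- nrow(ijk)
  comp <- integer(n)
  nextComp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    nextComp <- nextComp + 1L
    queue <- s
    comp[s] <- nextComp
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      adj <- which(comp == 0L &
                   abs(ijk[, 1] - ijk[v, 1]) <= 1L &
                   abs(ijk[, 2] - ijk[v, 2]) <= 1L &
                   abs(ijk[, 3] - ijk[v, 3]) <= 1L)
      comp[adj] <- nextComp
      queue <- c(queue, adj)
    }
  }
  lapply(seq_len(nextComp), function(cc) {
    vox <- sub@indices[comp == cc]
    centroid <- voxelToWorld(sub@grid,
                             colMeans(linearToIjk(sub@grid, vox)))
    new("Subregion", pattern = sub@pattern, grid = sub@grid,
        indices = vox, sizeMm3 = length(vox) * voxelVolume(sub@grid),
        centroidMni = as.numeric(centroid))
  })
}

#' Test one subregion's patients against the control sample
#'
#' Runs the rank-sum test of the scores of the patients lesioned in the
#' subregion versus the control scores. Patients with a missing score
#' remove the subregion from testing if fewer than `minOverlap` scored
#' patients remain; this is reported as a skip, never silently.
#'
#' @param sub a [Subregion-class].
#' @param patientScores named numeric vector, names = subject ids.
#' @param controlScores numeric vector of control scores (length >= 2).
#' @param minOverlap minimum scored patients required to test.
#' @return a list: `tested` (logical), and when tested `U`, `Umin`, `z`,
#'   `p`, `direction`, `nPatients`, `method`; when skipped a `reason`.
#' @export
testSubregion <- function(sub, patientScores, controlScores,
                          minOverlap = 3L) {
  if (length(controlScores) < 2L)
    stop("need at least 2 control scores", call. = FALSE)
  sc <- patientScores[sub@pattern]
  missing <- sub@pattern[is.na(sc) | !(sub@pattern %in% names(patientScores))]
  sc <- sc[!is.na(sc)]
  if (length(sc) < minOverlap) {
    warning(sprintf(
      "subregion (%d voxels) skipped: %d of %d patients scored (missing: %s)",
      length(sub@indices), length(sc), length(sub@pattern),
      paste(missing, collapse = ", ")), call. = FALSE)
    return(list(tested = FALSE,
                reason = sprintf("only %d scored patients", length(sc)),
                nPatients = length(sc)))
  }
  res <- rankSumTest(as.numeric(sc), as.numeric(controlScores))
  list(tested = TRUE, U = res$U, Umin = res$Umin, z = res$z, p = res$p,
       direction = res$direction, nPatients = length(sc),
       method = res$method)
}

#' Run the full lesion-symptom mapping for one behavioural measure
#'
#' Chains the procedure end to end: partition the cohort's lesioned voxels
#' into coverage-pattern subregions (at least `minOverlap` lesions),
#' rank-sum test each subregion's patients against controls on `measure`,
#' Holm-correct across all tested subregions of this one map, and return a
#' per-voxel [StatMap-class] (each voxel inheriting its subregion's raw p)
#' together with a report of significant subregions.
#'
#' Patients lacking the measure still contribute their lesion to the
#' overlap map and the coverage patterns (the anatomy is known even when
#' the score is not), but are excluded from every test; subregions left
#' with fewer than `minOverlap` scored patients are skipped and excluded
#' from the Holm family.
#'
#' @param masks list of [LesionMask-class] for the patients.
#' @param subjects data.frame with columns `subject_id`, `group`
#'   (`"patient"`/`"control"`) and one column per measure.
#' @param measure name of the score column to map.
#' @param minOverlap minimum lesions per tested subregion (default 3).
#' @param alpha family-wise level (default 0.05).
#' @return a list with `statMap` ([StatMap-class]), `report` (data.frame
#'   of significant subregions sorted by raw p: `label`, `x`, `y`, `z`,
#'   `p_raw`, `n_patients`, `size_mm3`, with `H`, `largest_rejected_p`,
#'   `alpha`, `m` as attributes), `holm`, `subregions`, `results`
#'   (per-subregion test outcomes), `measure`.
#' @export
runAnacom <- function(masks, subjects, measure, minOverlap = 3L,
                      alpha = 0.05) {
  checkSubjectTable(subjects, measure)
  grid <- masks[[1]]@grid
  patientScores <- subjectScores(subjects, measure, "patient")
  controlScores <- subjectScores(subjects, measure, "control")
  controlScores <- controlScores[!is.na(controlScores)]
  subs <- partitionSubregions(masks, minOverlap)
  if (!length(subs)) {
    warning("no subregion reaches the minimum overlap of ", minOverlap,
            call. = FALSE)
    return(emptyAnacomResult(grid, measure, alpha))
  }
  results <- lapply(subs, testSubregion, patientScores = patientScores,
                    controlScores = controlScores, minOverlap = minOverlap)
  tested <- vapply(results, `[[`, logical(1), "tested")
  if (!any(tested)) {
    warning("no subregion could be tested for measure '", measure, "'",
            call. = FALSE)
    return(emptyAnacomResult(grid, measure, alpha))
  }
  pRaw <- vapply(results[tested], `[[`, numeric(1), "p")
  holm <- holmCorrect(pRaw, alpha)

  p <- array(NA_real_, grid@dims)
  sig <- array(FALSE, grid@dims)
  testedSubs <- subs[tested]
  for (i in seq_along(testedSubs)) {
    p[testedSubs[[i]]@indices] <- pRaw[i]
    if (holm$rejected[i]) sig[testedSubs[[i]]@indices] <- TRUE
  }
  statMap <- new("StatMap", grid = grid, p = p, significant = sig)

  sigSubs <- testedSubs[holm$rejected]
  sigRes <- results[tested][holm$rejected]
  report <- regionReport(sigSubs, sigRes)
  attr(report, "H") <- holm$H
  attr(report, "largest_rejected_p") <- holm$largestRejectedP
  attr(report, "alpha") <- alpha
  attr(report, "m") <- holm$m
  list(statMap = statMap, report = report, holm = holm,
       subregions = subs, results = results, measure = measure)
}

emptyAnacomResult <- function(grid, measure, alpha) {
  report <- regionReport(list(), list())
  attr(report, "H") <- alpha
  attr(report, "largest_rejected_p") <- NA_real_
  attr(report, "alpha") <- alpha
  attr(report, "m") <- 0L
  list(statMap = new("StatMap", grid = grid,
                     p = array(NA_real_, grid@dims),
                     significant = array(FALSE, grid@dims)),
       report = report,
       holm = holmCorrect(numeric(0), alpha),
       subregions = list(), results = list(), measure = measure)
}

regionReport <- function(subs, results) {
  if (!length(subs)) {
    return(data.frame(label = character(0), x = integer(0), y = integer(0),
                      z = integer(0), p_raw = numeric(0),
                      n_patients = integer(0), size_mm3 = numeric(0)))
  }
  xyz <- t(vapply(subs, function(s) round(s@centroidMni), numeric(3)))
  df <- data.frame(
    label = "", x = as.integer(xyz[, 1]), y = as.integer(xyz[, 2]),
    z = as.integer(xyz[, 3]),
    p_raw = vapply(results, `[[`, numeric(1), "p"),
    n_patients = vapply(results, `[[`, integer(1), "nPatients"),
    size_mm3 = vapply(subs, function(s) s@sizeMm3, numeric(1)))
  df[order(df$p_raw), , drop = FALSE]
}

checkSubjectTable <- function(subjects, measures = NULL) {
  need <- c("subject_id", "group")
  if (!all(need %in% names(subjects)))
    stop("subject table must have columns subject_id and group",
         call. = FALSE)
  if (!all(subjects$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'", call. = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject ids in subject table", call. = FALSE)
  for (m in measures)
    if (!m %in% names(subjects))
      stop("measure '", m, "' not found in subject table", call. = FALSE)
  invisible(TRUE)
}

subjectScores <- function(subjects, measure, group) {
  rows <- subjects$group == group
  stats::setNames(as.numeric(subjects[[measure]][rows]),
                  subjects$subject_id[rows])
}

#' Contrast patients damaged in a region against the remaining patients
#'
#' Splits the patient cohort into those whose lesion shares at least one
#' voxel with the region and all others, then compares the two groups per
#' measure: numeric measures with the rank-sum test, measures named in
#' `categorical` with Pearson chi-square on the cross-tabulation, and
#' pairs in `paired` (within-subject comparisons, e.g. ongoing-task RT
#' before vs during the prospective-memory phase) with the Wilcoxon
#' signed-rank test across damaged patients.
#'
#' @param region a [Subregion-class] (or any object with voxel `indices`).
#' @param masks list of patient [LesionMask-class].
#' @param subjects subject table (see [runAnacom()]).
#' @param measures character vector of numeric measure columns.
#' @param categorical character vector of categorical columns.
#' @param paired optional list of 2-element character vectors naming
#'   measure pairs for within-group signed-rank tests.
#' @return data.frame with columns `measure`, `type`, `statistic`, `z`,
#'   `p`, `n_region`, `n_other`; skipped measures carry NA statistics and
#'   a warning.
#' @export
regionVsRest <- function(region, masks, subjects, measures,
                         categorical = character(0), paired = list()) {
  checkMaskList(masks)
  checkSubjectTable(subjects, c(measures, categorical, unlist(paired)))
  ids <- vapply(masks, subjectId, character(1))
  damaged <- ids[vapply(masks, function(m)
    any(m@indices %in% region@indices), logical(1))]
  pat <- subjects[subjects$group == "patient", , drop = FALSE]
  inRegion <- pat$subject_id %in% damaged
  rows <- list()
  addRow <- function(measure, type, statistic, z, p, n1, n2) {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, type = type, statistic = statistic, z = z, p = p,
      n_region = n1, n_other = n2)
  }
  for (m in measures) {
    g1 <- stats::na.omit(as.numeric(pat[[m]][inRegion]))
    g2 <- stats::na.omit(as.numeric(pat[[m]][!inRegion]))
    if (length(g1) < 2L || length(g2) < 2L) {
      warning("measure '", m, "' skipped: a group has fewer than 2 scores",
              call. = FALSE)
      addRow(m, "rank_sum", NA_real_, NA_real_, NA_real_,
             length(g1), length(g2))
      next
    }
    r <- rankSumTest(g1, g2)
    addRow(m, "rank_sum", r$U, r$z, r$p, length(g1), length(g2))
  }
  for (m in categorical) {
    tab <- table(factor(inRegion, levels = c(TRUE, FALSE)), pat[[m]])
    ok <- ncol(tab) >= 2L && all(rowSums(tab) > 0) && all(colSums(tab) > 0)
    if (!ok) {
      warning("categorical measure '", m, "' skipped: degenerate table",
              call. = FALSE)
      addRow(m, "chi_square", NA_real_, NA_real_, NA_real_,
             sum(inRegion), sum(!inRegion))
      next
    }
    r <- chiSquareTest(tab)
    addRow(m, "chi_square", r$statistic, NA_real_, r$p,
           sum(inRegion), sum(!inRegion))
  }
  for (pr in paired) {
    x <- as.numeric(pat[[pr[1]]][inRegion])
    y <- as.numeric(pat[[pr[2]]][inRegion])
    keep <- !(is.na(x) | is.na(y))
    lbl <- paste(pr, collapse = " vs ")
    if (sum(keep) < 2L) {
      warning("paired contrast '", lbl, "' skipped: fewer than 2 pairs",
              call. = FALSE)
      addRow(lbl, "signed_rank", NA_real_, NA_real_, NA_real_,
             sum(keep), 0L)
      next
    }
    r <- signedRankTest(x[keep], y[keep])
    addRow(lbl, "signed_rank", r$W, r$z, r$p, sum(keep), 0L)
  }
  do.call(rbind, rows)
}
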
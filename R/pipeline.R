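## Orchestration: load a mask directory and subject table, run the
## mapping for each requested measure, and write statistical maps,
## region reports and a patients-vs-controls group summary.

#' Read a run configuration
#'
#' A YAML or JSON file with fields `masks` (directory of
#' `<subject_id>.nii.gz` masks), `subjects` (CSV subject table), `out`
#' (output directory), `measures` (character vector), and optionally
#' `min_overlap` (default 3), `alpha` (default 0.05), `seed` (default 1).
#'
#' @param path configuration file path.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  defaults <- list(min_overlap = 3L, alpha = 0.05, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("masks", "subjects", "out", "measures"))
    if (is.null(cfg[[f]]))
      stop("run config missing field '", f, "'", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (cfg$min_overlap < 1L) stop("min_overlap must be >= 1", call. = FALSE)
  cfg
}

#' Load all lesion masks from a directory
#'
#' Reads every `.nii`/`.nii.gz` file; the subject id is the file name
#' minus extensions. All masks must share one grid (the first file's grid
#' is the reference).
#'
#' @param dir directory of mask volumes.
#' @return list of [LesionMask-class].
#' @export
readMaskDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no NIfTI masks in ", dir, call. = FALSE)
  first <- readMask(files[1])
  c(list(first),
    lapply(files[-1], readMask, referenceGrid = first@grid))
}

#' Run the full mapping pipeline for a configured analysis
#'
#' For every measure: builds the map with [runAnacom()], writes the
#' p-value and significance volumes (`p_<measure>.nii.gz` plus `_sig`
#' companion), and the region report as CSV and JSON (including the Holm
#' threshold). Also writes a patients-vs-controls group summary
#' (rank-sum U/z/p per measure) and a run log of every warning (skipped
#' subregions/subjects). All outputs are deterministic given the same
#' inputs and config.
#'
#' @param config a config list (see [readRunConfig()]) or a path to one.
#' @return invisibly, a list of per-measure [runAnacom()] results plus
#'   `groupSummary` and `warnings`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  masks <- readMaskDir(config$masks)
  subjects <- utils::read.csv(config$subjects, stringsAsFactors = FALSE)
  checkSubjectTable(subjects, config$measures)
  maskIds <- vapply(masks, subjectId, character(1))
  patIds <- subjects$subject_id[subjects$group == "patient"]
  unknown <- setdiff(maskIds, subjects$subject_id)
  if (length(unknown))
    stop("mask subject(s) absent from subject table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  masks <- masks[maskIds %in% patIds]

  logs <- character(0)
  note <- function(msg) {
    logs <<- c(logs, msg)
    message(msg)
  }
  results <- list()
  for (meas in config$measures) {
    res <- withCallingHandlers(
      runAnacom(masks, subjects, meas, minOverlap = config$min_overlap,
                alpha = config$alpha),
      warning = function(w) {
        note(paste0("[", meas, "] ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    writeStatMap(res$statMap,
                 file.path(config$out, paste0("p_", meas, ".nii.gz")))
    rep <- res$report
    rep$H <- rep(attr(res$report, "H"), nrow(rep))
    utils::write.csv(rep,
                     file.path(config$out, paste0("regions_", meas, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(measure = meas, alpha = attr(rep, "alpha"),
           m_tests = attr(rep, "m"), H = attr(rep, "H"),
           largest_rejected_p = attr(rep, "largest_rejected_p"),
           n_significant = nrow(rep), regions = rep),
      file.path(config$out, paste0("regions_", meas, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    if (nrow(rep) == 0L)
      note(paste0("[", meas, "] no significant subregions"))
    results[[meas]] <- res
  }
  groupSummary <- groupSummaryTable(subjects, config$measures)
  utils::write.csv(groupSummary,
                   file.path(config$out, "group_summary.csv"),
                   row.names = FALSE)
  writeLines(logs, file.path(config$out, "run_log.txt"))
  jsonlite::write_json(
    list(config = config[c("measures", "min_overlap", "alpha", "seed")],
         n_patients = sum(subjects$group == "patient"),
         n_controls = sum(subjects$group == "control"),
         n_masks = length(masks),
         package_version = as.character(utils::packageVersion("anacom")),
         warnings = logs),
    file.path(config$out, "run_metadata.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(c(results, list(groupSummary = groupSummary, warnings = logs)))
}

#' Patients-vs-controls summary for a set of measures
#'
#' One rank-sum comparison per measure between all patients and all
#' controls, in the U/z/p reporting format.
#'
#' @param subjects subject table.
#' @param measures measure column names.
#' @return data.frame with per-measure group means, U, z, p.
#' @export
groupSummaryTable <- function(subjects, measures) {
  rows <- lapply(measures, function(m) {
    pat <- stats::na.omit(subjects[[m]][subjects$group == "patient"])
    ctl <- stats::na.omit(subjects[[m]][subjects$group == "control"])
    r <- rankSumTest(pat, ctl)
    data.frame(measure = m, patient_mean = mean(pat),
               patient_sd = stats::sd(pat), control_mean = mean(ctl),
               control_sd = stats::sd(ctl), U = r$U, z = r$z, p = r$p,
               n_patients = length(pat), n_controls = length(ctl))
  })
  do.call(rbind, rows)
}
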
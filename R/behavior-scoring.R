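## Scoring of raw trial streams from the prospective-memory battery into
## the scalar measures the mapping consumes: ongoing-task accuracy and
## reaction time, event-based target credit, time-based inter-press
## intervals and clock checks, and time-estimation totals.
##
## A trial stream is a data.frame event log with columns: session_id,
## task, t_ms (nondecreasing), kind (stimulus_on / left / right /
## spacebar / clock_open / clock_close), is_pm_target (logical),
## correct_side ("left"/"right" or NA).

TRIAL_KINDS <- c("stimulus_on", "left", "right", "spacebar",
                 "clock_open", "clock_close")

#' Read / write a trial-stream event log as CSV
#'
#' @param path CSV path.
#' @param stream a trial-stream data.frame.
#' @return `readTrialStream` returns the validated data.frame.
#' @export
readTrialStream <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateTrialStream(df)
}

#' @rdname readTrialStream
#' @export
writeTrialStream <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

validateTrialStream <- function(df) {
  need <- c("session_id", "task", "t_ms", "kind", "is_pm_target",
            "correct_side")
  if (!all(need %in% names(df)))
    stop("trial stream must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(df$t_ms)) stop("timestamps must be nondecreasing",
                                 call. = FALSE)
  if (!all(df$kind %in% TRIAL_KINDS))
    stop("unknown event kind(s): ",
         paste(setdiff(unique(df$kind), TRIAL_KINDS), collapse = ", "),
         call. = FALSE)
  df$is_pm_target <- as.logical(df$is_pm_target)
  df
}

## Segment a stream into trials: each stimulus_on opens a trial that runs
## until the next stimulus_on (or stream end). Returns a data.frame of
## trial onsets with the first mouse response and first spacebar per trial.
segmentTrials <- function(stream) {
  stim <- which(stream$kind == "stimulus_on")
  if (!length(stim)) stop("stream contains no trials", call. = FALSE)
  onset <- stream$t_ms[stim]
  ends <- c(onset[-1], Inf)
  respKind <- rep(NA_character_, length(stim))
  respT <- spaceT <- rep(NA_real_, length(stim))
  isResp <- stream$kind %in% c("left", "right")
  isSpace <- stream$kind == "spacebar"
  trialOf <- findInterval(stream$t_ms, onset)
  # responses at exactly the next onset belong to the earlier trial is not
  # needed; generator emits responses strictly inside their trial
  for (i in seq_along(stim)) {
    inTrial <- trialOf == i & stream$t_ms >= onset[i] & stream$t_ms < ends[i]
    r <- which(inTrial & isResp)
    if (length(r)) { respKind[i] <- stream$kind[r[1]]
                     respT[i] <- stream$t_ms[r[1]] }
    s <- which(inTrial & isSpace)
    if (length(s)) spaceT[i] <- stream$t_ms[s[1]]
  }
  data.frame(onset = onset, end = ends,
             is_pm_target = as.logical(stream$is_pm_target[stim]),
             correct_side = stream$correct_side[stim],
             resp_kind = respKind, resp_t = respT, space_t = spaceT)
}

#' Score an ongoing-task phase
#'
#' Accuracy is the percentage of analysed trials whose first left/right
#' response matches `correct_side` (trials without a response count as
#' incorrect); mean reaction time is taken over correct analysed trials.
#' The first `discardFirst` trials are dropped from analysis (orientation
#' trials).
#'
#' @param stream a trial-stream data.frame.
#' @param discardFirst number of leading trials discarded (default 10).
#' @return list with `accuracy_pct`, `mean_rt_ms`, `n_trials`.
#' @export
scoreOngoing <- function(stream, discardFirst = 10L) {
  stream <- validateTrialStream(stream)
  tr <- segmentTrials(stream)
  if (nrow(tr) <= discardFirst)
    stop("stream has ", nrow(tr), " trials; cannot discard ", discardFirst,
         call. = FALSE)
  if (discardFirst > 0L) tr <- tr[-seq_len(discardFirst), , drop = FALSE]
  scoreTrialTable(tr)
}

scoreTrialTable <- function(tr) {
  correct <- !is.na(tr$resp_kind) & tr$resp_kind == tr$correct_side
  rt <- tr$resp_t - tr$onset
  list(accuracy_pct = 100 * mean(correct),
       mean_rt_ms = if (any(correct)) mean(rt[correct]) else NA_real_,
       n_trials = nrow(tr))
}

#' Score an event-based prospective-memory phase
#'
#' A target is credited when a spacebar press occurs anywhere from the
#' target's onset until the end of the following trial — the late-response
#' window: participants are instructed to press even after the cue has
#' disappeared, and one following trial is the narrowest window consistent
#' with that instruction. PM reaction time is the first such press minus
#' target onset, over credited targets. Non-target (ongoing) trials are
#' scored as in [scoreOngoing()] with no discard.
#'
#' @param stream a trial-stream data.frame of a PM-phase session.
#' @return list with `ogpm` (ongoing trials) and `pm`
#'   (`accuracy_pct`, `mean_rt_ms`, `n_targets`).
#' @export
scoreEventPM <- function(stream) {
  stream <- validateTrialStream(stream)
  tr <- segmentTrials(stream)
  targets <- which(tr$is_pm_target)
  if (!length(targets)) stop("no PM targets in stream", call. = FALSE)
  spaceT <- stream$t_ms[stream$kind == "spacebar"]
  streamEnd <- max(stream$t_ms) + 1
  credited <- logical(length(targets))
  rts <- rep(NA_real_, length(targets))
  for (j in seq_along(targets)) {
    k <- targets[j]
    winEnd <- if (k + 2L <= nrow(tr)) tr$onset[k + 2L] else streamEnd
    hit <- spaceT[spaceT >= tr$onset[k] & spaceT < winEnd]
    if (length(hit)) { credited[j] <- TRUE; rts[j] <- hit[1] - tr$onset[k] }
  }
  og <- tr[!tr$is_pm_target, , drop = FALSE]
  list(ogpm = scoreTrialTable(og),
       pm = list(accuracy_pct = 100 * mean(credited),
                 mean_rt_ms = if (any(credited)) mean(rts[credited])
                              else NA_real_,
                 n_targets = length(targets)))
}

#' Score a time-based prospective-memory phase
#'
#' The primary performance measure is the mean interval between two
#' successive spacebar presses, in seconds (ideal: the instructed
#' `targetInterval`). Also reports the press count, the press count as a
#' percentage of the ideal number `floor(duration / targetInterval)`, and
#' the number of clock checks (clock-box openings).
#'
#' @param stream a trial-stream data.frame.
#' @param targetInterval instructed press interval in seconds (default 30).
#' @param sessionDuration session length in seconds; default the span of
#'   the event timestamps.
#' @return list with `mean_interpress_s` (NA when fewer than 2 presses —
#'   undefined, never zero), `press_count`, `press_ratio_pct`,
#'   `clock_checks`.
#' @export
scoreTimePM <- function(stream, targetInterval = 30, sessionDuration = NULL) {
  stream <- validateTrialStream(stream)
  pressS <- stream$t_ms[stream$kind == "spacebar"] / 1000
  if (is.null(sessionDuration))
    sessionDuration <- (max(stream$t_ms) - min(stream$t_ms)) / 1000
  nIdeal <- floor(sessionDuration / targetInterval)
  list(mean_interpress_s = if (length(pressS) >= 2L) mean(diff(pressS))
                           else NA_real_,
       press_count = length(pressS),
       press_ratio_pct = if (nIdeal > 0) 100 * length(pressS) / nIdeal
                         else NA_real_,
       clock_checks = sum(stream$kind == "clock_open"))
}

#' Ideal per-trial produced durations of the time-estimation tasks
#'
#' Both variants span four trials totalling an ideal 100 s. The fast
#' variant (`TE1`, 1 s pace) continues counting to 20, 30, 40, 50; the
#' slow variant (`TE2`, 2 s pace) to 15, 20, 25, 30.
#'
#' @param variant `"TE1"` or `"TE2"`.
#' @return list with `pace_s`, `counts_remaining`, `ideal_durations_s`
#'   (10, 20, 30, 40 for both variants), `ideal_total_s` (100).
#' @export
teIdealSchedule <- function(variant = c("TE1", "TE2")) {
  variant <- match.arg(variant)
  pace <- if (variant == "TE1") 1 else 2
  counts <- if (variant == "TE1") c(10L, 20L, 30L, 40L) else
                                  c(5L, 10L, 15L, 20L)
  list(pace_s = pace, counts_remaining = counts,
       ideal_durations_s = pace * counts,
       ideal_total_s = sum(pace * counts))
}

#' Score a time-estimation session
#'
#' Each of the four trials shows ten externally paced numerals
#' (`stimulus_on` events) and ends with a spacebar press when the
#' participant has silently counted to the trial's end number. The
#' produced duration is the press time minus the onset of the last paced
#' numeral; the global score sums the four produced durations (ideal
#' 100 s for both variants). A trial without a press yields a missing
#' duration and the total is flagged `partial`.
#'
#' @param stream a trial-stream data.frame.
#' @param variant `"TE1"` or `"TE2"`.
#' @return list with `trial_durations_s` (length 4, NA allowed),
#'   `total_s`, `partial` (logical), `ideal_total_s`.
#' @export
scoreTimeEstimation <- function(stream, variant = c("TE1", "TE2")) {
  variant <- match.arg(variant)
  stream <- validateTrialStream(stream)
  ## a trial = one uninterrupted run of paced numerals; its produced
  ## duration ends at the first press before the next run starts
  isStim <- stream$kind == "stimulus_on"
  stimIdx <- which(isStim)
  if (!length(stimIdx)) stop("no paced numerals in stream", call. = FALSE)
  runId <- cumsum(c(1L, diff(stimIdx) > 1L))
  nTrials <- max(runId)
  if (nTrials != 4L)
    stop("time-estimation session has ", nTrials, " trials; expected 4",
         call. = FALSE)
  durations <- rep(NA_real_, 4L)
  spaceIdx <- which(stream$kind == "spacebar")
  for (tr in seq_len(4L)) {
    lastStimRow <- max(stimIdx[runId == tr])
    nextRunRow <- if (tr < 4L) min(stimIdx[runId == tr + 1L]) else
                  nrow(stream) + 1L
    press <- spaceIdx[spaceIdx > lastStimRow & spaceIdx < nextRunRow]
    if (length(press))
      durations[tr] <- (stream$t_ms[press[1]] -
                        stream$t_ms[lastStimRow]) / 1000
  }
  partial <- anyNA(durations)
  list(trial_durations_s = durations,
       total_s = sum(durations, na.rm = TRUE),
       partial = partial,
       ideal_total_s = teIdealSchedule(variant)$ideal_total_s)
}

#' The fixed event-based target schedule
#'
#' Numbers of ongoing trials intervening before each of the 15 PM targets
#' in the event-based phase; two further ongoing trials close the session.
#'
#' @return integer vector of length 15.
#' @export
pmEventSchedule <- function() {
  c(30L, 24L, 22L, 16L, 14L, 8L, 6L, 2L, 4L, 10L, 12L, 18L, 20L, 26L, 28L)
}

#' Design arithmetic of the event-based phase
#'
#' From the inter-target schedule: total ongoing trials (intervening plus
#' terminal), number of targets, and the target frequency as a percentage
#' of all counted trials (the terminal ongoing trials are excluded from
#' the frequency denominator).
#'
#' @param intervals inter-target ongoing-trial counts.
#' @param terminalTrials ongoing trials appended after the last target.
#' @return list with `n_og_trials`, `n_targets`, `target_frequency_pct`.
#' @export
eventScheduleSummary <- function(intervals = pmEventSchedule(),
                                 terminalTrials = 2L) {
  nTargets <- length(intervals)
  nOg <- sum(intervals) + terminalTrials
  list(n_og_trials = nOg, n_targets = nTargets,
       target_frequency_pct =
         round(100 * nTargets / (sum(intervals) + nTargets), 1))
}

#' Check an event-based stream against the fixed target schedule
#'
#' @param stream a trial-stream data.frame.
#' @param intervals the expected inter-target schedule.
#' @return TRUE invisibly; errors describe any deviation.
#' @export
validateEventSchedule <- function(stream, intervals = pmEventSchedule()) {
  tr <- segmentTrials(validateTrialStream(stream))
  tgt <- which(tr$is_pm_target)
  if (length(tgt) != length(intervals))
    stop("expected ", length(intervals), " targets, found ", length(tgt),
         call. = FALSE)
  before <- diff(c(0L, tgt)) - 1L
  if (!all(before == intervals))
    stop("intervening ongoing-trial counts deviate from schedule at ",
         "target(s) ", paste(which(before != intervals), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
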
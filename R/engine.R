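#' Engine parameters
#'
#' Tunables of the guidance loop that are not part of the task module
#' itself.
#'
#' @param presence_threshold Smoothed-presence decision threshold,
#'   inclusive; default 0.5 (midpoint of the score range, so that three
#'   positive binary frames out of a five-frame window count as present).
#' @param smoothing_mode Per-frame presence definition passed to
#'   [smooth_frames()]: `"confidence"` (default) or `"binary"`.
#' @return A list of engine parameters.
#' @export
engine_params <- function(presence_threshold = 0.5,
                          smoothing_mode = c("confidence", "binary")) {
  list(presence_threshold = presence_threshold,
       smoothing_mode = match.arg(smoothing_mode))
}

# Satisfaction of one step condition at every frame position.
# Presence parts are decided on the smoothed scores; spatial predicates are
# decided on the highest-confidence raw detections in the most recent frame
# (within the smoothing window) where both endpoints were detected.
condition_satisfaction <- function(cond, smoothed, frames, threshold) {
  n <- length(frames)
  res <- rep(TRUE, n)
  cols <- colnames(smoothed$presence)
  for (cls in cond$required_present) {
    j <- match(cls, cols)
    res <- res & (if (is.na(j)) FALSE else smoothed$presence[, j] >= threshold)
  }
  for (cls in cond$required_absent) {
    j <- match(cls, cols)
    if (!is.na(j)) res <- res & (smoothed$presence[, j] < threshold)
  }
  if (length(cond$spatial_predicates) && any(res)) {
    win <- smoothed$window
    for (i in which(res)) {
      for (p in cond$spatial_predicates) {
        ok <- FALSE
        for (jf in seq(i, max(1L, i - win + 1L))) {
          subj <- best_detection(frames[[jf]], p$subject)
          obj <- best_detection(frames[[jf]], p$object)
          if (!is.null(subj) && !is.null(obj)) {
            ok <- evaluate_spatial(p$relation, subj, obj)
            break
          }
        }
        if (!ok) { res[i] <- FALSE; break }
      }
    }
  }
  res
}

#' Run a guidance session over a detection-frame stream
#'
#' The heart of the cognitive prosthesis: a state machine that walks the
#' task's steps strictly in order over the smoothed detection stream.
#'
#' A step completes when its completion condition holds on `dwell_frames`
#' consecutive smoothed states; in assisted mode completion triggers the
#' positive-reinforcement message ("great") before the next instruction is
#' shown. When an error condition becomes stable, an `error_detected` event
#' is logged (both modes) and, in assisted mode, the corrective instruction
#' is shown; the completion dwell counter is reset, so the participant must
#' repeat the step correctly — the completion condition must hold afresh
#' after the error state clears. If the completion and an error condition
#' stabilise on the same frame, the error wins.
#'
#' Cue escalation (assisted mode): cue level k is issued when the step has
#' been active for its level-k stall timeout without completing; level 5
#' marks the step as performed by the assessor and force-advances. In
#' unassisted mode no feedback, corrective or cue events are emitted, but
#' the same stall milestones are tracked silently in `max_cue_level` so the
#' modified EFPT can be scored for unassisted runs, and errors and timings
#' are still logged.
#'
#' If the stream ends mid-task the remaining steps are marked incomplete
#' (this is a recorded outcome, not an error).
#'
#' @param module A validated `task_module`.
#' @param frames Non-empty, time-ordered list of [detection_frame()] objects.
#' @param assisted Logical; whether guidance feedback and cues are active.
#' @param params [engine_params()].
#' @param session_id,participant_id Identifiers copied into the record.
#' @return An object of class `session_record` with fields `events` (list
#'   of session events), `step_timings`, `max_cue_level`, `error_count`,
#'   `completed` and `total_completion_time_s` (NA unless every step
#'   completed). Deterministic: identical inputs give identical records.
#' @export
run_session <- function(module, frames, assisted = TRUE,
                        params = engine_params(),
                        session_id = "session", participant_id = "anonymous") {
  stopifnot(inherits(module, "task_module"))
  if (!length(frames)) stop("frames must be non-empty")
  v <- validate_task_module(module)
  if (length(v)) stop("invalid task module: ", paste(v, collapse = "; "))

  vocab <- task_vocabulary(module)
  sm <- smooth_frames(frames, module$smoothing_window, vocab,
                      mode = params$smoothing_mode)
  thr <- params$presence_threshold
  n <- length(frames)
  ts <- sm$timestamp_ms
  steps <- module$steps
  n_steps <- length(steps)
  ids <- step_ids(module)

  comp_sat <- lapply(steps, function(s)
    condition_satisfaction(s$completion_condition, sm, frames, thr))
  err_sat <- lapply(steps, function(s)
    lapply(s$error_conditions, function(e)
      condition_satisfaction(e$condition, sm, frames, thr)))

  events <- list()
  emit <- function(timestamp_ms, kind, step_id, detail = "", cue_level = NULL) {
    events[[length(events) + 1L]] <<- list(
      timestamp_ms = timestamp_ms, kind = kind, step_id = step_id,
      cue_level = cue_level, detail = detail)
  }

  completed <- rep(FALSE, n_steps)
  assessor_performed <- rep(FALSE, n_steps)
  max_cue <- rep(0L, n_steps)
  err_count <- rep(0L, n_steps)
  instr_ms <- rep(NA_real_, n_steps)
  first_hand_ms <- rep(NA_real_, n_steps)
  complete_ms <- rep(NA_real_, n_steps)

  s <- 1L
  instr_ms[1] <- ts[1]
  emit(ts[1], "instruction_shown", ids[1], steps[[1]]$instruction_text)
  dwell <- 0L
  err_dwell <- integer(length(steps[[1]]$error_conditions))
  err_engaged <- logical(length(steps[[1]]$error_conditions))

  activate <- function(k, t) {
    instr_ms[k] <<- t
    emit(t, "instruction_shown", ids[k], steps[[k]]$instruction_text)
    dwell <<- 0L
    err_dwell <<- integer(length(steps[[k]]$error_conditions))
    err_engaged <<- logical(length(steps[[k]]$error_conditions))
  }

  i <- 1L
  end_ms <- NA_real_
  while (i <= n && s <= n_steps) {
    t <- ts[i]
    step <- steps[[s]]

    if (is.na(first_hand_ms[s]) && frames[[i]]$hand_present &&
        t >= instr_ms[s])
      first_hand_ms[s] <- t

    # --- cue escalation / stall milestones ---
    elapsed_s <- (t - instr_ms[s]) / 1000
    cs <- step$cue_schedule
    forced <- FALSE
    while (max_cue[s] < nrow(cs) &&
           elapsed_s >= cs$stall_timeout_s[max_cue[s] + 1L]) {
      lvl <- max_cue[s] + 1L
      max_cue[s] <- lvl
      if (assisted) {
        emit(t, "cue_issued", ids[s], cs$text[lvl], cue_level = cs$level[lvl])
        if (cs$level[lvl] == 5L) {
          # physical-assistance ceiling: assessor performs the step
          assessor_performed[s] <- TRUE
          completed[s] <- TRUE
          complete_ms[s] <- t
          emit(t, "step_completed", ids[s], "performed_by_assessor")
          forced <- TRUE
          break
        }
      }
    }
    if (forced) {
      s <- s + 1L
      if (s <= n_steps) activate(s, t)
      i <- i + 1L
      next
    }

    # --- error conditions (edge-triggered per episode; error beats completion) ---
    error_fired <- FALSE
    esat <- err_sat[[s]]
    for (k in seq_along(esat)) {
      if (esat[[k]][i]) {
        err_dwell[k] <- err_dwell[k] + 1L
        need <- step$error_conditions[[k]]$condition$dwell_frames
        if (!err_engaged[k] && err_dwell[k] >= need) {
          err_engaged[k] <- TRUE
          err_count[s] <- err_count[s] + 1L
          error_fired <- TRUE
          emit(t, "error_detected", ids[s],
               step$error_conditions[[k]]$corrective_instruction)
          if (assisted)
            emit(t, "corrective_shown", ids[s],
                 step$error_conditions[[k]]$corrective_instruction)
        }
      } else {
        err_dwell[k] <- 0L
        err_engaged[k] <- FALSE
      }
    }
    if (error_fired || any(err_engaged)) {
      dwell <- 0L
      i <- i + 1L
      next
    }

    # --- completion condition ---
    if (comp_sat[[s]][i]) {
      dwell <- dwell + 1L
      if (dwell >= step$completion_condition$dwell_frames) {
        completed[s] <- TRUE
        complete_ms[s] <- t
        emit(t, "step_completed", ids[s], "")
        if (assisted) emit(t, "positive_feedback", ids[s], "great")
        s <- s + 1L
        if (s <= n_steps) activate(s, t)
      }
    } else {
      dwell <- 0L
    }
    i <- i + 1L
  }

  end_ms <- if (s > n_steps) complete_ms[n_steps] else ts[n]
  emit(end_ms, "session_end", if (s > n_steps) ids[n_steps] else ids[s], "")

  timings <- lapply(seq_len(n_steps), function(k) {
    list(initiation_time_s = if (is.na(first_hand_ms[k]) || is.na(instr_ms[k]))
           NA_real_ else (first_hand_ms[k] - instr_ms[k]) / 1000,
         duration_s = if (is.na(complete_ms[k]) || is.na(instr_ms[k]))
           NA_real_ else (complete_ms[k] - instr_ms[k]) / 1000,
         completed = completed[k])
  })
  names(timings) <- ids

  total <- if (all(completed)) (end_ms - instr_ms[1]) / 1000 else NA_real_

  structure(list(
    session_id = session_id, participant_id = participant_id,
    assisted = assisted, module_id = module$module_id,
    events = events,
    step_timings = timings,
    max_cue_level = stats::setNames(max_cue, ids),
    error_count = stats::setNames(err_count, ids),
    assessor_performed = stats::setNames(assessor_performed, ids),
    completed = stats::setNames(completed, ids),
    total_completion_time_s = total
  ), class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s / %s (%s), module %s\n",
              x$session_id, x$participant_id,
              if (x$assisted) "assisted" else "unassisted", x$module_id))
  cat(sprintf("  %d events; %d/%d steps completed; total %s s\n",
              length(x$events), sum(x$completed), length(x$completed),
              if (is.na(x$total_completion_time_s)) "NA"
              else format(round(x$total_completion_time_s, 2))))
  invisible(x)
}

#' Per-step and total session timings
#'
#' Initiation time is the delay from the step's instruction to the first
#' frame with a hand present at or after it; when no hand is ever seen
#' during the step, initiation is reported as missing (`NA`), not zero.
#' Duration runs from the instruction to step completion. Total completion
#' time spans the first instruction to the end of the session and is `NA`
#' when the task was not finished.
#'
#' @param record A `session_record`.
#' @return A data frame with one row per step (`step_id`, `completed`,
#'   `initiation_s`, `duration_s`, `errors`, `max_cue_level`) and the total
#'   completion time in the `total_completion_time_s` attribute.
#' @export
compute_timings <- function(record) {
  ids <- names(record$step_timings)
  df <- data.frame(
    step_id = ids,
    completed = vapply(record$step_timings, `[[`, FALSE, "completed"),
    initiation_s = vapply(record$step_timings, `[[`, 0, "initiation_time_s"),
    duration_s = vapply(record$step_timings, `[[`, 0, "duration_s"),
    errors = as.integer(record$error_count[ids]),
    max_cue_level = as.integer(record$max_cue_level[ids]),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(df, "total_completion_time_s") <- record$total_completion_time_s
  df
}

#' Write the session event log as JSON-lines
#'
#' One event object per line (`timestamp_ms`, `kind`, `step_id`,
#' `cue_level` where applicable, `detail`).
#'
#' @param record A `session_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_events <- function(record, path) {
  lines <- vapply(record$events, function(e)
    jsonlite::toJSON(e[!vapply(e, is.null, TRUE)], auto_unbox = TRUE,
                     digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore a full session record
#'
#' The full record (including the silently tracked stall milestones needed
#' to score unassisted runs) as a single JSON document.
#'
#' @param record A `session_record`.
#' @param path File path.
#' @return `write_session_record()` returns `path` invisibly;
#'   `read_session_record()` returns a `session_record`.
#' @export
write_session_record <- function(record, path) {
  rec <- unclass(record)
  # keep step names: named atomic vectors must become JSON objects
  for (f in c("max_cue_level", "error_count", "assessor_performed", "completed"))
    rec[[f]] <- as.list(rec[[f]])
  jsonlite::write_json(rec, path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_session_record
#' @export
read_session_record <- function(path) {
  raw <- jsonlite::read_json(path)
  rec <- raw
  rec$assisted <- isTRUE(raw$assisted)
  rec$events <- lapply(raw$events, function(e) {
    e$timestamp_ms <- as.numeric(e$timestamp_ms)
    if (!is.null(e$cue_level)) e$cue_level <- as.integer(e$cue_level)
    e
  })
  rec$step_timings <- lapply(raw$step_timings, function(tm)
    list(initiation_time_s = if (is.null(tm$initiation_time_s)) NA_real_
           else as.numeric(tm$initiation_time_s),
         duration_s = if (is.null(tm$duration_s)) NA_real_
           else as.numeric(tm$duration_s),
         completed = isTRUE(tm$completed)))
  for (f in c("max_cue_level", "error_count"))
    rec[[f]] <- vapply(raw[[f]], as.integer, 0L)
  for (f in c("assessor_performed", "completed"))
    rec[[f]] <- vapply(raw[[f]], isTRUE, TRUE)
  rec$total_completion_time_s <- if (is.null(raw$total_completion_time_s))
    NA_real_ else as.numeric(raw$total_completion_time_s)
  class(rec) <- "session_record"
  rec
}

#' Session summary as a CSV-ready table
#'
#' The per-step summary of [compute_timings()] plus a `total` row carrying
#' the whole-session completion time and the error/cue totals.
#'
#' @param record A `session_record`.
#' @param path Optional path; when given the table is written as CSV.
#' @return The summary data frame, invisibly when `path` is given.
#' @export
session_summary <- function(record, path = NULL) {
  df <- compute_timings(record)
  total <- data.frame(
    step_id = "total",
    completed = all(df$completed),
    initiation_s = NA_real_,
    duration_s = attr(df, "total_completion_time_s"),
    errors = sum(df$errors),
    max_cue_level = max(c(0L, df$max_cue_level)),
    stringsAsFactors = FALSE)
  out <- rbind(df, total)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
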
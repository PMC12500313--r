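# Programmatic fixtures: tiny task modules, scripted detection streams and
# random generators used by the property-style suites.

# A minimal one-step module: step completes when `cls` is stably present.
one_step_module <- function(cls = "widget", dwell = 1L, window = 1L,
                            time_limit_s = 30, timeouts = c(15, 30, 45, 60, 75)) {
  task_module(
    module_id = "mini", name = "one-step fixture",
    steps = list(task_step(
      "only_step", 0L, "do the thing",
      completion_condition = step_condition(required_present = cls,
                                            dwell_frames = dwell),
      time_limit_s = time_limit_s,
      cue_schedule = default_cue_schedule(timeouts))),
    frame_period_ms = 100, smoothing_window = window,
    efpt_components = list(list(component_id = "c1",
                                member_step_ids = "only_step")))
}

# A module whose k-th step completes on stable presence of class
# paste0("done_", k); optional error class paste0("err_", k).
scripted_module <- function(n_steps, dwell = 1L, window = 1L,
                            with_errors = FALSE, time_limit_s = 30,
                            timeouts = c(15, 30, 45, 60, 75)) {
  steps <- lapply(seq_len(n_steps), function(k) {
    errs <- if (with_errors) list(list(
      condition = step_condition(required_present = paste0("err_", k),
                                 dwell_frames = 1L),
      corrective_instruction = paste0("fix step ", k))) else list()
    task_step(paste0("step_", k), k - 1L, paste0("instruction ", k),
              completion_condition = step_condition(
                required_present = paste0("done_", k), dwell_frames = dwell),
              error_conditions = errs,
              time_limit_s = time_limit_s,
              cue_schedule = default_cue_schedule(timeouts))
  })
  task_module(
    module_id = "scripted", name = "scripted fixture", steps = steps,
    frame_period_ms = 100, smoothing_window = window,
    efpt_components = lapply(seq_len(n_steps), function(k)
      list(component_id = paste0("c", k),
           member_step_ids = paste0("step_", k))))
}

simple_det <- function(label, confidence = 0.9,
                       bbox = c(0.4, 0.4, 0.2, 0.2)) {
  object_detection(label, confidence, bbox)
}

# Frames every `period_ms` for `duration_s`, showing the classes returned
# by classes_at(t_seconds); hand present per hand_at(t_seconds).
scripted_frames <- function(duration_s, classes_at,
                            hand_at = function(t) TRUE, period_ms = 100) {
  times <- seq(0, duration_s * 1000, by = period_ms)
  lapply(times, function(tm) {
    cls <- classes_at(tm / 1000)
    detection_frame(tm, lapply(cls, simple_det), hand_at(tm / 1000))
  })
}

# Random stream over a small vocabulary; occasionally emits duplicate
# detections of one class to exercise tie-breaking.
random_frames <- function(n, vocab, p_present = 0.5, period_ms = 100) {
  lapply(seq_len(n), function(i) {
    dets <- list()
    for (cls in vocab) {
      if (stats::runif(1) < p_present) {
        k_dup <- if (stats::runif(1) < 0.1) 2L else 1L
        for (j in seq_len(k_dup)) {
          x <- stats::runif(1, 0, 0.7); y <- stats::runif(1, 0, 0.7)
          dets[[length(dets) + 1L]] <- object_detection(
            cls, stats::runif(1, 0.3, 1),
            c(x, y, stats::runif(1, 0.05, 0.3), stats::runif(1, 0.05, 0.3)))
        }
      }
    }
    detection_frame((i - 1) * period_ms, dets,
                    hand_present = stats::runif(1) < 0.5)
  })
}

# Random small module over vocabulary obj_1..obj_5 with random dwell
# requirements, error conditions, short cue timeouts (so escalation and
# level-5 force-advance are exercised) and occasional spatial predicates.
random_module <- function() {
  vocab <- paste0("obj_", 1:5)
  n_steps <- sample(2:4, 1)
  steps <- lapply(seq_len(n_steps), function(k) {
    present <- sample(vocab, sample(1:2, 1))
    absent <- if (stats::runif(1) < 0.4)
      sample(setdiff(vocab, present), 1) else character()
    preds <- if (stats::runif(1) < 0.3) {
      pair <- sample(vocab, 2)
      list(list(relation = sample(c("contains", "overlaps", "above"), 1),
                subject = pair[1], object = pair[2]))
    } else list()
    errs <- if (stats::runif(1) < 0.5) list(list(
      condition = step_condition(
        required_present = sample(setdiff(vocab, present), 1),
        dwell_frames = sample(1:2, 1)),
      corrective_instruction = paste0("corrective ", k))) else list()
    n_lvl <- sample(c(3L, 5L), 1)
    task_step(paste0("s", k), k - 1L, paste0("instr ", k),
              completion_condition = step_condition(
                required_present = present, required_absent = absent,
                spatial_predicates = preds,
                dwell_frames = sample(1:3, 1)),
              error_conditions = errs,
              time_limit_s = 5,
              cue_schedule = default_cue_schedule(
                seq_len(n_lvl) * stats::runif(1, 1.5, 4)))
  })
  task_module("rand", "random fixture", steps,
              frame_period_ms = 100,
              smoothing_window = sample(1:6, 1),
              efpt_components = lapply(seq_len(n_steps), function(k)
                list(component_id = paste0("c", k),
                     member_step_ids = paste0("s", k))))
}

# Hand-built session record for scoring rule-table tests.
make_record <- function(module, completed, errors, durations, max_cue,
                        assisted = TRUE) {
  ids <- vapply(module$steps, function(s) s$step_id, "")
  timings <- lapply(seq_along(ids), function(k)
    list(initiation_time_s = 0.5, duration_s = durations[k],
         completed = completed[k]))
  names(timings) <- ids
  structure(list(
    session_id = "fixture", participant_id = "fixture",
    assisted = assisted, module_id = module$module_id,
    events = list(),
    step_timings = timings,
    max_cue_level = stats::setNames(as.integer(max_cue), ids),
    error_count = stats::setNames(as.integer(errors), ids),
    assessor_performed = stats::setNames(max_cue >= 5, ids),
    completed = stats::setNames(completed, ids),
    total_completion_time_s = if (all(completed)) sum(durations) else NA_real_
  ), class = "session_record")
}
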
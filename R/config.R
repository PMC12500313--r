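#' Construct a step condition
#'
#' A step condition describes a recognisable scene state: object classes that
#' must be present, classes that must be absent, optional spatial relations
#' between detected objects, and how many consecutive smoothed frames the
#' state must persist (the dwell requirement) before it counts as satisfied.
#'
#' @param required_present Character vector of class labels that must all be
#'   present (smoothed presence at or above the engine threshold).
#' @param required_absent Character vector of class labels that must all be
#'   absent.
#' @param spatial_predicates List of 3-element lists/vectors
#'   `(relation, subject, object)` with `relation` one of `"contains"`,
#'   `"overlaps"`, `"above"`.
#' @param dwell_frames Positive integer; consecutive smoothed frames the
#'   condition must hold.
#' @return An object of class `step_condition`.
#' @export
step_condition <- function(required_present = character(),
                           required_absent = character(),
                           spatial_predicates = list(),
                           dwell_frames = 5L) {
  preds <- lapply(spatial_predicates, function(p) {
    p <- as.list(p)
    names(p) <- c("relation", "subject", "object")[seq_along(p)]
    list(relation = as.character(p$relation),
         subject = as.character(p$subject),
         object = as.character(p$object))
  })
  structure(list(
    required_present = as.character(required_present),
    required_absent = as.character(required_absent),
    spatial_predicates = preds,
    dwell_frames = as.integer(dwell_frames)
  ), class = "step_condition")
}

#' Construct a task step
#'
#' @param step_id Unique step identifier (lowercase snake-case by convention).
#' @param index Zero-based position of the step in the task.
#' @param instruction_text Instruction shown/read to the participant when the
#'   step becomes active.
#' @param completion_condition A [step_condition()] that, once stable, marks
#'   the step complete.
#' @param error_conditions List of error states; each element is a list with
#'   fields `condition` (a [step_condition()]) and `corrective_instruction`.
#' @param time_limit_s Per-step time allowance in seconds; exceeding it
#'   downgrades the completion score for the step from 2 to 1.
#' @param cue_schedule Data frame with columns `level` (1..5, a prefix),
#'   `stall_timeout_s` (strictly increasing) and `text`. Level k is issued
#'   when the step has been active for `stall_timeout_s[k]` seconds without
#'   completing.
#' @return An object of class `task_step`.
#' @export
task_step <- function(step_id, index, instruction_text,
                      completion_condition,
                      error_conditions = list(),
                      time_limit_s = 30,
                      cue_schedule = default_cue_schedule()) {
  errs <- lapply(error_conditions, function(e) {
    list(condition = e$condition,
         corrective_instruction = as.character(e$corrective_instruction))
  })
  structure(list(
    step_id = as.character(step_id),
    index = as.integer(index),
    instruction_text = as.character(instruction_text),
    completion_condition = completion_condition,
    error_conditions = errs,
    time_limit_s = as.numeric(time_limit_s),
    cue_schedule = as.data.frame(cue_schedule, stringsAsFactors = FALSE)
  ), class = "task_step")
}

#' Default five-level cue schedule
#'
#' The cue hierarchy mirrors the modified EFPT assistance scale: verbal
#' prompt, gestural prompt, direct verbal instruction, physical assistance,
#' and finally the step being performed by the assessor. Stall timeouts
#' default to 15/30/45/60/75 s and are configurable per step.
#'
#' @param timeouts Numeric vector of strictly increasing stall timeouts in
#'   seconds; its length (at most 5) selects the cue-level prefix used.
#' @return Data frame with columns `level`, `stall_timeout_s`, `text`.
#' @export
default_cue_schedule <- function(timeouts = c(15, 30, 45, 60, 75)) {
  texts <- c("verbal prompt", "gestural prompt", "direct verbal instruction",
             "physical assistance", "step performed by assessor")
  n <- length(timeouts)
  data.frame(level = seq_len(n), stall_timeout_s = as.numeric(timeouts),
             text = texts[seq_len(n)], stringsAsFactors = FALSE)
}

#' Construct a task module
#'
#' A task module is the declarative definition of one assistive task: an
#' ordered list of steps with recognition conditions, the EFPT component
#' grouping used for executive-function scoring, the nominal camera sampling
#' period and the rolling-average window used to stabilise detections.
#'
#' @param module_id,name Identifier and human-readable name.
#' @param steps List of [task_step()] objects, in index order.
#' @param frame_period_ms Nominal sampling interval of the detection stream
#'   in milliseconds (the deployed system sampled every 5 ms; streams carry
#'   their own timestamps, so this is informational).
#' @param smoothing_window Rolling-average window in frames (default 5).
#' @param efpt_components List of lists with fields `component_id` and
#'   `member_step_ids`; disjoint groupings of steps scored 0-5 each.
#' @param completion_rules List with logical fields `error_downgrades`,
#'   `overtime_downgrades` and integer `zero_credit_cue_level`; see
#'   [score_completion()].
#' @param class_vocabulary Optional character vector of all detector classes;
#'   classes referenced by conditions are always included.
#' @return An object of class `task_module`. The constructor does not
#'   validate; see [validate_task_module()].
#' @export
task_module <- function(module_id, name, steps,
                        frame_period_ms = 5,
                        smoothing_window = 5L,
                        efpt_components = list(),
                        completion_rules = default_completion_rules(),
                        class_vocabulary = character()) {
  structure(list(
    module_id = as.character(module_id),
    name = as.character(name),
    frame_period_ms = as.numeric(frame_period_ms),
    smoothing_window = as.integer(smoothing_window),
    steps = steps,
    efpt_components = lapply(efpt_components, function(co) {
      list(component_id = as.character(co$component_id),
           member_step_ids = as.character(co$member_step_ids))
    }),
    completion_rules = completion_rules,
    class_vocabulary = as.character(class_vocabulary)
  ), class = "task_module")
}

#' Default completion-score rule set
#'
#' Per step: 2 points for fully correct performance (completed, no error
#' events, within the time limit), 1 point for partially incorrect
#' (completed, but with at least one corrective episode or over the time
#' limit), and 0 for incorrect (not completed, or assistance reached the
#' level at which the assessor performs the step).
#'
#' @return A list of rule switches consumed by [score_completion()].
#' @export
default_completion_rules <- function() {
  list(error_downgrades = TRUE,
       overtime_downgrades = TRUE,
       zero_credit_cue_level = 5L)
}

#' @export
print.task_module <- function(x, ...) {
  cat(sprintf("<task_module> %s (\"%s\")\n", x$module_id, x$name))
  cat(sprintf("  %d steps, %d EFPT components, smoothing window %d, frame period %g ms\n",
              length(x$steps), length(x$efpt_components),
              x$smoothing_window, x$frame_period_ms))
  for (s in x$steps) {
    cat(sprintf("  [%d] %s: %s\n", s$index, s$step_id, s$instruction_text))
  }
  invisible(x)
}

#' All class labels a module can reference
#'
#' Union of the declared vocabulary and every class named in any completion
#' or error condition (including spatial predicate subjects/objects).
#'
#' @param module A `task_module`.
#' @return Character vector of class labels.
#' @export
task_vocabulary <- function(module) {
  cls <- module$class_vocabulary
  for (s in module$steps) {
    conds <- c(list(s$completion_condition),
               lapply(s$error_conditions, `[[`, "condition"))
    for (cc in conds) {
      cls <- c(cls, cc$required_present, cc$required_absent,
               unlist(lapply(cc$spatial_predicates,
                             function(p) c(p$subject, p$object))))
    }
  }
  sort(unique(cls))
}

step_ids <- function(module) vapply(module$steps, `[[`, "", "step_id")

validate_condition <- function(cond, where) {
  out <- character()
  if (length(intersect(cond$required_present, cond$required_absent)) > 0)
    out <- c(out, sprintf(
      "%s: required_present and required_absent overlap (%s)", where,
      paste(intersect(cond$required_present, cond$required_absent),
            collapse = ", ")))
  if (!is.finite(cond$dwell_frames) || cond$dwell_frames < 1)
    out <- c(out, sprintf("%s: dwell_frames must be >= 1", where))
  for (p in cond$spatial_predicates) {
    if (!p$relation %in% c("contains", "overlaps", "above"))
      out <- c(out, sprintf("%s: unknown spatial relation '%s'",
                            where, p$relation))
  }
  out
}

#' Validate a task module
#'
#' Checks every structural invariant of the task-module format and returns
#' the findings instead of erroring, so callers can report all problems at
#' once. An empty return value means the module is valid.
#'
#' @param module A `task_module`.
#' @return Character vector of violations, each naming the field and rule
#'   breached; `character(0)` if the module is valid.
#' @export
validate_task_module <- function(module) {
  v <- character()
  if (!inherits(module, "task_module"))
    return("module: not a task_module object")
  if (length(module$steps) < 1)
    v <- c(v, "steps: a task module must define at least one step")
  if (!is.finite(module$frame_period_ms) || module$frame_period_ms <= 0)
    v <- c(v, "frame_period_ms: must be > 0")
  if (!is.finite(module$smoothing_window) || module$smoothing_window < 1)
    v <- c(v, "smoothing_window: must be >= 1")

  ids <- step_ids(module)
  if (anyDuplicated(ids))
    v <- c(v, sprintf("steps.step_id: duplicated id(s): %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  idx <- vapply(module$steps, `[[`, 0L, "index")
  if (length(idx) && !identical(as.integer(idx), seq_along(idx) - 1L))
    v <- c(v, "steps.index: indices must be contiguous from 0 in list order")

  for (s in module$steps) {
    where <- sprintf("step '%s'", s$step_id)
    if (!is.finite(s$time_limit_s) || s$time_limit_s <= 0)
      v <- c(v, sprintf("%s: time_limit_s must be > 0", where))
    v <- c(v, validate_condition(s$completion_condition,
                                 paste0(where, " completion_condition")))
    for (k in seq_along(s$error_conditions)) {
      e <- s$error_conditions[[k]]
      v <- c(v, validate_condition(e$condition,
                                   sprintf("%s error_conditions[%d]", where, k)))
      if (!nzchar(e$corrective_instruction))
        v <- c(v, sprintf("%s error_conditions[%d]: corrective_instruction empty",
                          where, k))
    }
    cs <- s$cue_schedule
    if (nrow(cs)) {
      if (!identical(as.integer(cs$level), seq_len(nrow(cs))))
        v <- c(v, sprintf(
          "%s cue_schedule.level: levels must be the prefix 1..%d of the cue hierarchy",
          where, nrow(cs)))
      if (any(cs$level > 5))
        v <- c(v, sprintf("%s cue_schedule.level: levels above 5 are undefined", where))
      if (nrow(cs) > 1 && any(diff(cs$stall_timeout_s) <= 0))
        v <- c(v, sprintf(
          "%s cue_schedule.stall_timeout_s: stall timeouts must be strictly increasing",
          where))
      if (any(cs$stall_timeout_s <= 0))
        v <- c(v, sprintf("%s cue_schedule.stall_timeout_s: must be > 0", where))
    }
  }

  seen <- character()
  comp_ids <- vapply(module$efpt_components, `[[`, "", "component_id")
  if (anyDuplicated(comp_ids))
    v <- c(v, "efpt_components.component_id: duplicated component id(s)")
  for (co in module$efpt_components) {
    if (length(co$member_step_ids) < 1)
      v <- c(v, sprintf("efpt_components '%s': member_step_ids must be non-empty",
                        co$component_id))
    unknown <- setdiff(co$member_step_ids, ids)
    if (length(unknown))
      v <- c(v, sprintf("efpt_components '%s': unknown step id(s): %s",
                        co$component_id, paste(unknown, collapse = ", ")))
    overlap <- intersect(co$member_step_ids, seen)
    if (length(overlap))
      v <- c(v, sprintf(
        "efpt_components '%s': step(s) %s already belong to another component",
        co$component_id, paste(overlap, collapse = ", ")))
    seen <- c(seen, co$member_step_ids)
  }

  cr <- module$completion_rules
  needed <- c("error_downgrades", "overtime_downgrades", "zero_credit_cue_level")
  missing <- setdiff(needed, names(cr))
  if (length(missing))
    v <- c(v, sprintf("completion_rules: missing field(s): %s",
                      paste(missing, collapse = ", ")))
  v
}

condition_from_list <- function(x) {
  if (is.null(x)) x <- list()
  step_condition(
    required_present = x$required_present %||% character(),
    required_absent = x$required_absent %||% character(),
    spatial_predicates = x$spatial_predicates %||% list(),
    dwell_frames = x$dwell_frames %||% 5L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a task module from a YAML file
#'
#' Reads one YAML document describing a task module, coerces it into the
#' package's types and validates every invariant. Plain YAML 1.1 mappings
#' are sufficient; anchors and merge keys are not required.
#'
#' @param path Path to a YAML task-module file.
#' @return A validated `task_module`.
#' @seealso [write_task_module()], [validate_task_module()],
#'   [default_task_module()]
#' @export
load_task_module <- function(path) {
  if (!file.exists(path)) stop("task module file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("YAML parse failure in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  module <- task_module_from_list(raw)
  v <- validate_task_module(module)
  if (length(v))
    stop("invalid task module '", path, "':\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  module
}

task_module_from_list <- function(raw) {
  steps <- lapply(raw$steps %||% list(), function(s) {
    cs <- s$cue_schedule
    if (is.null(cs)) {
      cs_df <- default_cue_schedule()
    } else {
      cs_df <- do.call(rbind, lapply(cs, function(row)
        data.frame(level = as.integer(row$level),
                   stall_timeout_s = as.numeric(row$stall_timeout_s),
                   text = as.character(row$text %||% ""),
                   stringsAsFactors = FALSE)))
    }
    task_step(
      step_id = s$step_id, index = s$index %||% NA_integer_,
      instruction_text = s$instruction_text %||% "",
      completion_condition = condition_from_list(s$completion_condition),
      error_conditions = lapply(s$error_conditions %||% list(), function(e)
        list(condition = condition_from_list(e$condition),
             corrective_instruction = e$corrective_instruction %||% "")),
      time_limit_s = s$time_limit_s %||% 30,
      cue_schedule = cs_df
    )
  })
  cr <- raw$completion_rules %||% default_completion_rules()
  cr$zero_credit_cue_level <- as.integer(cr$zero_credit_cue_level %||% 5L)
  task_module(
    module_id = raw$module_id %||% "", name = raw$name %||% "",
    steps = steps,
    frame_period_ms = raw$frame_period_ms %||% 5,
    smoothing_window = raw$smoothing_window %||% 5L,
    efpt_components = raw$efpt_components %||% list(),
    completion_rules = cr,
    class_vocabulary = raw$class_vocabulary %||% character()
  )
}

task_module_to_list <- function(module) {
  list(
    module_id = module$module_id,
    name = module$name,
    frame_period_ms = module$frame_period_ms,
    smoothing_window = module$smoothing_window,
    class_vocabulary = as.list(module$class_vocabulary),
    steps = lapply(module$steps, function(s) list(
      step_id = s$step_id,
      index = s$index,
      instruction_text = s$instruction_text,
      time_limit_s = s$time_limit_s,
      completion_condition = condition_to_list(s$completion_condition),
      error_conditions = lapply(s$error_conditions, function(e) list(
        condition = condition_to_list(e$condition),
        corrective_instruction = e$corrective_instruction)),
      cue_schedule = lapply(seq_len(nrow(s$cue_schedule)), function(i) list(
        level = s$cue_schedule$level[i],
        stall_timeout_s = s$cue_schedule$stall_timeout_s[i],
        text = s$cue_schedule$text[i]))
    )),
    efpt_components = lapply(module$efpt_components, function(co) list(
      component_id = co$component_id,
      member_step_ids = as.list(co$member_step_ids))),
    completion_rules = module$completion_rules
  )
}

condition_to_list <- function(cond) {
  list(required_present = as.list(cond$required_present),
       required_absent = as.list(cond$required_absent),
       spatial_predicates = lapply(cond$spatial_predicates, function(p)
         list(relation = p$relation, subject = p$subject, object = p$object)),
       dwell_frames = cond$dwell_frames)
}

#' Write a task module to a YAML file
#'
#' Inverse of [load_task_module()]: `load_task_module(write_task_module(m, f))`
#' yields a structurally identical module.
#'
#' @param module A `task_module`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_module <- function(module, path) {
  yaml::write_yaml(task_module_to_list(module), path)
  invisible(path)
}

#' The default egg-boiling task module
#'
#' Loads the six-step simulated egg-boiling module shipped with the package:
#' place the pot on the cooker, fetch the water pitcher, pour water into the
#' pot, place the egg into the pot, close the cooker lid, press the cook
#' switch. Scene states are encoded as distinct detector classes (e.g.
#' `pot_empty`, `pot_with_water`, `cooker_on`), and the five EFPT components
#' group the pour-water and place-egg steps into a single component so the
#' instrument's 0-25 range is preserved.
#'
#' @return A validated `task_module` with 6 steps and 5 EFPT components.
#' @export
default_task_module <- function() {
  load_task_module(system.file("extdata", "egg_boiling.yaml",
                               package = "taskguide", mustWork = TRUE))
}
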
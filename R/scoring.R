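#' Daily Task Completion score
#'
#' Per-step 0/1/2 scoring of one session on the basis of task performance
#' accuracy and completion time: 2 points for fully correct performance
#' (step completed with no error episodes, within its time limit), 1 point
#' for partially incorrect performance (completed, but with at least one
#' corrective episode or over the time limit), and 0 for incorrect
#' performance (step not completed, or assistance escalated to the level at
#' which the assessor performs the step). The perfect score for the default
#' six-step module is 12.
#'
#' @param record A `session_record` produced from `module`.
#' @param module The `task_module` the session ran.
#' @return An object of class `completion_score`: list with `per_step`
#'   (named integer vector in `{0, 1, 2}`) and `total`.
#' @export
score_completion <- function(record, module) {
  ids <- step_ids(module)
  if (!setequal(names(record$completed), ids))
    stop("session record step ids do not match the task module")
  rules <- module$completion_rules
  per <- stats::setNames(integer(length(ids)), ids)
  for (s in module$steps) {
    id <- s$step_id
    cue5 <- record$max_cue_level[[id]] >= rules$zero_credit_cue_level
    if (!record$completed[[id]] || cue5) {
      per[[id]] <- 0L
      next
    }
    overtime <- isTRUE(record$step_timings[[id]]$duration_s > s$time_limit_s)
    flawed <- (rules$error_downgrades && record$error_count[[id]] > 0) ||
      (rules$overtime_downgrades && overtime)
    per[[id]] <- if (flawed) 1L else 2L
  }
  structure(list(per_step = per, total = sum(per)),
            class = "completion_score")
}

#' @export
print.completion_score <- function(x, ...) {
  cat(sprintf("<completion_score> total %d / %d\n",
              x$total, 2L * length(x$per_step)))
  invisible(x)
}

#' Modified EFPT score
#'
#' Executive-function score of one session under the five-level cueing
#' hierarchy: 0 no cue required, 1 verbal assistance, 2 gestural
#' assistance, 3 direct verbal assistance, 4 physical assistance, 5 task
#' performed by the assessor. Each EFPT component (a configurable grouping
#' of task steps) scores the worst — maximum — cue level reached across its
#' member steps; the total is the component sum, ranging 0-25 for the
#' default five-component configuration. Higher scores indicate greater
#' executive dysfunction. Unassisted sessions are scorable because the
#' engine tracks the same stall milestones silently.
#'
#' @param record A `session_record` produced from `module`.
#' @param module The `task_module` defining disjoint EFPT components.
#' @return An object of class `efpt_score`: list with `per_component`
#'   (named integer vector in 0..5) and `total`.
#' @export
score_efpt <- function(record, module) {
  ids <- step_ids(module)
  per <- stats::setNames(integer(length(module$efpt_components)),
                         vapply(module$efpt_components, `[[`, "", "component_id"))
  for (co in module$efpt_components) {
    unknown <- setdiff(co$member_step_ids, ids)
    if (length(unknown))
      stop("EFPT component '", co$component_id,
           "' references unknown step(s): ", paste(unknown, collapse = ", "))
    per[[co$component_id]] <-
      max(0L, as.integer(record$max_cue_level[co$member_step_ids]))
  }
  structure(list(per_component = per, total = sum(per)),
            class = "efpt_score")
}

#' @export
print.efpt_score <- function(x, ...) {
  cat(sprintf("<efpt_score> total %d / %d (higher = more assistance)\n",
              x$total, 5L * length(x$per_component)))
  invisible(x)
}

#' System Usability Scale score
#'
#' Standard SUS transformation of the 10 item responses (1-5 Likert): odd
#' items are positively worded and contribute `item - 1`; even items are
#' negatively worded and contribute `5 - item`; the sum is scaled by 2.5 to
#' a 0-100 score (always a multiple of 2.5). The interpretation band is
#' attached via [classify_sus()].
#'
#' @param item_scores Integer vector of exactly 10 responses, each in 1..5.
#'   Missing or out-of-range responses are an error; no imputation is done.
#' @return An object of class `sus_result`: list with `item_scores`,
#'   `score` and `band`.
#' @export
score_sus <- function(item_scores) {
  if (length(item_scores) != 10 || anyNA(item_scores))
    stop("SUS requires exactly 10 non-missing item responses")
  if (any(item_scores != round(item_scores)) ||
      any(item_scores < 1) || any(item_scores > 5))
    stop("SUS item responses must be integers in 1..5")
  item_scores <- as.integer(item_scores)
  odd <- item_scores[c(1, 3, 5, 7, 9)]
  even <- item_scores[c(2, 4, 6, 8, 10)]
  score <- 2.5 * (sum(odd - 1L) + sum(5L - even))
  structure(list(item_scores = item_scores, score = score,
                 band = classify_sus(score)),
            class = "sus_result")
}

#' @export
print.sus_result <- function(x, ...) {
  cat(sprintf("<sus_result> score %.1f (%s)\n", x$score, x$band))
  invisible(x)
}

#' SUS interpretation band
#'
#' Bands: below 50 indicates significant usability issues; 50 up to (but
#' not including) 68 marginal usability; 68 through 80 inclusive acceptable
#' usability; above 80 excellent usability.
#'
#' @param score SUS score in `[0, 100]`.
#' @return One of `"significant_issues"`, `"marginal"`, `"acceptable"`,
#'   `"excellent"`.
#' @export
classify_sus <- function(score) {
  if (score < 0 || score > 100) stop("SUS score must be in [0, 100]")
  if (score < 50) "significant_issues"
  else if (score < 68) "marginal"
  else if (score <= 80) "acceptable"
  else "excellent"
}

#' Score a CSV of SUS questionnaire responses
#'
#' @param path CSV with columns `participant_id`, `item_1` .. `item_10`.
#' @param out Optional output CSV path for the scored table.
#' @return Data frame with columns `participant_id`, `sus_score`, `band`.
#' @export
score_sus_file <- function(path, out = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- paste0("item_", 1:10)
  missing <- setdiff(c("participant_id", cols), names(df))
  if (length(missing))
    stop("SUS response file missing column(s): ",
         paste(missing, collapse = ", "))
  res <- lapply(seq_len(nrow(df)), function(i)
    score_sus(as.integer(df[i, cols])))
  scored <- data.frame(
    participant_id = df$participant_id,
    sus_score = vapply(res, `[[`, 0, "score"),
    band = vapply(res, `[[`, "", "band"),
    stringsAsFactors = FALSE)
  if (!is.null(out)) utils::write.csv(scored, out, row.names = FALSE)
  scored
}
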
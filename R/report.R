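#' Percent change between a before and an after measurement
#'
#' `100 * (before - after) / before`, reported to one decimal place:
#' positive values are reductions (improvements for time-like and
#' EFPT-like quantities where lower is better).
#'
#' @param before Baseline value; must be strictly positive.
#' @param after Follow-up value.
#' @return Percent change rounded to one decimal.
#' @examples
#' percent_change(134.75, 92.00)  # 31.7 — completion-time reduction
#' percent_change(4.25, 1.00)     # 76.5 — assistance reduction
#' @export
percent_change <- function(before, after) {
  if (!is.finite(before) || before <= 0)
    stop("percent_change requires before > 0")
  round(100 * (before - after) / before, 1)
}

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

fmt_miqr <- function(m) sprintf("%.2f (%.2f-%.2f)", m["median"], m["q1"], m["q3"])

safe_test <- function(expr) {
  tryCatch(suppressWarnings(expr), error = function(e) NULL)
}

#' Study-style summary of a paired two-group cohort
#'
#' Descriptive statistics (median and Q1-Q3 interquartile range, linear-
#' interpolation quantiles) by group and condition for completion time,
#' completion score and modified EFPT, plus the nonparametric tests used
#' for small paired feasibility cohorts: Mann-Whitney rank-sum between
#' groups within each condition, Wilcoxon signed-rank within each group
#' across conditions, and Fisher's exact test for the binary sex covariate.
#' All tests are two-sided; exact null distributions are used when the
#' sample permits (no ties, n <= 25 for the signed-rank), the normal
#' approximation otherwise. A paired test with no non-tied pairs is
#' reported as not computable (`NA`) rather than an error.
#'
#' @param dataset A `cohort_dataset` (or equivalent data frame with columns
#'   `participant_id`, `group`, `assisted`, `completion_time_s`,
#'   `completion_score`, `efpt_score`, optionally `sex`).
#' @return An object of class `group_comparison_report`: `descriptives`
#'   (data frame of medians/IQRs per measure x group x condition),
#'   `between_group` (rank-sum W/U statistic and p per measure x
#'   condition), `within_group` (signed-rank V and p per measure x group),
#'   and `sex_comparison` (Fisher's exact p, when `sex` is available).
#' @export
summarize_cohort <- function(dataset) {
  d <- as.data.frame(dataset)
  needed <- c("participant_id", "group", "assisted", "completion_time_s",
              "completion_score", "efpt_score")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stop("dataset missing column(s): ", paste(missing, collapse = ", "))
  groups <- sort(unique(d$group))
  if (!all(table(d$group) >= 2))
    stop("each group needs at least one participant with paired sessions")
  measures <- c(completion_time_s = "completion_time_s",
                completion_score = "completion_score",
                efpt_score = "efpt_score")

  desc <- list()
  for (m in names(measures)) for (g in groups) for (a in c(FALSE, TRUE)) {
    x <- d[[m]][d$group == g & d$assisted == a]
    mi <- median_iqr(x)
    desc[[length(desc) + 1L]] <- data.frame(
      measure = m, group = g,
      condition = if (a) "assisted" else "unassisted",
      n = length(x), median = mi["median"], q1 = mi["q1"], q3 = mi["q3"],
      formatted = fmt_miqr(mi), row.names = NULL, stringsAsFactors = FALSE)
  }
  desc <- do.call(rbind, desc)

  between <- list()
  if (length(groups) == 2) {
    for (m in names(measures)) for (a in c(FALSE, TRUE)) {
      x <- d[[m]][d$group == groups[1] & d$assisted == a]
      y <- d[[m]][d$group == groups[2] & d$assisted == a]
      wt <- safe_test(stats::wilcox.test(x, y, exact = TRUE))
      between[[length(between) + 1L]] <- data.frame(
        measure = m, condition = if (a) "assisted" else "unassisted",
        group_a = groups[1], group_b = groups[2],
        statistic_w = if (is.null(wt)) NA_real_ else unname(wt$statistic),
        p_value = if (is.null(wt)) NA_real_ else wt$p.value,
        row.names = NULL, stringsAsFactors = FALSE)
    }
    between <- do.call(rbind, between)
  } else between <- NULL

  within <- list()
  for (m in names(measures)) for (g in groups) {
    sub <- d[d$group == g, ]
    wide <- merge(sub[!sub$assisted, c("participant_id", m)],
                  sub[sub$assisted, c("participant_id", m)],
                  by = "participant_id", suffixes = c("_un", "_as"))
    diffs <- wide[[paste0(m, "_un")]] - wide[[paste0(m, "_as")]]
    if (all(diffs == 0)) {
      within[[length(within) + 1L]] <- data.frame(
        measure = m, group = g, n_pairs = nrow(wide),
        statistic_v = NA_real_, p_value = NA_real_,
        note = "all pairs tied; signed-rank not computable",
        row.names = NULL, stringsAsFactors = FALSE)
      next
    }
    wt <- safe_test(stats::wilcox.test(
      wide[[paste0(m, "_un")]], wide[[paste0(m, "_as")]],
      paired = TRUE, exact = nrow(wide) <= 25))
    within[[length(within) + 1L]] <- data.frame(
      measure = m, group = g, n_pairs = nrow(wide),
      statistic_v = if (is.null(wt)) NA_real_ else unname(wt$statistic),
      p_value = if (is.null(wt)) NA_real_ else wt$p.value,
      note = "", row.names = NULL, stringsAsFactors = FALSE)
  }
  within <- do.call(rbind, within)

  sex_cmp <- NULL
  if ("sex" %in% names(d) && length(groups) == 2) {
    one <- d[!duplicated(d$participant_id), ]
    tab <- table(one$group, one$sex)
    if (all(dim(tab) == c(2, 2))) {
      ft <- safe_test(stats::fisher.test(tab))
      sex_cmp <- list(table = tab,
                      p_value = if (is.null(ft)) NA_real_ else ft$p.value)
    }
  }

  structure(list(descriptives = desc, between_group = between,
                 within_group = within, sex_comparison = sex_cmp),
            class = "group_comparison_report")
}

#' @export
print.group_comparison_report <- function(x, ...) {
  cat("<group_comparison_report>\n\nDescriptives (median (Q1-Q3)):\n")
  print(x$descriptives[, c("measure", "group", "condition", "n", "formatted")],
        row.names = FALSE)
  if (!is.null(x$between_group)) {
    cat("\nBetween-group rank-sum tests:\n")
    print(x$between_group, row.names = FALSE, digits = 3)
  }
  cat("\nWithin-group signed-rank tests (unassisted vs assisted):\n")
  print(x$within_group, row.names = FALSE, digits = 3)
  if (!is.null(x$sex_comparison))
    cat(sprintf("\nSex distribution: Fisher exact p = %.3f\n",
                x$sex_comparison$p_value))
  invisible(x)
}

#' Write a group-comparison report to CSV + JSON
#'
#' @param report A `group_comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$descriptives,
                   file.path(dir, "descriptives.csv"), row.names = FALSE)
  if (!is.null(report$between_group))
    utils::write.csv(report$between_group,
                     file.path(dir, "between_group.csv"), row.names = FALSE)
  utils::write.csv(report$within_group,
                   file.path(dir, "within_group.csv"), row.names = FALSE)
  json <- list(
    descriptives = report$descriptives,
    between_group = report$between_group,
    within_group = report$within_group,
    sex_comparison = if (is.null(report$sex_comparison)) NULL else
      list(p_value = report$sex_comparison$p_value))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
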
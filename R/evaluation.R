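#' Per-class confusion counts over labelled frames
#'
#' Class-set membership comparison per frame: a class counts as TP when it
#' is in both the true and the predicted set, FP when predicted only, FN
#' when true only. Counts are additive over frames, so concatenating two
#' pair lists sums their tables.
#'
#' @param pairs A `label_pairs` list (see [label_frames()]).
#' @return Data frame with columns `class`, `tp`, `fp`, `fn`, sorted by
#'   class.
#' @export
confusion_matrix <- function(pairs) {
  if (!length(pairs)) stop("pairs must be non-empty")
  classes <- sort(unique(unlist(lapply(pairs, function(p)
    c(p$true_classes, p$predicted_classes)))))
  tp <- fp <- fn <- stats::setNames(integer(length(classes)), classes)
  for (p in pairs) {
    tr <- p$true_classes; pr <- p$predicted_classes
    hit <- intersect(tr, pr)
    tp[hit] <- tp[hit] + 1L
    fp[setdiff(pr, tr)] <- fp[setdiff(pr, tr)] + 1L
    fn[setdiff(tr, pr)] <- fn[setdiff(tr, pr)] + 1L
  }
  data.frame(class = classes, tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), row.names = NULL, stringsAsFactors = FALSE)
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Detection-quality report per task step
#'
#' Frames are grouped by the task step active at their timestamp (from the
#' ground-truth log); within each step, precision and recall are
#' micro-averaged over frames on class-set membership. The cumulative
#' summary is the mean and standard deviation of the per-step values across
#' steps — the form in which the deployed recogniser's quality was
#' reported (cumulative precision 0.93, recall 0.94 in the feasibility
#' study). Steps whose denominator is zero (e.g. no predictions at all for
#' precision) are reported as `NA` and excluded from the cumulative summary
#' with a warning.
#'
#' @param pairs A `label_pairs` list.
#' @param module The `task_module`; every pair's `step_id` must be one of
#'   its steps.
#' @param sd_type `"population"` (divide by N, default) or `"sample"`.
#' @return An object of class `detection_eval_report`: `per_step` data
#'   frame (`step_id`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1`),
#'   `cumulative_precision` and `cumulative_recall` (each `c(mean, sd)`),
#'   and the per-class `confusion` table.
#' @export
evaluate_detections <- function(pairs, module,
                                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!length(pairs)) stop("pairs must be non-empty")
  ids <- step_ids(module)
  got <- unique(vapply(pairs, `[[`, "", "step_id"))
  unknown <- setdiff(got, ids)
  if (length(unknown))
    stop("pairs reference step id(s) not in the module: ",
         paste(unknown, collapse = ", "))

  per <- lapply(ids, function(id) {
    sub <- Filter(function(p) p$step_id == id, pairs)
    if (!length(sub))
      return(data.frame(step_id = id, tp = NA_integer_, fp = NA_integer_,
                        fn = NA_integer_, precision = NA_real_,
                        recall = NA_real_, f1 = NA_real_,
                        stringsAsFactors = FALSE))
    tp <- fp <- fn <- 0L
    for (p in sub) {
      tr <- p$true_classes; pr <- p$predicted_classes
      tp <- tp + length(intersect(tr, pr))
      fp <- fp + length(setdiff(pr, tr))
      fn <- fn + length(setdiff(tr, pr))
    }
    m <- prf(tp, fp, fn)
    data.frame(step_id = id, tp = tp, fp = fp, fn = fn,
               precision = m["precision"], recall = m["recall"],
               f1 = m["f1"], row.names = NULL, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)

  sdf <- if (sd_type == "population") pop_sd else stats::sd
  cum <- function(x, what) {
    ok <- !is.na(x)
    if (any(!ok))
      warning(sum(!ok), " step(s) with undefined ", what,
              " excluded from the cumulative summary")
    if (!any(ok)) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(x[ok]), sd = sdf(x[ok]))
  }
  structure(list(
    per_step = per,
    cumulative_precision = cum(per$precision, "precision"),
    cumulative_recall = cum(per$recall, "recall"),
    confusion = confusion_matrix(pairs),
    sd_type = sd_type
  ), class = "detection_eval_report")
}

#' @export
print.detection_eval_report <- function(x, ...) {
  cat("<detection_eval_report>\n")
  cat(sprintf("  cumulative precision %.3f (SD %.3f), recall %.3f (SD %.3f)\n",
              x$cumulative_precision["mean"], x$cumulative_precision["sd"],
              x$cumulative_recall["mean"], x$cumulative_recall["sd"]))
  print(x$per_step, digits = 3)
  invisible(x)
}
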
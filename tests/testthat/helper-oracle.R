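# Independent reference implementations used as oracles.  These deliberately
# avoid the package's internals: smoothing is a literal windowed mean, the
# replay interpreter rescans and re-averages the stream for every query, and
# the geometry/statistics are re-derived from first principles.

oracle_frame_value <- function(fr, cls, mode = "confidence") {
  vals <- c()
  for (d in fr$detections) if (d$label == cls) vals <- c(vals, d$confidence)
  if (!length(vals)) return(0)
  if (mode == "binary") 1 else max(vals)
}

oracle_smooth_at <- function(frames, k, cls, window, mode = "confidence") {
  idx <- seq(max(1, k - window + 1), k)
  mean(vapply(frames[idx], function(fr) oracle_frame_value(fr, cls, mode), 0))
}

oracle_smooth <- function(frames, window, vocab, mode = "confidence") {
  out <- matrix(0, length(frames), length(vocab), dimnames = list(NULL, vocab))
  for (k in seq_along(frames))
    for (cls in vocab)
      out[k, cls] <- oracle_smooth_at(frames, k, cls, window, mode)
  out
}

oracle_best_det <- function(fr, cls) {
  best <- NULL
  for (d in fr$detections) {
    if (d$label != cls) next
    if (is.null(best) ||
        d$confidence > best$confidence ||
        (d$confidence == best$confidence &&
         (d$bbox[1] < best$bbox[1] ||
          (d$bbox[1] == best$bbox[1] && d$bbox[2] < best$bbox[2]))))
      best <- d
  }
  best
}

oracle_spatial <- function(relation, su, ob) {
  scx <- su$bbox[1] + su$bbox[3] / 2; scy <- su$bbox[2] + su$bbox[4] / 2
  ocx <- ob$bbox[1] + ob$bbox[3] / 2; ocy <- ob$bbox[2] + ob$bbox[4] / 2
  if (relation == "contains")
    return(scx >= ob$bbox[1] && scx <= ob$bbox[1] + ob$bbox[3] &&
           scy >= ob$bbox[2] && scy <= ob$bbox[2] + ob$bbox[4])
  if (relation == "above") return(scy < ocy)
  # overlaps: positive intersection area
  ix <- min(su$bbox[1] + su$bbox[3], ob$bbox[1] + ob$bbox[3]) -
    max(su$bbox[1], ob$bbox[1])
  iy <- min(su$bbox[2] + su$bbox[4], ob$bbox[2] + ob$bbox[4]) -
    max(su$bbox[2], ob$bbox[2])
  ix > 0 && iy > 0
}

oracle_cond_sat <- function(frames, k, cond, window, thr, mode = "confidence") {
  for (cls in cond$required_present)
    if (oracle_smooth_at(frames, k, cls, window, mode) < thr) return(FALSE)
  for (cls in cond$required_absent)
    if (oracle_smooth_at(frames, k, cls, window, mode) >= thr) return(FALSE)
  for (p in cond$spatial_predicates) {
    found <- FALSE
    for (j in seq(k, max(1, k - window + 1))) {
      su <- oracle_best_det(frames[[j]], p$subject)
      ob <- oracle_best_det(frames[[j]], p$object)
      if (!is.null(su) && !is.null(ob)) {
        if (!oracle_spatial(p$relation, su, ob)) return(FALSE)
        found <- TRUE
        break
      }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# Naive replay interpreter: per-frame, per-step brute-force re-evaluation
# with the same guidance semantics as the engine (cues, then errors, then
# completion; error beats completion; edge-triggered error episodes;
# level-5 force-advance when assisted).
oracle_run_session <- function(module, frames, assisted, thr = 0.5,
                               mode = "confidence") {
  n <- length(frames)
  ts <- vapply(frames, function(f) f$timestamp_ms, 0)
  window <- module$smoothing_window
  steps <- module$steps
  n_steps <- length(steps)
  ids <- vapply(steps, function(s) s$step_id, "")

  events <- list()
  emit <- function(t, kind, id, detail = "", cue = NULL)
    events[[length(events) + 1L]] <<- list(timestamp_ms = t, kind = kind,
                                           step_id = id, cue_level = cue,
                                           detail = detail)
  completed <- rep(FALSE, n_steps); max_cue <- rep(0L, n_steps)
  errs <- rep(0L, n_steps)
  instr <- first_hand <- compl <- rep(NA_real_, n_steps)

  s <- 1L
  instr[1] <- ts[1]
  emit(ts[1], "instruction_shown", ids[1], steps[[1]]$instruction_text)
  dwell <- 0L
  err_dwell <- integer(length(steps[[1]]$error_conditions))
  err_eng <- logical(length(steps[[1]]$error_conditions))
  activate <- function(k, t) {
    instr[k] <<- t
    emit(t, "instruction_shown", ids[k], steps[[k]]$instruction_text)
    dwell <<- 0L
    err_dwell <<- integer(length(steps[[k]]$error_conditions))
    err_eng <<- logical(length(steps[[k]]$error_conditions))
  }

  i <- 1L
  while (i <= n && s <= n_steps) {
    t <- ts[i]; step <- steps[[s]]
    if (is.na(first_hand[s]) && frames[[i]]$hand_present && t >= instr[s])
      first_hand[s] <- t
    elapsed <- (t - instr[s]) / 1000
    cs <- step$cue_schedule
    forced <- FALSE
    while (max_cue[s] < nrow(cs) &&
           elapsed >= cs$stall_timeout_s[max_cue[s] + 1L]) {
      lvl <- max_cue[s] + 1L
      max_cue[s] <- lvl
      if (assisted) {
        emit(t, "cue_issued", ids[s], cs$text[lvl], cue = cs$level[lvl])
        if (cs$level[lvl] == 5L) {
          completed[s] <- TRUE; compl[s] <- t
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
    fired <- FALSE
    for (k in seq_along(step$error_conditions)) {
      ec <- step$error_conditions[[k]]
      if (oracle_cond_sat(frames, i, ec$condition, window, thr, mode)) {
        err_dwell[k] <- err_dwell[k] + 1L
        if (!err_eng[k] && err_dwell[k] >= ec$condition$dwell_frames) {
          err_eng[k] <- TRUE
          errs[s] <- errs[s] + 1L
          fired <- TRUE
          emit(t, "error_detected", ids[s], ec$corrective_instruction)
          if (assisted)
            emit(t, "corrective_shown", ids[s], ec$corrective_instruction)
        }
      } else {
        err_dwell[k] <- 0L
        err_eng[k] <- FALSE
      }
    }
    if (fired || any(err_eng)) {
      dwell <- 0L
      i <- i + 1L
      next
    }
    if (oracle_cond_sat(frames, i, step$completion_condition, window, thr, mode)) {
      dwell <- dwell + 1L
      if (dwell >= step$completion_condition$dwell_frames) {
        completed[s] <- TRUE; compl[s] <- t
        emit(t, "step_completed", ids[s], "")
        if (assisted) emit(t, "positive_feedback", ids[s], "great")
        s <- s + 1L
        if (s <= n_steps) activate(s, t)
      }
    } else dwell <- 0L
    i <- i + 1L
  }
  end_ms <- if (s > n_steps) compl[n_steps] else ts[n]
  emit(end_ms, "session_end", if (s > n_steps) ids[n_steps] else ids[s], "")
  list(events = events,
       completed = stats::setNames(completed, ids),
       max_cue_level = stats::setNames(max_cue, ids),
       error_count = stats::setNames(errs, ids),
       instr = instr, first_hand = first_hand, compl = compl,
       total = if (all(completed)) (end_ms - instr[1]) / 1000 else NA_real_)
}

events_table <- function(events) {
  do.call(rbind, lapply(events, function(e) data.frame(
    timestamp_ms = e$timestamp_ms, kind = e$kind, step_id = e$step_id,
    cue_level = if (is.null(e$cue_level)) NA_integer_ else e$cue_level,
    detail = e$detail, stringsAsFactors = FALSE)))
}

# Brute-force confusion counts via per-frame set comparison.
oracle_confusion <- function(pairs) {
  counts <- list()
  bump <- function(cls, slot) {
    cur <- counts[[cls]]
    if (is.null(cur)) cur <- c(tp = 0L, fp = 0L, fn = 0L)
    cur[slot] <- cur[slot] + 1L
    counts[[cls]] <<- cur
  }
  for (p in pairs) {
    for (cls in union(p$true_classes, p$predicted_classes)) {
      in_t <- cls %in% p$true_classes
      in_p <- cls %in% p$predicted_classes
      if (in_t && in_p) bump(cls, "tp")
      else if (in_p) bump(cls, "fp")
      else bump(cls, "fn")
    }
  }
  cls <- sort(names(counts))
  data.frame(class = cls,
             tp = vapply(counts[cls], `[[`, 0L, "tp"),
             fp = vapply(counts[cls], `[[`, 0L, "fp"),
             fn = vapply(counts[cls], `[[`, 0L, "fn"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Mann-Whitney U by direct pair counting, and its exact two-sided p-value
# by exhaustive enumeration of all group assignments of the pooled sample.
oracle_u_statistic <- function(x, y) {
  # U of the first sample: pairs where x exceeds y (ties count half)
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

oracle_u_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pooled), n)
  null_u <- apply(combs, 2, function(idx)
    oracle_u_statistic(pooled[idx], pooled[-idx]))
  obs <- oracle_u_statistic(x, y)
  mu <- length(x) * length(y) / 2
  mean(abs(null_u - mu) >= abs(obs - mu) - 1e-9)
}
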
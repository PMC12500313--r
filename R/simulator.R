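#' Behavioural profile of a synthetic participant
#'
#' The semi-Markov behaviour model driving the simulator: per step the
#' virtual participant hesitates (log-normal pre-action delay), then either
#' performs the action or enters an error state (Bernoulli), and responds to
#' cues (assisted) or self-corrects (unassisted) with the given
#' probabilities. The profile is deliberately minimal — the guidance engine
#' only ever sees detection states, so this is the least structure that can
#' reproduce the assisted/unassisted behavioural contrast.
#'
#' @param profile_id Identifier.
#' @param per_step_error_prob Probability of entering the step's error state.
#' @param hesitation_log_mean,hesitation_log_sd Log-scale parameters of the
#'   per-step pre-action delay in seconds.
#' @param cue_responsiveness Numeric vector of length 5, non-decreasing:
#'   probability of resuming correct action within one stall interval after
#'   a cue of each level. Level 1 also governs the response to corrective
#'   instructions after an error.
#' @param base_action_duration_s Time the correct action itself takes.
#' @param assisted_hesitation_factor Multiplier applied to hesitation when
#'   step-by-step instructions are shown (below 1 for participants whose
#'   planning, not motor execution, is the bottleneck).
#' @param unassisted_recovery_prob Per-interval probability of
#'   self-correcting an error without guidance.
#' @param error_state_duration_s Minimum visible duration of an error state.
#' @param recovery_check_interval_s Interval between correction
#'   opportunities while in an error state.
#' @param hesitation_cap_s Upper bound on a single hesitation draw, keeping
#'   session length finite.
#' @param seed Profile-level seed offset mixed into session seeds.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(profile_id,
                                per_step_error_prob = 0.1,
                                hesitation_log_mean = log(3),
                                hesitation_log_sd = 0.4,
                                cue_responsiveness = c(0.8, 0.85, 0.9, 0.95, 1.0),
                                base_action_duration_s = 4,
                                assisted_hesitation_factor = 1.0,
                                unassisted_recovery_prob = 0.3,
                                error_state_duration_s = 4,
                                recovery_check_interval_s = 5,
                                hesitation_cap_s = 120,
                                seed = 0L) {
  stopifnot(per_step_error_prob >= 0, per_step_error_prob <= 1,
            hesitation_log_sd >= 0, base_action_duration_s > 0,
            length(cue_responsiveness) == 5,
            all(cue_responsiveness >= 0), all(cue_responsiveness <= 1),
            all(diff(cue_responsiveness) >= -1e-12))
  structure(list(
    profile_id = as.character(profile_id),
    per_step_error_prob = per_step_error_prob,
    hesitation_log_mean = hesitation_log_mean,
    hesitation_log_sd = hesitation_log_sd,
    cue_responsiveness = cue_responsiveness,
    base_action_duration_s = base_action_duration_s,
    assisted_hesitation_factor = assisted_hesitation_factor,
    unassisted_recovery_prob = unassisted_recovery_prob,
    error_state_duration_s = error_state_duration_s,
    recovery_check_interval_s = recovery_check_interval_s,
    hesitation_cap_s = hesitation_cap_s,
    seed = as.integer(seed)
  ), class = "participant_profile")
}

#' Default mild-dementia-like participant profile
#'
#' Slow planning (median ~10 s hesitation per step), frequent errors, good
#' responsiveness to cues, and a strong benefit from explicit step
#' instructions. Chosen so simulated unassisted/assisted sessions land in
#' the magnitude range reported for the patient group (minutes-scale
#' unassisted completion, clear assisted speed-up); these are plausibility
#' settings, not estimates of any real cohort.
#'
#' @return A `participant_profile`.
#' @export
patient_profile <- function() {
  participant_profile(
    profile_id = "patient",
    per_step_error_prob = 0.35,
    hesitation_log_mean = log(10), hesitation_log_sd = 0.6,
    cue_responsiveness = c(0.8, 0.85, 0.9, 0.95, 1.0),
    base_action_duration_s = 5,
    assisted_hesitation_factor = 0.6)
}

#' Default healthy-control participant profile
#'
#' Fast (median ~2 s hesitation), rare errors, instructions neither help
#' nor hinder much.
#'
#' @return A `participant_profile`.
#' @export
control_profile <- function() {
  participant_profile(
    profile_id = "control",
    per_step_error_prob = 0.05,
    hesitation_log_mean = log(2), hesitation_log_sd = 0.3,
    cue_responsiveness = c(0.9, 0.95, 1.0, 1.0, 1.0),
    base_action_duration_s = 3,
    assisted_hesitation_factor = 1.05)
}

#' Frame-level detection noise model
#'
#' Emulates an imperfect recogniser on top of the true scene: each true
#' class is dropped per frame with `false_negative_rate`; each vocabulary
#' class not in the scene is spuriously detected with
#' `false_positive_rate`; confidences and bbox coordinates receive Gaussian
#' jitter.
#'
#' @param false_negative_rate,false_positive_rate Per-frame, per-class
#'   rates in `[0, 1]`.
#' @param confidence_jitter_sd,bbox_jitter_sd Gaussian jitter SDs
#'   (normalised units for the bbox).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(false_negative_rate = 0.05,
                        false_positive_rate = 0.01,
                        confidence_jitter_sd = 0.05,
                        bbox_jitter_sd = 0.01) {
  stopifnot(false_negative_rate >= 0, false_negative_rate <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1,
            confidence_jitter_sd >= 0, bbox_jitter_sd >= 0)
  structure(list(false_negative_rate = false_negative_rate,
                 false_positive_rate = false_positive_rate,
                 confidence_jitter_sd = confidence_jitter_sd,
                 bbox_jitter_sd = bbox_jitter_sd),
            class = "noise_model")
}

#' An exact, noise-free detector
#' @return A `noise_model` with all rates and jitters zero.
#' @export
zero_noise <- function() noise_model(0, 0, 0, 0)

# Deterministic 31-bit string hash (for seed derivation).
string_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Derive a session-level seed
#'
#' One generator per session, derived from the experiment seed, the
#' participant identity and the condition, so that paired sessions of one
#' participant share participant-level draws but differ in
#' condition-dependent ones.
#'
#' @param seed Experiment-level integer seed.
#' @param ... Further strings/integers mixed in (participant id, condition).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (part in list(...)) {
    p <- if (is.character(part)) string_hash(part) else as.numeric(part)
    h <- (h * 69069 + p + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# Nominal scene layout: normalised bboxes (x, y, w, h), top-left origin.
.scene_layout <- list(
  table = c(0.00, 0.55, 1.00, 0.44),
  pot_empty = c(0.08, 0.62, 0.18, 0.15),
  pot_with_water = c(0.635, 0.625, 0.18, 0.15),
  pot_with_egg = c(0.635, 0.625, 0.18, 0.15),
  pot_upside_down = c(0.635, 0.625, 0.18, 0.15),
  pitcher = c(0.30, 0.58, 0.12, 0.22),
  pitcher_lifted = c(0.38, 0.33, 0.12, 0.22),
  wrong_object_lifted = c(0.18, 0.33, 0.10, 0.18),
  egg = c(0.47, 0.63, 0.06, 0.06),
  egg_in_hand = c(0.45, 0.40, 0.06, 0.06),
  egg_dropped = c(0.44, 0.80, 0.08, 0.08),
  water_spilled = c(0.50, 0.78, 0.20, 0.10),
  cooker_off = c(0.55, 0.55, 0.35, 0.30),
  cooker_on = c(0.55, 0.55, 0.35, 0.30),
  cooker_lid_open = c(0.55, 0.46, 0.35, 0.10),
  cooker_lid_closed = c(0.55, 0.50, 0.35, 0.10),
  lid_misaligned = c(0.58, 0.48, 0.35, 0.10),
  wrong_button = c(0.57, 0.80, 0.04, 0.04),
  sponge = c(0.05, 0.80, 0.08, 0.06)
)

nominal_bbox <- function(label) {
  b <- .scene_layout[[label]]
  if (!is.null(b)) return(b)
  # unknown classes: deterministic grid placement from the label hash
  h <- string_hash(label)
  c(0.05 + (h %% 8) * 0.11, 0.05 + ((h %/% 8) %% 4) * 0.11, 0.10, 0.10)
}

# Place a subject bbox so that a spatial predicate holds w.r.t. object_bbox.
place_for_predicate <- function(relation, subject_bbox, object_bbox) {
  w <- subject_bbox[3]; h <- subject_bbox[4]
  oc <- c(object_bbox[1] + object_bbox[3] / 2, object_bbox[2] + object_bbox[4] / 2)
  pos <- switch(relation,
    contains = ,
    overlaps = c(oc[1] - w / 2, oc[2] - h / 2),
    above = c(oc[1] - w / 2, max(0, object_bbox[2] - h - 0.02)),
    c(oc[1] - w / 2, oc[2] - h / 2))
  c(min(max(pos[1], 0), 1 - w), min(max(pos[2], 0), 1 - h), w, h)
}

# Scene = named list label -> bbox.  Apply a step's completion condition.
apply_completion <- function(scene, cond) {
  for (cls in cond$required_absent) scene[[cls]] <- NULL
  for (cls in cond$required_present)
    if (is.null(scene[[cls]])) scene[[cls]] <- nominal_bbox(cls)
  for (p in cond$spatial_predicates) {
    ob <- scene[[p$object]] %||% nominal_bbox(p$object)
    scene[[p$subject]] <- place_for_predicate(
      p$relation, scene[[p$subject]] %||% nominal_bbox(p$subject), ob)
  }
  scene
}

error_classes <- function(step) {
  if (!length(step$error_conditions)) return(character())
  step$error_conditions[[1]]$condition$required_present
}

initial_scene <- function(module) {
  err_cls <- unique(unlist(lapply(module$steps, function(s)
    unlist(lapply(s$error_conditions,
                  function(e) e$condition$required_present)))))
  init <- character()
  for (s in module$steps)
    init <- c(init, s$completion_condition$required_absent)
  init <- setdiff(unique(init), err_cls)
  # props used later in the task sit on the table from the start
  for (s in module$steps)
    for (p in s$completion_condition$spatial_predicates)
      init <- union(init, p$object)
  scene <- lapply(init, nominal_bbox)
  names(scene) <- init
  scene
}

#' Simulate one guided or unguided session
#'
#' Generates a time-ordered detection-frame stream for one virtual
#' participant performing the task, together with the ground truth (true
#' per-frame class sets, active step, and state-change times). Per step the
#' participant hesitates, may enter the step's error state, and responds to
#' cues (assisted) or self-corrects (unassisted); the scene evolves by
#' applying each step's completion condition to a cumulative scene state.
#' Fully reproducible: identical arguments and seed give byte-identical
#' streams.
#'
#' @param module A validated `task_module`.
#' @param profile A [participant_profile()].
#' @param noise A [noise_model()].
#' @param assisted Logical; simulated condition.
#' @param frame_period_ms Sampling interval of the generated stream. The
#'   default 100 ms keeps a minutes-scale session at a desk-friendly ~10^3
#'   frames; the deployed system's 5 ms interval is equally valid input.
#' @param seed Integer seed for the session's generator.
#' @param participant_id Identifier recorded in the ground truth.
#' @param participant_effects Optional list with `hesitation_frailty`
#'   (multiplier) and `error_shift` (logit shift), shared between the two
#'   paired sessions of one participant; see [simulate_cohort()].
#' @return A list with `frames` (list of [detection_frame()]) and `ground_truth`
#'   (class `ground_truth`: per-frame `true_classes`, `step_id`,
#'   `timestamp_ms`, plus a `changes` data frame of true state-change
#'   times).
#' @export
simulate_session <- function(module, profile, noise = noise_model(),
                             assisted = TRUE, frame_period_ms = 100,
                             seed = 1L,
                             participant_id = profile$profile_id,
                             participant_effects = NULL) {
  stopifnot(inherits(module, "task_module"),
            inherits(profile, "participant_profile"),
            inherits(noise, "noise_model"), frame_period_ms > 0)
  fp_s <- frame_period_ms / 1000
  eff <- participant_effects %||% list(hesitation_frailty = 1, error_shift = 0)
  p_err <- profile$per_step_error_prob
  if (p_err > 0 && p_err < 1)
    p_err <- stats::plogis(stats::qlogis(p_err) + eff$error_shift)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(derive_seed(seed, profile$seed))

  settle_s <- (module$smoothing_window +
    max(vapply(module$steps,
               function(s) s$completion_condition$dwell_frames, 0L))) * fp_s + 0.2

  segments <- list()   # each: start_s, scene, hand, step_id
  changes <- list()
  add_seg <- function(start_s, scene, hand, step_id)
    segments[[length(segments) + 1L]] <<- list(start_s = start_s,
                                               scene = scene, hand = hand,
                                               step_id = step_id)
  add_change <- function(time_s, step_id, what)
    changes[[length(changes) + 1L]] <<- data.frame(
      time_s = time_s, step_id = step_id, what = what,
      stringsAsFactors = FALSE)

  scene <- initial_scene(module)
  t_now <- 0
  for (step in module$steps) {
    id <- step$step_id
    add_seg(t_now, scene, FALSE, id)   # hesitation: hand withdrawn

    h <- min(stats::rlnorm(1, profile$hesitation_log_mean,
                           profile$hesitation_log_sd) * eff$hesitation_frailty,
             profile$hesitation_cap_s)
    if (assisted) h <- h * profile$assisted_hesitation_factor

    assessor <- FALSE
    a <- h
    if (assisted && nrow(step$cue_schedule)) {
      cs <- step$cue_schedule
      for (k in seq_len(nrow(cs))) {
        if (a <= cs$stall_timeout_s[k]) break
        if (cs$level[k] == 5L) {         # assessor takes over
          assessor <- TRUE
          a <- cs$stall_timeout_s[k] + 1
          break
        }
        if (stats::runif(1) < profile$cue_responsiveness[cs$level[k]])
          a <- cs$stall_timeout_s[k] + stats::runif(1, 0.5, 3)
      }
    }

    act_start <- t_now + a
    add_seg(act_start, scene, TRUE, id)
    add_change(act_start, id, "action_start")

    erred <- !assessor && p_err > 0 && stats::runif(1) < p_err
    if (erred) {
      err_scene <- scene
      for (cls in error_classes(step))
        err_scene[[cls]] <- nominal_bbox(cls)
      add_seg(act_start, err_scene, TRUE, id)
      add_change(act_start, id, "error_start")
      p_rec <- if (assisted) profile$cue_responsiveness[1]
               else profile$unassisted_recovery_prob
      fails <- if (p_rec >= 1) 0L else min(stats::rgeom(1, max(p_rec, 1e-3)), 24L)
      clear_s <- act_start + profile$error_state_duration_s +
        fails * profile$recovery_check_interval_s
      add_seg(clear_s, scene, TRUE, id)
      add_change(clear_s, id, "error_clear")
      act_start <- clear_s
    }

    act_dur <- profile$base_action_duration_s *
      (if (assessor) 0.5 else stats::runif(1, 0.8, 1.2))
    t_complete <- act_start + act_dur
    scene <- apply_completion(scene, step$completion_condition)
    add_seg(t_complete, scene, TRUE, id)
    add_change(t_complete, id, "completion_state")
    t_now <- t_complete + settle_s
  }
  t_end <- t_now + 1

  seg_starts <- vapply(segments, `[[`, 0, "start_s")
  times_s <- seq(0, t_end, by = fp_s)
  seg_idx <- findInterval(times_s, seg_starts)
  seg_idx[seg_idx < 1L] <- 1L

  vocab <- union(task_vocabulary(module), names(.scene_layout))
  n <- length(times_s)
  frames <- vector("list", n)
  true_classes <- vector("list", n)
  gt_step <- character(n)
  for (i in seq_len(n)) {
    seg <- segments[[seg_idx[i]]]
    tru <- seg$scene
    true_classes[[i]] <- names(tru)
    gt_step[i] <- seg$step_id
    dets <- list()
    for (cls in names(tru)) {
      if (noise$false_negative_rate > 0 &&
          stats::runif(1) < noise$false_negative_rate) next
      conf <- 0.9
      if (noise$confidence_jitter_sd > 0)
        conf <- min(max(conf + stats::rnorm(1, 0, noise$confidence_jitter_sd),
                        0.05), 1)
      bb <- tru[[cls]]
      if (noise$bbox_jitter_sd > 0) {
        bb[1:2] <- bb[1:2] + stats::rnorm(2, 0, noise$bbox_jitter_sd)
        bb[1] <- min(max(bb[1], 0), 1 - bb[3])
        bb[2] <- min(max(bb[2], 0), 1 - bb[4])
      }
      dets[[length(dets) + 1L]] <- object_detection(cls, conf, bb)
    }
    if (noise$false_positive_rate > 0) {
      for (cls in setdiff(vocab, names(tru))) {
        if (stats::runif(1) < noise$false_positive_rate) {
          dets[[length(dets) + 1L]] <- object_detection(
            cls, stats::runif(1, 0.5, 0.85), nominal_bbox(cls))
        }
      }
    }
    hand <- isTRUE(seg$hand)
    centroid <- NULL
    if (hand) {
      ref <- if (length(true_classes[[i]]))
        tru[[true_classes[[i]] [1]]] else c(0.45, 0.45, 0.1, 0.1)
      centroid <- c(min(max(ref[1] + ref[3] / 2, 0), 1),
                    min(max(ref[2] + ref[4] / 2, 0), 1))
    }
    frames[[i]] <- detection_frame(round(times_s[i] * 1000, 6), dets, hand, centroid)
  }

  gt <- structure(list(
    participant_id = participant_id,
    assisted = assisted,
    timestamp_ms = round(times_s * 1000, 6),
    true_classes = true_classes,
    step_id = gt_step,
    changes = do.call(rbind, changes)
  ), class = "ground_truth")
  list(frames = frames, ground_truth = gt)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s (%s), %d frames, %d state changes\n",
              x$participant_id,
              if (x$assisted) "assisted" else "unassisted",
              length(x$timestamp_ms), nrow(x$changes)))
  invisible(x)
}

#' Simulate a paired two-condition cohort
#'
#' For every virtual participant, one unassisted and one assisted session
#' are generated (paired design), run through the guidance engine, and
#' scored with the completion and modified-EFPT instruments. Participant-
#' level random effects (hesitation frailty, error-propensity shift and a
#' binary sex covariate) are drawn once per participant from a seed derived
#' from the participant identity, so the paired sessions share them while
#' condition-dependent draws differ.
#'
#' @param module A validated `task_module`.
#' @param n_patients,n_controls Group sizes (the feasibility-study layout
#'   was 12 patients and 7 controls).
#' @param patient_profile_,control_profile_ Behaviour profiles per group.
#' @param noise A [noise_model()].
#' @param seed Experiment-level seed.
#' @param frame_period_ms Sampling interval for the generated streams.
#' @return A data frame (class `cohort_dataset`) with one row per session:
#'   `participant_id`, `group`, `sex`, `assisted`, `completion_time_s`,
#'   `completion_score`, `efpt_score`, `errors`, `steps_completed`.
#' @export
simulate_cohort <- function(module, n_patients, n_controls,
                            patient_profile_ = patient_profile(),
                            control_profile_ = control_profile(),
                            noise = noise_model(), seed = 1L,
                            frame_period_ms = 100) {
  stopifnot(n_patients >= 1, n_controls >= 1)
  roster <- rbind(
    data.frame(participant_id = sprintf("patient_%02d", seq_len(n_patients)),
               group = "patient", stringsAsFactors = FALSE),
    data.frame(participant_id = sprintf("control_%02d", seq_len(n_controls)),
               group = "control", stringsAsFactors = FALSE))
  rows <- list()
  for (r in seq_len(nrow(roster))) {
    pid <- roster$participant_id[r]
    grp <- roster$group[r]
    prof <- if (grp == "patient") patient_profile_ else control_profile_

    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(seed, pid))
    effects <- list(hesitation_frailty = stats::rlnorm(1, 0, 0.2),
                    error_shift = stats::rnorm(1, 0, 0.5),
                    sex = if (stats::runif(1) < 0.2) "male" else "female")
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

    for (assisted in c(FALSE, TRUE)) {
      cond <- if (assisted) "assisted" else "unassisted"
      sim <- simulate_session(
        module, prof, noise, assisted = assisted,
        frame_period_ms = frame_period_ms,
        seed = derive_seed(seed, pid, cond),
        participant_id = pid, participant_effects = effects)
      rec <- run_session(module, sim$frames, assisted = assisted,
                         session_id = paste(pid, cond, sep = "_"),
                         participant_id = pid)
      comp <- score_completion(rec, module)
      efpt <- score_efpt(rec, module)
      tt <- rec$total_completion_time_s
      if (is.na(tt))
        tt <- (utils::tail(sim$ground_truth$timestamp_ms, 1) -
                 sim$ground_truth$timestamp_ms[1]) / 1000
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, group = grp, sex = effects$sex,
        assisted = assisted,
        completion_time_s = tt,
        completion_score = comp$total,
        efpt_score = efpt$total,
        errors = sum(rec$error_count),
        steps_completed = sum(rec$completed),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_dataset", "data.frame")
  out
}

#' Pair per-frame ground truth with (noisy) predictions
#'
#' Builds the labelled evaluation pairs consumed by
#' [evaluate_detections()]: for every frame, the true class set from the
#' simulator's ground truth and the predicted class set from the frame's
#' detections.
#'
#' @param ground_truth `ground_truth` from [simulate_session()].
#' @param frames The matching frame stream.
#' @return A list of frame-label pairs, each a list with `timestamp_ms`,
#'   `true_classes`, `predicted_classes`, `step_id` (class `label_pairs`).
#' @export
label_frames <- function(ground_truth, frames) {
  if (length(frames) != length(ground_truth$timestamp_ms))
    stop("frames and ground truth have different lengths (",
         length(frames), " vs ", length(ground_truth$timestamp_ms), ")")
  pairs <- lapply(seq_along(frames), function(i) {
    list(timestamp_ms = frames[[i]]$timestamp_ms,
         true_classes = sort(unique(ground_truth$true_classes[[i]])),
         predicted_classes =
           sort(unique(vapply(frames[[i]]$detections, `[[`, "", "label"))),
         step_id = ground_truth$step_id[i])
  })
  structure(pairs, class = "label_pairs")
}

#' Read/write labelled frame pairs as JSON-lines
#'
#' @param pairs A `label_pairs` list.
#' @param path File path.
#' @return `write_label_pairs()` returns `path` invisibly;
#'   `read_label_pairs()` returns a `label_pairs` list.
#' @export
write_label_pairs <- function(pairs, path) {
  lines <- vapply(pairs, function(p)
    jsonlite::toJSON(list(timestamp_ms = p$timestamp_ms,
                          true_classes = as.list(p$true_classes),
                          predicted_classes = as.list(p$predicted_classes),
                          step_id = p$step_id),
                     auto_unbox = TRUE, digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_label_pairs
#' @export
read_label_pairs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  structure(lapply(seq_along(lines), function(i) {
    obj <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    list(timestamp_ms = as.numeric(obj$timestamp_ms),
         true_classes = as.character(unlist(obj$true_classes)),
         predicted_classes = as.character(unlist(obj$predicted_classes)),
         step_id = as.character(obj$step_id))
  }), class = "label_pairs")
}

#' Write the cohort session-summary table as CSV
#'
#' @param dataset A `cohort_dataset` from [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param path Input CSV path.
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$assisted <- as.logical(out$assisted)
  class(out) <- c("cohort_dataset", "data.frame")
  out
}
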
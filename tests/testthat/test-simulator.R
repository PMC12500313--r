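perfect_profile <- function() {
  participant_profile("perfect", per_step_error_prob = 0,
                      hesitation_log_mean = log(0.3),
                      hesitation_log_sd = 0.01,
                      base_action_duration_s = 2)
}

test_that("a noiseless perfect participant earns completion 12 and EFPT 0", {
  m <- default_task_module()
  sim <- simulate_session(m, perfect_profile(), zero_noise(),
                          assisted = TRUE, seed = 5)
  rec <- run_session(m, sim$frames, assisted = TRUE)
  expect_true(all(rec$completed))
  expect_identical(score_completion(rec, m)$total, 12L)
  expect_identical(score_efpt(rec, m)$total, 0L)
  expect_identical(sum(rec$error_count), 0L)
})

test_that("identical seeds reproduce the stream byte for byte; seeds differ otherwise", {
  m <- default_task_module()
  p <- patient_profile()
  s1 <- simulate_session(m, p, noise_model(), assisted = FALSE, seed = 11)
  s2 <- simulate_session(m, p, noise_model(), assisted = FALSE, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_frames(s1$frames, f1)
  write_frames(s2$frames, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(s1$ground_truth, s2$ground_truth)

  s3 <- simulate_session(m, p, noise_model(), assisted = FALSE, seed = 12)
  expect_false(identical(s1$frames, s3$frames))
  # and the simulator leaves the caller's RNG stream untouched
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(simulate_session(m, p, noise_model(), seed = 2))
  expect_identical(stats::runif(1), before)
})

test_that("generated streams are valid, time-ordered and ground-truth aligned", {
  m <- default_task_module()
  sim <- simulate_session(m, patient_profile(), noise_model(),
                          assisted = TRUE, seed = 21)
  ts <- vapply(sim$frames, `[[`, 0, "timestamp_ms")
  expect_true(all(diff(ts) > 0))
  expect_identical(length(sim$frames), length(sim$ground_truth$timestamp_ms))
  expect_true(all(vapply(sim$ground_truth$step_id, nzchar, TRUE)))
  expect_true(all(sim$ground_truth$changes$time_s >= 0))
  # state-change log covers every step's completion
  expect_setequal(
    unique(sim$ground_truth$changes$step_id[
      sim$ground_truth$changes$what == "completion_state"]),
    vapply(m$steps, `[[`, "", "step_id"))
})

test_that("simulated total time tracks the scripted hesitation+action budget", {
  m <- default_task_module()
  prof <- participant_profile("steady", per_step_error_prob = 0,
                              hesitation_log_mean = log(2),
                              hesitation_log_sd = 0.01,
                              base_action_duration_s = 3)
  sim <- simulate_session(m, prof, zero_noise(), assisted = FALSE, seed = 9)
  rec <- run_session(m, sim$frames, assisted = FALSE)
  expect_true(all(rec$completed))
  # ~6 x (2 s hesitation + ~3 s action) plus detection/settle overhead
  expect_gt(rec$total_completion_time_s, 25)
  expect_lt(rec$total_completion_time_s, 45)
})

test_that("impaired profiles take longer than healthy ones without assistance", {
  m <- scripted_module_for_speed <- default_task_module()
  healthy <- control_profile()
  impaired <- patient_profile()
  t_h <- t_i <- numeric(8)
  for (k in 1:8) {
    sh <- simulate_session(m, healthy, zero_noise(), assisted = FALSE,
                           seed = 3000 + k)
    si <- simulate_session(m, impaired, zero_noise(), assisted = FALSE,
                           seed = 3000 + k)
    t_h[k] <- run_session(m, sh$frames, FALSE)$total_completion_time_s
    t_i[k] <- run_session(m, si$frames, FALSE)$total_completion_time_s
  }
  expect_false(anyNA(t_h))
  expect_gt(median(t_i), median(t_h))
  expect_true(all(t_i > t_h))  # separation is large at these defaults
})

test_that("error-state frequency rises with per_step_error_prob (seed grid)", {
  m <- scripted_module(2, dwell = 3L, window = 3L, with_errors = TRUE)
  mean_errs <- vapply(c(0.1, 0.5, 0.9), function(p) {
    prof <- participant_profile("err", per_step_error_prob = p,
                                hesitation_log_mean = log(1),
                                hesitation_log_sd = 0.1,
                                base_action_duration_s = 2)
    mean(vapply(1:30, function(k) {
      sim <- simulate_session(m, prof, zero_noise(), assisted = TRUE,
                              seed = 7000 + k)
      sum(run_session(m, sim$frames, TRUE)$error_count)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_errs) > 0))
})

test_that("assistance speeds up error-prone, cue-responsive participants", {
  m <- default_task_module()
  prof <- participant_profile("responsive", per_step_error_prob = 0.4,
                              hesitation_log_mean = log(8),
                              hesitation_log_sd = 0.5,
                              cue_responsiveness = c(0.9, 0.95, 1, 1, 1),
                              base_action_duration_s = 4,
                              assisted_hesitation_factor = 0.6)
  t_u <- t_a <- numeric(12)
  for (k in 1:12) {
    su <- simulate_session(m, prof, zero_noise(), assisted = FALSE,
                           seed = 9000 + k)
    sa <- simulate_session(m, prof, zero_noise(), assisted = TRUE,
                           seed = 9000 + k)
    gu <- su$ground_truth; ga <- sa$ground_truth
    t_u[k] <- utils::tail(gu$timestamp_ms, 1) / 1000
    t_a[k] <- utils::tail(ga$timestamp_ms, 1) / 1000
  }
  expect_lt(median(t_a), median(t_u))
})

test_that("label_frames pairs truth with predictions and degenerates correctly", {
  m <- default_task_module()
  clean <- simulate_session(m, perfect_profile(), zero_noise(),
                            assisted = TRUE, seed = 31)
  pairs <- label_frames(clean$ground_truth, clean$frames)
  expect_true(all(vapply(pairs, function(p)
    identical(p$predicted_classes, p$true_classes), TRUE)))

  blind <- simulate_session(m, perfect_profile(),
                            noise_model(false_negative_rate = 1,
                                        false_positive_rate = 0,
                                        confidence_jitter_sd = 0,
                                        bbox_jitter_sd = 0),
                            assisted = TRUE, seed = 31)
  bpairs <- label_frames(blind$ground_truth, blind$frames)
  expect_true(all(vapply(bpairs, function(p)
    length(p$predicted_classes) == 0, TRUE)))

  expect_error(label_frames(clean$ground_truth, clean$frames[-1]),
               "different lengths")

  # JSONL round trip
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_label_pairs(pairs[1:50], path)
  expect_equal(read_label_pairs(path), structure(pairs[1:50],
                                                 class = "label_pairs"))
})

test_that("false-positive label rate matches its binomial expectation", {
  m <- one_step_module(cls = "widget", dwell = 1L, window = 1L)
  # 10 extra vocabulary classes available for spurious detections
  m$class_vocabulary <- c(paste0("decoy_", 1:10), "widget")
  prof <- perfect_profile()
  sim <- simulate_session(m, prof,
                          noise_model(false_negative_rate = 0,
                                      false_positive_rate = 0.1,
                                      confidence_jitter_sd = 0,
                                      bbox_jitter_sd = 0),
                          assisted = FALSE, seed = 77, frame_period_ms = 10)
  pairs <- label_frames(sim$ground_truth, sim$frames)
  spurious <- vapply(pairs, function(p)
    length(setdiff(p$predicted_classes, p$true_classes)), 0)
  n_total <- length(union(task_vocabulary(m),
                          names(taskguide:::.scene_layout)))
  # per frame the spurious count is Binomial(#vocab - #true, 0.1)
  expected <- 0.1 * mean(vapply(pairs, function(p)
    n_total - length(p$true_classes), 0))
  expect_equal(mean(spurious), expected, tolerance = 0.15)
})

test_that("the paired cohort has the study layout and is seed-reproducible", {
  m <- default_task_module()
  coh <- simulate_cohort(m, n_patients = 3, n_controls = 2, seed = 19)
  expect_identical(nrow(coh), 10L)  # (3+2) participants x 2 conditions
  expect_setequal(unique(coh$group), c("patient", "control"))
  expect_true(all(table(coh$participant_id) == 2))
  coh2 <- simulate_cohort(m, n_patients = 3, n_controls = 2, seed = 19)
  expect_equal(as.data.frame(coh), as.data.frame(coh2))

  # paired sessions share participant-level effects: sex identical within id
  sex_by_id <- tapply(coh$sex, coh$participant_id,
                      function(x) length(unique(x)))
  expect_true(all(sex_by_id == 1))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, csv)
  expect_equal(as.data.frame(read_cohort(csv)), as.data.frame(coh))
})

test_that("a tiny zero-noise cohort of perfect participants scores 12 everywhere", {
  m <- default_task_module()
  coh <- simulate_cohort(m, 1, 1,
                         patient_profile_ = perfect_profile(),
                         control_profile_ = perfect_profile(),
                         noise = zero_noise(), seed = 4)
  expect_identical(nrow(coh), 4L)
  expect_true(all(coh$completion_score == 12))
  expect_true(all(coh$efpt_score == 0))
})
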
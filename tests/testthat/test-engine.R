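# Scripted streams drive the state machine through known trajectories; the
# quadratic replay interpreter in helper-oracle.R is the reference.

test_that("a perfect scripted run completes every step with positive feedback only", {
  m <- scripted_module(6, dwell = 1L, window = 1L)
  # step k's completion class appears at 10k seconds and persists
  frames <- scripted_frames(65, function(t)
    paste0("done_", seq_len(min(6, floor(t / 10)))))
  rec <- run_session(m, frames, assisted = TRUE)
  kinds <- vapply(rec$events, `[[`, "", "kind")
  expect_identical(sum(kinds == "step_completed"), 6L)
  expect_identical(sum(kinds == "positive_feedback"), 6L)
  expect_identical(sum(kinds == "error_detected"), 0L)
  expect_identical(sum(kinds == "cue_issued"), 0L)
  expect_true(all(rec$completed))
  expect_true(all(rec$max_cue_level == 0))
  expect_true(all(vapply(rec$events[kinds == "positive_feedback"],
                         `[[`, "", "detail") == "great"))
})

test_that("one error episode triggers one corrective and the step still completes", {
  m <- scripted_module(3, dwell = 1L, window = 1L, with_errors = TRUE)
  # step 2: error state from t=12..15, then correct completion at t=18
  frames <- scripted_frames(32, function(t) {
    cls <- character()
    if (t >= 5) cls <- c(cls, "done_1")
    if (t >= 12 && t < 15) cls <- c(cls, "err_2")
    if (t >= 18) cls <- c(cls, "done_2")
    if (t >= 25) cls <- c(cls, "done_3")
    cls
  })
  rec <- run_session(m, frames, assisted = TRUE)
  kinds <- vapply(rec$events, `[[`, "", "kind")
  expect_identical(sum(kinds == "error_detected"), 1L)
  expect_identical(sum(kinds == "corrective_shown"), 1L)
  expect_identical(unname(rec$error_count["step_2"]), 1L)
  expect_true(all(rec$completed))
  # identical satisfaction trace in the reference interpreter
  o <- oracle_run_session(m, frames, assisted = TRUE)
  expect_equal(events_table(rec$events), events_table(o$events))
})

test_that("a stream ending mid-task marks the remaining steps incomplete", {
  m <- scripted_module(6, dwell = 1L, window = 1L)
  frames <- scripted_frames(32, function(t)
    paste0("done_", seq_len(min(3, floor(t / 10)))))
  rec <- run_session(m, frames, assisted = TRUE)
  expect_identical(unname(rec$completed),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(rec$total_completion_time_s))
  expect_false(any(is.na(vapply(rec$step_timings[1:3], `[[`, 0, "duration_s"))))
  expect_true(all(is.na(vapply(rec$step_timings[4:6], `[[`, 0, "duration_s"))))
})

test_that("cue levels escalate in order and level 5 force-advances when assisted", {
  m <- one_step_module(dwell = 1L, window = 1L, timeouts = c(1, 2, 3, 4, 5))
  frames <- scripted_frames(8, function(t) character())  # nothing ever happens
  rec <- run_session(m, frames, assisted = TRUE)
  cues <- Filter(function(e) e$kind == "cue_issued", rec$events)
  expect_identical(vapply(cues, `[[`, 0L, "cue_level"), 1:5)
  expect_true(rec$completed[["only_step"]])
  expect_true(rec$assessor_performed[["only_step"]])
  expect_identical(unname(rec$max_cue_level), 5L)

  # unassisted: same milestones tracked silently, no events, no force-advance
  rec_u <- run_session(m, frames, assisted = FALSE)
  kinds_u <- vapply(rec_u$events, `[[`, "", "kind")
  expect_false(any(kinds_u %in% c("cue_issued", "positive_feedback",
                                  "corrective_shown")))
  expect_identical(unname(rec_u$max_cue_level), 5L)
  expect_false(rec_u$completed[["only_step"]])
})

test_that("assisted and unassisted modes agree on completion times; only feedback differs", {
  set.seed(404)
  for (rep in 1:10) {
    m <- random_module()
    frames <- random_frames(sample(80:300, 1), paste0("obj_", 1:5),
                            p_present = stats::runif(1, 0.3, 0.8))
    # strip level-5 cues so assisted mode cannot force-advance
    m$steps <- lapply(m$steps, function(s) {
      s$cue_schedule <- s$cue_schedule[s$cue_schedule$level < 5, ]
      s
    })
    ra <- run_session(m, frames, assisted = TRUE)
    ru <- run_session(m, frames, assisted = FALSE)
    expect_identical(ra$completed, ru$completed)
    expect_identical(ra$error_count, ru$error_count)
    expect_identical(ra$max_cue_level, ru$max_cue_level)
    expect_equal(ra$step_timings, ru$step_timings)
    ka <- vapply(ra$events, `[[`, "", "kind")
    ku <- vapply(ru$events, `[[`, "", "kind")
    drop <- c("cue_issued", "positive_feedback", "corrective_shown")
    expect_identical(events_table(ra$events[!ka %in% drop]),
                     events_table(ru$events[!ku %in% drop]))
  }
})

test_that("runs are deterministic and step completions are ordered", {
  set.seed(99)
  m <- random_module()
  frames <- random_frames(150, paste0("obj_", 1:5))
  r1 <- run_session(m, frames, assisted = TRUE)
  r2 <- run_session(m, frames, assisted = TRUE)
  expect_identical(r1, r2)
  done <- Filter(function(e) e$kind == "step_completed", r1$events)
  idx <- match(vapply(done, `[[`, "", "step_id"),
               vapply(m$steps, `[[`, "", "step_id"))
  expect_true(all(diff(idx) > 0))
})

test_that("the engine matches the naive replay interpreter on random streams", {
  set.seed(515)
  for (rep in 1:60) {
    m <- random_module()
    frames <- random_frames(sample(30:250, 1), paste0("obj_", 1:5),
                            p_present = stats::runif(1, 0.2, 0.9))
    assisted <- rep %% 2 == 0
    rec <- run_session(m, frames, assisted = assisted)
    o <- oracle_run_session(m, frames, assisted = assisted)
    expect_equal(events_table(rec$events), events_table(o$events))
    expect_identical(rec$completed, o$completed)
    expect_identical(rec$max_cue_level, o$max_cue_level)
    expect_identical(rec$error_count, o$error_count)
    expect_equal(rec$total_completion_time_s, o$total)
  }
})

test_that("timings: initiation from first hand frame, durations and totals in seconds", {
  # instruction at t=0, hand first at t=1.5 s, completion state at t=9 s
  m <- one_step_module(dwell = 1L, window = 1L)
  frames <- scripted_frames(10, function(t) if (t >= 9) "widget" else character(),
                            hand_at = function(t) t >= 1.5)
  rec <- run_session(m, frames, assisted = TRUE)
  tm <- compute_timings(rec)
  expect_equal(tm$initiation_s, 1.5)
  expect_equal(tm$duration_s, 9.0)

  # six back-to-back steps with durations 10,15,20,15,20,12 -> total 92 s
  m6 <- scripted_module(6, dwell = 1L, window = 1L)
  ends <- cumsum(c(10, 15, 20, 15, 20, 12))
  frames6 <- scripted_frames(95, function(t)
    paste0("done_", which(ends <= t + 1e-9)))
  rec6 <- run_session(m6, frames6, assisted = TRUE)
  expect_true(all(rec6$completed))
  expect_equal(rec6$total_completion_time_s, 92)
  expect_equal(compute_timings(rec6)$duration_s, c(10, 15, 20, 15, 20, 12))

  # hand present from frame 0 with instruction at frame 0 -> initiation 0
  frames0 <- scripted_frames(3, function(t) if (t >= 1) "widget" else character(),
                             hand_at = function(t) TRUE)
  rec0 <- run_session(m, frames0, assisted = TRUE)
  expect_equal(compute_timings(rec0)$initiation_s, 0)

  # no hand ever seen -> initiation missing, not zero
  frames_nh <- scripted_frames(3, function(t) if (t >= 1) "widget" else character(),
                               hand_at = function(t) FALSE)
  rec_nh <- run_session(m, frames_nh, assisted = TRUE)
  expect_true(is.na(compute_timings(rec_nh)$initiation_s))
})

test_that("session records and event logs survive serialization", {
  m <- scripted_module(2, dwell = 1L, window = 1L)
  frames <- scripted_frames(25, function(t)
    paste0("done_", seq_len(min(2, floor(t / 10)))))
  rec <- run_session(m, frames, assisted = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_session_record(rec, path)
  rec2 <- read_session_record(path)
  expect_equal(events_table(rec2$events), events_table(rec$events))
  expect_identical(rec2$max_cue_level, rec$max_cue_level)
  expect_equal(rec2$step_timings, rec$step_timings)
  expect_equal(rec2$total_completion_time_s, rec$total_completion_time_s)

  ev_path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_events(rec, ev_path)
  expect_length(readLines(ev_path), length(rec$events))

  summ <- session_summary(rec)
  expect_identical(nrow(summ), 3L)  # 2 steps + totals row
  expect_identical(summ$step_id[3], "total")
})
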
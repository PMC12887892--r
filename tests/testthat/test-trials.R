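# Stimulus scheduling, metric arithmetic, trial segmentation and session
# summaries.

test_that("a default schedule is 16 balanced scenarios lasting 80 s", {
  log <- schedule_session(seed = 1)
  expect_equal(nrow(log$scenarios), 16L)
  expect_equal(sum(log$scenarios$type == "offensive"), 8L)
  expect_equal(sum(log$scenarios$type == "defensive"), 8L)
  expect_equal(session_duration_s(log), 80)
  expect_true(all(diff(log$scenarios$onset_time_s) > 0))
  # distinct (type, zone) combinations
  expect_false(anyDuplicated(log$scenarios[, c("type", "target_zone")]) > 0)
})

test_that("scheduling is seed-deterministic and balanced across seeds", {
  expect_identical(schedule_session(42), schedule_session(42))
  expect_false(identical(schedule_session(1)$scenarios$target_zone,
                         schedule_session(2)$scenarios$target_zone))
  for (seed in 1:200) {
    tab <- table(schedule_session(seed)$scenarios$type)
    expect_equal(as.integer(tab[c("offensive", "defensive")]), c(8L, 8L))
  }
  expect_error(schedule_session(1, n_scenarios = 15), "even")
})

test_that("stimulus schedules survive a JSON round trip", {
  log <- schedule_session(seed = 8)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_stimuli_json(log, path)
  back <- read_stimuli_json(path)
  expect_equal(back$fps, log$fps)
  expect_equal(back$scenarios$target_zone, log$scenarios$target_zone)
  expect_equal(back$scenarios$onset_time_s, log$scenarios$onset_time_s)
})

test_that("frame-to-seconds metric arithmetic matches hand values", {
  expect_equal(compute_vmrs(100, 124, 30), 0.8)
  expect_equal(round(compute_vmrs(100, 104, 30), 3), 0.133)
  expect_equal(compute_vmrs(100, 100, 30), 0)
  expect_error(compute_vmrs(100, 90, 30), "precede")

  expect_equal(compute_ds(124, 148, 30), 0.8)
  expect_equal(round(compute_ds(100, 101.6, 30), 3), 0.053)
  expect_equal(compute_ds(50, 50, 30), 0)
  expect_error(compute_ds(50, 40, 30), "precede")

  expect_equal(compute_rc(16, 16), 100)
  expect_equal(compute_rc(15, 16), 93.75)
  expect_equal(compute_rc(0, 16), 0)
  expect_error(compute_rc(1, 0), "undefined")
  expect_error(compute_rc(17, 16), "n_correct")

  expect_equal(compute_cms(0.8, 0.7), 1.5)
  expect_equal(compute_cms(0, 0), 0)
  expect_equal(compute_cms(0.77, 0.76), 1.53)
})

# hand-built trial ingredients: three scenarios with known events
segmentation_fixture <- function() {
  log <- schedule_session(seed = 3, n_scenarios = 4L)
  zs <- square_zone_set()
  sf <- round(log$scenarios$onset_time_s * log$fps)
  tz <- log$scenarios$target_zone
  mk <- function(zone, frame) {
    e <- mk_event(zs$polygons[[zone]], frame = as.integer(frame))
    e$zone <- zone
    e
  }
  wrong1 <- setdiff(paste0("P", 1:8), tz[2])[1]
  events <- list(
    mk(tz[1], sf[1] + 50),   # correct arrival for scenario 1
    mk(wrong1, sf[2] + 45),  # wrong zone for scenario 2
    mk(tz[4], sf[4] + 200)   # after scenario 4's window: no response
  )
  onsets <- list(
    list(onset_frame = sf[1] + 24L, foot = "right", flag = NA_character_),
    list(onset_frame = sf[2] + 20L, foot = "right", flag = NA_character_),
    list(onset_frame = NA_integer_, foot = NA_character_, flag = NA_character_),
    list(onset_frame = sf[4] + 30L, foot = "left", flag = NA_character_)
  )
  list(log = log, events = events, onsets = onsets, sf = sf)
}

test_that("trials classify as correct / incorrect / no_response", {
  fx <- segmentation_fixture()
  tr <- segment_trials(fx$log, fx$events, fx$onsets)
  expect_equal(tr$outcome, c("correct", "incorrect", "no_response", "no_response"))
  expect_equal(tr$vmrs_s[1], 24 / 30)
  expect_equal(tr$ds_s[1], (50 - 24) / 30)
  expect_true(is.na(tr$vmrs_s[3]) && is.na(tr$ds_s[3]))
  # outcome is a total function over trials
  expect_true(all(tr$outcome %in% c("correct", "incorrect", "no_response")))
  expect_error(segment_trials(fx$log, fx$events, fx$onsets, fps = 25),
               "synchronization")
})

test_that("session summaries aggregate the four metrics", {
  fx <- segmentation_fixture()
  tr <- segment_trials(fx$log, fx$events, fx$onsets)
  m <- summarize_session(tr, athlete_id = "a1")
  expect_equal(m$rc_percent, 25)
  expect_equal(m$cms_s, m$mean_vmrs_s + m$mean_ds_s)

  # constant 16-trial session: 0.8 / 0.7 / 100 / 1.5
  const <- data.frame(outcome = rep("correct", 16),
                      vmrs_s = rep(0.8, 16), ds_s = rep(0.7, 16))
  mc <- summarize_session(const)
  expect_equal(as.numeric(mc[, c("mean_vmrs_s", "mean_ds_s", "rc_percent", "cms_s")]),
               c(0.8, 0.7, 100, 1.5))

  # 15 correct + 1 no response -> 93.75%, means over the 15 defined trials
  mixed <- data.frame(outcome = c(rep("correct", 15), "no_response"),
                      vmrs_s = c(rep(0.8, 15), NA), ds_s = c(rep(0.7, 15), NA))
  expect_equal(summarize_session(mixed)$rc_percent, 93.75)
  expect_equal(summarize_session(mixed)$mean_vmrs_s, 0.8)

  expect_error(summarize_session(const[0, ]), "without trials")
  # all no-response: time metrics undefined but RC still reported
  nr <- data.frame(outcome = rep("no_response", 4),
                   vmrs_s = NA_real_, ds_s = NA_real_)
  mnr <- summarize_session(nr)
  expect_true(is.na(mnr$cms_s))
  expect_equal(mnr$rc_percent, 0)
})

test_that("metrics tables survive a CSV round trip", {
  m <- data.frame(athlete_id = c("a", "b"), n_trials = c(16L, 16L),
                  mean_vmrs_s = c(0.77, 0.96), mean_ds_s = c(0.76, 0.64),
                  rc_percent = c(100, 93.75), cms_s = c(1.53, 1.6))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_metrics_csv(m, path)
  expect_equal(read_metrics_csv(path), m)
})
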
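test_that("identical config and seed reproduce the experiment bit for bit", {
  cfg <- small_config()
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$sessions[[1]]$F, e2$sessions[[1]]$F)
  expect_identical(e1$sessions[[2]]$motion, e2$sessions[[2]]$motion)
  expect_equal(e1$ground_truth$spines, e2$ground_truth$spines)
  expect_equal(e1$ground_truth$releases, e2$ground_truth$releases)
  e3 <- generate_experiment(small_config(seed = 12L))
  expect_false(identical(e1$sessions[[1]]$F, e3$sessions[[1]]$F))
})

test_that("configuration rejects invalid protocol parameters", {
  expect_error(experiment_config(pulse_duration = -0.01), "pulse_duration")
  expect_error(experiment_config(fraction_connected = 1.2), "fraction_connected")
  expect_error(experiment_config(n_sessions = 1), "n_sessions")
  expect_error(experiment_config(category_probs = c(0.5, 0.5, 0.5, 0.5)),
               "category_probs")
})

test_that("dendritic-event and release rates match their configured values", {
  cfg <- experiment_config(n_spines = 1, n_sessions = 5,
                           n_trials_per_session = 400,
                           fraction_connected = 1, generate_images = FALSE,
                           seed = 21L)
  e <- generate_experiment(cfg)
  ev <- e$ground_truth$events
  n <- nrow(ev)
  expect_gte(n, 2000)
  se <- sqrt(cfg$dendritic_event_rate * (1 - cfg$dendritic_event_rate) / n)
  expect_lt(abs(mean(ev$dendritic_event) - cfg$dendritic_event_rate), 3 * se)

  rel <- e$ground_truth$releases
  p <- cfg$release_probability
  ci <- qbinom(c(0.0025, 0.9975), nrow(rel), p) / nrow(rel)
  expect_gte(mean(rel$success), ci[1])
  expect_lte(mean(rel$success), ci[2])
})

test_that("presence schedules honour their category and round-trip exactly", {
  all_there <- generate_presence_schedules(20, 5, c(1, 0, 0, 0), seed = 3)
  expect_true(all(all_there$presence$present))

  formed <- generate_presence_schedules(50, 5, c(0, 0, 1, 0), seed = 4)
  m <- matrix(formed$presence$present[order(formed$presence$spine_id,
                                            formed$presence$session)],
              ncol = 5, byrow = TRUE)
  expect_true(all(!m[, 1]))          # every schedule starts absent
  expect_true(all(m[, 5]))           # and ends present
  for (i in seq_len(nrow(m))) {      # no gap after onset
    first <- which(m[i, ])[1]
    expect_true(all(m[i, first:5]))
  }

  big <- generate_presence_schedules(5000, 5, seed = 5)
  got <- classify_spine_dynamics(big$presence)
  truth <- big$categories[match(got$spine_id, big$categories$spine_id), ]
  expect_identical(as.character(got$category), truth$category)
})

test_that("ground truth survives a JSON write/read round trip", {
  e <- generate_experiment(small_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(e$ground_truth, path)
  back <- read_ground_truth(path)
  norm <- function(d) as.data.frame(lapply(d, function(col)
    if (is.numeric(col)) as.numeric(col) else col))
  for (tbl in c("spines", "presence", "categories", "events", "releases")) {
    expect_equal(norm(back[[tbl]]), norm(e$ground_truth[[tbl]]), info = tbl)
  }
})

test_that("tidy trace export matches the internal matrices and CSV round-trips", {
  e <- generate_experiment(small_config())
  tr <- experiment_traces(e, sessions = 1)
  one <- tr[tr$roi_id == "spine_001", ]
  expect_equal(one$fluorescence, unname(e$sessions[[1]]$F[, "spine_001"]))
  expect_equal(nrow(tr), nrow(e$sessions[[1]]$F) * ncol(e$sessions[[1]]$F))

  dir <- withr::local_tempdir()
  write_experiment(e, dir)
  back <- read_traces_csv(file.path(dir, "traces.csv"))
  expect_equal(back$fluorescence, experiment_traces(e)$fluorescence)
  expect_identical(back$motion_flag, experiment_traces(e)$motion_flag)
  trials <- read_trials_csv(file.path(dir, "trials.csv"))
  expect_equal(trials$onset_frame[trials$session == 1], e$sessions[[1]]$onset_frames)
})

test_that("volume images yield zero, monotone and scale-invariant estimates", {
  blank <- generate_volume_image(0, seed = 1, noise = FALSE)
  expect_warning(v0 <- estimate_volume(blank), "volume 0")
  expect_equal(v0$volume, 0)

  vols <- seq(0.3, 4, length.out = 50)
  est <- vapply(seq_along(vols), function(i) {
    estimate_volume(generate_volume_image(vols[i], seed = 100 + i))$volume
  }, numeric(1))
  expect_gte(cor(vols, est, method = "spearman"), 0.9)

  img <- generate_volume_image(1.5, seed = 9)
  scaled <- img
  scaled$intensity <- img$intensity * 7
  expect_equal(estimate_volume(scaled)$volume, estimate_volume(img)$volume)
})
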
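test_that("the null model is constant at baseline with no events", {
  m <- episode_model(n_seconds = 60, episodes = list(), noise_sd = 0)
  g <- generate_recording(m)
  expect_equal(g$events$n_e, 0L)
  s <- regularize(g$recording)
  for (f in s$names)
    expect_equal(as.numeric(s$values[, f]),
                 rep(unname(m$baseline[f]), s$n))
})

test_that("an episode plateau sits at baseline plus the state difference", {
  m <- episode_model(n_seconds = 300, episodes = list(c(100, 160)),
                     expression_gain = 1, noise_sd = 0)
  g <- generate_recording(m)
  s <- regularize(g$recording)
  tt <- series_times(s)
  plateau <- tt >= 102 & tt <= 160
  expect_equal(unique(s$values[plateau, "h9"]), 0.8199 + 0.0715)
  expect_equal(unique(s$values[plateau, "a4"]), 1.0431 - 0.0614)
  expect_equal(unique(s$values[plateau, "a1"]), 0.4270 - 0.0289)
  expect_equal(unique(s$values[plateau, "a3"]), 0.0901 - 0.0398)
  # outside episodes the features are at baseline; the ramp is linear
  expect_equal(as.numeric(s$values[tt == 50, "h9"]), 0.8199)
  expect_equal(as.numeric(s$values[tt == 101, "h9"]), 0.8199 + 0.0715 / 2)
  expect_equal(g$events$events$time, c(100, 160))
  expect_equal(g$events$events$polarity, c("happy_onset", "happy_offset"))
  # attenuation scales the excursion, not the baseline
  g2 <- generate_recording(episode_model(n_seconds = 300,
                                         episodes = list(c(100, 160)),
                                         expression_gain = 0.1, noise_sd = 0))
  s2 <- regularize(g2$recording)
  expect_equal(unique(s2$values[plateau, "h9"]), 0.8199 + 0.1 * 0.0715)
})

test_that("generation is reproducible from the seed", {
  mk <- function(seed) episode_model(n_seconds = 120, episodes = list(c(30, 60)),
                                     seed = seed)
  g1 <- generate_recording(mk(42))
  g2 <- generate_recording(mk(42))
  g3 <- generate_recording(mk(43))
  expect_identical(g1$recording$records, g2$recording$records)
  expect_false(identical(g1$recording$records$value,
                         g3$recording$records$value))
})

test_that("model validation rejects impossible configurations", {
  expect_error(episode_model(episodes = list(c(100, 300), c(250, 400))),
               class = "facepoi_config_error")
  expect_error(episode_model(episodes = list(c(200, 100))),
               class = "facepoi_config_error")
  expect_error(episode_model(expression_gain = 0), class = "facepoi_config_error")
  expect_error(episode_model(episodes = list(c(1100, 1300))),
               class = "facepoi_config_error")
})

test_that("sparse frame intervals emit fewer raw samples that pad back to 1 Hz", {
  m <- episode_model(n_seconds = 90, episodes = list(), noise_sd = 0,
                     frame_interval = 3)
  g <- generate_recording(m)
  expect_equal(sum(g$recording$records$feature == "h9"), 30L)
  s <- regularize(g$recording, step = 1)
  expect_equal(s$n, 88L)  # floor((87 - 0)/1) + 1
})

test_that("score test vectors are the documented fixtures", {
  expect_equal(score_testvector("constant", length = 10, value = 3), rep(3, 10))
  expect_equal(score_testvector("step", length = 10, pre = 0, post = 5,
                                change_at = 5),
               c(rep(0, 5), rep(5, 5)))
  expect_equal(score_testvector("two_excursions"), c(0, 3, 0, 0, 5, 6, 0))
})

test_that("detection quality degrades when expressions become micro", {
  # the standardization step and the adaptive variance make the change score
  # nearly amplitude-invariant, so attenuating the expression mainly floods
  # the candidate list with noise-driven excursions: the degradation shows
  # up as lost precision, not as lost recall
  run_gain <- function(gain, seed) {
    m <- episode_model(expression_gain = gain, seed = seed)
    g <- generate_recording(m)
    run_pipeline(run_config(g$recording, events = g$events))$report$precision
  }
  seeds <- 1:20
  full <- vapply(seeds, function(s) run_gain(1, s), numeric(1))
  micro <- vapply(seeds, function(s) run_gain(0.1, s), numeric(1))
  expect_lte(mean(micro), mean(full))
})
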
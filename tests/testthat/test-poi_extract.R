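mk_scores <- function(values, burn_in = 0, start = 0, step = 1) {
  change_score_series(times = start + (seq_along(values) - 1) * step,
                      scores = values, burn_in = burn_in)
}

test_that("gamma is the post-burn-in mean plus one (or n) sd", {
  s <- mk_scores(c(0, 0, 2, 2))
  pol0 <- threshold_policy(burn_in = 0)
  expect_equal(compute_threshold(s, pol0), 2)  # mean 1 + population sd 1
  expect_equal(compute_threshold(s, threshold_policy("raw_mean_nsd", n_sigma = 2,
                                                     burn_in = 0)), 3)
  const <- mk_scores(rep(4, 50), burn_in = 10)
  expect_equal(compute_threshold(const, threshold_policy(burn_in = 10)), 4)
  short <- mk_scores(rep(1, 20), burn_in = 30)
  expect_error(compute_threshold(short, threshold_policy(burn_in = 30)),
               class = "facepoi_insufficient_error")
  # burn-in and flagged samples are excluded from the statistics
  s2 <- mk_scores(c(100, 0, 0, 2, 2), burn_in = 1)
  expect_equal(compute_threshold(s2, threshold_policy(burn_in = 1)),
               mean(c(0, 0, 2, 2)) + 1)
})

test_that("each excursion contributes exactly one candidate at its argmax", {
  p <- extract_poi(mk_scores(c(0, 0, 3, 4, 3, 0, 0)), gamma = 2)
  expect_equal(p$n_p, 1L)
  expect_equal(p$n_o, 3L)
  expect_equal(p$candidates$time, 3)            # index of the 4 (0-based times)
  expect_equal(p$candidates$score, 4)
  expect_equal(p$candidates$excursion_start, 2)
  expect_equal(p$candidates$excursion_end, 5)

  none <- extract_poi(mk_scores(c(1, 1, 1)), gamma = 2)
  expect_equal(none$n_p, 0L)
  expect_equal(none$n_o, 0L)

  two <- extract_poi(mk_scores(score_testvector("two_excursions")), gamma = 2)
  expect_equal(two$candidates$time, c(1, 5))    # the 3 and the 6
  expect_equal(two$n_o, 3L)

  # excursion still open at the end of the series still yields its candidate
  open <- extract_poi(mk_scores(c(0, 0, 3, 5)), gamma = 2)
  expect_equal(open$candidates$time, 3)
  expect_equal(open$candidates$excursion_end, 4)

  # tie inside an excursion: the earliest maximum wins
  tie <- extract_poi(mk_scores(c(0, 4, 4, 0)), gamma = 2)
  expect_equal(tie$candidates$time, 1)
})

test_that("extraction matches the brute-force run enumeration", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(5:400, 1)
    # rounding forces ties; occasional high tail ends the series above gamma
    sc <- round(rnorm(n, sd = 2), 1)
    gamma <- round(stats::quantile(sc, probs = runif(1, 0.5, 0.95)), 1)
    got <- extract_poi(mk_scores(sc), gamma = gamma)
    want <- oracle_extract_poi(sc, gamma)
    expect_equal(got$candidates$time, want$idx - 1)  # times are 0-based
    expect_equal(got$n_o, want$n_o)
    # structural invariants
    expect_true(all(diff(got$candidates$time) > 0))
    expect_lte(got$n_p, got$n_o)
    expect_true(all(got$candidates$score > gamma))
  }
})

test_that("raising gamma never finds more exceedance samples or candidates", {
  set.seed(19)
  sc <- round(rnorm(300), 1)
  gammas <- sort(runif(6, -2, 2))
  res <- lapply(gammas, function(g) extract_poi(mk_scores(sc), gamma = g))
  n_o <- vapply(res, `[[`, integer(1), "n_o")
  expect_true(all(diff(n_o) <= 0))
  n_p <- vapply(res, function(r) r$n_p, integer(1))
  # n_p monotonicity verified against brute force at each level
  for (i in seq_along(gammas))
    expect_equal(n_p[i], length(oracle_extract_poi(sc, gammas[i])$idx))
})

test_that("the burn-in window never produces candidates", {
  sc <- c(rep(10, 30), rep(0, 60), 5, 0, 0)
  s <- mk_scores(sc, burn_in = 30)
  p <- extract_poi(s, gamma = 2)
  expect_true(all(p$candidates$time >= 30))
  expect_equal(p$candidates$time, 90)
  expect_equal(p$n, 63L)  # ratios use the post-burn-in sample count
})

test_that("the raw-value baseline applies the same excursion rule", {
  p <- raw_threshold_baseline(c(0, 0, 4, 0), n_sigma = 0, burn_in = 0)
  expect_equal(p$gamma, 1)           # the mean
  expect_equal(p$candidates$time, 2)
  # constant series: sd 0, no strict exceedance
  expect_equal(raw_threshold_baseline(rep(5, 40), n_sigma = 1, burn_in = 0)$n_p, 0L)
  expect_equal(raw_threshold_baseline(rep(5, 40), n_sigma = 0, burn_in = 0)$n_p, 0L)
  # candidate count is non-increasing in the multiplier
  set.seed(23)
  x <- rnorm(500)
  np <- vapply(c(0, 0.5, 1, 2), function(ns)
    raw_threshold_baseline(x, ns, burn_in = 0)$n_p, integer(1))
  expect_true(all(diff(np) <= 0))
})
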
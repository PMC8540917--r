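test_that("parameter defaults follow the study settings", {
  p <- changefinder_params()
  expect_equal(p$order, 1L)
  expect_equal(p$discount, 0.025)
  expect_equal(p$smooth_width, 5L)
  expect_equal(p$second_width, 2L)  # round-half-even of 5/2
  expect_equal(changefinder_params(smooth_width = 7)$second_width, 4L)
  expect_error(changefinder_params(discount = 1), class = "facepoi_config_error")
  expect_error(changefinder_params(order = 0), class = "facepoi_config_error")
})

test_that("one-step prediction evaluates the AR form on the history", {
  st <- sdar_new(1, 0.025)
  st$mean <- 5; st$coefficients <- 0; st$history <- 7
  expect_equal(sdar_predict(st)$predicted, 5)      # zero coefficient -> mean
  st$mean <- 0; st$coefficients <- 1; st$history <- 3
  expect_equal(sdar_predict(st)$predicted, 3)
  st2 <- sdar_new(2, 0.025)
  st2$mean <- 0; st2$coefficients <- c(0.5, 0.25); st2$history <- c(2, 4)
  expect_equal(sdar_predict(st2)$predicted, 2)     # 0.5*2 + 0.25*4
  expect_error(sdar_predict(sdar_new(1, 0.025)),
               class = "facepoi_insufficient_error")
})

test_that("the discounted mean update is exact and constants are a fixed point", {
  st <- sdar_new(1, 0.025)
  st <- sdar_update(st, 0)   # seeds the mean at the first observation
  st <- sdar_update(st, 1)
  expect_identical(st$mean, (1 - 0.025) * 0 + 0.025 * 1)

  # discount conservation on a random stream, exact equality
  set.seed(3)
  st <- sdar_new(1, 0.1)
  for (x in rnorm(50)) {
    mu_before <- if (st$t == 0L) x else st$mean
    st <- sdar_update(st, x)
    expect_identical(st$mean, (1 - 0.1) * mu_before + 0.1 * x)
  }

  # constant input: mean pinned, zero residuals, zero variance
  st <- sdar_new(1, 0.025)
  for (i in 1:20) st <- sdar_update(st, 4)
  expect_equal(st$mean, 4)
  expect_equal(st$variance, 0)
})

test_that("a six-step SDAR trajectory matches the hand-derived recurrences", {
  # k = 1, r = 0.5, input 0,1,0,1,0,1, worked through the update equations
  # by hand with exact fractions
  st <- sdar_new(1, 0.5)
  for (v in c(0, 1, 0, 1, 0, 1)) st <- sdar_update(st, v)
  expect_equal(st$mean, 21 / 32, tolerance = 1e-12)
  expect_equal(st$autocov[1], 0.11279296875, tolerance = 1e-12)
  expect_equal(st$autocov[2], -0.21533203125, tolerance = 1e-12)
  expect_equal(st$coefficients, -21 / 11, tolerance = 1e-12)
  expect_equal(st$variance, 13 / 288 + 1 / 242, tolerance = 1e-12)
})

test_that("Yule-Walker solutions match closed forms and explicit inversion", {
  expect_equal(solve_yule_walker(c(2, 1), 1)$coefficients, 0.5)
  deg <- solve_yule_walker(c(0, 0), 1)
  expect_true(deg$singular)
  expect_equal(deg$coefficients, 0)
  # k = 2 against an explicit 2x2 inversion
  C <- c(1, 0.5, 0.25)
  M <- rbind(c(C[1], C[2]), c(C[2], C[1]))
  expect_equal(solve_yule_walker(C, 2)$coefficients,
               as.numeric(solve(M) %*% C[2:3]), tolerance = 1e-12)
})

test_that("log loss evaluates the Gaussian negative log density", {
  expect_equal(log_loss(0, 0, 1 / (2 * pi)), 0)
  expect_equal(log_loss(0, 0, 1), 0.5 * log(2 * pi))
  expect_equal(log_loss(1, 0, 1), 0.5 * log(2 * pi) + 0.5)
  # the floor keeps zero-variance scores finite
  expect_true(is.finite(log_loss(1, 0, 0)))
  expect_error(log_loss(1, 0, -1), class = "facepoi_config_error")
})

test_that("causal smoothing averages the trailing window with a prefix rule", {
  expect_equal(causal_smooth(rep(1, 5), 5), rep(1, 5))
  expect_equal(causal_smooth(c(0, 0, 0, 0, 5), 5)[5], 1)
  expect_equal(causal_smooth(c(1, 2, 3), 2), c(1, 1.5, 2.5))
  expect_equal(causal_smooth(numeric(0), 3), numeric(0))
})

test_that("two-stage scores match the literal batch transcription oracle", {
  set.seed(11)
  x <- c(rnorm(40), rnorm(40, 3))
  got <- change_score(x)$scores
  expect_equal(got, oracle_change_score(x), tolerance = 1e-9)
  # a second-order model exercises the full Toeplitz solve
  x2 <- as.numeric(stats::filter(rnorm(80), c(0.6, -0.3), method = "recursive"))
  p2 <- changefinder_params(order = 2, discount = 0.05, smooth_width = 4)
  expect_equal(change_score(x2, p2)$scores,
               oracle_change_score(x2, k = 2, r = 0.05, w = 4, w2 = 2),
               tolerance = 1e-9)
})

test_that("constant input yields flat (flagged) scores", {
  s <- change_score(rep(3, 100))
  expect_true(all(s$flagged))
  post <- s$scores[31:100]
  expect_lt(max(post) - min(post), 1e-6)
})

test_that("a large mean shift is located to within seconds", {
  set.seed(123)
  x <- c(rnorm(600), rnorm(300, mean = 8))
  s <- change_score(x)
  post <- which(s$times >= 30)
  peak_t <- s$times[post][which.max(s$scores[post])]
  expect_gte(peak_t, 600)
  expect_lte(peak_t, 615)
  # peak after the change strictly exceeds everything before it
  pre_max <- max(s$scores[s$times >= 30 & s$times < 600])
  expect_gt(max(s$scores[s$times >= 600]), pre_max)
})

test_that("scores are shift-equivariant and change location is scale-free", {
  set.seed(21)
  x <- c(rnorm(150), rnorm(100, 4))
  base <- change_score(x)
  m <- 7L
  padded <- change_score(c(rep(x[1], m), x))
  # a constant pad leaves the learner at its fixed point, so the detected
  # change location shifts by exactly m positions (score values near the
  # start differ slightly through the smoothing prefix, and the discounted
  # learner remembers that difference with geometrically decaying weight)
  # compare beyond the startup transient (which the pad also shifts)
  post_b <- which(base$times >= 60)
  post_p <- which(padded$times >= 60 + m)
  expect_equal(post_p[which.max(padded$scores[post_p])],
               post_b[which.max(base$scores[post_b])] + m)

  s1 <- change_score(x)
  s10 <- change_score(10 * x)
  post <- which(s1$times >= 30)
  expect_equal(which.max(s1$scores[post]), which.max(s10$scores[post]))
})
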
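# Independent oracles, written as literal batch transcriptions of the
# published recurrences and as brute-force enumerations. They share the
# package's documented conventions (mean seeded with the first observation,
# zero-initialized covariances, scoring gated until the residual variance is
# positive, prefix-mean smoothing) but none of its code paths: plain loops,
# no incremental state objects, explicit window means.

# one SDAR learning round over the whole vector, two passes (scores then
# smoothing), k x k Yule-Walker solved by explicit Toeplitz construction
oracle_stage <- function(x, k, r, w, floor = 1e-12) {
  n <- length(x)
  y <- numeric(n)
  mu <- x[1]
  C <- rep(0, k + 1)
  a <- rep(0, k)
  sigma <- 0
  for (t in seq_len(n)) {
    if (t > k && sigma > 0) {
      xhat <- mu + sum(a * (x[t - seq_len(k)] - mu))
      v <- max(sigma, floor)
      y[t] <- 0.5 * log(2 * pi * v) + (x[t] - xhat)^2 / (2 * v)
    }
    # prediction from the pre-update model, for the variance recurrence
    xhat_pre <- if (t > k) mu + sum(a * (x[t - seq_len(k)] - mu)) else mu
    mu <- (1 - r) * mu + r * x[t]
    C[1] <- (1 - r) * C[1] + r * (x[t] - mu)^2
    for (i in seq_len(min(k, t - 1))) {
      C[i + 1] <- (1 - r) * C[i + 1] + r * (x[t] - mu) * (x[t - i] - mu)
    }
    M <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) M[i, j] <- C[abs(i - j) + 1]
    a_new <- tryCatch(solve(M, C[2:(k + 1)]), error = function(e) NULL)
    a <- if (is.null(a_new) || any(!is.finite(a_new))) rep(0, k) else as.numeric(a_new)
    sigma <- (1 - r) * sigma + r * (x[t] - xhat_pre)^2
  }
  # causal moving average with explicit window means
  sm <- numeric(n)
  for (t in seq_len(n)) sm[t] <- mean(y[seq(max(1, t - w + 1), t)])
  sm
}

# full two-stage change score; returns scores with the leading unscorable
# prefix zeroed, mirroring the documented flagging convention
oracle_change_score <- function(x, k = 1, r = 0.025, w = 5,
                                w2 = max(1, round(w / 2))) {
  s1 <- oracle_stage(x, k, r, w)
  s2 <- oracle_stage(s1, k, r, w2)
  # a stage scores sample t once t > k and some earlier residual was nonzero;
  # recompute the scored prefixes literally
  scored_from <- function(z, k) {
    n <- length(z)
    mu <- z[1]; sigma <- 0; a <- 0; first <- n + 1
    C <- rep(0, k + 1)
    for (t in seq_len(n)) {
      if (t > k && sigma > 0 && first > n) { first <- t; break }
      xhat_pre <- if (t > k) mu + sum(a * (z[t - seq_len(k)] - mu)) else mu
      mu_new <- (1 - r) * mu + r * z[t]
      sigma <- (1 - r) * sigma + r * (z[t] - xhat_pre)^2
      C[1] <- (1 - r) * C[1] + r * (z[t] - mu_new)^2
      for (i in seq_len(min(k, t - 1)))
        C[i + 1] <- (1 - r) * C[i + 1] + r * (z[t] - mu_new) * (z[t - i] - mu_new)
      M <- matrix(0, k, k)
      for (i in seq_len(k)) for (j in seq_len(k)) M[i, j] <- C[abs(i - j) + 1]
      a_new <- tryCatch(solve(M, C[2:(k + 1)]), error = function(e) NULL)
      a <- if (is.null(a_new) || any(!is.finite(a_new))) rep(0, k) else as.numeric(a_new)
      mu <- mu_new
    }
    first
  }
  f1 <- scored_from(x, k)
  f2 <- scored_from(s1, k)
  flag_until <- max(f1, f2) - 1
  if (flag_until >= 1) s2[seq_len(min(length(s2), flag_until))] <- 0
  s2
}

# brute-force excursion enumeration: maximal runs of score > gamma, one
# candidate per run at the earliest argmax
oracle_extract_poi <- function(score, gamma) {
  times <- numeric(0)
  n_o <- 0L
  i <- 1L
  n <- length(score)
  while (i <= n) {
    if (score[i] > gamma) {
      j <- i
      while (j < n && score[j + 1] > gamma) j <- j + 1L
      run <- score[i:j]
      times <- c(times, (i:j)[which(run == max(run))[1]])
      n_o <- n_o + (j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  list(idx = times, n_o = n_o)
}

# exhaustive pairwise matching
oracle_match <- function(cand, ev, tol) {
  n_c <- 0L
  hit <- logical(length(cand))
  for (e in ev) {
    any_hit <- FALSE
    for (i in seq_along(cand)) {
      if (abs(cand[i] - e) <= tol) { any_hit <- TRUE; hit[i] <- TRUE }
    }
    if (any_hit) n_c <- n_c + 1L
  }
  list(n_c = n_c, correct = sort(unique(as.numeric(cand[hit]))))
}
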
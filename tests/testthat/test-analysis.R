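test_that("the symmetry index reproduces longhand arithmetic and is
          scale-invariant", {
  expect_equal(symmetry_index(1.0, 1.0), 1.0)
  expect_equal(symmetry_index(0.8, 1.0), 1.2)
  expect_equal(symmetry_index(1.2, 1.0), 0.8)
  for (c in c(0.1, 2, 37)) {
    expect_equal(symmetry_index(0.8 * c, 1.0 * c), 1.2)
  }
  expect_error(symmetry_index(1, 0), "non-zero")
  expect_equal(SYMMETRY_THRESHOLD, 1.15)
})

test_that("stance detection finds half-sine stances with hysteresis and a
          minimum duration", {
  fs <- 200
  t <- seq(0, 2, by = 1 / fs)
  bw <- 700
  grf <- rep(0, length(t))
  st1 <- t >= 0.2 & t <= 0.8
  grf[st1] <- bw * sin(pi * (t[st1] - 0.2) / 0.6)
  iv <- detect_stance(grf, t, bw)
  expect_equal(nrow(iv), 1)
  # borders within one sample of the 5%-BW crossings
  cross <- range(t[grf > 0.05 * bw])
  expect_lt(abs(iv$start - cross[1]), 1.5 / fs)
  expect_lt(abs(iv$end - cross[2]), 1.5 / fs)
  # two separated half-sines give two intervals
  st2 <- t >= 1.2 & t <= 1.7
  grf[st2] <- bw * sin(pi * (t[st2] - 1.2) / 0.5)
  expect_equal(nrow(detect_stance(grf, t, bw)), 2)
  expect_equal(nrow(detect_stance(rep(0, length(t)), t, bw)), 0)
})

test_that("windowed peaks respect the portion and break ties to the
          earliest sample", {
  t <- seq(0, 1, by = 0.01)
  ramp <- t
  pk <- peak_in_window(ramp, t, c(0, 1), "first_half")
  expect_equal(pk$time, 0.5)
  expect_equal(pk$value, 0.5)
  # double-peaked loading curve: first peak selected in the first half
  curve <- sin(pi * t)^2 + 0.4 * sin(2 * pi * t - 0.3)
  p1 <- peak_in_window(curve, t, c(0, 1), "first_half")
  expect_lt(p1$time, 0.5 + 1e-9)
  flat <- rep(1, length(t))
  expect_equal(peak_in_window(flat, t, c(0.2, 0.8), "full")$time, 0.2)
  expect_error(peak_in_window(ramp, t, c(-1, 0.5)), "outside")
})

test_that("bodyweight normalization and its inverse round-trip", {
  expect_equal(normalize_force(686.7, 70), 100, tolerance = 1e-12)
  expect_equal(normalize_moment(0, 70, 1.8), 0)
  set.seed(2)
  f <- runif(20, -1000, 1000)
  m <- runif(20, 50, 100); h <- runif(20, 1.5, 2)
  expect_equal(normalize_force(f, m) * m * GRAVITY / 100, f,
               tolerance = 1e-12)
  expect_equal(normalize_moment(f, m, h) * m * GRAVITY * h / 100, f,
               tolerance = 1e-12)
})

test_that("EMG envelopes rise during bursts, block DC, and scale linearly", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  burst <- t >= 0.8 & t <= 1.2
  raw <- rnorm(length(t), 0, 0.01)
  raw[burst] <- raw[burst] + sin(2 * pi * 100 * t[burst])
  env <- emg_envelope(raw, fs)
  expect_gt(mean(env[burst]), 5 * mean(env[t < 0.5]))
  dc <- emg_envelope(rep(1, length(t)), fs)
  expect_lt(max(abs(dc[500:3500])), 0.02)
  env2 <- emg_envelope(2 * raw, fs)
  expect_equal(env2[burst], 2 * env[burst], tolerance = 0.05)
  expect_error(emg_envelope(raw, 800), "exceed 1000")
})

test_that("alignment removes a constructed delay and offset exactly and
          matches the expected error under white noise", {
  set.seed(4)
  a <- cbind(sin(seq(0, 8, by = 0.02)), cos(seq(0, 8, by = 0.02)))
  b <- rbind(matrix(0.5, 5, 2), a) + 0.03
  res <- align_and_compare(a, b[1:nrow(a), ])
  expect_equal(res$delay, -5)
  expect_equal(unname(res$offset), c(0.03, 0.03), tolerance = 1e-9)
  expect_lt(res$mae, 1e-9)
  ident <- align_and_compare(a, a)
  expect_equal(ident$delay, 0)
  expect_lt(ident$rmse, 1e-12)
  sigma <- 0.05
  noisy <- a + matrix(rnorm(length(a), 0, sigma), ncol = 2)
  rn <- align_and_compare(a, noisy)
  expect_lt(abs(rn$mae - sigma * sqrt(2 / pi)) / (sigma * sqrt(2 / pi)), 0.07)
})

test_that("the rank AUC matches exhaustive pair counting and the Youden
          threshold behaves", {
  # perfectly separated
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  # small worked set vs brute force over all (pos, neg) pairs, with ties
  scores <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.7)
  labels <- c(0, 0, 1, 1, 0, 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  brute <- mean(outer(pos, neg, function(p, n)
    (p > n) + 0.5 * (p == n)))
  expect_equal(roc_analysis(scores, labels)$auc, brute)
  # shuffled labels at large n give AUC near 0.5
  set.seed(12)
  sc <- rnorm(400)
  lb <- sample(rep(c(TRUE, FALSE), 200))
  expect_lt(abs(roc_analysis(sc, lb)$auc - 0.5), 0.06)
  # monotone transform invariance
  expect_equal(roc_analysis(exp(sc), lb)$auc, roc_analysis(sc, lb)$auc)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  sc <- c(rnorm(40, 1), rnorm(40))
  lb <- rep(c(TRUE, FALSE), each = 40)
  ours <- roc_analysis(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("paired comparisons gate on normality and flag degenerate input", {
  set.seed(6)
  x <- rnorm(12); y <- x - rnorm(12, mean = 1, sd = 0.3)
  res <- paired_comparison(x, y)
  expect_equal(res$test, "paired_t")
  expect_lt(res$p, 0.01)
  d <- paired_comparison(x, x)
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  # heavy-tailed differences exercise the Wilcoxon branch
  set.seed(8)
  reps <- vapply(1:60, function(i) {
    x <- rnorm(15)
    y <- x + rt(15, df = 1)
    paired_comparison(x, y)$test
  }, character(1))
  expect_true(any(reps == "wilcoxon"))
  # a normal 1-SD shift at n = 10 selects the t test in > 90% of reps
  set.seed(10)
  tests <- vapply(1:300, function(i) {
    x <- rnorm(10)
    y <- x + rnorm(10, mean = 1)
    paired_comparison(x, y)$test
  }, character(1))
  expect_gt(mean(tests == "paired_t"), 0.9)
})

test_that("BH adjustment matches longhand arithmetic and its invariants", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(0.03, 5)), rep(0.03, 5))
  set.seed(3)
  p <- runif(30)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("post-hoc power matches Monte-Carlo rejection rates and is
          monotone", {
  pw <- posthoc_power(1.0, 10, 0.05, "t")
  set.seed(14)
  rej <- mean(vapply(1:20000, function(i) {
    d <- rnorm(10, mean = 1)
    stats::t.test(d)$p.value < 0.05
  }, logical(1)))
  expect_lt(abs(pw - rej), 0.02)
  expect_equal(posthoc_power(0, 25), 0.05, tolerance = 1e-6)
  ns <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(vapply(ns, function(n)
    posthoc_power(0.6, n), numeric(1))) > 0))
  expect_lt(posthoc_power(0.8, 12, test = "wilcoxon"),
            posthoc_power(0.8, 12, test = "t"))
})

test_that("the comparison battery adjusts within the family", {
  set.seed(5)
  df <- data.frame(
    metric = rep(c("hip", "knee", "ankle"), each = 10),
    natural = rnorm(30),
    modified = rnorm(30) + rep(c(2, 0, 0.3), each = 10))
  rep <- comparison_battery(df, "natural", "modified", by = "metric")
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$p_adjusted >= rep$p))
  expect_equal(rep$p_adjusted, adjust_bh(rep$p))
})
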
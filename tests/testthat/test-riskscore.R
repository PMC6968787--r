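test_that("find_split separates a perfectly separating feature at the gap", {
  x <- c(1, 2, 3, 10, 11, 12)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  s <- find_split(x, y)
  expect_identical(s$threshold, 6.5)
  expect_identical(s$direction, "<")
  # the gap split dominates every other candidate
  o <- naive_split_oracle(x, y)
  expect_identical(s$threshold, o$threshold)
  expect_equal(s$logworth, o$logworth, tolerance = 1e-9)
})

test_that("find_split handles two distinct values and degenerate input", {
  x <- rep(c(0, 1), 5)
  y <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  s <- find_split(x, y)
  expect_identical(s$threshold, 0.5)
  expect_error(find_split(rep(1, 6), y[1:6]), "constant")
  expect_error(find_split(1:6, rep(TRUE, 6)), "both classes")
})

test_that("find_split agrees with a naive scan oracle on shuffled labels", {
  set.seed(1)
  for (i in 1:50) {
    x <- rnorm(24)
    y <- sample(rep(c(TRUE, FALSE), c(10, 14)))
    s <- find_split(x, y)
    o <- naive_split_oracle(x, y)
    expect_equal(s$logworth, o$logworth, tolerance = 1e-9)
    expect_identical(s$threshold, o$threshold)
  }
})

test_that("the enumerated fit equals a naive brute-force oracle", {
  set.seed(2)
  for (i in 1:4) {
    n <- 26
    X <- as.data.frame(matrix(rnorm(n * 7), n, 7))
    names(X) <- paste0("v", 1:7)
    y <- sample(rep(c(TRUE, FALSE), c(11, 15)))
    X$v4 <- X$v4 + y * 1.2
    m <- fit_risk_score(X, y, max_terms = 3)
    o <- brute_risk_oracle(X, y, max_terms = 3)
    expect_equal(m$objective, o$obj, tolerance = 1e-9)
    expect_identical(sort(match(m$terms$feature, names(X))), sort(o$sub))
    expect_identical(m$intercept, o$b0)
  }
})

test_that("a strong penalty on all-noise features yields the intercept-only model", {
  set.seed(3)
  X <- as.data.frame(matrix(rnorm(32 * 10), 32, 10))
  y <- rep(c(TRUE, FALSE), each = 16)
  m <- fit_risk_score(X, y, l0_penalty = 50)
  expect_identical(nrow(m$terms), 0L)
  # oracle: with no terms the best intercept maximizes the Bernoulli likelihood
  lls <- vapply(-10:10, function(b)
    sum(ifelse(y, plogis(b, log.p = TRUE), plogis(-b, log.p = TRUE))), 0)
  expect_identical(m$intercept, (-10:10)[which.max(lls)])
})

test_that("planted signal features are recovered with correct directions", {
  set.seed(4)
  ok <- vapply(1:5, function(i) {
    n <- 80
    X <- as.data.frame(matrix(rnorm(n * 19), n, 19))
    names(X) <- paste0("f", sprintf("%02d", 1:19))
    y <- rep(c(TRUE, FALSE), each = 40)
    X$f03 <- X$f03 + y * 2.5
    X$f07 <- X$f07 - y * 2.5
    X$f11 <- X$f11 + y * 2.5
    m <- fit_risk_score(X, y)
    identical(sort(m$terms$feature), c("f03", "f07", "f11")) &&
      all(m$terms$points == 1L)
  }, TRUE)
  expect_gte(mean(ok), 0.8)
})

test_that("the search is invariant to row and feature order", {
  set.seed(5)
  n <- 30
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- paste0("w", 1:6)
  y <- rep(c(TRUE, FALSE), each = 15)
  X$w2 <- X$w2 + y
  m0 <- fit_risk_score(X, y, max_terms = 2)
  perm <- sample(n)
  m1 <- fit_risk_score(X[perm, ], y[perm], max_terms = 2)
  expect_identical(m0$terms, m1$terms)
  expect_identical(m0$intercept, m1$intercept)
  m2 <- fit_risk_score(X[, 6:1], y, max_terms = 2)
  expect_setequal(m0$terms$feature, m2$terms$feature)
  expect_equal(m0$objective, m2$objective, tolerance = 1e-9)
})

test_that("calibration rows are exact count ratios over achievable scores", {
  set.seed(6)
  n <- 40L
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(X) <- paste0("q", 1:5)
  y <- rep(c(TRUE, FALSE), each = 20)
  X$q1 <- X$q1 + y * 2
  m <- fit_risk_score(X, y, max_terms = 2)
  cal <- m$calibration
  expect_identical(sum(cal$n), n)
  expect_identical(cal$score, acuteqeeg:::.score_range(m$terms))
  sc <- predict(m, X, type = "score")
  for (i in seq_len(nrow(cal))) {
    expect_identical(cal$n[i], sum(sc == cal$score[i]))
    expect_identical(cal$n_susceptible[i], sum(sc == cal$score[i] & y))
    if (cal$n[i] > 0)
      expect_identical(cal$empirical_prob[i], cal$n_susceptible[i] / cal$n[i])
  }
})

test_that("the reference scorecard reproduces the published worked examples", {
  tool <- susceptibility_scorecard()
  hit <- data.frame(coh_delta = 0.5, pct_beta_contra = 2, kurtosis_contra = 3.5)
  res <- score_features(tool, hit)
  expect_identical(res$score, 3L)
  expect_equal(100 * res$probability, 88.9, tolerance = 1e-12)
  miss <- data.frame(coh_delta = 3.2, pct_beta_contra = 5, kurtosis_contra = 6)
  res0 <- score_features(tool, miss)
  expect_identical(res0$score, 0L)
  expect_equal(100 * res0$probability, 6.7, tolerance = 1e-12)
  one <- data.frame(coh_delta = 0.5, pct_beta_contra = 5, kurtosis_contra = 6)
  expect_equal(100 * score_features(tool, one)$probability, 6.7,
               tolerance = 1e-12)
  # the printed coherence threshold lies outside [0, 1] and is flagged
  expect_true(any(grepl("coh_delta", tool$range_flags)))
  expect_error(predict(tool, data.frame(coh_delta = 0.5)), "missing feature")
})

test_that("risk_score_tool validates rules and calibration coverage", {
  terms <- data.frame(feature = c("a", "b"), threshold = c(1, 2),
                      direction = "<", points = 1L)
  expect_error(risk_score_tool(terms,
                               calibration = data.frame(score = 0:1,
                                                        empirical_prob = c(0.1, 0.5))),
               "every achievable score")
  tool <- risk_score_tool(terms, intercept = -2)
  pr <- predict(tool, data.frame(a = 0, b = 0))
  expect_identical(pr$score, 2L)
  expect_equal(pr$probability, plogis(0))
})

test_that("fit preconditions are enforced", {
  X <- data.frame(a = rnorm(10), b = rnorm(10))
  expect_error(fit_risk_score(X, rep(TRUE, 10)), "both classes")
  expect_error(fit_risk_score(X, c(TRUE, TRUE, rep(FALSE, 8))), ">= 3 subjects")
  Xc <- data.frame(a = rnorm(12), b = rep(1, 12))
  expect_message(fit_risk_score(Xc, rep(c(TRUE, FALSE), 6), max_terms = 1),
                 "constant feature")
})

test_that("cross-validated discrimination of PPKS exceeds chance on synthetic cohorts", {
  auc_rank <- function(p, y) {
    r <- rank(p)
    n1 <- sum(y)
    n0 <- sum(!y)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  aucs <- vapply(1:8, function(i) {
    man <- cohort_manifest(16, seed = 700 + i, presets = strain_presets(fs = 128))
    cf <- compute_cohort_features(man, labels = c("baseline", "post_0.5"))
    post <- cf$features[cf$features$epoch == "post_0.5", ]
    X <- post[, feature_names()]
    y <- post$strain == "PPKS"
    set.seed(i)
    fold <- integer(nrow(X))
    fold[y] <- sample(rep(1:2, length.out = sum(y)))
    fold[!y] <- sample(rep(1:2, length.out = sum(!y)))
    p <- numeric(nrow(X))
    for (f in 1:2) {
      m <- fit_risk_score(X[fold != f, ], y[fold != f], max_terms = 3)
      p[fold == f] <- predict(m, X[fold == f, ], type = "score")
    }
    auc_rank(p, y)
  }, 0)
  ci <- t.test(aucs, mu = 0.5)$conf.int
  expect_gt(mean(aucs), 0.5)
  expect_gt(ci[1], 0.5)
})
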
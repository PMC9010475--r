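test_that("vigilance summaries: strict 500 ms lapse threshold, median and sample variance", {
  expect_equal(pvtSummary(c(300, 501, 700))$lapses, 2L)
  expect_equal(pvtSummary(rep(500, 10))$lapses, 0L)  # boundary is not a lapse
  s <- pvtSummary(c(400, 600))
  expect_equal(s$medianRT, 500)
  expect_equal(s$varRT, 20000)  # sample variance convention
  expect_error(pvtSummary(numeric()), "empty")
  expect_error(pvtSummary(c(300, -1)), "positive")
})

test_that("interaction model: contract errors and centring invariance", {
  set.seed(40)
  grp <- factor(rep(c("NSW", "SD"), each = 6))
  means <- matrix(rnorm(12), 12, 1,
                  dimnames = list(sprintf("S%02d", 1:12), "C1"))
  # measure constant within each group -> collinear with group
  expect_error(interactionModel(means, grp, rep(c(0, 1), each = 6)),
               "rank")
  expect_error(interactionModel(means[1:5, , drop = FALSE],
                                grp[1:5], rnorm(5)),
               "at least 3")

  m <- rnorm(12)
  a <- interactionModel(means, grp, m)
  b <- interactionModel(means, grp, m - mean(m))
  expect_equal(a$p_interaction, b$p_interaction, tolerance = 1e-10)
  expect_equal(a$beta_interaction, b$beta_interaction, tolerance = 1e-10)
})

test_that("interaction model reports within-group correlations that match cor.test", {
  set.seed(41)
  grp <- factor(rep(c("NSW", "SD"), c(7, 8)))
  means <- matrix(rnorm(15), 15, 2,
                  dimnames = list(sprintf("S%02d", 1:15), c("C1", "C2")))
  m <- rnorm(15)
  res <- interactionModel(means, grp, m)
  expect_true(all(abs(c(res$r_NSW, res$r_SD)) <= 1))
  for (cl in 1:2) {
    ref <- cor.test(means[grp == "SD", cl], m[grp == "SD"])
    expect_equal(res$r_SD[cl], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p_r_SD[cl], ref$p.value, tolerance = 1e-12)
  }
  # the interaction p equals lm's interaction coefficient p
  ref <- summary(lm(means[, 1] ~ grp * m))$coefficients
  expect_equal(res$p_interaction[1], ref["grpSD:m", "Pr(>|t|)"],
               tolerance = 1e-10)
  # listwise deletion with a message and counts
  m2 <- m; m2[c(2, 9)] <- NA
  expect_message(res2 <- interactionModel(means, grp, m2), "2 subject")
  expect_equal(unique(res2$n), 13)
})

test_that("equal slopes in both groups give calibrated interaction p; opposite slopes are detected", {
  set.seed(42)
  ps <- replicate(150, {
    grp <- factor(rep(c("a", "b"), each = 8))
    m <- rnorm(16)
    y <- matrix(0.5 * m + rnorm(16, 0, 1), 16, 1,
                dimnames = list(sprintf("S%02d", 1:16), "C1"))
    interactionModel(y, grp, m)$p_interaction
  })
  rate <- mean(ps < 0.05)
  expect_lt(rate, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 150) + 0.01)

  hits <- replicate(60, {
    grp <- factor(rep(c("a", "b"), each = 10))
    m <- rnorm(20)
    slope <- ifelse(grp == "a", 1, -1)
    y <- matrix(slope * m + rnorm(20, 0, 0.5), 20, 1,
                dimnames = list(sprintf("S%02d", 1:20), "C1"))
    interactionModel(y, grp, m)$p_interaction < 0.05
  })
  expect_gt(mean(hits), 0.5)
})

test_that("BH adjustment matches the step-by-step oracle and preserves order", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.37), 0.37)
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- fdrAdjust(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  ordered <- sort(runif(10))
  expect_true(all(diff(fdrAdjust(ordered)) >= 0))
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
  expect_error(fdrAdjust(c(0.5, NA)), "missing")
})
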
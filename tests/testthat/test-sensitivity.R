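test_that("cluster means are per-subject averages over member regions", {
  toy <- toyCohort(nRegions = 4, seed = 2)
  ch <- computeSPC(toy$cohort)
  Y <- changeValues(ch)

  one <- extractClusterMeans(ch, list("P02"))
  expect_equal(unname(one[, 1]), unname(Y[, "P02"]))

  two <- extractClusterMeans(ch, list(c("P01", "P03")))
  expect_equal(unname(two[, 1]), unname((Y[, "P01"] + Y[, "P03"]) / 2))
  # region order within the cluster is irrelevant
  expect_equal(extractClusterMeans(ch, list(c("P03", "P01"))), two)
  # means bounded by member-region values per subject
  expect_true(all(two[, 1] >= pmin(Y[, "P01"], Y[, "P03"]) &
                  two[, 1] <= pmax(Y[, "P01"], Y[, "P03"])))
  expect_error(extractClusterMeans(ch, list("P09")), "unknown region")
  expect_error(extractClusterMeans(ch, list()), "no clusters")
})

test_that("cluster-mean extraction commutes with subject subsetting", {
  toy <- toyCohort(nRegions = 5, seed = 8)
  ch <- computeSPC(toy$cohort)
  keep <- c("S01", "S03", "S06")
  sub <- toy$cohort[, keep]
  m1 <- extractClusterMeans(computeSPC(sub), list(c("P01", "P02")))
  m2 <- extractClusterMeans(ch, list(c("P01", "P02")))[keep, , drop = FALSE]
  expect_equal(m1, m2)
})

test_that("covariate adjustment leaves the group test nearly unchanged when covariates are irrelevant", {
  set.seed(30)
  diffs <- replicate(40, {
    toy <- toyCohort(nA = 10, nB = 10, shift = 0.06,
                     shiftRegions = c("P01", "P02"), seed = sample.int(1e6, 1))
    ch <- computeSPC(toy$cohort)
    means <- extractClusterMeans(ch, list(c("P01", "P02")))
    grp <- cohortGroups(toy$cohort)
    covs <- data.frame(noise = rnorm(20), row.names = rownames(means))
    pAdj <- covariateAdjustedTest(means, grp, covs)$p
    pRaw <- summary(lm(means[, 1] ~ grp))$coefficients[2, 4]
    pAdj - pRaw
  })
  expect_lt(abs(mean(diffs)), 0.05)

  toy <- toyCohort(seed = 1)
  means <- extractClusterMeans(computeSPC(toy$cohort), list("P01"))
  grp <- cohortGroups(toy$cohort)
  const <- data.frame(flat = rep(1.7, 8), row.names = rownames(means))
  expect_error(covariateAdjustedTest(means, grp, const), "constant")
  expect_warning(res <- covariateAdjustedTest(means, grp, const,
                                              onConstant = "drop"),
                 "dropping")
  expect_equal(nrow(res), 1L)
})

test_that("adjusted p-values are calibrated under a zero group effect", {
  set.seed(31)
  ps <- replicate(100, {
    toy <- toyCohort(nA = 8, nB = 8, shift = 0, seed = sample.int(1e6, 1))
    means <- extractClusterMeans(computeSPC(toy$cohort), list(c("P01", "P02")))
    covs <- data.frame(x = rnorm(16), row.names = rownames(means))
    covariateAdjustedTest(means, cohortGroups(toy$cohort), covs)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("exclusion rerun drops exactly one subject and reports stability", {
  toy <- toyCohort(nA = 6, nB = 6, shift = 0.08,
                   shiftRegions = c("P04", "P05", "P06"), seed = 12)
  out <- excludeAndRerun(toy$cohort, toy$graph, "S03",
                         nPermutations = 100, seed = 5)
  expect_equal(ncol(out$after$stats), ncol(out$before$stats))
  expect_equal(nrow(out$after$stats), nrow(out$before$stats))
  expect_named(out$comparison,
               c("significant_clusters", "significant_regions", "jaccard"))
  expect_error(excludeAndRerun(toy$cohort, toy$graph, "nope"), "unknown")

  # a planted extreme subject changes the picture once removed
  coh <- toy$cohort
  tp2 <- SummarizedExperiment::assay(coh, "tp2")
  tp2[, "S12"] <- tp2[, "S12"] + 0.8   # one wildly changed subject
  coh2 <- cohortTable(SummarizedExperiment::assay(coh, "tp1"), tp2,
                      cohortGroups(coh),
                      as.data.frame(SummarizedExperiment::colData(coh)[-1]))
  out2 <- excludeAndRerun(coh2, toy$graph, "S12",
                          nPermutations = 100, seed = 5)
  expect_false(identical(as.vector(out2$before$stats$t),
                         as.vector(out2$after$stats$t)))
})

test_that("dropping a subject that empties a group is refused", {
  toy <- toyCohort(nA = 2, nB = 4, seed = 3)
  expect_error(dropSubject(toy$cohort, "S01"), "fewer than 2")
})

test_that("depth reruns are independent per depth and identical for identical tables", {
  toy <- toyCohort(nA = 5, nB = 5, shift = 0.06,
                   shiftRegions = c("P02", "P03"), seed = 14)
  cohorts <- list(`30` = toy$cohort, `50` = toy$cohort, `70` = toy$cohort)
  out <- runDepthSensitivity(cohorts, toy$graph, nPermutations = 60, seed = 2)
  expect_equal(out$results[["30"]]$stats, out$results[["70"]]$stats)
  expect_true(all(out$overlap == 1 | is.na(out$overlap)))

  # effect present at one depth only: perturbing another depth's table
  # never touches this depth's result
  toyNull <- toyCohort(nA = 5, nB = 5, shift = 0, seed = 14)
  mixed <- list(`30` = toyNull$cohort, `50` = toy$cohort)
  out2 <- runDepthSensitivity(mixed, toy$graph, nPermutations = 60, seed = 2)
  expect_equal(out2$results[["50"]]$stats, out$results[["50"]]$stats)
  expect_false(identical(out2$results[["30"]]$stats, out2$results[["50"]]$stats))

  badSubjects <- toyCohort(nA = 5, nB = 6, shift = 0, seed = 1)
  expect_error(runDepthSensitivity(list(a = toy$cohort, b = badSubjects$cohort),
                                   toy$graph),
               "share")
})

test_that("p-value summaries over a region subset are plain order statistics", {
  st <- S4Vectors::DataFrame(p = c(0.02, 0.10, 0.55),
                             row.names = c("R1", "R2", "R3"))
  expect_equal(summarizeRegionPvalues(st, c("R1", "R2", "R3")),
               c(median = 0.10, min = 0.02, max = 0.55))
  expect_equal(unname(summarizeRegionPvalues(st, "R2")), rep(0.10, 3))
  expect_error(summarizeRegionPvalues(st, character()), "empty")
  expect_error(summarizeRegionPvalues(st, "R9"), "unknown")
})

test_that("homotopic mapping is a pure data lookup in either direction", {
  pairs <- data.frame(lh = c("L_1", "L_2"), rh = c("R_1", "R_2"))
  expect_equal(mapHomotopic(c("R_2", "L_1"), pairs), c("L_2", "R_1"))
  expect_error(mapHomotopic("X", pairs), "counterpart")
})

test_that("outlier flagging marks only far-out cluster means", {
  m <- matrix(c(rnorm(19, 0, 0.1), 5), 20, 1,
              dimnames = list(sprintf("S%02d", 1:20), "C1"))
  flags <- flagOutliers(m, k = 3)
  expect_true(flags[20])
  expect_false(any(flags[1:19]))
})
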
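fakeStats <- function(p, ids) S4Vectors::DataFrame(p = p, row.names = ids)

test_that("cluster formation respects adjacency and the strict threshold", {
  g <- pathGraph(c("A", "B", "C"))
  st <- fakeStats(c(0.01, 0.20, 0.01), c("A", "B", "C"))
  expect_equal(formClusters(st, g, 0.05), list("A", "C"))

  expect_equal(formClusters(fakeStats(c(0.5, 0.9, 0.05), c("A", "B", "C")), g,
                            0.05),
               list())  # p == threshold is not supra-threshold

  expect_error(formClusters(fakeStats(0.01, "A"), g), "lacks")
})

test_that("cluster formation agrees with the component oracle on random p-fields", {
  for (i in 1:25) {
    g <- randomTestGraph(sample(5:16, 1), 0.3, seed = 300 + i)
    p <- runif(nRegions(g))
    st <- fakeStats(p, regionIds(g))
    got <- formClusters(st, g, 0.3)
    want <- oracleComponents(regionIds(g), edgeMatrix(g),
                             regionIds(g)[p < 0.3])
    expect_equal(got, want)
  }
})

test_that("corrected p follows the add-one counting convention", {
  g <- pathGraph(c("A", "B", "C", "D", "E"))
  null <- c(0L, 0L, 3L, 5L)
  res <- clusterPValues(list(c("A", "B", "C")), null, g)
  expect_equal(correctedP(res), (1 + 2) / 5)  # k = 3 vs null (0,0,3,5)

  res1 <- clusterPValues(list("A"), rep(1L, 100), g)
  expect_equal(correctedP(res1), 1)  # k = 1, every null max >= 1

  big <- clusterPValues(list(c("A", "B", "C", "D", "E")), rep(2L, 5000), g)
  expect_equal(correctedP(big), 1 / 5001)

  none <- clusterPValues(list(), null, g)
  expect_length(correctedP(none), 0)
  expect_equal(clusterSizes(none), integer())
})

test_that("identical outcomes for all subjects give an all-zero null", {
  toy <- toyCohort(nRegions = 5, noiseSd = 0, seed = 2)
  ch <- computeRawDiff(toy$cohort)  # exactly zero everywhere
  null <- permutationNull(ch, toy$cohort, toy$graph, nPermutations = 50,
                          seed = 1, scheme = "montecarlo")
  expect_equal(as.integer(null), rep(0L, 50))
})

test_that("the permutation null is reproducible given a seed", {
  toy <- toyCohort(seed = 6)
  ch <- computeSPC(toy$cohort)
  n1 <- permutationNull(ch, toy$cohort, toy$graph, nPermutations = 200,
                        seed = 42, scheme = "montecarlo")
  n2 <- permutationNull(ch, toy$cohort, toy$graph, nPermutations = 200,
                        seed = 42, scheme = "montecarlo")
  expect_identical(as.integer(n1), as.integer(n2))
  n3 <- permutationNull(ch, toy$cohort, toy$graph, nPermutations = 200,
                        seed = 43, scheme = "montecarlo")
  expect_false(identical(as.integer(n1), as.integer(n3)))
})

test_that("small cohorts switch to exhaustive enumeration of all labelings", {
  toy <- toyCohort(nA = 4, nB = 4, seed = 3)
  ch <- computeSPC(toy$cohort)
  expect_message(
    null <- permutationNull(ch, toy$cohort, toy$graph, nPermutations = 500),
    "70 distinct labelings")
  expect_length(null, choose(8, 4))
  expect_true(attr(null, "exhaustive"))
})

test_that("corrected p is monotone in observed cluster size", {
  g <- pathGraph(sprintf("P%02d", 1:6))
  null <- as.integer(c(0, 1, 1, 2, 3, 5, 2, 0))
  ids <- regionIds(g)
  res <- clusterPValues(list(ids[1:4], ids[5:6]), null, g)
  expect_true(correctedP(res)[1] <= correctedP(res)[2])
})

test_that("consistently relabeling subjects leaves observed clusters unchanged", {
  toy <- toyCohort(nA = 5, nB = 5, shift = 0.05,
                   shiftRegions = c("P04", "P05", "P06"), seed = 10)
  ch <- computeSPC(toy$cohort)
  grp <- cohortGroups(toy$cohort)
  st <- fitRegionModels(ch, grp)
  cl <- formClusters(st, toy$graph)

  perm <- sample(nrow(changeValues(ch)))
  # reorder subjects consistently in outcome and labels
  Y <- changeValues(ch)[perm, , drop = FALSE]
  ch2 <- computeRawDiff(matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(Y)), Y)
  st2 <- fitRegionModels(ch2, grp[perm])
  expect_equal(formClusters(st2, toy$graph), cl)
})
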
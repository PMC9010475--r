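test_that("lattice graphs have the expected structure", {
  cfg4 <- simulationConfig(nRegionsPerHemi = 4)
  g4 <- makeGraph(cfg4)
  for (h in c("LH", "RH")) {
    ids <- regionIds(g4)[hemispheres(g4) == h]
    e <- edgeMatrix(g4)
    inHemi <- e[, 1] %in% ids
    expect_equal(sum(inHemi), 4L)  # 2x2 grid
  }

  cfg180 <- simulationConfig(nRegionsPerHemi = 180)
  g <- makeGraph(cfg180)
  expect_equal(nRegions(g), 360L)
  e <- edgeMatrix(g)
  hemiOf <- hemispheres(g)
  expect_true(all(hemiOf[e[, 1]] == hemiOf[e[, 2]]))  # zero LH-RH edges
  expect_equal(sum(hemiOf[e[, 1]] == "LH"), 333L)     # 12x15 grid: 12*14 + 15*11
  expect_equal(sum(hemiOf[e[, 1]] == "RH"), 333L)
  # each hemisphere internally connected
  comps <- connectedComponents(g, regionIds(g))
  expect_equal(lengths(comps), c(180L, 180L))
})

test_that("the planted region set is contiguous and in the configured hemisphere", {
  cfg <- simulationConfig(nRegionsPerHemi = 30, effectNRegions = 10,
                          effectSize = 0.8, effectHemi = "LH", seed = 2)
  g <- makeGraph(cfg)
  coh <- simulateCohort(g, cfg)
  eff <- S4Vectors::metadata(coh)$effectRegions
  expect_length(eff, 10L)
  expect_true(all(hemispheres(g)[eff] == "LH"))
  expect_length(connectedComponents(g, eff), 1L)
})

test_that("same seed reproduces the cohort exactly; different seed does not", {
  cfg <- simulationConfig(nRegionsPerHemi = 12, seed = 11)
  g <- makeGraph(cfg)
  a <- simulateCohort(g, cfg)
  b <- simulateCohort(g, cfg)
  expect_identical(SummarizedExperiment::assay(a, "tp1"),
                   SummarizedExperiment::assay(b, "tp1"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  c2 <- simulateCohort(g, simulationConfig(nRegionsPerHemi = 12, seed = 12))
  expect_false(identical(SummarizedExperiment::assay(a, "tp1"),
                         SummarizedExperiment::assay(c2, "tp1")))
})

test_that("simulation configurations round-trip through JSON", {
  cfg <- simulationConfig(nGroupA = 9, nRegionsPerHemi = 20,
                          effectNRegions = 4, effectSize = 0.6, seed = 99)
  path <- tempfile(fileext = ".json")
  writeSimulationConfig(cfg, path)
  cfg2 <- readSimulationConfig(path)
  for (s in methods::slotNames(cfg))
    expect_equal(methods::slot(cfg2, s), methods::slot(cfg, s))
})

test_that("noise-free null cohort has TP1 == TP2 and all-zero SPC", {
  cfg <- simulationConfig(nRegionsPerHemi = 6, baselineSd = 0,
                          subjectSd = 0, noiseSd = 0, drift = 0,
                          effectSize = 0, seed = 5)
  g <- makeGraph(cfg)
  coh <- simulateCohort(g, cfg)
  expect_identical(SummarizedExperiment::assay(coh, "tp1"),
                   SummarizedExperiment::assay(coh, "tp2"))
  expect_true(all(changeValues(computeSPC(coh)) == 0))
})

test_that("generated measures are strictly positive so SPC is defined", {
  cfg <- simulationConfig(nRegionsPerHemi = 8, baselineMean = 0.3,
                          baselineSd = 0.05, noiseSd = 0.05, seed = 9)
  coh <- simulateCohort(makeGraph(cfg), cfg)
  expect_true(all(SummarizedExperiment::assay(coh, "tp1") > 0))
  expect_true(all(SummarizedExperiment::assay(coh, "tp2") > 0))
})

test_that("under the global null, region tests reject at the nominal rate and p-values are uniform", {
  # 200 small replicates; pool one fixed region's p across replicates
  nRep <- 200
  rej <- numeric(nRep)
  pFirst <- numeric(nRep)
  for (i in seq_len(nRep)) {
    cfg <- simulationConfig(nGroupA = 10, nGroupB = 10, nRegionsPerHemi = 8,
                            effectSize = 0, seed = 20000 + i)
    coh <- simulateCohort(makeGraph(cfg), cfg)
    st <- fitRegionModels(computeSPC(coh), coh)
    rej[i] <- mean(st$p < 0.05)
    pFirst[i] <- st$p[1L]
  }
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / (nRep * 16))
  expect_gt(rate, 0.05 - 1.96 * se - 0.01)
  expect_lt(rate, 0.05 + 1.96 * se + 0.01)
  ks <- suppressWarnings(stats::ks.test(pFirst, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the planted effect size calibration lands near the target Hedges g", {
  # Monte-Carlo check of the delta-method calibration: average observed
  # per-region g in effect regions across replicates
  gs <- numeric(60)
  for (i in seq_len(60)) {
    cfg <- simulationConfig(nRegionsPerHemi = 16, effectNRegions = 6,
                            effectSize = 0.8, seed = 31000 + i)
    coh <- simulateCohort(makeGraph(cfg), cfg)
    eff <- S4Vectors::metadata(coh)$effectRegions
    st <- fitRegionModels(computeSPC(coh), coh)
    gs[i] <- mean(st[eff, "g"])
  }
  expect_gt(mean(gs), 0.8 - 0.15)
  expect_lt(mean(gs), 0.8 + 0.15)
})
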
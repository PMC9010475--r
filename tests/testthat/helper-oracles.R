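# Independent brute-force oracles and fixture builders used across tests.

# Connected components by repeated neighbour-set expansion (no igraph):
# grow each component from a seed node by absorbing adjacent subset
# members until a fixpoint.
oracleComponents <- function(nodes, edges, subset) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (NROW(edges)) {
    for (k in seq_len(nrow(edges))) {
      adj[edges[k, 1], edges[k, 2]] <- TRUE
      adj[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  remaining <- subset
  comps <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grown <- remaining[remaining %in% comp |
        apply(adj[remaining, comp, drop = FALSE], 1L, any)]
      if (setequal(grown, comp)) break
      comp <- grown
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(-vapply(comps, length, 1L), vapply(comps, `[`, "", 1L))]
}

# Step-by-step Benjamini-Hochberg: p * m / rank, step-up monotonicity
# from the largest p down, capped at 1, restored to input order.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# Classical mixed-design sums-of-squares decomposition for a 2 (group,
# between) x 2 (time, within) design; sequential SS as in the standard
# weighted-means analysis.
oracleMixedAnova <- function(group, y1, y2) {
  n <- length(y1)
  y <- cbind(y1, y2)
  gm <- mean(y)
  subjMean <- rowMeans(y)
  timeMean <- colMeans(y)
  grpMean <- tapply(subjMean, group, mean)
  ng <- table(group)
  ssBetweenSubj <- 2 * sum((subjMean - gm)^2)
  ssGroup <- 2 * sum(ng * (grpMean - gm)^2)
  ssSubjWithin <- ssBetweenSubj - ssGroup
  ssTotal <- sum((y - gm)^2)
  ssWithin <- ssTotal - ssBetweenSubj
  ssTime <- n * sum((timeMean - gm)^2)
  cellMean <- rbind(tapply(y1, group, mean), tapply(y2, group, mean))
  ssCells <- sum(rep(ng, each = 2) * (cellMean - gm)^2)
  ssInter <- ssCells - ssGroup - ssTime
  ssErr <- ssWithin - ssTime - ssInter
  dfe <- n - 2
  data.frame(
    F = c(ssGroup / (ssSubjWithin / dfe),
          ssTime / (ssErr / dfe),
          ssInter / (ssErr / dfe)),
    row.names = c("group", "time", "group:time")
  )
}

# Random single-hemisphere Erdos-Renyi style graph for oracle comparisons.
randomTestGraph <- function(nNodes, pEdge, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(nNodes))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- stats::runif(nrow(pairs)) < pEdge
  parcellationGraph(
    regionIds = nodes,
    hemisphere = stats::setNames(rep("LH", nNodes), nodes),
    edges = if (any(keep)) pairs[keep, , drop = FALSE] else NULL
  )
}

# Path-graph parcellation (all LH) with given region names.
pathGraph <- function(ids) {
  parcellationGraph(
    regionIds = ids,
    hemisphere = stats::setNames(rep("LH", length(ids)), ids),
    edges = if (length(ids) > 1L) cbind(ids[-length(ids)], ids[-1L]) else NULL
  )
}

# Small deterministic cohort on a path graph: nA + nB subjects, nRegions
# regions, optional additive TP2 shift for group B on selected regions.
toyCohort <- function(nA = 4L, nB = 4L, nRegions = 10L, shift = 0,
                      shiftRegions = character(), seed = 1L,
                      noiseSd = 0.02) {
  ids <- sprintf("P%02d", seq_len(nRegions))
  graph <- pathGraph(ids)
  n <- nA + nB
  set.seed(seed)
  subjects <- sprintf("S%02d", seq_len(n))
  group <- factor(rep(c("NSW", "SD"), c(nA, nB)), levels = c("NSW", "SD"))
  base <- matrix(1.5, nRegions, n) +
    matrix(rnorm(nRegions * n, 0, 0.05), nRegions, n)
  tp1 <- base + matrix(rnorm(nRegions * n, 0, noiseSd), nRegions, n)
  tp2 <- base + matrix(rnorm(nRegions * n, 0, noiseSd), nRegions, n)
  tp2[ids %in% shiftRegions, group == "SD"] <-
    tp2[ids %in% shiftRegions, group == "SD"] + shift
  dimnames(tp1) <- dimnames(tp2) <- list(ids, subjects)
  cohort <- cohortTable(tp1, tp2, group,
                        covariates = data.frame(
                          eulerTP1 = round(rnorm(n, -40, 15)),
                          eulerTP2 = round(rnorm(n, -40, 15)),
                          row.names = subjects),
                        hemisphere = hemispheres(graph))
  list(graph = graph, cohort = cohort)
}
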
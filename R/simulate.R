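#' Configure the synthetic cohort generator
#'
#' The generator emulates a two-group, two-timepoint regional MRI study: a
#' control group following a normal sleep-wake cycle (default n = 23) and an
#' exposed, sleep-deprived group (default n = 18), measured on a parcellation
#' with 180 regions per hemisphere. A group-differential change is planted on
#' a contiguous region set in one hemisphere; its magnitude is given on the
#' Hedges-g scale of the symmetrised-percentage-change group difference, so
#' \code{effectSize = 0.8} plants an effect comparable to reported
#' cluster-level effect sizes. Region baselines, subject random intercepts
#' and independent measurement noise are Gaussian.
#'
#' Default variance components are stated on the T1w/T2w-ratio scale:
#' baselines 1.5 (SD 0.1 across regions), subject intercept SD 0.05,
#' residual SD 0.02 per region and timepoint. \code{drift} is a common
#' change added to every subject and region at the second timepoint
#' (emulating a time-of-day decrease when negative).
#'
#' @param nGroupA,nGroupB subject counts for the control and exposed groups.
#' @param nRegionsPerHemi regions per hemisphere (lattice is chosen as the
#'   most nearly square grid of this size, 180 = 12 x 15).
#' @param graphKind only \code{"lattice"}: a rectangular grid with
#'   4-neighbour adjacency per hemisphere, hemispheres disconnected.
#' @param effectNRegions size of the planted contiguous region set.
#' @param effectSize planted standardized group difference (Hedges-g scale)
#'   of the SPC in effect regions; 0 for a global null.
#' @param effectHemi hemisphere carrying the planted effect.
#' @param baselineMean,baselineSd mean and between-region SD of region
#'   baselines.
#' @param subjectSd SD of the subject random intercept.
#' @param noiseSd residual SD per region and timepoint.
#' @param drift common additive change at timepoint 2.
#' @param covariateGroupEffect if TRUE, nuisance covariates (head movement,
#'   haematocrit) are drawn with a group shift — a confounded scenario for
#'   robustness testing. Default FALSE: independent of group.
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nGroupA = 23L, nGroupB = 18L,
                             nRegionsPerHemi = 180L,
                             graphKind = "lattice",
                             effectNRegions = min(10L, nRegionsPerHemi),
                             effectSize = 0,
                             effectHemi = "RH",
                             baselineMean = 1.5, baselineSd = 0.1,
                             subjectSd = 0.05, noiseSd = 0.02,
                             drift = 0,
                             covariateGroupEffect = FALSE,
                             seed = 1L) {
  new("SimulationConfig",
      nGroupA = as.integer(nGroupA), nGroupB = as.integer(nGroupB),
      nRegionsPerHemi = as.integer(nRegionsPerHemi),
      graphKind = graphKind,
      effectNRegions = as.integer(effectNRegions),
      effectSize = as.numeric(effectSize),
      effectHemi = effectHemi,
      baselineMean = baselineMean, baselineSd = baselineSd,
      subjectSd = subjectSd, noiseSd = noiseSd,
      drift = drift,
      covariateGroupEffect = isTRUE(covariateGroupEffect),
      seed = as.integer(seed))
}

#' Round-trip a simulation configuration through JSON
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path JSON file path.
#' @return \code{readSimulationConfig}: the configuration, validated.
#' @name simulationConfig-io
#' @export
writeSimulationConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  jsonlite::write_json(vals, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname simulationConfig-io
#' @export
readSimulationConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simulationConfig, vals)
}

# most nearly square factorisation r x c = n with r <= c
.gridDims <- function(n) {
  r <- floor(sqrt(n))
  while (r >= 1L && n %% r != 0L) r <- r - 1L
  c(r, n %/% r)
}

.hemiRegionNames <- function(hemi, n) {
  sprintf("%s_%03d", if (hemi == "LH") "L" else "R", seq_len(n))
}

#' Generate the synthetic parcellation graph
#'
#' Builds a two-hemisphere lattice: each hemisphere is a rectangular grid
#' with 4-neighbour adjacency (internally connected), and no edge joins the
#' hemispheres. A grid of r x c regions has \code{r*(c-1) + c*(r-1)} edges;
#' the 180-region hemisphere is a 12 x 15 grid with 333 edges.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ParcellationGraph} with \code{2 * nRegionsPerHemi}
#'   regions.
#' @export
makeGraph <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@nRegionsPerHemi
  dims <- .gridDims(n)
  edges <- NULL
  hemi <- character()
  for (h in c("LH", "RH")) {
    ids <- .hemiRegionNames(h, n)
    hemi <- c(hemi, stats::setNames(rep(h, n), ids))
    # row-major grid: region (i, j) at index (i-1)*c + j
    r <- dims[1L]; cc <- dims[2L]
    idx <- matrix(seq_len(n), nrow = r, ncol = cc, byrow = TRUE)
    right <- cbind(ids[idx[, -cc, drop = FALSE]], ids[idx[, -1L, drop = FALSE]])
    down <- cbind(ids[idx[-r, , drop = FALSE]], ids[idx[-1L, , drop = FALSE]])
    edges <- rbind(edges, right, down)
  }
  parcellationGraph(regionIds = names(hemi), hemisphere = hemi, edges = edges)
}

# deterministic contiguous region set: breadth-first growth from the
# lattice centre of the chosen hemisphere
.effectRegions <- function(graph, config) {
  k <- config@effectNRegions
  if (k == 0L) return(character())
  ids <- regionIds(graph)
  inHemi <- hemispheres(graph) == config@effectHemi
  cand <- ids[inHemi]
  # row-major grid: the geometric centre cell, so the planted blob is
  # compact and away from the lattice boundary
  dims <- .gridDims(length(cand))
  seedRegion <- cand[(ceiling(dims[1L] / 2) - 1L) * dims[2L] +
                       ceiling(dims[2L] / 2)]
  nbr <- .neighborList(graph)
  pos <- match(seedRegion, ids)
  chosen <- pos
  frontier <- pos
  while (length(chosen) < k && length(frontier)) {
    nxt <- sort(unique(unlist(nbr[frontier])))
    nxt <- setdiff(nxt, chosen)
    frontier <- nxt
    chosen <- c(chosen, nxt)
  }
  if (length(chosen) < k)
    stop("cannot grow a connected effect set of ", k, " regions")
  sort(ids[chosen[seq_len(k)]])
}

#' Simulate a two-group, two-timepoint cohort
#'
#' Draws a cohort under the generative model
#' \deqn{TP1_{sr} = b_r + u_s + \epsilon_{sr},\qquad
#'       TP2_{sr} = b_r + u_s + d + \delta\,1[s \in B]\,1[r \in E] +
#'       \epsilon'_{sr}}
#' with region baselines \eqn{b_r}, subject intercepts
#' \eqn{u_s \sim N(0, \sigma_u^2)}, independent noise
#' \eqn{\epsilon \sim N(0, \sigma_e^2)}, common drift \eqn{d}, and an
#' additive shift \eqn{\delta} for exposed subjects in the planted region
#' set \eqn{E}. \eqn{\delta} is calibrated by a delta-method argument so
#' that the expected Hedges g of the SPC group difference in effect regions
#' equals \code{effectSize}: the SPC difference of means is
#' \eqn{\approx 100\delta/(2 b_r)} with within-group SD
#' \eqn{\approx 100\sqrt{2}\sigma_e/(2 b_r)}, hence
#' \eqn{\delta = g\sqrt{2}\sigma_e} independent of the baseline.
#'
#' Covariates: head-movement index (surface Euler number) and haematocrit
#' per timepoint, cluster-relevant thickness change, demographics, and
#' behavioural change scores (sleepiness on the KSS, vigilance-lapse count
#' and reaction-time summaries) drawn with group-specific means mirroring
#' the emulated study design. Any draw making \code{TP1 + TP2 <= 0} is
#' redrawn so the symmetrised percentage change is defined everywhere.
#'
#' @param graph parcellation from [makeGraph()] (or any
#'   \linkS4class{ParcellationGraph} covering the configured region count).
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{CohortTable}; \code{metadata()} records the
#'   config, seed, planted region set and the calibrated \eqn{\delta}.
#' @export
simulateCohort <- function(graph, config) {
  stopifnot(is(graph, "ParcellationGraph"), is(config, "SimulationConfig"))
  set.seed(config@seed)
  ids <- regionIds(graph)
  R <- length(ids)
  nA <- config@nGroupA; nB <- config@nGroupB
  n <- nA + nB
  subjects <- sprintf("S%02d", seq_len(n))
  group <- factor(rep(c("NSW", "SD"), c(nA, nB)), levels = c("NSW", "SD"))

  effect <- .effectRegions(graph, config)
  delta <- config@effectSize * sqrt(2) * config@noiseSd

  b <- stats::rnorm(R, config@baselineMean, config@baselineSd)
  for (i in 1:100) {
    low <- b <= 0
    if (!any(low)) break
    b[low] <- stats::rnorm(sum(low), config@baselineMean, config@baselineSd)
  }
  if (any(b <= 0))
    stop("baseline distribution places too much mass at non-positive values")
  u <- stats::rnorm(n, 0, config@subjectSd)

  base <- outer(b, u, `+`)               # regions x subjects
  shift <- matrix(0, R, n)
  shift[match(effect, ids), group == "SD"] <- delta
  tp1 <- base + matrix(stats::rnorm(R * n, 0, config@noiseSd), R, n)
  tp2 <- base + config@drift + shift +
    matrix(stats::rnorm(R * n, 0, config@noiseSd), R, n)
  for (i in 1:100) {
    bad <- tp1 <= 0 | tp2 <= 0 | (tp1 + tp2) <= 0
    if (!any(bad)) break
    nb <- sum(bad)
    tp1[bad] <- base[bad] + stats::rnorm(nb, 0, config@noiseSd)
    tp2[bad] <- base[bad] + config@drift + shift[bad] +
      stats::rnorm(nb, 0, config@noiseSd)
  }
  if (any(tp1 <= 0 | tp2 <= 0))
    stop("positivity unattainable under the configured baseline and noise")
  dimnames(tp1) <- dimnames(tp2) <- list(ids, subjects)

  gshift <- function(amount) if (config@covariateGroupEffect)
    amount * (group == "SD") else 0
  sd2 <- group == "SD"
  covariates <- data.frame(
    eulerTP1 = round(stats::rnorm(n, -40, 15) + gshift(-15)),
    eulerTP2 = round(stats::rnorm(n, -40, 15) + gshift(-15)),
    hctTP1 = stats::rnorm(n, 0.42, 0.03),
    hctTP2 = stats::rnorm(n, 0.42, 0.03) + gshift(-0.01),
    thicknessChange = stats::rnorm(n, 0, 0.02),
    age = round(stats::rnorm(n, 26, 7)),
    sex = stats::rbinom(n, 1L, 0.63),
    deltaKSS = ifelse(sd2, stats::rnorm(n, 2.2, 3.0), stats::rnorm(n, -0.6, 1.5)),
    deltaLapses = round(ifelse(sd2, stats::rnorm(n, 3.9, 6.5),
                               stats::rnorm(n, 1.4, 3.3))),
    deltaMedianRT = ifelse(sd2, stats::rnorm(n, 40, 35), stats::rnorm(n, 5, 15)),
    deltaVarRT = ifelse(sd2, stats::rnorm(n, 4000, 5000),
                        stats::rnorm(n, 200, 1500)),
    row.names = subjects
  )

  out <- cohortTable(tp1, tp2, group, covariates,
                     hemisphere = hemispheres(graph), depth = 50)
  metadata(out)$seed <- config@seed
  metadata(out)$config <- config
  metadata(out)$effectRegions <- effect
  metadata(out)$delta <- delta
  out
}
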
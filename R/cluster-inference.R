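#' Form clusters of supra-threshold regions
#'
#' A cluster is a maximal connected set of adjacent regions whose
#' uncorrected model p-value lies strictly below the cluster-forming
#' threshold. Connectivity is taken from the parcellation adjacency, so a
#' cluster never spans hemispheres.
#'
#' @param stats region statistics from [fitRegionModels()]; rownames must
#'   cover every graph region.
#' @param graph a \linkS4class{ParcellationGraph}.
#' @param threshold cluster-forming p threshold in (0, 1); default 0.05.
#' @return List of character vectors (member regions per cluster), largest
#'   first; empty list when no region is supra-threshold.
#' @export
formClusters <- function(stats, graph, threshold = 0.05) {
  stopifnot(is(graph, "ParcellationGraph"),
            threshold > 0, threshold < 1)
  missing <- setdiff(regionIds(graph), rownames(stats))
  if (length(missing))
    stop("stats table lacks graph region(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  p <- stats$p[match(regionIds(graph), rownames(stats))]
  supra <- regionIds(graph)[p < threshold]
  connectedComponents(graph, supra)
}

#' Permutation null of the maximum cluster size
#'
#' Repeats the region-wise group analysis under random relabelings of group
#' membership: in each permutation the group labels are shuffled across
#' subjects (covariates and outcomes stay attached to their subjects), the
#' full region-wise model is refit, supra-threshold regions are clustered
#' on the adjacency graph, and the size of the largest cluster anywhere on
#' the graph is recorded (0 when no region is supra-threshold). The
#' resulting distribution is the family-wise null against which observed
#' cluster sizes are compared.
#'
#' Labelings are sampled uniformly with replacement (standard Monte Carlo);
#' when the number of distinct labelings \eqn{\binom{n}{n_A}} does not
#' exceed \code{nPermutations} the null is instead enumerated exhaustively,
#' once per labeling (with a message), which makes small-cohort nulls
#' exact.
#'
#' @inheritParams formClusters
#' @param change a \linkS4class{ChangeMatrix}.
#' @param group two-level factor over subjects (or a
#'   \linkS4class{CohortTable}).
#' @param covariates optional complete numeric covariates, kept fixed to
#'   subjects across permutations.
#' @param nPermutations number of permutations (default 5000).
#' @param seed RNG seed for reproducibility.
#' @param scheme \code{"auto"} (exhaustive when feasible), \code{"montecarlo"}
#'   or \code{"exhaustive"}.
#' @return Integer vector of maximum cluster sizes, with attributes
#'   \code{exhaustive} (logical) and \code{seed}.
#' @export
permutationNull <- function(change, group, graph, covariates = NULL,
                            threshold = 0.05, nPermutations = 5000L,
                            seed = NULL,
                            scheme = c("auto", "montecarlo", "exhaustive")) {
  stopifnot(is(change, "ChangeMatrix"), nPermutations >= 1L)
  scheme <- match.arg(scheme)
  if (is(group, "CohortTable")) group <- cohortGroups(group)
  group <- as.factor(group)
  Y <- change@values
  ids <- regionIds(graph)
  if (!setequal(colnames(Y), ids))
    stop("change matrix regions do not match the graph")
  Y <- Y[, ids, drop = FALSE]
  n <- nrow(Y)
  X <- .designMatrix(group, covariates)
  nbr <- .neighborList(graph)
  df <- n - ncol(X)
  tcrit <- stats::qt(1 - threshold / 2, df)
  isB <- X[, 2L] == 1
  nB <- sum(isB)

  nDistinct <- suppressWarnings(choose(n, nB))
  exhaustive <- scheme == "exhaustive" ||
    (scheme == "auto" && is.finite(nDistinct) && nDistinct <= nPermutations)
  if (exhaustive) {
    if (scheme != "exhaustive")
      message("only ", nDistinct, " distinct labelings; enumerating the ",
              "null exhaustively")
    labelSets <- utils::combn(n, nB, simplify = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    labelSets <- NULL
  }
  B <- if (exhaustive) length(labelSets) else as.integer(nPermutations)

  maxSizes <- integer(B)
  gvec <- numeric(n)
  for (b in seq_len(B)) {
    gvec[] <- 0
    if (exhaustive) gvec[labelSets[[b]]] <- 1
    else gvec[sample.int(n, nB)] <- 1
    X[, 2L] <- gvec
    fit <- .regionOLS(X, Y, pvalues = FALSE)
    supra <- which(abs(fit$t) > tcrit)
    maxSizes[b] <- .maxComponentSize(supra, nbr)
  }
  structure(maxSizes, exhaustive = exhaustive,
            seed = if (exhaustive) NA_integer_ else seed)
}

#' Corrected p-values for observed clusters
#'
#' Compares each observed cluster's size with the permutation null of the
#' maximum cluster size. The add-one convention
#' \eqn{p = (1 + \#\{null \ge k\})/(1 + B)} keeps p strictly positive, so a
#' cluster larger than every one of 5000 permutation maxima gets
#' \eqn{p = 1/5001 \approx 0.0002}, reported as p < 0.0005 rather than 0.
#' Clusters of equal size get identical corrected p (the statistic is size
#' only).
#'
#' @param clusters list of region-id sets from [formClusters()].
#' @param nullMaxSizes integer vector from [permutationNull()].
#' @inheritParams formClusters
#' @param seed seed recorded in the result (taken from the null's
#'   attribute when present).
#' @return A \linkS4class{ClusterResult}.
#' @export
clusterPValues <- function(clusters, nullMaxSizes, graph, threshold = 0.05,
                           seed = NULL) {
  stopifnot(length(nullMaxSizes) >= 1L)
  sizes <- vapply(clusters, length, 1L)
  B <- length(nullMaxSizes)
  pcorr <- vapply(sizes, function(k)
    (1 + sum(nullMaxSizes >= k)) / (1 + B), 0)
  hemi <- vapply(clusters, function(cl) {
    h <- unique(hemispheres(graph)[cl])
    if (length(h) != 1L) stop("cluster spans hemispheres")
    h
  }, "")
  if (is.null(seed)) seed <- attr(nullMaxSizes, "seed") %||% NA_integer_
  new("ClusterResult",
      clusters = clusters,
      hemisphere = hemi,
      correctedP = pcorr,
      nullMaxSizes = as.integer(nullMaxSizes),
      threshold = threshold,
      nPermutations = B,
      seed = as.integer(seed))
}

#' Cluster-corrected group comparison
#'
#' The main inferential step: fit the region-wise model on the observed
#' labels, form clusters of adjacent supra-threshold regions, build the
#' permutation null of the maximum cluster size, and assign family-wise
#' corrected p-values. One pooled null over the whole graph (both
#' hemispheres) controls the family-wise error across all reported
#' clusters.
#'
#' @inheritParams permutationNull
#' @return A list with \code{stats} (the region table), \code{clusters}
#'   (a \linkS4class{ClusterResult}), and \code{threshold}.
#' @examples
#' cfg <- simulationConfig(nRegionsPerHemi = 16, effectSize = 0, seed = 7)
#' g <- makeGraph(cfg)
#' cohort <- simulateCohort(g, cfg)
#' res <- clusterCorrect(computeSPC(cohort), cohort, g,
#'                       nPermutations = 99, seed = 7)
#' res$clusters
#' @export
clusterCorrect <- function(change, group, graph, covariates = NULL,
                           threshold = 0.05, nPermutations = 5000L,
                           seed = NULL,
                           scheme = c("auto", "montecarlo", "exhaustive")) {
  if (is(group, "CohortTable")) group <- cohortGroups(group)
  stats <- fitRegionModels(change, group, covariates)
  clusters <- formClusters(stats, graph, threshold)
  nullMax <- permutationNull(change, group, graph, covariates,
                             threshold, nPermutations, seed,
                             match.arg(scheme))
  list(stats = stats,
       clusters = clusterPValues(clusters, nullMax, graph, threshold, seed),
       threshold = threshold)
}

#' Accessors for ClusterResult
#'
#' @param x a \linkS4class{ClusterResult}.
#' @return \code{clusterRegions}: list of member-region sets;
#'   \code{clusterSizes}: integer sizes; \code{correctedP}: corrected
#'   p-values; \code{nullMaxSizes}: the permutation null.
#' @name clusterResult-accessors
NULL

#' @rdname clusterResult-accessors
#' @export
setMethod("clusterRegions", "ClusterResult", function(x) x@clusters)

#' @rdname clusterResult-accessors
#' @export
setMethod("clusterSizes", "ClusterResult",
          function(x) vapply(x@clusters, length, 1L))

#' @rdname clusterResult-accessors
#' @export
setMethod("correctedP", "ClusterResult", function(x) x@correctedP)

#' @rdname clusterResult-accessors
#' @export
setMethod("nullMaxSizes", "ClusterResult", function(x) x@nullMaxSizes)

setMethod("show", "ClusterResult", function(object) {
  k <- length(object@clusters)
  cat(sprintf(
    "ClusterResult: %d cluster(s), forming threshold p < %g, %d permutations\n",
    k, object@threshold, object@nPermutations))
  if (k) {
    df <- data.frame(
      size = vapply(object@clusters, length, 1L),
      hemisphere = object@hemisphere,
      corrected_p = signif(object@correctedP, 3L)
    )
    rownames(df) <- paste0("C", seq_len(k))
    print(df)
  }
})

#' Tabulate a ClusterResult
#'
#' @param x a \linkS4class{ClusterResult}.
#' @return data.frame with cluster id, hemisphere, size, corrected p and a
#'   comma-separated member list — the table the pipeline writes to disk.
#' @export
clusterTable <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  k <- length(x@clusters)
  data.frame(
    cluster = if (k) paste0("C", seq_len(k)) else character(),
    hemisphere = x@hemisphere,
    size = vapply(x@clusters, length, 1L),
    corrected_p = x@correctedP,
    regions = vapply(x@clusters, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
}
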
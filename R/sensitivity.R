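#' Per-subject cluster means
#'
#' Averages the change outcome over a cluster's member regions for every
#' subject — the cluster-level summary on which all sensitivity and
#' interaction analyses operate.
#'
#' @param change a \linkS4class{ChangeMatrix}.
#' @param clusters a \linkS4class{ClusterResult} or a plain list of
#'   region-id sets.
#' @param which indices of clusters to extract (default all).
#' @return Numeric matrix, subjects x clusters, columns \code{C1, C2, ...}.
#' @export
extractClusterMeans <- function(change, clusters, which = NULL) {
  stopifnot(is(change, "ChangeMatrix"))
  sets <- if (is(clusters, "ClusterResult")) clusterRegions(clusters)
          else clusters
  if (!length(sets)) stop("no clusters to extract")
  if (!is.null(which)) sets <- sets[which]
  Y <- change@values
  unknown <- setdiff(unlist(sets), colnames(Y))
  if (length(unknown))
    stop("cluster references unknown region(s): ",
         paste(unknown, collapse = ", "))
  out <- vapply(sets, function(cl)
    rowMeans(Y[, cl, drop = FALSE]), numeric(nrow(Y)))
  out <- matrix(out, nrow = nrow(Y),
                dimnames = list(rownames(Y), paste0("C", seq_along(sets))))
  out
}

#' Covariate-adjusted cluster-level group test
#'
#' Refits the group comparison on each cluster's mean change, adding
#' nuisance covariates (typically the haematocrit change as a hydration
#' index and the cluster-mean cortical thickness change). The question it
#' answers: does the cluster-level group difference survive adjustment?
#'
#' @param clusterMeans subjects x clusters matrix from
#'   [extractClusterMeans()].
#' @param group two-level factor (or \linkS4class{CohortTable}).
#' @param covariates data.frame/matrix of per-subject adjustment covariates,
#'   complete.
#' @param onConstant what to do with a zero-variance covariate:
#'   \code{"error"} (default) or \code{"drop"} with a warning.
#' @return data.frame per cluster: \code{beta} (group coefficient),
#'   \code{t}, \code{df}, \code{p}.
#' @export
covariateAdjustedTest <- function(clusterMeans, group, covariates,
                                  onConstant = c("error", "drop")) {
  onConstant <- match.arg(onConstant)
  if (is(group, "CohortTable")) group <- cohortGroups(group)
  covariates <- as.matrix(as.data.frame(covariates))
  const <- apply(covariates, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    if (onConstant == "error")
      stop("constant covariate(s): ",
           paste(colnames(covariates)[const], collapse = ", "))
    warning("dropping constant covariate(s): ",
            paste(colnames(covariates)[const], collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  X <- .designMatrix(group, covariates)
  fit <- .regionOLS(X, as.matrix(clusterMeans))
  data.frame(beta = fit$beta, t = fit$t, df = fit$df, p = fit$p,
             row.names = colnames(clusterMeans))
}

#' Exclude a subject and rerun the cluster analysis
#'
#' Reruns the full pipeline (change metric, region models, cluster
#' formation, permutation null) on the cohort without one subject, as done
#' when a single participant drives extreme cluster values. Reports the
#' clusters before and after plus a stability comparison.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param graph a \linkS4class{ParcellationGraph}.
#' @param subjectId subject to exclude.
#' @param metric \code{"SPC"} or \code{"RAW_DIFF"}.
#' @param useEuler include the head-movement index as covariate.
#' @inheritParams permutationNull
#' @return A list: \code{before} and \code{after} (each as returned by
#'   [clusterCorrect()]) and \code{comparison}, a data.frame of significant
#'   cluster counts/region totals and the Jaccard overlap of significant
#'   region sets.
#' @export
excludeAndRerun <- function(cohort, graph, subjectId,
                            metric = c("SPC", "RAW_DIFF"),
                            useEuler = TRUE, threshold = 0.05,
                            nPermutations = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  runOne <- function(coh) {
    change <- if (metric == "SPC") computeSPC(coh) else computeRawDiff(coh)
    covs <- if (useEuler) headMovementIndex(coh) else NULL
    clusterCorrect(change, coh, graph, covs, threshold, nPermutations, seed)
  }
  before <- runOne(cohort)
  after <- runOne(dropSubject(cohort, subjectId))
  sigRegions <- function(res) {
    cr <- res$clusters
    sig <- correctedP(cr) < 0.05
    sort(unique(unlist(clusterRegions(cr)[sig])))
  }
  a <- sigRegions(before); b <- sigRegions(after)
  uni <- union(a, b)
  list(before = before, after = after,
       comparison = data.frame(
         significant_clusters = c(sum(correctedP(before$clusters) < 0.05),
                                  sum(correctedP(after$clusters) < 0.05)),
         significant_regions = c(length(a), length(b)),
         jaccard = rep(if (length(uni)) length(intersect(a, b)) / length(uni)
                       else NA_real_, 2L),
         row.names = c("before", "after")))
}

#' Flag extreme cluster-mean values (optional screening aid)
#'
#' Marks subjects whose cluster mean lies more than \code{k} interquartile
#' ranges from the cluster median. This is a screening extension: exclusion
#' itself stays an explicit, by-id decision via [excludeAndRerun()].
#'
#' @param clusterMeans subjects x clusters matrix.
#' @param k IQR multiplier (default 3).
#' @return Logical matrix of the same shape.
#' @export
flagOutliers <- function(clusterMeans, k = 3) {
  apply(clusterMeans, 2L, function(v)
    abs(v - stats::median(v)) > k * stats::IQR(v))
}

#' Rerun the pipeline at each cortical depth
#'
#' The measure can be sampled at several depths into the cortex (30/50/70%);
#' each depth's table gets an independent full analysis, and the overlap of
#' significant regions across depths is reported. Each rerun is a pure
#' function of its own table: depths never mix.
#'
#' @param cohorts named list of \linkS4class{CohortTable}s (e.g.
#'   \code{list(`30` = ..., `50` = ..., `70` = ...)}), sharing subjects and
#'   regions.
#' @inheritParams excludeAndRerun
#' @return A list: \code{results} (per-depth [clusterCorrect()] output) and
#'   \code{overlap}, the Jaccard matrix of significant region sets between
#'   depths.
#' @export
runDepthSensitivity <- function(cohorts, graph,
                                metric = c("SPC", "RAW_DIFF"),
                                useEuler = TRUE, threshold = 0.05,
                                nPermutations = 1000L, seed = NULL) {
  metric <- match.arg(metric)
  ref <- cohorts[[1L]]
  for (nm in names(cohorts)) {
    if (!identical(colnames(cohorts[[nm]]), colnames(ref)) ||
        !identical(rownames(cohorts[[nm]]), rownames(ref)))
      stop("depth table '", nm, "' does not share subjects/regions")
  }
  results <- lapply(cohorts, function(coh) {
    change <- if (metric == "SPC") computeSPC(coh) else computeRawDiff(coh)
    covs <- if (useEuler) headMovementIndex(coh) else NULL
    clusterCorrect(change, coh, graph, covs, threshold, nPermutations, seed)
  })
  sig <- lapply(results, function(res) {
    cr <- res$clusters
    sort(unique(unlist(clusterRegions(cr)[correctedP(cr) < 0.05])))
  })
  d <- length(sig)
  overlap <- matrix(NA_real_, d, d, dimnames = list(names(sig), names(sig)))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    uni <- union(sig[[i]], sig[[j]])
    overlap[i, j] <- if (length(uni))
      length(intersect(sig[[i]], sig[[j]])) / length(uni) else NA_real_
  }
  list(results = results, overlap = overlap)
}

#' Summarise uncorrected p-values over a region subset
#'
#' Order statistics (median, min, max) of the uncorrected region p-values
#' over a named subset — used to ask whether regions significant only in
#' one hemisphere show sub-threshold trends in their homotopic counterparts.
#'
#' @param stats region table from [fitRegionModels()].
#' @param regions nonempty character vector of region ids.
#' @return Named numeric vector \code{median}, \code{min}, \code{max}.
#' @export
summarizeRegionPvalues <- function(stats, regions) {
  regions <- as.character(regions)
  if (!length(regions)) stop("empty region subset")
  missing <- setdiff(regions, rownames(stats))
  if (length(missing))
    stop("unknown region(s): ", paste(missing, collapse = ", "))
  p <- stats[regions, "p"]
  c(median = stats::median(p), min = min(p), max = max(p))
}

#' Map regions to their homotopic counterparts
#'
#' Homotopy (the LH/RH pairing of parcels) is supplied as data, a
#' two-column pair map; nothing is inferred from region names.
#'
#' @param regions region ids to map.
#' @param pairs two-column data.frame/matrix of paired region ids (either
#'   order).
#' @return Character vector of counterparts, in input order.
#' @export
mapHomotopic <- function(regions, pairs) {
  pairs <- as.matrix(pairs)
  lut <- c(stats::setNames(pairs[, 2L], pairs[, 1L]),
           stats::setNames(pairs[, 1L], pairs[, 2L]))
  missing <- setdiff(regions, names(lut))
  if (length(missing))
    stop("no homotopic counterpart for: ", paste(missing, collapse = ", "))
  unname(lut[regions])
}
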
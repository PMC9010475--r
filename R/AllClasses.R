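#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
NULL

#' ParcellationGraph: region adjacency of a cortical parcellation
#'
#' Holds the regions of a parcellation, their hemisphere membership, and the
#' border-adjacency edges between them. Clusters of supra-threshold regions
#' are connected components of this graph, so it is the substrate for all
#' cluster-level inference. Hemispheres are disjoint components: no edge may
#' join a left-hemisphere region to a right-hemisphere one.
#'
#' @slot regionIds character vector of unique region identifiers, in a fixed
#'   order that all region-indexed results follow.
#' @slot hemisphere named character vector, one of \code{"LH"}/\code{"RH"}
#'   per region.
#' @slot edges two-column character matrix of unordered region pairs, one row
#'   per border; duplicates and self-loops are rejected by the validity check.
#'
#' @seealso [parcellationGraph()], [loadAdjacency()], [connectedComponents()]
#' @export
setClass("ParcellationGraph",
  representation(
    regionIds = "character",
    hemisphere = "character",
    edges = "matrix"
  )
)

setValidity("ParcellationGraph", function(object) {
  msg <- character()
  ids <- object@regionIds
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicated region ids")
  hemi <- object@hemisphere
  if (!setequal(names(hemi), ids) || length(hemi) != length(ids))
    msg <- c(msg, "hemisphere map must cover exactly the region ids")
  if (!all(hemi %in% c("LH", "RH")))
    msg <- c(msg, "hemisphere labels must be 'LH' or 'RH'")
  e <- object@edges
  if (ncol(e) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L]))
      msg <- c(msg, "self-loop edges are not allowed")
    unknown <- setdiff(c(e), ids)
    if (length(unknown))
      msg <- c(msg, paste0("edge endpoint(s) not in region ids: ",
                           paste(unknown, collapse = ", ")))
    else {
      cross <- hemi[e[, 1L]] != hemi[e[, 2L]]
      if (any(cross))
        msg <- c(msg, paste0("edge(s) join LH to RH: ",
                             paste(e[cross, 1L], e[cross, 2L],
                                   sep = "--", collapse = ", ")))
    }
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated edges")
  }
  if (length(msg)) msg else TRUE
})

#' CohortTable: a two-timepoint, two-group regional measure cohort
#'
#' A \linkS4class{SummarizedExperiment} with regions as rows and subjects as
#' columns, carrying the two timepoint measurements as assays \code{"tp1"}
#' and \code{"tp2"} (e.g. regional T1w/T2w ratio), the group label and any
#' per-subject covariates in \code{colData}, and the hemisphere label per
#' region in \code{rowData}. Measure values must be strictly positive and
#' complete so that the symmetrised percentage change is defined everywhere.
#'
#' @seealso [cohortTable()], [simulateCohort()], [computeSPC()]
#' @export
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("tp1", "tp2") %in% an))
    return("assays 'tp1' and 'tp2' are required")
  for (a in c("tp1", "tp2")) {
    v <- assay(object, a)
    if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, sprintf("assay '%s' contains missing or non-finite values", a))
    else if (any(v <= 0))
      msg <- c(msg, sprintf("assay '%s' contains non-positive values", a))
  }
  cd <- colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- cd$group
    if (!is.factor(g) || nlevels(g) != 2L)
      msg <- c(msg, "'group' must be a factor with exactly two levels")
    else if (!all(levels(g) %in% as.character(g)))
      msg <- c(msg, "both group levels must be present")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique region rownames are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique subject colnames are required")
  if (length(msg)) msg else TRUE
})

#' ChangeMatrix: per-subject, per-region change in the outcome
#'
#' Subjects-by-regions matrix of the change metric: symmetrised percentage
#' change (\code{"SPC"}, in percent, bounded in (-100, 100) for positive
#' inputs) or the raw between-timepoint difference (\code{"RAW_DIFF"}, in
#' the units of the measure).
#'
#' @slot values numeric matrix, subjects in rows, regions in columns.
#' @slot metric \code{"SPC"} or \code{"RAW_DIFF"}.
#' @slot depth cortical sampling depth in percent (30/50/70), \code{NA} if
#'   not applicable.
#' @seealso [computeSPC()], [computeRawDiff()], [fitRegionModels()]
#' @export
setClass("ChangeMatrix",
  representation(values = "matrix", metric = "character", depth = "numeric")
)

setValidity("ChangeMatrix", function(object) {
  msg <- character()
  if (!object@metric %in% c("SPC", "RAW_DIFF"))
    msg <- c(msg, "metric must be 'SPC' or 'RAW_DIFF'")
  v <- object@values
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "change values must be complete and finite")
  else if (object@metric == "SPC" && any(abs(v) >= 100))
    msg <- c(msg, "SPC values must lie strictly in (-100, 100)")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "subject rownames and region colnames are required")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: clusters of adjacent supra-threshold regions with
#' permutation-corrected p-values
#'
#' The result of the cluster-size correction: each observed cluster (a
#' connected set of regions whose uncorrected model p fell below the
#' cluster-forming threshold) with its size, hemisphere and family-wise
#' corrected p-value, plus the permutation null distribution of the maximum
#' cluster size from which the corrected p-values were computed.
#'
#' @slot clusters list of character vectors, the member regions per cluster,
#'   ordered by decreasing size (ties broken by smallest member id).
#' @slot hemisphere character, hemisphere of each cluster.
#' @slot correctedP numeric, corrected p per cluster (add-one convention, so
#'   never exactly zero).
#' @slot nullMaxSizes integer vector of maximum cluster sizes across the
#'   permutations (0 when a permutation produced no cluster).
#' @slot threshold cluster-forming p threshold.
#' @slot nPermutations length of the null.
#' @slot seed RNG seed used for the permutations (NA when exhaustive).
#' @seealso [clusterCorrect()], [clusterPValues()], [permutationNull()]
#' @export
setClass("ClusterResult",
  representation(
    clusters = "list",
    hemisphere = "character",
    correctedP = "numeric",
    nullMaxSizes = "integer",
    threshold = "numeric",
    nPermutations = "integer",
    seed = "integer"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  k <- length(object@clusters)
  if (length(object@correctedP) != k || length(object@hemisphere) != k)
    msg <- c(msg, "clusters, hemisphere and correctedP lengths differ")
  if (k && (any(object@correctedP <= 0) || any(object@correctedP > 1)))
    msg <- c(msg, "corrected p must lie in (0, 1]")
  if (length(object@nullMaxSizes) != object@nPermutations)
    msg <- c(msg, "null length must equal nPermutations")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' Bundles every knob of the synthetic study: group sizes (defaults 23
#' normal sleep-wake vs 18 sleep-deprived, the design the generator
#' emulates), the parcellation lattice size, where and how strong the
#' planted group-differential change is, the variance components, and the
#' covariate distributions. The planted effect size is expressed on the
#' Hedges-g scale of the SPC group difference, so it is directly comparable
#' to reported cluster effect sizes.
#'
#' @seealso [simulationConfig()], [makeGraph()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nGroupA = "integer", nGroupB = "integer",
    nRegionsPerHemi = "integer",
    graphKind = "character",
    effectNRegions = "integer",
    effectSize = "numeric",
    effectHemi = "character",
    baselineMean = "numeric", baselineSd = "numeric",
    subjectSd = "numeric", noiseSd = "numeric",
    drift = "numeric",
    covariateGroupEffect = "logical",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nGroupA < 2L || object@nGroupB < 2L)
    msg <- c(msg, "at least 2 subjects per group")
  if (object@nRegionsPerHemi < 1L)
    msg <- c(msg, "nRegionsPerHemi must be >= 1")
  if (!object@graphKind %in% "lattice")
    msg <- c(msg, "graphKind must be 'lattice'")
  if (any(c(object@baselineSd, object@subjectSd, object@noiseSd) < 0))
    msg <- c(msg, "standard deviations must be >= 0")
  if (object@effectNRegions < 0L ||
      object@effectNRegions > object@nRegionsPerHemi)
    msg <- c(msg, "effectNRegions must be between 0 and nRegionsPerHemi")
  if (!object@effectHemi %in% c("LH", "RH"))
    msg <- c(msg, "effectHemi must be 'LH' or 'RH'")
  if (object@baselineMean <= 0)
    msg <- c(msg, "baselineMean must be positive (ratio measures are positive)")
  if (length(msg)) msg else TRUE
})
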
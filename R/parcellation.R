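#' Construct a ParcellationGraph
#'
#' Builds and validates the region-adjacency graph of a parcellation from an
#' edge list and a hemisphere map. Duplicate edges (including reversed
#' duplicates) are collapsed and each edge is stored with its endpoints in
#' lexicographic order, so two graphs built from differently ordered edge
#' lists compare equal.
#'
#' @param regionIds character vector of unique region identifiers. If
#'   missing, taken as the sorted names of \code{hemisphere}.
#' @param hemisphere named character vector (\code{"LH"}/\code{"RH"}) or a
#'   two-column data.frame of region id and hemisphere.
#' @param edges two-column matrix or data.frame of region-id pairs, one
#'   border per row. May be empty (isolated regions).
#' @param crossHemisphereEdges what to do with an edge joining the two
#'   hemispheres: \code{"error"} (default) or \code{"drop"} with a warning.
#'
#' @return A validated \linkS4class{ParcellationGraph}.
#' @examples
#' g <- parcellationGraph(
#'   hemisphere = c(A = "LH", B = "LH", C = "LH"),
#'   edges = rbind(c("A", "B"), c("B", "A"), c("B", "C"))
#' )
#' nRegions(g)   # 3
#' edgeMatrix(g) # 2 edges: the duplicate A-B is collapsed
#' @export
parcellationGraph <- function(regionIds, hemisphere, edges = NULL,
                              crossHemisphereEdges = c("error", "drop")) {
  crossHemisphereEdges <- match.arg(crossHemisphereEdges)
  if (is.data.frame(hemisphere)) {
    hemisphere <- stats::setNames(as.character(hemisphere[[2L]]),
                                  as.character(hemisphere[[1L]]))
  }
  if (missing(regionIds)) regionIds <- sort(names(hemisphere))
  regionIds <- as.character(regionIds)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("edge list must have exactly two columns")
  }
  unknown <- setdiff(c(edges), names(hemisphere))
  if (length(unknown))
    stop("region(s) in edge list missing from hemisphere map: ",
         paste(sort(unique(unknown)), collapse = ", "))
  if (nrow(edges)) {
    # normalise order, drop self-loops deliberately kept as errors downstream
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    keep <- !duplicated(paste(a, b))
    edges <- cbind(a[keep], b[keep])
    cross <- hemisphere[edges[, 1L]] != hemisphere[edges[, 2L]]
    if (any(cross) && crossHemisphereEdges == "drop") {
      warning(sum(cross), " cross-hemisphere edge(s) dropped")
      edges <- edges[!cross, , drop = FALSE]
    }
  }
  colnames(edges) <- c("from", "to")
  new("ParcellationGraph", regionIds = regionIds,
      hemisphere = hemisphere[regionIds], edges = edges)
}

#' Load a ParcellationGraph from edge-list and hemisphere-map files
#'
#' @param edgePath path to a two-column tab-separated edge list, one border
#'   per line.
#' @param hemispherePath path to a two-column tab-separated file of region id
#'   and hemisphere (\code{LH}/\code{RH}).
#' @param header logical; whether the files carry a header line.
#' @param crossHemisphereEdges passed to [parcellationGraph()].
#' @return A \linkS4class{ParcellationGraph}.
#' @export
loadAdjacency <- function(edgePath, hemispherePath, header = TRUE,
                          crossHemisphereEdges = c("error", "drop")) {
  for (p in c(edgePath, hemispherePath))
    if (!file.exists(p)) stop("file not found: ", p)
  hemi <- utils::read.delim(hemispherePath, header = header,
                            colClasses = "character")
  edges <- utils::read.delim(edgePath, header = header,
                             colClasses = "character")
  if (nrow(edges) && ncol(edges) != 2L)
    stop("edge list must have exactly two columns")
  parcellationGraph(hemisphere = hemi, edges = edges,
                    crossHemisphereEdges = crossHemisphereEdges)
}

#' @describeIn parcellationGraph Region identifiers, in graph order.
#' @param x a \code{ParcellationGraph}.
#' @export
setMethod("regionIds", "ParcellationGraph", function(x) x@regionIds)

#' @describeIn parcellationGraph Named hemisphere labels per region.
#' @export
setMethod("hemispheres", "ParcellationGraph", function(x) x@hemisphere)

#' @describeIn parcellationGraph Two-column character matrix of edges.
#' @export
setMethod("edgeMatrix", "ParcellationGraph", function(x) x@edges)

#' @describeIn parcellationGraph Number of regions.
#' @export
setMethod("nRegions", "ParcellationGraph", function(x) length(x@regionIds))

setMethod("show", "ParcellationGraph", function(object) {
  tab <- table(object@hemisphere)
  cat("ParcellationGraph with", length(object@regionIds), "regions (",
      paste(names(tab), as.integer(tab), collapse = ", "), ") and",
      nrow(object@edges), "border edges\n")
})

# igraph view of the adjacency, vertices in regionIds order
.asIgraph <- function(graph) {
  igraph::graph_from_data_frame(
    as.data.frame(graph@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph@regionIds,
                          stringsAsFactors = FALSE)
  )
}

# integer adjacency list indexed by position in regionIds; used by the
# permutation loop where igraph object churn would dominate runtime
.neighborList <- function(graph) {
  n <- length(graph@regionIds)
  idx <- seq_len(n)
  names(idx) <- graph@regionIds
  nbr <- vector("list", n)
  for (i in idx) nbr[[i]] <- integer()
  if (nrow(graph@edges)) {
    a <- idx[graph@edges[, 1L]]
    b <- idx[graph@edges[, 2L]]
    for (k in seq_along(a)) {
      nbr[[a[k]]] <- c(nbr[[a[k]]], b[k])
      nbr[[b[k]]] <- c(nbr[[b[k]]], a[k])
    }
  }
  nbr
}

# size of the largest connected component among the supra-threshold
# vertices (integer positions); plain BFS on the precomputed adjacency list
.maxComponentSize <- function(supra, nbr) {
  if (!length(supra)) return(0L)
  inset <- logical(length(nbr))
  inset[supra] <- TRUE
  seen <- logical(length(nbr))
  best <- 0L
  for (v in supra) {
    if (seen[v]) next
    size <- 0L
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      size <- size + 1L
      nb <- nbr[[u]]
      nb <- nb[inset[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    if (size > best) best <- size
  }
  best
}

#' Connected components of a region subset
#'
#' Partitions a subset of regions into maximal connected sets under the
#' subgraph induced by the parcellation adjacency. This is the cluster
#' definition used throughout: a cluster is a set of mutually reachable
#' adjacent regions. Components are returned sorted by decreasing size, ties
#' broken by the lexicographically smallest member, so output order is
#' deterministic.
#'
#' @param graph a \linkS4class{ParcellationGraph}.
#' @param subset character vector of region ids, a subset of
#'   \code{regionIds(graph)}.
#' @return A list of character vectors (each sorted), one per component.
#'   Empty subset gives an empty list.
#' @examples
#' g <- parcellationGraph(hemisphere = c(A = "LH", B = "LH", C = "LH"),
#'                        edges = rbind(c("A", "B"), c("B", "C")))
#' connectedComponents(g, c("A", "C"))  # two singleton components
#' @export
connectedComponents <- function(graph, subset) {
  stopifnot(is(graph, "ParcellationGraph"))
  subset <- as.character(subset)
  bad <- setdiff(subset, graph@regionIds)
  if (length(bad))
    stop("subset region(s) not in graph: ", paste(bad, collapse = ", "))
  if (!length(subset)) return(list())
  ig <- igraph::induced_subgraph(.asIgraph(graph), subset)
  comp <- igraph::components(ig)
  comps <- split(names(comp$membership), comp$membership)
  comps <- lapply(unname(comps), sort)
  ord <- order(-vapply(comps, length, 1L),
               vapply(comps, `[`, "", 1L))
  comps[ord]
}
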
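.changeMatrix <- function(values, metric, depth = NA_real_) {
  out <- new("ChangeMatrix", values = values, metric = metric,
             depth = as.numeric(depth))
  validObject(out)
  out
}

.checkShapes <- function(tp1, tp2) {
  if (!identical(dim(tp1), dim(tp2)))
    stop("timepoint matrices have different shapes: ",
         paste(dim(tp1), collapse = "x"), " vs ",
         paste(dim(tp2), collapse = "x"))
}

#' Symmetrised percentage change
#'
#' The change outcome \eqn{(TP2 - TP1)/(TP2 + TP1) \times 100}: bounded in
#' (-100, 100) for positive measures, antisymmetric under swapping the
#' timepoints, and invariant to rescaling both timepoints by a common
#' factor — which makes it robust to global intensity differences between
#' sessions, unlike plain percentage change.
#'
#' Matrix inputs are taken as subjects by regions; a
#' \linkS4class{CohortTable} supplies both timepoints itself (assays are
#' regions by subjects and are transposed internally).
#'
#' @param tp1,tp2 numeric matrices of identical shape with
#'   \code{tp1 + tp2 > 0} everywhere, or a \code{CohortTable} as \code{tp1}
#'   with \code{tp2} missing.
#' @param ... unused.
#' @return A \linkS4class{ChangeMatrix} with \code{metric == "SPC"}, in
#'   percent.
#' @examples
#' computeSPC(matrix(1, dimnames = list("s1", "r1")),
#'            matrix(3, dimnames = list("s1", "r1")))  # 50%
#' @export
setMethod("computeSPC", signature("matrix", "matrix"), function(tp1, tp2, ...) {
  .checkShapes(tp1, tp2)
  den <- tp1 + tp2
  if (any(den <= 0)) {
    bad <- which(den <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-positive TP1 + TP2 at subject '%s', region '%s': SPC undefined",
      rownames(tp1)[bad[1L]] %||% bad[1L],
      colnames(tp1)[bad[2L]] %||% bad[2L]))
  }
  .changeMatrix((tp2 - tp1) / den * 100, "SPC")
})

#' @rdname computeSPC
#' @export
setMethod("computeSPC", signature("CohortTable", "missing"),
  function(tp1, tp2, ...) {
    cm <- computeSPC(t(assay(tp1, "tp1")), t(assay(tp1, "tp2")))
    cm@depth <- as.numeric(metadata(tp1)$depth %||% NA_real_)
    cm
  })

#' Raw between-timepoint difference
#'
#' The sensitivity-analysis outcome \eqn{TP2 - TP1}, in the measure's own
#' units. Same orientation conventions as [computeSPC()].
#'
#' @inheritParams computeSPC
#' @return A \linkS4class{ChangeMatrix} with \code{metric == "RAW_DIFF"}.
#' @export
setMethod("computeRawDiff", signature("matrix", "matrix"),
  function(tp1, tp2, ...) {
    .checkShapes(tp1, tp2)
    .changeMatrix(tp2 - tp1, "RAW_DIFF")
  })

#' @rdname computeRawDiff
#' @export
setMethod("computeRawDiff", signature("CohortTable", "missing"),
  function(tp1, tp2, ...) {
    cm <- computeRawDiff(t(assay(tp1, "tp1")), t(assay(tp1, "tp2")))
    cm@depth <- as.numeric(metadata(tp1)$depth %||% NA_real_)
    cm
  })

#' Accessors for ChangeMatrix
#'
#' @param x a \linkS4class{ChangeMatrix}.
#' @return \code{changeValues}: the subjects-by-regions numeric matrix;
#'   \code{changeMetric}: \code{"SPC"} or \code{"RAW_DIFF"}.
#' @name changeMatrix-accessors
NULL

#' @rdname changeMatrix-accessors
#' @export
setMethod("changeValues", "ChangeMatrix", function(x) x@values)

#' @rdname changeMatrix-accessors
#' @export
setMethod("changeMetric", "ChangeMatrix", function(x) x@metric)

setMethod("show", "ChangeMatrix", function(object) {
  cat(sprintf("ChangeMatrix (%s%s): %d subjects x %d regions, range [%.3g, %.3g]\n",
              object@metric,
              if (is.na(object@depth)) "" else paste0(", depth ", object@depth, "%"),
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
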
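#' Assemble a CohortTable
#'
#' Builds the central cohort container from two timepoint measure matrices,
#' a group label, and optional per-subject covariates. Matrices are regions
#' by subjects (the usual assay orientation); wide subject-by-region tables
#' read from disk should be transposed first (the file readers do this).
#'
#' @param tp1,tp2 numeric matrices, regions x subjects, strictly positive,
#'   identical dimnames.
#' @param group factor (or coercible) with exactly two levels; the first
#'   level is the reference group (e.g. \code{NSW}), the second the exposed
#'   group (e.g. \code{SD} for sleep-deprived).
#' @param covariates optional data.frame of per-subject covariates (head
#'   movement index, haematocrit, demographics, behaviour change scores).
#' @param hemisphere optional named character vector giving \code{LH}/\code{RH}
#'   per region, stored in \code{rowData}.
#' @param depth cortical sampling depth in percent; stored in metadata.
#'
#' @return A validated \linkS4class{CohortTable}.
#' @export
cohortTable <- function(tp1, tp2, group, covariates = NULL,
                        hemisphere = NULL, depth = NA_real_) {
  tp1 <- as.matrix(tp1); tp2 <- as.matrix(tp2)
  if (!identical(dim(tp1), dim(tp2)))
    stop("tp1 and tp2 dimensions differ")
  if (!identical(dimnames(tp1), dimnames(tp2)))
    stop("tp1 and tp2 dimnames differ")
  if (is.null(rownames(tp1)) || is.null(colnames(tp1)))
    stop("region rownames and subject colnames are required")
  bad <- which(tp1 <= 0 | tp2 <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive measure value at region '%s', subject '%s'",
                 rownames(tp1)[bad[1L, 1L]], colnames(tp1)[bad[1L, 2L]]))
  group <- as.factor(group)
  if (length(group) != ncol(tp1))
    stop("group length must equal the number of subjects")
  cd <- DataFrame(group = group, row.names = colnames(tp1))
  if (!is.null(covariates)) {
    if (nrow(covariates) != ncol(tp1))
      stop("covariates must have one row per subject")
    cd <- cbind(cd, DataFrame(covariates))
  }
  rd <- if (is.null(hemisphere)) DataFrame(row.names = rownames(tp1))
        else DataFrame(hemisphere = hemisphere[rownames(tp1)],
                       row.names = rownames(tp1))
  se <- SummarizedExperiment(assays = list(tp1 = tp1, tp2 = tp2),
                             colData = cd, rowData = rd)
  out <- new("CohortTable", se)
  metadata(out)$depth <- depth
  validObject(out)
  out
}

#' @describeIn cohortTable Group factor of a cohort.
#' @param x a \code{CohortTable}.
#' @export
cohortGroups <- function(x) colData(x)$group

#' @describeIn cohortTable Drop one subject (used by the outlier-exclusion
#'   sensitivity rerun). Errors if the subject is unknown or a group would
#'   fall below two members.
#' @param subjectId subject column name to remove.
#' @export
dropSubject <- function(x, subjectId) {
  stopifnot(is(x, "CohortTable"))
  if (!subjectId %in% colnames(x))
    stop("unknown subject id: ", subjectId)
  out <- x[, setdiff(colnames(x), subjectId)]
  g <- droplevels(cohortGroups(out))
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop("removing subject '", subjectId,
         "' leaves fewer than 2 subjects in a group")
  out
}
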
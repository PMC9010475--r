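# All tabular I/O is header-bearing tab-separated UTF-8 text. Measure
# tables are wide: one subject per row, one region per column, first
# column "subject".

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write / read a wide measure table
#'
#' @param mat regions x subjects numeric matrix (assay orientation).
#' @param path file path.
#' @return \code{readMeasureTable}: regions x subjects matrix.
#' @name measure-io
#' @export
writeMeasureTable <- function(mat, path) {
  df <- data.frame(subject = colnames(mat), t(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTSV(df, path)
  invisible(path)
}

#' @rdname measure-io
#' @export
readMeasureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(subject = "character"))
  if (colnames(df)[1L] != "subject")
    stop("measure table must start with a 'subject' column: ", path)
  if (anyDuplicated(df$subject))
    stop("duplicate subject id(s): ",
         paste(df$subject[duplicated(df$subject)], collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$subject
  t(m)
}

#' Write a cohort to its delimited file set
#'
#' Writes \code{<prefix>_tp1.tsv}, \code{<prefix>_tp2.tsv} (wide measure
#' tables) and \code{<prefix>_covariates.tsv} (subject, group, covariates) —
#' the same files [readCohort()] consumes, so cohorts round-trip.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the three paths.
#' @export
writeCohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_tp1.tsv", "_tp2.tsv",
                                           "_covariates.tsv")))
  writeMeasureTable(assay(cohort, "tp1"), paths[1L])
  writeMeasureTable(assay(cohort, "tp2"), paths[2L])
  cd <- as.data.frame(colData(cohort))
  cov <- data.frame(subject = rownames(cd), cd,
                    check.names = FALSE, stringsAsFactors = FALSE)
  .writeTSV(cov, paths[3L])
  invisible(paths)
}

#' Read a cohort from its delimited file set
#'
#' Validates as it loads: unique subject ids, exactly two group levels both
#' present, identical subject/region sets across the two timepoints,
#' strictly positive measures (a negative T1w/T2w ratio is an upstream
#' extraction fault, not data). Subject counts per group are reported via a
#' message.
#'
#' @param tp1Path,tp2Path wide measure tables.
#' @param covariatesPath per-subject table with columns \code{subject},
#'   \code{group}, and any covariates.
#' @param hemisphere optional named hemisphere vector for \code{rowData}.
#' @param depth recorded sampling depth.
#' @return A validated \linkS4class{CohortTable}.
#' @export
readCohort <- function(tp1Path, tp2Path, covariatesPath,
                       hemisphere = NULL, depth = NA_real_) {
  tp1 <- readMeasureTable(tp1Path)
  tp2 <- readMeasureTable(tp2Path)
  if (!setequal(colnames(tp1), colnames(tp2)) ||
      !setequal(rownames(tp1), rownames(tp2)))
    stop("tp1 and tp2 tables cover different subjects or regions")
  tp2 <- tp2[rownames(tp1), colnames(tp1), drop = FALSE]
  cov <- utils::read.delim(covariatesPath, check.names = FALSE,
                           colClasses = c(subject = "character"))
  if (anyDuplicated(cov$subject))
    stop("duplicate subject id(s) in covariate table")
  if (!"group" %in% colnames(cov))
    stop("covariate table lacks a 'group' column")
  miss <- setdiff(colnames(tp1), cov$subject)
  if (length(miss))
    stop("subject(s) missing from covariate table: ",
         paste(miss, collapse = ", "))
  cov <- cov[match(colnames(tp1), cov$subject), , drop = FALSE]
  grp <- as.factor(cov$group)
  if (nlevels(grp) != 2L)
    stop("'group' must take exactly two values, got: ",
         paste(levels(grp), collapse = ", "))
  extras <- cov[, setdiff(colnames(cov), c("subject", "group")), drop = FALSE]
  rownames(extras) <- cov$subject
  cohort <- cohortTable(tp1, tp2, grp,
                        covariates = if (ncol(extras)) extras else NULL,
                        hemisphere = hemisphere, depth = depth)
  message("loaded cohort: ",
          paste(sprintf("%s n=%d", levels(grp), table(grp)), collapse = ", "),
          "; ", nrow(cohort), " regions")
  cohort
}

#' Write a parcellation graph to edge-list and hemisphere-map files
#'
#' @param graph a \linkS4class{ParcellationGraph}.
#' @param edgePath,hemispherePath output paths (tab-separated, with
#'   headers), readable by [loadAdjacency()].
#' @return Invisibly, the two paths.
#' @export
writeGraph <- function(graph, edgePath, hemispherePath) {
  e <- as.data.frame(edgeMatrix(graph), stringsAsFactors = FALSE)
  .writeTSV(e, edgePath)
  h <- hemispheres(graph)
  .writeTSV(data.frame(region = names(h), hemisphere = unname(h),
                       stringsAsFactors = FALSE), hemispherePath)
  invisible(c(edgePath, hemispherePath))
}

#' Assemble and validate a pipeline run configuration
#'
#' @param tp1,tp2,covariates,edges,hemispheres input file paths.
#' @param metric change metric, \code{"SPC"} or \code{"RAW_DIFF"}.
#' @param threshold cluster-forming p threshold.
#' @param nPermutations permutation count (study convention: 5000).
#' @param seed RNG seed.
#' @param useEuler include the head-movement index covariate in the
#'   region-wise models.
#' @param outputDir where [runPipeline()] writes its results.
#' @return A validated named list of class \code{"runConfig"}.
#' @seealso [readRunConfig()], [writeRunConfig()]
#' @export
runConfig <- function(tp1, tp2, covariates, edges, hemispheres,
                      metric = "SPC", threshold = 0.05,
                      nPermutations = 5000L, seed = 1L,
                      useEuler = TRUE, outputDir = "cortexperm-run") {
  config <- list(tp1 = tp1, tp2 = tp2, covariates = covariates,
                 edges = edges, hemispheres = hemispheres,
                 metric = metric, threshold = threshold,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed), useEuler = isTRUE(useEuler),
                 outputDir = outputDir)
  class(config) <- "runConfig"
  validateRunConfig(config)
  config
}

#' @rdname runConfig
#' @param config a run configuration.
#' @export
validateRunConfig <- function(config) {
  for (f in c("tp1", "tp2", "covariates", "edges", "hemispheres"))
    if (!file.exists(config[[f]]))
      stop("configured ", f, " path does not exist: ", config[[f]])
  if (!config$metric %in% c("SPC", "RAW_DIFF"))
    stop("metric must be 'SPC' or 'RAW_DIFF'")
  if (config$threshold <= 0 || config$threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (config$nPermutations < 1L)
    stop("nPermutations must be >= 1")
  invisible(config)
}

#' Round-trip a run configuration through JSON
#'
#' @param config a configuration from [runConfig()].
#' @param path JSON file path.
#' @return \code{readRunConfig}: the configuration, validated.
#' @name runConfig-io
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname runConfig-io
#' @export
readRunConfig <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  config$nPermutations <- as.integer(config$nPermutations)
  config$seed <- as.integer(config$seed)
  class(config) <- "runConfig"
  validateRunConfig(config)
}
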
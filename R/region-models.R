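# Multi-outcome OLS for the region-wise model. X is the n x p design with
# the group column at position 2; Y is n x R. Returns the group
# coefficient, its t and two-sided p per region (column of Y).
.regionOLS <- function(X, Y, pvalues = TRUE) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e)
    stop("rank-deficient design matrix", call. = FALSE))
  inv <- chol2inv(ch)
  beta <- inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  df <- n - p
  sigma2 <- .colSums(resid * resid, n, ncol(Y)) / df
  # guard against numerically-zero residual variance (constant outcomes):
  # the group test is then degenerate, not borderline
  scale <- pmax(.colSums(Y * Y, n, ncol(Y)) / n, 1)
  degen <- sigma2 <= 1e-20 * scale
  se <- sqrt(sigma2 * inv[2L, 2L])
  b <- beta[2L, ]
  t <- ifelse(se > 0, b / se, 0)
  t[degen] <- ifelse(abs(b[degen]) < 1e-10 * sqrt(scale[degen]), 0, Inf)
  b[degen & t == 0] <- 0
  out <- list(beta = b, se = se, t = t, df = df)
  if (pvalues) {
    pval <- 2 * stats::pt(-abs(t), df)
    pval[degen & t == 0] <- 1
    out$p <- pval
  }
  out
}

# n x p design with intercept, 0/1 group (second level = 1) and covariates
.designMatrix <- function(group, covariates = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2L || !all(levels(group) %in% as.character(group)))
    stop("group must be a two-level factor with both levels present")
  X <- cbind(`(Intercept)` = 1, group = as.numeric(group == levels(group)[2L]))
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    if (anyNA(covariates)) {
      bad <- which(rowSums(is.na(covariates)) > 0)
      stop("missing covariate value for subject(s): ",
           paste(rownames(covariates)[bad] %||% bad, collapse = ", "))
    }
    X <- cbind(X, covariates)
  }
  X
}

#' Fit region-wise linear models of change on group
#'
#' For every region, fits by ordinary least squares
#' \code{change ~ group + covariates} across subjects, where group is coded
#' 0 for the reference (first) level and 1 for the exposed (second) level —
#' so a positive coefficient means the exposed group's measure increased
#' more. Reports the group coefficient, its t statistic on the residual
#' degrees of freedom, the two-sided p, and Hedges g of the unadjusted
#' group difference in change (effect sizes are conventionally computed
#' without nuisance covariates). All regions share one design matrix, so
#' the fit is a single multi-outcome least-squares solve.
#'
#' @param change a \linkS4class{ChangeMatrix}.
#' @param group two-level factor over subjects, or a
#'   \linkS4class{CohortTable} whose \code{group} column is used.
#' @param covariates optional numeric data.frame/matrix of per-subject
#'   nuisance covariates (e.g. the head-movement index from
#'   [headMovementIndex()]); must be complete.
#' @return A \link[S4Vectors]{DataFrame}, one row per region, with columns
#'   \code{beta}, \code{se}, \code{t}, \code{df}, \code{p}, \code{g},
#'   \code{nA}, \code{nB}. \code{g} is oriented exposed minus reference.
#' @export
fitRegionModels <- function(change, group, covariates = NULL) {
  stopifnot(is(change, "ChangeMatrix"))
  if (is(group, "CohortTable")) group <- cohortGroups(group)
  Y <- change@values
  group <- as.factor(group)
  if (length(group) != nrow(Y))
    stop("group length must match the number of subjects")
  X <- .designMatrix(group, covariates)
  fit <- .regionOLS(X, Y)
  isB <- group == levels(group)[2L]
  nA <- sum(!isB); nB <- sum(isB)
  mA <- .colMeans(Y[!isB, , drop = FALSE], nA, ncol(Y))
  mB <- .colMeans(Y[isB, , drop = FALSE], nB, ncol(Y))
  vA <- .colSums(sweep(Y[!isB, , drop = FALSE], 2L, mA)^2, nA, ncol(Y)) / (nA - 1)
  vB <- .colSums(sweep(Y[isB, , drop = FALSE], 2L, mB)^2, nB, ncol(Y)) / (nB - 1)
  sp <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2))
  g <- ifelse(sp > 0, .hedgesJ(nA + nB - 2) * (mB - mA) / sp,
              ifelse(abs(mB - mA) < 1e-12, 0, NA_real_))
  DataFrame(beta = fit$beta, se = fit$se, t = fit$t, df = fit$df,
            p = fit$p, g = g, nA = nA, nB = nB,
            row.names = colnames(Y))
}

#' Per-subject head-movement index from surface Euler numbers
#'
#' The surface reconstruction Euler number indexes in-scanner head movement;
#' the change model needs one value per subject, so the two timepoints are
#' combined — by default their mean, with per-timepoint or difference
#' alternatives.
#'
#' @param cohort a \linkS4class{CohortTable} with \code{eulerTP1} and
#'   \code{eulerTP2} covariates.
#' @param combine \code{"mean"} (default), \code{"tp1"}, \code{"tp2"} or
#'   \code{"diff"} (TP2 - TP1).
#' @return A one-column data.frame \code{euler}, rownames = subjects.
#' @export
headMovementIndex <- function(cohort,
                              combine = c("mean", "tp1", "tp2", "diff")) {
  combine <- match.arg(combine)
  cd <- colData(cohort)
  if (!all(c("eulerTP1", "eulerTP2") %in% colnames(cd)))
    stop("cohort lacks eulerTP1/eulerTP2 covariates")
  v <- switch(combine,
    mean = (cd$eulerTP1 + cd$eulerTP2) / 2,
    tp1 = cd$eulerTP1,
    tp2 = cd$eulerTP2,
    diff = cd$eulerTP2 - cd$eulerTP1)
  data.frame(euler = v, row.names = rownames(cd))
}
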
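#' Vigilance-task reaction-time summaries
#'
#' Reduces a psychomotor-vigilance reaction-time series to the three
#' measures used as behavioural outcomes: the number of minor attentional
#' lapses (reaction times strictly greater than 500 ms — a 500 ms response
#' is not a lapse), the median reaction time, and reaction-time variability
#' as the sample variance.
#'
#' @param rt numeric vector of reaction times in milliseconds, all > 0.
#' @return List with \code{lapses} (integer), \code{medianRT} (ms) and
#'   \code{varRT} (ms^2; \code{NA} for a single trial).
#' @examples
#' pvtSummary(c(300, 501, 700))$lapses  # 2
#' @export
pvtSummary <- function(rt) {
  if (!length(rt)) stop("empty reaction-time series")
  if (any(!is.finite(rt)) || any(rt <= 0))
    stop("reaction times must be positive and finite")
  list(lapses = sum(rt > 500),
       medianRT = stats::median(rt),
       varRT = if (length(rt) > 1L) stats::var(rt) else NA_real_)
}

#' Change-by-group interaction model at cluster level
#'
#' Tests whether the association between a behavioural change score (e.g.
#' sleepiness change on the KSS, or change in vigilance lapses) and the
#' cluster-mean microstructural change differs between groups: OLS of the
#' cluster mean on \code{group + measure + group:measure}, with the
#' interaction term's two-sided p as the headline statistic. Within-group
#' correlations between the cluster mean and the measure are reported
#' descriptively (Pearson by default). Subjects with a missing measure are
#' dropped listwise, with counts returned.
#'
#' @param clusterMeans subjects x clusters matrix from
#'   [extractClusterMeans()].
#' @param group two-level factor (or \linkS4class{CohortTable}).
#' @param measure numeric behavioural change score per subject; may contain
#'   \code{NA}.
#' @param method correlation type for the descriptive within-group
#'   association: \code{"pearson"} (default) or \code{"spearman"}.
#' @return data.frame per cluster: \code{p_interaction}, \code{beta_interaction},
#'   \code{r_<level>} and \code{p_r_<level>} per group, and \code{n} complete
#'   subjects.
#' @export
interactionModel <- function(clusterMeans, group, measure,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is(group, "CohortTable")) group <- cohortGroups(group)
  group <- as.factor(group)
  clusterMeans <- as.matrix(clusterMeans)
  ok <- stats::complete.cases(measure, group)
  if (sum(ok) < length(measure))
    message(length(measure) - sum(ok), " subject(s) dropped (missing measure)")
  g <- droplevels(group[ok])
  m <- measure[ok]
  Y <- clusterMeans[ok, , drop = FALSE]
  if (nlevels(g) != 2L || any(table(g) < 3L))
    stop("need at least 3 complete subjects per group (have ",
         paste(table(g), collapse = "/"), ")")
  gnum <- as.numeric(g == levels(g)[2L])
  X <- cbind(1, gnum, m, gnum * m)
  if (qr(X)$rank < 4L)
    stop("rank-deficient interaction design (constant measure within groups?)")
  n <- nrow(X); df <- n - 4L
  inv <- chol2inv(chol(crossprod(X)))
  beta <- inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * inv[4L, 4L])
  tstat <- beta[4L, ] / se
  out <- data.frame(
    beta_interaction = beta[4L, ],
    p_interaction = 2 * stats::pt(-abs(tstat), df),
    n = n,
    row.names = colnames(Y)
  )
  for (lev in levels(g)) {
    sel <- g == lev
    ct <- apply(Y[sel, , drop = FALSE], 2L, function(y)
      stats::cor.test(y, m[sel], method = method, exact = FALSE))
    out[[paste0("r_", lev)]] <- vapply(ct, function(z) unname(z$estimate), 0)
    out[[paste0("p_r_", lev)]] <- vapply(ct, function(z) z$p.value, 0)
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values, input
#' order preserved. The family is whatever vector is passed — by
#' convention, all clusters x all behavioural measures of one run.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order (and names) as input.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}
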
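.hedgesJ <- function(df, correction = c("approx", "exact")) {
  correction <- match.arg(correction)
  if (correction == "approx") 1 - 3 / (4 * df - 1)
  else exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
}

#' Hedges g standardized mean difference
#'
#' \eqn{g = J \cdot (\bar{x}_a - \bar{x}_b)/s_p}, with \eqn{s_p} the pooled
#' SD weighted by \eqn{(n_a - 1, n_b - 1)} and the small-sample bias
#' correction \eqn{J = 1 - 3/(4\,df - 1)} (df = \eqn{n_a + n_b - 2}); the
#' exact gamma-function correction is available via
#' \code{correction = "exact"} and agrees to well beyond two decimals at
#' these sample sizes. The sign follows the argument order:
#' \code{hedgesG(a, b)} is positive when group \code{a} has the larger mean.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param correction \code{"approx"} (default) or \code{"exact"} bias factor.
#' @return Hedges g (a single number).
#' @seealso [hedgesGFromSummary()] for the printed-summary form.
#' @export
hedgesG <- function(a, b, correction = c("approx", "exact")) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  hedgesGFromSummary(mean(a), stats::sd(a), length(a),
                     mean(b), stats::sd(b), length(b),
                     correction = correction)
}

#' Hedges g from group summaries
#'
#' Summary-statistic form of [hedgesG()], for recomputing effect sizes from
#' printed means, SDs and counts (e.g. demographics tables).
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @inheritParams hedgesG
#' @return Hedges g.
#' @examples
#' # age: 25.7 (6.97), n = 23 vs 26.28 (7.05), n = 18
#' round(hedgesGFromSummary(25.7, 6.97, 23, 26.28, 7.05, 18), 2)  # -0.08
#' @export
hedgesGFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                               correction = c("approx", "exact")) {
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 observations")
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
  if (sp2 == 0) {
    if (meanA == meanB) return(0)
    stop("zero pooled variance with unequal means: g undefined")
  }
  .hedgesJ(df, correction) * (meanA - meanB) / sqrt(sp2)
}

#' Welch two-sample t-test from vectors or summaries
#'
#' Welch's unequal-variance t statistic with Welch–Satterthwaite degrees of
#' freedom, the test used for demographic and sleep-wake group comparisons
#' (its fractional df reproduce printed table values). The summary form
#' takes printed means/SDs/counts; the vector form computes the summaries
#' first, so both agree exactly on the same data.
#'
#' @param a,b numeric vectors (vector form).
#' @return A list with \code{t}, \code{df} and two-sided \code{p}.
#' @examples
#' welchTFromSummary(25.7, 6.97, 23, 26.28, 7.05, 18)  # t = -0.26, df = 36.46
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  welchTFromSummary(mean(a), stats::sd(a), length(a),
                    mean(b), stats::sd(b), length(b))
}

#' @rdname welchT
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries (summary form).
#' @export
welchTFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (sdA == 0 && sdB == 0) stop("both group variances are zero")
  va <- sdA^2 / nA
  vb <- sdB^2 / nB
  t <- (meanA - meanB) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (nA - 1) + vb^2 / (nB - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Paired t-test
#'
#' One-sample t on the within-subject differences (used to compare sleep
#' duration the night before the study against the weekly average).
#'
#' @param before,after numeric vectors of equal length (n >= 2), pairwise
#'   complete.
#' @return A list with \code{t}, \code{df} (= n - 1) and two-sided \code{p}.
#' @export
pairedT <- function(before, after) {
  if (length(before) != length(after)) stop("unequal lengths")
  ok <- stats::complete.cases(before, after)
  before <- before[ok]; after <- after[ok]
  n <- length(before)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1))
    stop("zero-variance differences with nonzero mean: t undefined")
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mixed two-way (group x time) ANOVA
#'
#' Classical mixed-design ANOVA with one two-level between-subject factor
#' (group) and one two-level within-subject factor (e.g. night-before vs
#' weekly-average sleep duration), fit via \code{stats::aov} with an
#' \code{Error(subject)} stratum. Incomplete subjects are dropped listwise.
#' Each F statistic has (1, n - 2) degrees of freedom.
#'
#' @param group factor of length n with two levels.
#' @param y1,y2 the two within-subject measurements per subject.
#' @return A data.frame with rows \code{group}, \code{time},
#'   \code{group:time} and columns \code{F}, \code{df1}, \code{df2},
#'   \code{p}.
#' @export
mixedAnova <- function(group, y1, y2) {
  ok <- stats::complete.cases(group, y1, y2)
  group <- droplevels(as.factor(group[ok]))
  y1 <- y1[ok]; y2 <- y2[ok]
  if (nlevels(group) != 2L) stop("group must have two levels")
  if (any(table(group) < 2L)) stop("need at least 2 subjects per group")
  n <- length(y1)
  long <- data.frame(
    y = c(y1, y2),
    time = factor(rep(c("t1", "t2"), each = n)),
    group = rep(group, 2L),
    subject = factor(rep(seq_len(n), 2L))
  )
  fit <- stats::aov(y ~ group * time + Error(subject), data = long)
  sm <- summary(fit)
  betw <- sm[["Error: subject"]][[1L]]
  with <- sm[["Error: Within"]][[1L]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
      p = tab[i, "Pr(>F)"])
  }
  out <- rbind(group = pick(betw, "group"),
               time = pick(with, "time"),
               `group:time` = pick(with, "group:time"))
  as.data.frame(out)
}
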
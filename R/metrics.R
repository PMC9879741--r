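## Positioning-error metrics and cohort statistics. Sign convention
## throughout: negative values place the centerline below the gantry
## isocenter (lower table height), positive above it.
##
##   BCAP = BCDL - BCGTH     automatic-positioning error (body)
##   BCMP = BCGTH - isocenter  manual mis-centering (body)
##   LCAP = LCDL - LCGTH     automatic-positioning error (lungs)
##   LCMP = LCGTH - isocenter  manual mis-centering (lungs)

#' Positioning errors for one case
#'
#' Exact arithmetic on the ground-truth and predicted centerline reports;
#' both must live in the same scanner frame (same isocenter).
#'
#' @param reportGT ground-truth \code{\link{CenterlineReport-class}}.
#' @param reportDL predicted \code{\link{CenterlineReport-class}} for the
#'   same case.
#' @param isocenterY mm; defaults to the reports' isocenter.
#' @param bodySize mm effective body diameter carried along for the
#'   body-size correlation (optional).
#' @return One-row data.frame: caseId, bcap, bcmp, lcap, lcmp, their
#'   absolute values, bodySize.
#' @examples
#' # bcdl = 10, bcgth = 12, isocenter = 0 -> bcap = -2, bcmp = 12
#' @export
positioningErrors <- function(reportGT, reportDL,
                              isocenterY = NULL, bodySize = NA_real_) {
  if (reportGT@isocenterY != reportDL@isocenterY)
    stop("reports are not in the same scanner frame (isocenter mismatch)")
  if (is.null(isocenterY)) isocenterY <- reportGT@isocenterY
  bcap <- reportDL@bodyCenterline - reportGT@bodyCenterline
  bcmp <- reportGT@bodyCenterline - isocenterY
  lcap <- reportDL@lungCenterline - reportGT@lungCenterline
  lcmp <- reportGT@lungCenterline - isocenterY
  data.frame(caseId = reportGT@caseId,
             bcap = bcap, bcmp = bcmp, lcap = lcap, lcmp = lcmp,
             absBcap = abs(bcap), absBcmp = abs(bcmp),
             absLcap = abs(lcap), absLcmp = abs(lcmp),
             bodySize = bodySize)
}

#' Effective body diameter
#'
#' Geometric mean of the AP and lateral diameters, the default "body size"
#' for the size-error correlation.
#' @param spec a \code{\link{PhantomSpec-class}}.
#' @return mm.
#' @export
effectiveDiameter <- function(spec) {
  sqrt(bodyDiameterAP(spec) * bodyDiameterLat(spec))
}

#' Cohort summary of positioning errors
#'
#' Mean, SD, normal-approximation 95\% CI of the mean, median, IQR, the
#' fraction of cases with |error| strictly above 10 mm and the count above
#' 20 mm, for each signed metric and its absolute value.
#'
#' @param errors data.frame of per-case rows from
#'   \code{\link{positioningErrors}} (or any data.frame of numeric metric
#'   columns).
#' @param metrics which columns to summarize.
#' @return data.frame, one row per metric.
#' @export
cohortSummary <- function(errors,
                          metrics = c("bcap", "bcmp", "lcap", "lcmp",
                                      "absBcap", "absBcmp", "absLcap",
                                      "absLcmp")) {
  metrics <- intersect(metrics, names(errors))
  rows <- lapply(metrics, function(mname) {
    x <- errors[[mname]]
    x <- x[is.finite(x)]
    if (length(x) < 2) stop("cohort summary needs at least two cases per metric")
    m <- mean(x); s <- sd(x); half <- 1.96 * s / sqrt(length(x))
    data.frame(metric = mname, n = length(x), mean = m, sd = s,
               ciLow = m - half, ciHigh = m + half,
               median = median(x), iqr = unname(diff(quantile(x, c(.25, .75)))),
               fracOver10 = mean(abs(x) > 10), countOver20 = sum(abs(x) > 20))
  })
  do.call(rbind, rows)
}

mwStatistic <- function(a, b) {
  ## rank-sum form with midranks, so ties contribute 1/2
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by full enumeration of the label assignments when the
#' smaller sample has at most \code{exactThreshold} observations (and the
#' enumeration is tractable); otherwise the normal approximation with tie
#' correction and continuity correction. Identical pooled values give p = 1
#' with a warning.
#'
#' @param a,b numeric samples.
#' @param exactThreshold largest min(n) for which enumeration is used.
#' @return List: \code{U} (statistic for sample \code{a}), \code{p}
#'   (two-sided), \code{method}.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$p   # exact: 0.1
#' @export
mannWhitney <- function(a, b, exactThreshold = 8L) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b)
  U <- mwStatistic(a, b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples; p = 1")
    return(list(U = U, p = 1, method = "degenerate"))
  }
  nSmall <- min(na, nb)
  if (nSmall <= exactThreshold &&
      choose(na + nb, na) <= 5e5) {
    sel <- utils::combn(na + nb, na)
    uPerm <- apply(sel, 2, function(ix)
      mwStatistic(pooled[ix], pooled[-ix]))
    uLo <- min(U, na * nb - U)
    p <- mean(pmin(uPerm, na * nb - uPerm) <= uLo)
    return(list(U = U, p = p, method = "exact"))
  }
  N <- na + nb
  ties <- table(pooled)
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  mu <- na * nb / 2
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks on ties; two-sided p from the t distribution with n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return List: \code{rho}, \code{p}, \code{n}.
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired samples with n >= 3")
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Kolmogorov-Smirnov normality test (Lilliefors-style)
#'
#' One-sample KS statistic against a normal with the sample's mean and SD;
#' because the parameters are estimated, the p value is obtained by Monte
#' Carlo under the null (seeded, hence reproducible) rather than from the
#' classical KS distribution.
#'
#' @param x numeric sample (n >= 5).
#' @param nsim Monte Carlo replicates.
#' @param seed integer for the simulation.
#' @return List: \code{statistic} (in [0,1]), \code{p}.
#' @export
ksNormality <- function(x, nsim = 1999L, seed = 1L) {
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  stat <- function(v) {
    v <- sort(v)
    p <- pnorm(v, mean(v), sd(v))
    i <- seq_len(length(v))
    max(i / length(v) - p, p - (i - 1) / length(v))
  }
  d0 <- stat(x)
  set.seed(as.integer(seed))
  dSim <- replicate(nsim, stat(rnorm(n)))
  list(statistic = d0, p = (1 + sum(dSim >= d0)) / (nsim + 1))
}
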
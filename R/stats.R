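## Functionals of the fluctuation process and their null distributions.
##
## Under parameter invariance each column of B is asymptotically an
## independent standard Brownian bridge; the statistics below summarize
## departures and their p-values come from the bridge law (analytically for
## DM, WDMo and LMuo, by Monte-Carlo path simulation for CvM, maxLM and
## maxLMo).

evalPoints <- function(process) {
  be <- process@ordering$blockEnds
  list(idx = be, t = be / process@nPersons)
}

#' Test statistic of a fluctuation process
#'
#' \describe{
#'   \item{DM}{double maximum \code{max_v max_j |B_vj|} (metric).}
#'   \item{CvM}{Cramer-von Mises \code{N^-1 sum_v sum_j B_vj^2} (metric).}
#'   \item{maxLM}{\code{max_v [t(1-t)]^-1 sum_j B_vj^2} over the trimmed
#'     range (metric).}
#'   \item{WDMo}{weighted double maximum over the m-1 category boundaries
#'     (ordinal).}
#'   \item{maxLMo}{maximum LM over the category boundaries (ordinal).}
#'   \item{LMuo}{unordered LM: sum over categories of squared process
#'     increments, scaled by the category proportions (categorical); the
#'     scaled form has the chi-square((m-1)k) null used for its analytic
#'     p-value.  \code{scaleLMuo = FALSE} gives the unscaled literal form
#'     (for sensitivity checks; no analytic p-value).}
#' }
#' Metric statistics are evaluated at tie-block boundaries only, since the
#' within-block order is arbitrary; ordinal/categorical statistics at the
#' category boundaries.
#'
#' @param process a \code{\linkS4class{FluctuationProcess}}.
#' @param which statistic name.
#' @param trim trimming fraction for maxLM: the maximum is taken over
#'   t in [trim, 1 - trim] (default 0.1; must lie in (0, .5)).
#' @param scaleLMuo use the per-category scaling (default TRUE).
#' @return scalar statistic value.
#' @export
fluctuationStatistic <- function(process,
                                 which = c("DM", "CvM", "maxLM", "WDMo",
                                           "maxLMo", "LMuo"),
                                 trim = 0.1, scaleLMuo = TRUE) {
  which <- match.arg(which)
  ep <- evalPoints(process)
  B <- process@B[ep$idx, , drop = FALSE]
  tvec <- ep$t
  kind <- process@ordering$kind
  if (which %in% c("WDMo", "maxLMo", "LMuo") && kind == "metric")
    stop(which, " requires a covariate with categories")
  switch(which,
    DM = max(abs(B)),
    CvM = {
      sizes <- diff(c(0L, ep$idx))
      sum(sizes * rowSums(B^2)) / process@nPersons
    },
    maxLM = {
      if (trim <= 0 || trim >= 0.5) stop("trim must be in (0, 0.5)")
      keep <- tvec >= trim & tvec <= 1 - trim & tvec < 1
      if (!any(keep)) stop("no evaluation points inside the trimmed range")
      max(rowSums(B[keep, , drop = FALSE]^2) / (tvec[keep] * (1 - tvec[keep])))
    },
    WDMo = {
      tb <- head(tvec, -1L); Bb <- B[-nrow(B), , drop = FALSE]
      max(apply(abs(Bb), 1L, max) / sqrt(tb * (1 - tb)))
    },
    maxLMo = {
      tb <- head(tvec, -1L); Bb <- B[-nrow(B), , drop = FALSE]
      max(rowSums(Bb^2) / (tb * (1 - tb)))
    },
    LMuo = {
      dB <- diff(rbind(0, B))
      if (scaleLMuo) sum(rowSums(dB^2) / diff(c(0, tvec)))
      else sum(rowSums(dB^2))
    })
}

#' Kolmogorov distribution function
#'
#' CDF of the supremum of the absolute value of a standard Brownian bridge,
#' \code{F(c) = 1 - 2 sum_{i>=1} (-1)^(i+1) exp(-2 i^2 c^2)}.
#'
#' @param c nonnegative quantile.
#' @return probability.
#' @export
pKolmogorov <- function(c) {
  vapply(c, function(ci) {
    if (ci <= 0) return(0)
    i <- seq_len(200L)
    term <- (-1)^(i + 1L) * exp(-2 * i^2 * ci^2)
    max(0, min(1, 1 - 2 * sum(term)))
  }, numeric(1))
}

## P(|B(t_l)| <= c * sqrt(t_l (1-t_l)) for all boundaries) for one bridge
## component, by iterated Gaussian transition integration (the bridge is
## Markov across the ordered boundaries), on a fixed grid.
wdmoComponentProb <- function(c, t, gridN = 801L) {
  if (c <= 0) return(0)
  m1 <- length(t)
  a <- c * sqrt(t[1L] * (1 - t[1L]))
  grid <- seq(-a, a, length.out = gridN)
  f <- dnorm(grid, 0, sqrt(t[1L] * (1 - t[1L])))
  if (m1 > 1L) {
    for (l in 2:m1) {
      s <- t[l - 1L]; tt <- t[l]
      shrink <- (1 - tt) / (1 - s)
      sdq <- sqrt((tt - s) * (1 - tt) / (1 - s))
      aNew <- c * sqrt(tt * (1 - tt))
      gridNew <- seq(-aNew, aNew, length.out = gridN)
      db <- grid[2L] - grid[1L]
      wts <- rep(db, gridN); wts[c(1L, gridN)] <- db / 2
      K <- outer(gridNew, grid * shrink, function(b, mu) dnorm(b, mu, sdq))
      f <- as.vector(K %*% (f * wts))
      grid <- gridNew
    }
  }
  db <- grid[2L] - grid[1L]
  wts <- rep(db, gridN); wts[c(1L, gridN)] <- db / 2
  min(1, sum(f * wts))
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Monte-Carlo null draws of a statistic from simulated Brownian-bridge paths
simulateNullStats <- function(which, k, nsim = 10000L, seed = 1L,
                              gridN = 1000L, trim = 0.1, t = NULL) {
  withSeed(seed, {
    if (which %in% c("CvM", "maxLM")) {
      tg <- seq_len(gridN) / gridN
      keep <- tg >= trim & tg <= 1 - trim & tg < 1
      chunk <- 2000L
      done <- 0L
      out <- numeric(0)
      while (done < nsim) {
        nb <- min(chunk, nsim - done)
        SSQ <- matrix(0, gridN, nb)
        for (comp in seq_len(k)) {
          E <- matrix(rnorm(gridN * nb), gridN, nb) / sqrt(gridN)
          CS <- apply(E, 2L, cumsum)
          Bm <- CS - tg %o% CS[gridN, ]
          SSQ <- SSQ + Bm^2
        }
        out <- c(out, if (which == "CvM") colMeans(SSQ)
                 else apply(SSQ[keep, , drop = FALSE] /
                            (tg[keep] * (1 - tg[keep])), 2L, max))
        done <- done + nb
      }
      out
    } else if (which == "maxLMo") {
      times <- c(t, 1)
      dt <- diff(c(0, times))
      m <- length(times)
      SSQ <- matrix(0, m - 1L, nsim)
      for (comp in seq_len(k)) {
        E <- matrix(rnorm(m * nsim), m, nsim) * sqrt(dt)
        CS <- apply(E, 2L, cumsum)
        Bm <- CS[-m, , drop = FALSE] -
          t %o% CS[m, ]
        SSQ <- SSQ + Bm^2
      }
      apply(SSQ / (t * (1 - t)), 2L, max)
    } else stop("no Monte-Carlo null implemented for ", which)
  })
}

#' p-value of a score-based test statistic
#'
#' DM uses the Kolmogorov law of the bridge supremum with independence over
#' the k decorrelated components; WDMo uses the exact joint normal law of the
#' bridge at the category boundaries (iterated Gaussian integration); LMuo
#' (scaled) uses the chi-square((m-1)k) survival function.  CvM, maxLM and
#' maxLMo use Monte-Carlo simulation of Brownian-bridge paths with a fixed
#' seed.
#'
#' @param statistic observed statistic.
#' @param which statistic name.
#' @param k number of tested parameters.
#' @param t boundary proportions (ordinal/categorical statistics; without the
#'   final value 1 for WDMo/maxLMo; including all m categories for LMuo,
#'   where only m is used).
#' @param m number of categories (LMuo).
#' @param trim maxLM trimming fraction.
#' @param nsim Monte-Carlo paths for simulated p-values.
#' @param seed Monte-Carlo seed.
#' @param gridN time-grid resolution for simulated paths.
#' @return list with \code{p} and \code{method} ("analytic" or "simulated").
#' @export
scorePValue <- function(statistic, which, k, t = NULL, m = NULL, trim = 0.1,
                        nsim = 10000L, seed = 1L, gridN = 1000L) {
  stopifnot(is.finite(statistic))
  which <- match.arg(which, c("DM", "CvM", "maxLM", "WDMo", "maxLMo", "LMuo"))
  if (which == "DM") {
    list(p = 1 - pKolmogorov(statistic)^k, method = "analytic")
  } else if (which == "WDMo") {
    if (is.null(t)) stop("WDMo needs the boundary proportions t")
    list(p = 1 - wdmoComponentProb(statistic, t)^k, method = "analytic")
  } else if (which == "LMuo") {
    if (is.null(m)) stop("LMuo needs the number of categories m")
    list(p = pchisq(statistic, df = (m - 1L) * k, lower.tail = FALSE),
         method = "analytic")
  } else {
    null <- simulateNullStats(which, k, nsim = nsim, seed = seed,
                              gridN = gridN, trim = trim, t = t)
    list(p = (1 + sum(null >= statistic)) / (nsim + 1), method = "simulated")
  }
}

#' Score-based parameter-invariance test
#'
#' End-to-end test: score contributions at the estimate, OPG covariance of
#' the tested subset, decorrelated cumulative process ordered by the
#' covariate, test statistic and p-value.  The default statistic follows the
#' covariate kind: DM for metric, WDMo for ordinal, LMuo for unordered
#' categorical covariates.
#'
#' @param fit an \code{\linkS4class{IRTreeFit}}.
#' @param covariate person covariate (length N).
#' @param kind covariate kind; see \code{\link{covariateOrdering}}.
#' @param subset tested parameters; see \code{\link{resolveSubset}}.
#' @param statistic statistic name (default by kind).  Using a metric
#'   statistic on an ordinal covariate is allowed on explicit request but
#'   triggers a warning recommending WDMo/maxLMo.
#' @param covariateName label stored in the result.
#' @param scores optional precomputed score matrix (saves recomputation when
#'   several subsets are tested on one fit).
#' @param trim,nsim,seed,decorrelate passed to the component functions.
#' @return an \code{\linkS4class{InvarianceTest}}.
#' @examples
#' \donttest{
#' sim <- simulateStudyData(simConfig(nPersons = 400, replications = 1), 1)
#' fit <- fitIRTree(sim$responses, sim$model,
#'                  options = fitOptions(quadPoints = 3))
#' invarianceTest(fit, sim$covariate, kind = "categorical",
#'                subset = "alpha_e")
#' }
#' @export
invarianceTest <- function(fit, covariate,
                           kind = c("metric", "ordinal", "categorical"),
                           subset = "alpha_nm", statistic = NULL,
                           covariateName = deparse(substitute(covariate)),
                           scores = NULL, trim = 0.1, nsim = 10000L,
                           seed = 1L, decorrelate = c("subset", "full")) {
  kind <- match.arg(kind)
  decorrelate <- match.arg(decorrelate)
  if (is.null(statistic))
    statistic <- switch(kind, metric = "DM", ordinal = "WDMo",
                        categorical = "LMuo")
  statistic <- match.arg(statistic,
                         c("DM", "CvM", "maxLM", "WDMo", "maxLMo", "LMuo"))
  if (kind == "ordinal" && statistic %in% c("DM", "CvM", "maxLM"))
    warning("metric statistic ", statistic,
            " used with an ordinal covariate; WDMo or maxLMo is recommended")
  if (kind == "metric" && statistic %in% c("WDMo", "maxLMo", "LMuo"))
    stop(statistic, " requires an ordinal or categorical covariate")
  subsetNames <- resolveSubset(fit@model, subset)
  if (is.null(scores)) scores <- scoreContributions(fit)
  ordering <- covariateOrdering(covariate, kind)
  process <- fluctuationProcess(scores, ordering, subsetNames, decorrelate)
  stat <- fluctuationStatistic(process, statistic, trim = trim)
  k <- length(subsetNames)
  tBound <- head(evalPoints(process)$t, -1L)
  pv <- scorePValue(stat, statistic, k, t = tBound,
                    m = if (is.na(ordering$m)) NULL else ordering$m,
                    trim = trim, nsim = nsim, seed = seed)
  new("InvarianceTest", statisticName = statistic, statistic = stat,
      pValue = pv$p, pMethod = pv$method, subset = subsetNames,
      k = as.integer(k), covariateName = as.character(covariateName)[1L],
      covariateKind = kind,
      nsim = if (pv$method == "simulated") as.integer(nsim) else 0L,
      seed = if (pv$method == "simulated") as.numeric(seed) else NA_real_,
      process = process)
}
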
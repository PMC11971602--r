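## Model-based partitioning: after a significant invariance test, locate the
## covariate value at which the parameters change by profiling the summed
## log-likelihood of two independently refitted subgroup models over all
## admissible cutpoints, then recurse within the subgroups.

admissibleCuts <- function(covariate, minSize) {
  u <- sort(unique(covariate))
  if (length(u) < 2L) return(numeric(0))
  nLeft <- cumsum(table(factor(covariate, levels = u)))
  ok <- which(nLeft >= minSize & (length(covariate) - nLeft) >= minSize)
  ok <- ok[ok < length(u)]
  u[ok]
}

#' Locate the cutpoint at which model parameters change
#'
#' Candidate cutpoints are the boundaries between distinct covariate values
#' that leave at least \code{minSize} respondents on each side.  Every
#' candidate is evaluated by two independent full refits (all item parameters
#' and the latent covariance free on each side); the returned cutpoint
#' maximizes the summed log-likelihood.  For large candidate sets
#' \code{maxCandidates} thins the profile to cutpoints evenly spaced in the
#' left-subsample fraction.
#'
#' @param responses N x I category matrix.
#' @param covariate numeric (metric or ordinal-coded) person covariate.
#' @param model an \code{\linkS4class{IRTreeModel}}.
#' @param options \code{\link{fitOptions}} for the subgroup refits.
#' @param minSize minimum subsample size per side (default 300).
#' @param maxCandidates maximum number of candidate cutpoints evaluated.
#' @param init optional warm-start parameter vector (e.g. pooled estimate).
#' @return list with \code{cutpoint}, the full \code{profile} data frame
#'   (cut, nLeft, loglik) and \code{fits} (left/right fits at the optimum).
#'   Errors when no admissible split exists.
#' @export
findCutpoint <- function(responses, covariate, model, options = fitOptions(),
                         minSize = 300L, maxCandidates = Inf, init = NULL) {
  responses <- as.matrix(responses)
  cuts <- admissibleCuts(covariate, minSize)
  if (length(cuts) == 0L)
    stop("no admissible split: every cutpoint leaves a side below ", minSize)
  if (length(cuts) > maxCandidates) {
    fracs <- vapply(cuts, function(cc) mean(covariate <= cc), numeric(1))
    target <- seq(min(fracs), max(fracs), length.out = maxCandidates)
    keep <- unique(vapply(target, function(tt) which.min(abs(fracs - tt)),
                          integer(1)))
    cuts <- cuts[keep]
  }
  prof <- vector("list", length(cuts))
  for (ii in seq_along(cuts)) {
    sl <- splitLogLik(responses, covariate, cuts[ii], model, options,
                      minSize = minSize, init = init)
    prof[[ii]] <- list(cut = cuts[ii], nLeft = sum(covariate <= cuts[ii]),
                       loglik = sl$loglik, fits = sl[c("left", "right")])
  }
  ll <- vapply(prof, `[[`, numeric(1), "loglik")
  best <- which.max(ll)
  list(cutpoint = cuts[best],
       profile = data.frame(cut = cuts,
                            nLeft = vapply(prof, `[[`, numeric(1), "nLeft"),
                            loglik = ll),
       fits = prof[[best]]$fits)
}

## exhaustive binary partitions of a (small) category set; greedy fallback
## by category-wise statistic contribution is intentionally simple and
## documented as beyond the original algorithm
categoricalCuts <- function(covariate, minSize, maxExhaustive = 6L) {
  lev <- levels(factor(covariate))
  m <- length(lev)
  if (m > maxExhaustive)
    stop("categorical splitting with more than ", maxExhaustive,
         " categories is not supported; merge categories first")
  sets <- list()
  for (mask in seq_len(2^(m - 1L) - 1L)) {
    inSet <- lev[as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))]
    nl <- sum(covariate %in% inSet)
    if (nl >= minSize && length(covariate) - nl >= minSize)
      sets[[length(sets) + 1L]] <- inSet
  }
  sets
}

findCategoricalCut <- function(responses, covariate, model, options,
                               minSize, init = NULL) {
  sets <- categoricalCuts(covariate, minSize)
  if (length(sets) == 0L)
    stop("no admissible split: every category partition leaves a side below ",
         minSize)
  evalOne <- function(inSet) {
    left <- covariate %in% inSet
    fl <- fitIRTree(responses[left, , drop = FALSE], model, options, init = init)
    fr <- fitIRTree(responses[!left, , drop = FALSE], model, options, init = init)
    list(loglik = fl@loglik + fr@loglik, left = fl, right = fr)
  }
  res <- lapply(sets, evalOne)
  ll <- vapply(res, `[[`, numeric(1), "loglik")
  best <- which.max(ll)
  list(set = sets[[best]],
       profile = data.frame(set = vapply(sets, paste, character(1),
                                         collapse = ","), loglik = ll),
       fits = res[[best]][c("left", "right")])
}

#' Score-based partitioning of the sample
#'
#' Tests the parameter subsets on the full sample; if the smallest p-value is
#' below \code{level}, locates the cutpoint by \code{\link{findCutpoint}},
#' splits, and recurses within the subgroups until non-significance, the
#' minimum subgroup size, or \code{maxDepth}.  By default only the subsets
#' that triggered the parent split are retested in the children
#' (\code{retestAll = TRUE} retests all subsets everywhere).
#'
#' @param responses N x I category matrix.
#' @param covariate person covariate.
#' @param kind covariate kind ("metric", "ordinal", "categorical").
#' @param model model specification (default Rasch-style; for two-trait
#'   simulation designs pass the matching model).
#' @param subsets list of parameter subsets tested at each node.
#' @param level significance level for splitting (default .05).
#' @param minSize minimum subgroup size (default 300).
#' @param maxDepth maximum number of nested splits.
#' @param statistic test statistic (default by covariate kind).
#' @param options fit options.
#' @param maxCandidates see \code{\link{findCutpoint}}.
#' @param retestAll retest all subsets within subgroups.
#' @param covariateName label for reports.
#' @return the root \code{\linkS4class{PartitionNode}}.
#' @export
partitionIRTree <- function(responses, covariate,
                            kind = c("metric", "ordinal", "categorical"),
                            model = NULL,
                            subsets = list("alpha_nm", "alpha_e"),
                            level = 0.05, minSize = 300L, maxDepth = 3L,
                            statistic = NULL, options = fitOptions(),
                            maxCandidates = Inf, retestAll = FALSE,
                            covariateName = "covariate") {
  kind <- match.arg(kind)
  responses <- as.matrix(responses)
  if (is.null(model)) model <- irtreeModel(ncol(responses))
  if (!is.list(subsets)) subsets <- list(subsets)

  grow <- function(resp, cov, condition, depth, activeSubsets, init) {
    n <- nrow(resp)
    fit <- fitIRTree(resp, model, options, init = init)
    node <- function(tests = list(), cutpoint = NA_real_, children = list(),
                     note = "") {
      new("PartitionNode", condition = condition, n = as.integer(n),
          fit = fit, tests = tests, cutpoint = cutpoint,
          children = children, note = note)
    }
    if (n < 2L * minSize)
      return(node(note = "below twice the minimum size; not tested"))
    scores <- scoreContributions(fit)
    tests <- lapply(activeSubsets, function(ss)
      invarianceTest(fit, cov, kind = kind, subset = ss,
                     statistic = statistic, covariateName = covariateName,
                     scores = scores))
    names(tests) <- vapply(activeSubsets, paste, character(1), collapse = "+")
    pvals <- vapply(tests, function(tt) tt@pValue, numeric(1))
    if (min(pvals) >= level || depth >= maxDepth)
      return(node(tests = tests))
    childSubsets <- if (retestAll) activeSubsets
                    else activeSubsets[pvals < level]
    if (kind == "categorical") {
      fc <- tryCatch(findCategoricalCut(resp, cov, model, options, minSize,
                                        init = fit@psi),
                     error = function(e) e)
      if (inherits(fc, "error")) return(node(tests = tests, note = conditionMessage(fc)))
      inSet <- cov %in% fc$set
      condL <- sprintf("%s in {%s}", covariateName, paste(fc$set, collapse = ","))
      condR <- sprintf("%s not in {%s}", covariateName, paste(fc$set, collapse = ","))
      cutVal <- NA_real_
    } else {
      fc <- tryCatch(findCutpoint(resp, cov, model, options, minSize,
                                  maxCandidates, init = fit@psi),
                     error = function(e) e)
      if (inherits(fc, "error")) return(node(tests = tests, note = conditionMessage(fc)))
      inSet <- cov <= fc$cutpoint
      condL <- sprintf("%s <= %s", covariateName, format(fc$cutpoint))
      condR <- sprintf("%s > %s", covariateName, format(fc$cutpoint))
      cutVal <- fc$cutpoint
    }
    kids <- list(
      grow(resp[inSet, , drop = FALSE], cov[inSet], condL, depth + 1L,
           childSubsets, fit@psi),
      grow(resp[!inSet, , drop = FALSE], cov[!inSet], condR, depth + 1L,
           childSubsets, fit@psi))
    node(tests = tests, cutpoint = cutVal, children = kids)
  }
  grow(responses, covariate, "<all respondents>", 0L, subsets, NULL)
}

partitionRows <- function(node, depth = 0L) {
  st <- paramStructures(node@fit@model, node@fit@psi)
  row <- data.frame(
    depth = depth, condition = node@condition, n = node@n,
    alphaNm = mean(st$alphaNm), alphaE = mean(st$alphaE),
    cutpoint = node@cutpoint,
    minP = if (length(node@tests))
      min(vapply(node@tests, function(tt) tt@pValue, numeric(1))) else NA_real_,
    note = node@note, stringsAsFactors = FALSE)
  do.call(rbind, c(list(row),
                   lapply(node@children, partitionRows, depth = depth + 1L)))
}

#' Flat summary of a partition tree
#'
#' @param node a \code{\linkS4class{PartitionNode}}.
#' @return data frame with one row per node (depth, condition, n, mean
#'   loadings, cutpoint, smallest test p-value, note).
#' @export
partitionTable <- function(node) partitionRows(node)

#' Export a partition tree as JSON
#'
#' @param node a \code{\linkS4class{PartitionNode}}.
#' @param path output file.
#' @export
writePartitionJSON <- function(node, path) {
  asList <- function(nd) {
    st <- paramStructures(nd@fit@model, nd@fit@psi)
    list(condition = nd@condition, n = nd@n,
         loglik = nd@fit@loglik,
         alphaNm = mean(st$alphaNm), alphaE = mean(st$alphaE),
         tests = lapply(nd@tests, function(tt)
           list(statistic = tt@statisticName, value = tt@statistic,
                p = tt@pValue, subset = tt@subset)),
         cutpoint = if (is.na(nd@cutpoint)) NULL else nd@cutpoint,
         note = if (nzchar(nd@note)) nd@note else NULL,
         children = lapply(nd@children, asList))
  }
  jsonlite::write_json(asList(node), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
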
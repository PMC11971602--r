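#' Per-person score contributions at the estimate
#'
#' Row v is the gradient of person v's marginal log-likelihood with respect
#' to the full free parameter vector Psi, evaluated by the same quadrature
#' rule as the fit.  At the MLE the columns sum to (numerically) zero.
#'
#' @param fit an \code{\linkS4class{IRTreeFit}}.
#' @param psi optional parameter vector at which to evaluate (default: the
#'   estimate; other values are useful for derivative checks).
#' @param responses optional category matrix to score other data.
#' @return N x p matrix with registry parameter names as columns.
#' @export
scoreContributions <- function(fit, psi = NULL, responses = NULL) {
  model <- fit@model
  Y <- if (is.null(responses)) fit@pseudoData
       else expandResponses(responses, model@tree)
  if (is.null(psi)) psi <- fit@psi
  quad <- fit@quad
  ctx <- makeLikContext(Y, quad)
  lp <- likParts(model, psi, quad)
  P <- plogis(lp$LP)
  post <- posteriorParts(ctx, lp)
  W <- post$W
  N <- nrow(Y); D <- latentDims(model)
  reg <- model@registry
  S <- matrix(0, N, nrow(reg), dimnames = list(NULL, reg$name))
  ## intercepts: posterior-expected working residuals
  G <- ctx$Y1 - ctx$obs * (W %*% P)
  S[, reg$type == "delta"] <- G
  ## weighted residual moments against latent values (Z) and standard nodes (X)
  momFor <- function(col) {
    ctx$Y1 * as.vector(W %*% col) - ctx$obs * (W %*% (P * as.vector(col)))
  }
  TZ <- lapply(seq_len(model@nTraits), function(d) momFor(lp$Z[, d]))
  TX <- lapply(seq_len(D), function(e) momFor(quad$X[, e]))
  item <- pseudoItemOf(model); node <- pseudoNodeOf(model)
  td <- model@itemTraitMap[item]
  sgn <- c(1, -1, 1, -1, 1)[node]
  accum <- function(js) {
    out <- numeric(N)
    for (j in js) out <- out + sgn[j] * TZ[[td[j]]][, j]
    out
  }
  if (model@variant == "rasch") {
    S[, reg$type == "alpha_nm"] <- accum(which(node %in% 2:3))
    S[, reg$type == "alpha_e"]  <- accum(which(node %in% 4:5))
  } else {
    for (i in seq_len(model@nItems)) {
      S[, reg$type == "alpha1" & reg$item == i]   <- accum(which(item == i & node == 1L))
      S[, reg$type == "alpha_nm" & reg$item == i] <- accum(which(item == i & node %in% 2:3))
      S[, reg$type == "alpha_e" & reg$item == i]  <- accum(which(item == i & node %in% 4:5))
    }
  }
  ch <- which(reg$type == "chol")
  Ld <- diag(lp$st$L)
  for (k in ch) {
    d <- reg$dim1[k]; e <- reg$dim2[k]
    v <- as.vector(TX[[e]] %*% lp$st$A[d, ])
    if (reg$logScale[k]) v <- v * Ld[d]
    S[, k] <- v
  }
  S
}

#' Outer-product-of-gradients covariance of the score contributions
#'
#' The uncentered cross-product convention \code{I-hat = (1/N) sum s_v s_v'}
#' is used: at the MLE the mean score is zero, so centering is asymptotically
#' irrelevant, and the uncentered form matches the observed cross-product of
#' the gradients.
#'
#' @param scores N x p score matrix.
#' @return symmetric positive semi-definite p x p matrix.
#' @export
opgCovariance <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) <= ncol(scores))
    warning("N <= p: the OPG covariance estimate is rank deficient")
  crossprod(scores) / nrow(scores)
}

## symmetric inverse square root with an eigenvalue floor; eigenvalues below
## the floor indicate a (numerically) singular information block
matInvSqrt <- function(M, floor = 1e-10) {
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(eg$values < floor * max(eg$values)))
    stop("information matrix is rank deficient; test a smaller parameter subset")
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

#' Ordering of persons by a covariate
#'
#' Builds the ordering used by the cumulative score process.  Metric
#' covariates are sorted with tied values forming one block; the process is
#' only evaluated at block boundaries since the within-block order is
#' arbitrary.  Ordinal and categorical covariates form one block per
#' category, with boundaries at the cumulative category counts.
#'
#' @param x covariate vector (numeric, or factor for categorical).
#' @param kind \code{"metric"}, \code{"ordinal"} or \code{"categorical"}.
#' @return list with the permutation \code{order}, evaluation indices
#'   \code{blockEnds}, their proportions \code{t}, the number of categories
#'   \code{m} (NA for metric), the block values, and \code{kind}.
#' @export
covariateOrdering <- function(x, kind = c("metric", "ordinal", "categorical")) {
  kind <- match.arg(kind)
  n <- length(x)
  if (is.factor(x) && kind != "categorical") x <- as.numeric(x)
  if (length(unique(x[!is.na(x)])) < 2L)
    stop("constant covariate carries no ordering information")
  if (anyNA(x)) stop("missing values in the covariate")
  if (kind == "categorical" && !is.factor(x)) x <- factor(x)
  ord <- order(if (is.factor(x)) as.integer(x) else x)
  xs <- x[ord]
  blockEnds <- which(xs[-n] != xs[-1L])
  blockEnds <- c(blockEnds, n)
  values <- xs[blockEnds]
  m <- if (kind == "metric") NA_integer_ else length(blockEnds)
  if (!is.na(m) && m < 2L) stop("fewer than two observed categories")
  list(order = ord, blockEnds = blockEnds, t = blockEnds / n,
       values = values, m = m, kind = kind, n = n)
}

#' Decorrelated cumulative score process
#'
#' Orders the score contributions by the covariate, restricts them to the
#' tested parameter subset, and forms
#' \code{B(t) = Ihat^{-1/2} N^{-1/2} * cumulative sums}.  By default the
#' covariance used for decorrelation is the subset block of the full OPG
#' covariance (the tested parameters' own cross-products);
#' \code{decorrelate = "full"} instead decorrelates all parameters jointly
#' and then selects the subset columns (non-default, for sensitivity checks).
#'
#' @param scores N x p score matrix with parameter names.
#' @param ordering a \code{\link{covariateOrdering}}.
#' @param subset character vector of tested parameter names (default: all).
#' @param decorrelate \code{"subset"} (default) or \code{"full"}.
#' @return a \code{\linkS4class{FluctuationProcess}}.
#' @export
fluctuationProcess <- function(scores, ordering, subset = colnames(scores),
                               decorrelate = c("subset", "full")) {
  decorrelate <- match.arg(decorrelate)
  scores <- as.matrix(scores)
  if (length(subset) == 0L) stop("empty parameter subset")
  if (!all(subset %in% colnames(scores)))
    stop("subset parameters not found in the score matrix: ",
         paste(setdiff(subset, colnames(scores)), collapse = ", "))
  N <- nrow(scores)
  stopifnot(length(ordering$order) == N)
  if (decorrelate == "subset") {
    sub <- scores[ordering$order, subset, drop = FALSE]
    info <- opgCovariance(scores)[subset, subset, drop = FALSE]
    B <- apply(sub, 2L, cumsum) %*% matInvSqrt(info) / sqrt(N)
  } else {
    info <- opgCovariance(scores)
    dec <- scores[ordering$order, , drop = FALSE] %*% matInvSqrt(info)
    colnames(dec) <- colnames(scores)
    B <- apply(dec[, subset, drop = FALSE], 2L, cumsum) / sqrt(N)
    info <- info[subset, subset, drop = FALSE]
  }
  if (N == 1L) B <- matrix(B, 1L)
  colnames(B) <- subset
  new("FluctuationProcess", B = B, subset = subset, info = info,
      ordering = ordering, nPersons = as.integer(N))
}

#' Export a score matrix or fluctuation process as delimited text
#'
#' @param x a score matrix or \code{\linkS4class{FluctuationProcess}}.
#' @param path output file.
#' @param sep field separator.
#' @export
writeProcessTable <- function(x, path, sep = ",") {
  if (is(x, "FluctuationProcess")) {
    df <- data.frame(index = seq_len(nrow(x@B)),
                     t = seq_len(nrow(x@B)) / x@nPersons, x@B,
                     check.names = FALSE)
  } else {
    df <- data.frame(index = seq_len(nrow(x)), x, check.names = FALSE)
  }
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom graphics abline lines matplot
#' @describeIn fluctuationProcess plot method: one line per tested parameter
#'   with category-boundary markers for ordinal/categorical covariates.
#' @param x,y,... standard plot arguments.
#' @export
setMethod("plot", signature(x = "FluctuationProcess", y = "missing"),
  function(x, y, ...) {
    tgrid <- seq_len(x@nPersons) / x@nPersons
    matplot(tgrid, x@B, type = "l", lty = 1, xlab = "t (covariate order)",
            ylab = "decorrelated cumulative score", ...)
    abline(h = 0, col = "grey")
    if (x@ordering$kind != "metric")
      abline(v = head(x@ordering$t, -1L), lty = 3, col = "grey40")
    invisible(x)
  })
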
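## Marginal maximum likelihood for the IRTree model.
##
## The latent vector is integrated out on a fixed (non-adaptive) Gauss-Hermite
## product grid for a standard normal latent vector u; the covariance enters
## through z = L u with L the free Cholesky factor, so the prior carries no
## parameters and all free parameters sit in the measurement part.  The same
## grid is shared by fitting, person-wise log-likelihoods and score
## contributions, so the score identity (columns of the score matrix summing
## to zero at the MLE) holds numerically.

#' Gauss-Hermite product grid for a standard normal latent vector
#'
#' @param D number of latent dimensions.
#' @param pointsPerDim quadrature points per dimension (>= 3).
#' @return list with nodes \code{X} (Q x D) and weights \code{w} (sum 1).
#' @export
ghGrid <- function(D, pointsPerDim) {
  stopifnot(pointsPerDim >= 3L)
  gh <- pracma::gaussHermite(pointsPerDim)
  z <- gh$x * sqrt(2)
  w <- gh$w / sqrt(pi)
  X <- as.matrix(expand.grid(rep(list(z), D), KEEP.OUT.ATTRS = FALSE))
  Wg <- as.matrix(expand.grid(rep(list(w), D), KEEP.OUT.ATTRS = FALSE))
  dimnames(X) <- NULL
  list(X = X, w = exp(rowSums(log(Wg))))
}

#' Estimation options
#'
#' @param method \code{"em"} (quadrature EM, default) or \code{"bfgs"}
#'   (direct quasi-Newton on the same quadrature marginal likelihood; both
#'   are deterministic and maximize the identical objective).
#' @param quadPoints quadrature points per latent dimension; default 11 for
#'   up to 3 latent dimensions, 7 for 4.
#' @param tol convergence threshold on the maximum absolute parameter change
#'   between outer iterations (default .001).
#' @param maxIter maximum outer iterations.
#' @param minPersons documented minimum sample size; smaller samples error.
#' @param verbose print progress.
#' @return list of options for \code{\link{fitIRTree}}.
#' @export
fitOptions <- function(method = c("em", "bfgs"), quadPoints = NULL,
                       tol = 1e-3, maxIter = 500L, minPersons = 100L,
                       verbose = FALSE) {
  stopifnot(tol > 0)
  list(method = match.arg(method), quadPoints = quadPoints, tol = tol,
       maxIter = as.integer(maxIter), minPersons = as.integer(minPersons),
       verbose = isTRUE(verbose))
}

## linear predictors and log response probabilities on the grid
likParts <- function(model, psi, quad) {
  st <- paramStructures(model, psi)
  Z <- quad$X %*% t(st$L)
  LP <- Z %*% st$A
  LP <- sweep(LP, 2L, st$delta, "+")
  list(st = st, Z = Z, LP = LP,
       logP = plogis(LP, log.p = TRUE), log1mP = plogis(-LP, log.p = TRUE))
}

## per-fit constants: indicator matrices and the quadrature-weight matrix
makeLikContext <- function(Y, quad) {
  obs <- !is.na(Y)
  Y1 <- matrix(0, nrow(Y), ncol(Y)); Y1[obs & Y == 1L] <- 1
  Y0 <- matrix(0, nrow(Y), ncol(Y)); Y0[obs & Y == 0L] <- 1
  list(Y1 = Y1, Y0 = Y0, obs = obs + 0, YY = cbind(Y1, Y0),
       w = quad$w, wRow = matrix(quad$w, nrow(Y), length(quad$w),
                                 byrow = TRUE))
}

## person-wise marginal log-likelihood and posterior grid weights; one GEMM
## and one exp per evaluation
posteriorParts <- function(ctx, lp, wantW = TRUE) {
  Lmat <- ctx$YY %*% t(cbind(lp$logP, lp$log1mP))
  mx <- Lmat[cbind(seq_len(nrow(Lmat)), max.col(Lmat, "first"))]
  expL <- exp(Lmat - mx)
  s <- as.vector(expL %*% ctx$w)
  out <- list(ll = mx + log(s))
  if (wantW) out$W <- (expL * ctx$wRow) / s
  out
}

## expected complete-data log-likelihood (the EM Q-function) and its gradient
qFunction <- function(model, psi, quad, C1, C0) {
  lp <- likParts(model, psi, quad)
  sum(C1 * lp$logP) + sum(C0 * lp$log1mP)
}

qGradient <- function(model, psi, quad, C1, C0) {
  lp <- likParts(model, psi, quad)
  P <- plogis(lp$LP)
  Gq <- C1 - (C1 + C0) * P            # Q x J expected working residuals
  reg <- model@registry
  grad <- numeric(nrow(reg))
  names(grad) <- reg$name
  grad[reg$type == "delta"] <- colSums(Gq)
  GZ <- crossprod(Gq, lp$Z)           # J x D
  item <- pseudoItemOf(model); node <- pseudoNodeOf(model)
  td <- model@itemTraitMap[item]
  sgn <- c(1, -1, 1, -1, 1)[node]
  contrib <- sgn * GZ[cbind(seq_along(item), td)]
  if (model@variant == "rasch") {
    grad[reg$type == "alpha_nm"] <- sum(contrib[node %in% 2:3])
    grad[reg$type == "alpha_e"]  <- sum(contrib[node %in% 4:5])
  } else {
    grad[reg$type == "alpha1"]   <- rowsum(contrib * (node == 1L), item)[, 1L]
    grad[reg$type == "alpha_nm"] <- rowsum(contrib * (node %in% 2:3), item)[, 1L]
    grad[reg$type == "alpha_e"]  <- rowsum(contrib * (node %in% 4:5), item)[, 1L]
  }
  dL <- lp$st$A %*% crossprod(Gq, quad$X)   # D x D
  ch <- which(reg$type == "chol")
  v <- dL[cbind(reg$dim1[ch], reg$dim2[ch])]
  lg <- reg$logScale[ch]
  v[lg] <- v[lg] * diag(lp$st$L)[reg$dim1[ch][lg]]
  grad[ch] <- v
  grad
}

checkPseudoData <- function(Y, model) {
  nm <- colnames(Y)
  for (j in seq_len(ncol(Y))) {
    yj <- Y[, j]
    yj <- yj[!is.na(yj)]
    if (length(yj) == 0L)
      stop(sprintf("pseudo-item %s is never reached in the data", nm[j]))
    if (all(yj == 0L) || all(yj == 1L))
      stop(sprintf("degenerate pseudo-item %s: only outcome %d observed",
                   nm[j], yj[1L]))
  }
  invisible(TRUE)
}

#' Fit an IRTree model by marginal maximum likelihood
#'
#' Estimates the structural parameters (loadings, intercepts and latent
#' covariance; latent means fixed at zero) by numerical-quadrature marginal
#' ML.  The default algorithm is an EM iteration whose M-step maximizes the
#' expected complete-data log-likelihood by quasi-Newton; the marginal
#' log-likelihood is non-decreasing across EM iterations.  \code{"bfgs"}
#' maximizes the same objective directly with the analytic marginal gradient.
#'
#' @param responses N x I matrix of Likert categories 0..5 (NA allowed), or
#'   an already expanded pseudo-item matrix if \code{expanded = TRUE}.
#' @param model an \code{\linkS4class{IRTreeModel}}; default Rasch-style
#'   single-trait model for \code{ncol(responses)} items.
#' @param options see \code{\link{fitOptions}}.
#' @param init optional starting values for Psi (warm starts).
#' @param expanded set TRUE when passing pseudo-item data directly.
#' @return an \code{\linkS4class{IRTreeFit}}.  Non-convergence within
#'   \code{maxIter} yields a warning and \code{converged = FALSE}, not an
#'   error.  A negative estimate of a trait loading triggers a warning (the
#'   positivity of alpha_nm, alpha_e is a modeling assumption, not an
#'   optimizer bound).
#' @examples
#' \donttest{
#' sim <- simulateStudyData(simConfig(nPersons = 300, replications = 1), 1)
#' fit <- fitIRTree(sim$responses, sim$model,
#'                  options = fitOptions(quadPoints = 3))
#' coef(fit)[c("alpha_nm", "alpha_e")]
#' }
#' @export
fitIRTree <- function(responses, model = NULL, options = fitOptions(),
                      init = NULL, expanded = FALSE) {
  if (expanded) {
    Y <- as.matrix(responses)
    if (is.null(model)) stop("model must be given with expanded data")
  } else {
    if (is.null(model)) model <- irtreeModel(ncol(as.matrix(responses)))
    Y <- expandResponses(responses, model@tree)
  }
  if (ncol(Y) != nPseudo(model))
    stop("data has ", ncol(Y), " pseudo-items but the model expects ", nPseudo(model))
  N <- nrow(Y)
  if (N < 10L) stop("too few persons (N = ", N, ")")
  if (N < options$minPersons)
    warning("N = ", N, " is below the documented minimum of ", options$minPersons)
  checkPseudoData(Y, model)
  D <- latentDims(model)
  qp <- options$quadPoints
  if (is.null(qp)) qp <- if (D <= 3L) 11L else 7L
  quad <- ghGrid(D, qp)
  ctx <- makeLikContext(Y, quad)
  J <- nPseudo(model)
  psi <- if (is.null(init)) defaultPsi(model) else init
  stopifnot(length(psi) == nParams(model))

  llPath <- numeric(0)
  converged <- FALSE
  iter <- 0L
  if (options$method == "em") {
    repeat {
      iter <- iter + 1L
      lp <- likParts(model, psi, quad)
      post <- posteriorParts(ctx, lp)
      llPath <- c(llPath, sum(post$ll))
      CC <- crossprod(post$W, ctx$YY)
      C1 <- CC[, seq_len(J), drop = FALSE]
      C0 <- CC[, J + seq_len(J), drop = FALSE]
      ## capped quasi-Newton M-step: a generalized EM step that increases the
      ## Q-function, keeping the marginal log-likelihood monotone
      opt <- optim(psi, fn = function(p) -qFunction(model, p, quad, C1, C0),
                   gr = function(p) -qGradient(model, p, quad, C1, C0),
                   method = "BFGS", control = list(maxit = 25, reltol = 1e-10))
      delta <- max(abs(opt$par - psi))
      psi <- opt$par
      if (options$verbose)
        message(sprintf("EM iter %d: loglik %.4f, max |dPsi| %.2e",
                        iter, llPath[iter], delta))
      if (delta < options$tol) { converged <- TRUE; break }
      if (iter >= options$maxIter) break
    }
  } else {
    ## the posterior weights from the last objective evaluation are cached so
    ## that the gradient (only requested at accepted points) reuses them
    env <- new.env()
    env$key <- NULL
    evalLik <- function(p) {
      if (!identical(p, env$key)) {
        lp <- likParts(model, p, quad)
        post <- posteriorParts(ctx, lp)
        env$key <- p
        env$ll <- sum(post$ll)
        env$W <- post$W
      }
      invisible(NULL)
    }
    opt <- optim(psi, fn = function(p) { evalLik(p); -env$ll },
                 gr = function(p) {
                   evalLik(p)
                   CC <- crossprod(env$W, ctx$YY)
                   -qGradient(model, p, quad, CC[, seq_len(J), drop = FALSE],
                              CC[, J + seq_len(J), drop = FALSE])
                 },
                 method = "BFGS",
                 control = list(maxit = options$maxIter, reltol = 1e-10))
    psi <- opt$par
    iter <- as.integer(opt$counts[["gradient"]])
    converged <- opt$convergence == 0L
  }
  ## final evaluation at psi-hat
  lp <- likParts(model, psi, quad)
  post <- posteriorParts(ctx, lp)
  CC <- crossprod(post$W, ctx$YY)
  grad <- qGradient(model, psi, quad, CC[, seq_len(J), drop = FALSE],
                    CC[, J + seq_len(J), drop = FALSE])
  if (!converged)
    warning("IRTree fit did not converge within ", options$maxIter,
            " iterations (max |score| = ", format(max(abs(grad)), digits = 3), ")")
  st <- paramStructures(model, psi)
  if (any(st$alphaNm < 0) || any(st$alphaE < 0))
    warning("negative trait loading estimate; the model assumes alpha_nm, alpha_e > 0")
  names(psi) <- paramNames(model)
  new("IRTreeFit", model = model, psi = psi, sigma = st$Sigma,
      loglik = sum(post$ll), nPersons = as.integer(N), converged = converged,
      iterations = iter, method = options$method, gradNorm = max(abs(grad)),
      loglikPath = llPath, quad = c(quad, list(pointsPerDim = qp)),
      pseudoData = Y)
}

#' Per-person marginal log-likelihood
#'
#' Evaluates the log of the latent-space integral of the conditional
#' Bernoulli likelihood for each person, using the same quadrature rule as
#' the fit, at \code{psi} (default: the estimate).  Summing over persons
#' reproduces the fitted total log-likelihood; a person with all responses
#' missing contributes 0.
#'
#' @param fit an \code{\linkS4class{IRTreeFit}}.
#' @param responses optional category matrix to evaluate on other data.
#' @param psi optional parameter vector.
#' @return numeric vector of length N.
#' @export
personLogLik <- function(fit, responses = NULL, psi = NULL) {
  Y <- if (is.null(responses)) fit@pseudoData
       else expandResponses(responses, fit@model@tree)
  if (is.null(psi)) psi <- fit@psi
  ctx <- makeLikContext(Y, fit@quad)
  lp <- likParts(fit@model, psi, fit@quad)
  posteriorParts(ctx, lp, wantW = FALSE)$ll
}

#' Summed log-likelihood of two independent subgroup fits at a cutpoint
#'
#' Splits the sample at \code{cut} on the covariate (left: value <= cut),
#' refits the full model independently on each side (all item parameters and
#' the latent covariance are allowed to differ) and returns the sum of the
#' two log-likelihoods, the quantity maximized by the cutpoint search.
#'
#' @param responses N x I category matrix.
#' @param covariate numeric person covariate.
#' @param cut split value.
#' @param model an \code{\linkS4class{IRTreeModel}}.
#' @param options \code{\link{fitOptions}} for the subgroup fits.
#' @param minSize minimum subsample size per side (default 300).
#' @param init optional warm-start parameter vector (e.g. the pooled
#'   estimate).
#' @return list with \code{loglik} (sum), \code{left} and \code{right} fits.
#' @export
splitLogLik <- function(responses, covariate, cut, model,
                        options = fitOptions(), minSize = 300L, init = NULL) {
  responses <- as.matrix(responses)
  stopifnot(length(covariate) == nrow(responses))
  left <- covariate <= cut
  if (sum(left) < minSize || sum(!left) < minSize)
    stop(sprintf("split at %s leaves a subsample below the minimum size %d (%d | %d)",
                 format(cut), minSize, sum(left), sum(!left)))
  fl <- fitIRTree(responses[left, , drop = FALSE], model, options, init = init)
  fr <- fitIRTree(responses[!left, , drop = FALSE], model, options, init = init)
  list(loglik = fl@loglik + fr@loglik, left = fl, right = fr)
}
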
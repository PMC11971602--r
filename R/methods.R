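#' @importFrom stats coef logLik
NULL

setMethod("show", "IRTreeSpec", function(object) {
  cat(sprintf("IRTree with %d categories and %d decision nodes\n",
              object@nCategories, object@nNodes))
  print(object@branchTable)
})

setMethod("show", "IRTreeModel", function(object) {
  cat(sprintf("IRTree model: %d items, %d trait(s) + 2 response styles, %s variant\n",
              object@nItems, object@nTraits, object@variant))
  cat(sprintf("  %d pseudo-items, %d free parameters\n",
              nPseudo(object), nParams(object)))
})

setMethod("show", "IRTreeFit", function(object) {
  cat(sprintf("IRTree fit (%s): N = %d, loglik = %.3f, %sconverged in %d iterations\n",
              object@method, object@nPersons, object@loglik,
              if (object@converged) "" else "NOT ", object@iterations))
  st <- paramStructures(object@model, object@psi)
  if (object@model@variant == "rasch") {
    cat(sprintf("  alpha_nm = %.3f, alpha_e = %.3f\n",
                st$alphaNm[1L], st$alphaE[1L]))
  } else {
    cat(sprintf("  mean loadings: agree %.3f, nonmoderate %.3f, extreme %.3f\n",
                mean(st$alpha1), mean(st$alphaNm), mean(st$alphaE)))
  }
  cat("  latent covariance:\n")
  print(round(object@sigma, 3))
})

#' @describeIn fitIRTree estimated parameter vector Psi.
#' @param object an \code{IRTreeFit}.
#' @export
setMethod("coef", "IRTreeFit", function(object, ...) object@psi)

#' @describeIn fitIRTree total marginal log-likelihood with attributes
#'   \code{df} and \code{nobs}.
#' @export
setMethod("logLik", "IRTreeFit", function(object, ...) {
  structure(object@loglik, df = nParams(object@model),
            nobs = object@nPersons, class = "logLik")
})

#' Accessors for fitted IRTree models
#'
#' @param fit an \code{\linkS4class{IRTreeFit}}.
#' @return \code{latentCovariance}: the estimated covariance matrix of the
#'   latent dimensions; \code{traitLoadings}: the estimated trait loadings
#'   (per item in the itemwise variant).
#' @export
latentCovariance <- function(fit) fit@sigma

#' @rdname latentCovariance
#' @export
traitLoadings <- function(fit) {
  st <- paramStructures(fit@model, fit@psi)
  list(alpha1 = st$alpha1, alphaNm = st$alphaNm, alphaE = st$alphaE)
}

#' @rdname latentCovariance
#' @export
interceptMatrix <- function(fit) {
  d <- matrix(paramStructures(fit@model, fit@psi)$delta,
              ncol = 5L, byrow = TRUE)
  dimnames(d) <- list(paste0("item", seq_len(fit@model@nItems)),
                      paste0("d", 1:5))
  d
}

setMethod("show", "FluctuationProcess", function(object) {
  cat(sprintf("Fluctuation process: N = %d, %d tested parameter(s) [%s], %s covariate\n",
              object@nPersons, length(object@subset),
              paste(object@subset, collapse = ", "), object@ordering$kind))
  cat(sprintf("  terminal value (should be ~0 at the MLE): max |B_N| = %.2e\n",
              max(abs(object@B[nrow(object@B), ]))))
})

setMethod("show", "InvarianceTest", function(object) {
  cat(sprintf("Score-based invariance test (%s, %s covariate '%s')\n",
              object@statisticName, object@covariateKind, object@covariateName))
  cat(sprintf("  parameters tested (k = %d): %s\n", object@k,
              paste(object@subset, collapse = ", ")))
  cat(sprintf("  statistic = %.4f, p = %.4g (%s%s)\n", object@statistic,
              object@pValue, object@pMethod,
              if (object@pMethod == "simulated")
                sprintf(", nsim = %d, seed = %d", object@nsim,
                        as.integer(object@seed)) else ""))
})

setMethod("show", "PartitionNode", function(object) {
  rec <- function(nd, indent) {
    pad <- strrep("  ", indent)
    st <- paramStructures(nd@fit@model, nd@fit@psi)
    cat(sprintf("%s%s  [n = %d, alpha_nm = %.3f, alpha_e = %.3f]\n",
                pad, nd@condition, nd@n, mean(st$alphaNm), mean(st$alphaE)))
    for (tt in nd@tests)
      cat(sprintf("%s  test %s on %s: stat = %.3f, p = %.4g\n", pad,
                  tt@statisticName, paste(tt@subset, collapse = "+"),
                  tt@statistic, tt@pValue))
    if (!is.na(nd@cutpoint))
      cat(sprintf("%s  split at %s\n", pad, format(nd@cutpoint)))
    if (nzchar(nd@note)) cat(sprintf("%s  note: %s\n", pad, nd@note))
    for (ch in nd@children) rec(ch, indent + 1L)
  }
  rec(object, 0L)
})
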
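## Shared fixtures, built once per test run and memoized.  Everything is
## generated in code; sizes are kept small (coarse quadrature, moderate N)
## because these fixtures back unit tests, not calibration experiments.

.fixtures <- new.env()

## two-trait study-design replicate with a converged fit (no heterogeneity)
sharedNullFit <- function() {
  if (is.null(.fixtures$null)) {
    cfg <- simConfig(nPersons = 500, replications = 1, quadPoints = 3,
                     covariate = "metric", seed = 11)
    dat <- simulateStudyData(cfg, 1)
    fit <- fitIRTree(dat$responses, dat$model,
                     fitOptions(method = "bfgs", quadPoints = 3))
    .fixtures$null <- list(dat = dat, fit = fit,
                           scores = scoreContributions(fit))
  }
  .fixtures$null
}

## single-trait (3-dimensional) empirical-style data at given loadings
makeOneTraitData <- function(n, alphaNm = 0.75, alphaE = 0.6, seed = 1,
                             nItems = 6) {
  ip <- simulateItemParams(nItems, alphaNm, alphaE, nTraits = 1L,
                           seed = 900 + nItems)
  latent <- simulateLatent(n, defaultLatentCovariance(1L), seed = seed)
  resp <- simulateResponses(latent, ip, seed = seed + 1L)
  list(responses = resp, model = ip$model, itemParams = ip, latent = latent)
}

## build a FluctuationProcess by hand from a given B matrix and ordering
manualProcess <- function(B, ordering) {
  new("FluctuationProcess", B = as.matrix(B),
      subset = colnames(B) %||% paste0("p", seq_len(ncol(as.matrix(B)))),
      info = diag(ncol(as.matrix(B))), ordering = ordering,
      nPersons = as.integer(nrow(as.matrix(B))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ordering object for n persons with given covariate values
orderingFor <- function(x, kind) covariateOrdering(x, kind)
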
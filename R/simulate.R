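## Synthetic data generator emulating the simulation design: two substantive
## traits loading on half of the items each plus nonmoderate and extreme
## response-style dimensions, uniform intercept distributions, two-group /
## metric / ordinal person covariates, and additive shifts on the trait
## loadings alpha_nm and alpha_e in a focal group.

#' Default latent covariance of the study design
#'
#' For two traits: variances 2.89 and 1.44 with correlation .5 between the
#' traits, style variances 1.00 and 2.25 with correlation .5, traits and
#' styles uncorrelated.  For one trait (empirical-style three-dimensional
#' model) the first trait block is kept and the second dropped.
#'
#' @param nTraits 1 or 2.
#' @return covariance matrix of dimension nTraits + 2.
#' @export
defaultLatentCovariance <- function(nTraits = 2L) {
  full <- rbind(c(2.89, 1.02, 0.00, 0.00),
                c(1.02, 1.44, 0.00, 0.00),
                c(0.00, 0.00, 1.00, 0.75),
                c(0.00, 0.00, 0.75, 2.25))
  if (nTraits == 2L) full else full[-2L, -2L]
}

#' Draw latent person parameters
#'
#' Rows are i.i.d. multivariate normal with mean zero and covariance
#' \code{sigma} (traits first, then eta_nm, eta_e).
#'
#' @param n number of persons.
#' @param sigma positive-definite covariance matrix.
#' @param seed RNG seed (optional).
#' @return n x ncol(sigma) matrix.
#' @export
simulateLatent <- function(n, sigma = defaultLatentCovariance(), seed = NULL) {
  R <- tryCatch(chol(sigma), error = function(e)
    stop("sigma must be positive definite"))
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * ncol(sigma)), n) %*% R
}

#' Draw item parameters for the study design
#'
#' Intercepts are uniform: d1 ~ U(-1, 1) at the agreement node, d2, d3 ~
#' U(-1, .5) at the nonmoderate nodes, d4, d5 ~ U(-2.5, -1.5) at the
#' extremity nodes.  The first half of the items loads on trait 1, the
#' second half on trait 2.
#'
#' @param nItems number of rating items (6 or 10 in the study design).
#' @param alphaNm,alphaE base trait loadings at the nonmoderate/extremity
#'   nodes.
#' @param nTraits number of traits (2 in the study design).
#' @param seed RNG seed; the study design keeps item parameters fixed for all
#'   cells with the same test length, so callers derive this from the test
#'   length, not from the cell seed.
#' @return list with \code{delta} (nItems x 5), \code{alphaNm},
#'   \code{alphaE}, \code{itemTraitMap} and the matching \code{model}.
#' @export
simulateItemParams <- function(nItems, alphaNm = 0.8, alphaE = 0.8,
                               nTraits = 2L, seed = NULL) {
  stopifnot(nItems >= 1L)
  if (!is.null(seed)) set.seed(seed)
  delta <- cbind(runif(nItems, -1, 1),
                 runif(nItems, -1, 0.5), runif(nItems, -1, 0.5),
                 runif(nItems, -2.5, -1.5), runif(nItems, -2.5, -1.5))
  colnames(delta) <- paste0("d", 1:5)
  model <- irtreeModel(nItems, nTraits = nTraits)
  list(delta = delta, alphaNm = alphaNm, alphaE = alphaE,
       itemTraitMap = model@itemTraitMap, model = model)
}

#' Draw a person covariate and the focal-group mask
#'
#' Kinds: \code{"categorical"} (two groups, probability .5 each; group 2 is
#' focal), \code{"metric"} (uniform on (20, 80); focal below the true change
#' point 40) and \code{"ordinal"} (integer categories 1..5 with the given
#' probabilities; focal at category 3 or less, i.e. the change lies between
#' categories 3 and 4).
#'
#' @param kind covariate kind.
#' @param n number of persons.
#' @param probs ordinal category probabilities (default uniform .2 each; the
#'   skewed design uses c(.1, .1, .35, .35, .1)).
#' @param seed RNG seed.
#' @return list with \code{value}, logical \code{focal}, and \code{kind}.
#' @export
simulateCovariate <- function(kind = c("categorical", "metric", "ordinal"),
                              n, probs = rep(0.2, 5), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  switch(kind,
    categorical = {
      value <- sample(1:2, n, replace = TRUE)
      list(value = factor(value), focal = value == 2L, kind = kind)
    },
    metric = {
      value <- runif(n, 20, 80)
      list(value = value, focal = value <= 40, kind = kind)
    },
    ordinal = {
      stopifnot(length(probs) == 5L, abs(sum(probs) - 1) < 1e-8)
      value <- sample(1:5, n, replace = TRUE, prob = probs)
      list(value = value, focal = value <= 3L, kind = kind)
    })
}

#' Simulate Likert responses from the IRTree model
#'
#' Generates categories 0..5 from the tree model with per-item node
#' probabilities implied by the latent values, item parameters and (for
#' focal-group members) shifted trait loadings.  A shifted loading is allowed
#' to be negative (off-design, no error).
#'
#' @param latent n x (nTraits + 2) latent matrix (traits, eta_nm, eta_e).
#' @param itemParams list from \code{\link{simulateItemParams}}.
#' @param focal logical focal-group mask (NULL for none).
#' @param shift additive loading shift in the focal group (0, +-.2, +-.5 in
#'   the study design).
#' @param shiftWhich apply the shift to both loadings (default, the study
#'   design) or to alpha_nm / alpha_e alone.
#' @param seed RNG seed.
#' @return n x nItems integer matrix of categories.
#' @export
simulateResponses <- function(latent, itemParams, focal = NULL, shift = 0,
                              shiftWhich = c("both", "alpha_nm", "alpha_e"),
                              seed = NULL) {
  shiftWhich <- match.arg(shiftWhich)
  if (!is.null(seed)) set.seed(seed)
  latent <- as.matrix(latent)
  n <- nrow(latent)
  nTraits <- ncol(latent) - 2L
  etaNm <- latent[, nTraits + 1L]; etaE <- latent[, nTraits + 2L]
  if (is.null(focal)) focal <- rep(FALSE, n)
  aNm <- rep(itemParams$alphaNm, n); aE <- rep(itemParams$alphaE, n)
  if (shiftWhich %in% c("both", "alpha_nm")) aNm[focal] <- aNm[focal] + shift
  if (shiftWhich %in% c("both", "alpha_e"))  aE[focal]  <- aE[focal] + shift
  nItems <- nrow(itemParams$delta)
  out <- matrix(NA_integer_, n, nItems)
  for (i in seq_len(nItems)) {
    th <- latent[, itemParams$itemTraitMap[i]]
    d <- itemParams$delta[i, ]
    p1 <- plogis(th + d[1L])
    p2 <- plogis(etaNm - aNm * th + d[2L])
    p3 <- plogis(etaNm + aNm * th + d[3L])
    p4 <- plogis(etaE - aE * th + d[4L])
    p5 <- plogis(etaE + aE * th + d[5L])
    pc <- cbind((1 - p1) * p2 * p4,        # 0: disagree, nonmoderate, extreme
                (1 - p1) * p2 * (1 - p4),  # 1
                (1 - p1) * (1 - p2),       # 2
                p1 * (1 - p3),             # 3
                p1 * p3 * (1 - p5),        # 4
                p1 * p3 * p5)              # 5
    u <- runif(n)
    cum <- pc %*% upper.tri(diag(6), diag = TRUE)
    out[, i] <- as.integer(rowSums(u > cum))
  }
  colnames(out) <- paste0("item", seq_len(nItems))
  out
}

#' Configuration of one simulation cell
#'
#' Defaults are the scaled-down harness settings (100 replications, N = 1000,
#' 6 items, 5 quadrature points per dimension); the full study design varies
#' nItems in {6, 10}, nPersons in {1000, 2000}, base loadings in {.2, .8} and
#' shifts in {0, +-.2, +-.5}.
#'
#' @param nItems,nPersons,alphaNm,alphaE,shift,shiftWhich design cell.
#' @param covariate covariate kind; \code{ordinalProbs} its distribution.
#' @param sigma latent covariance (default: the study matrix).
#' @param replications Monte-Carlo replications.
#' @param seed cell seed; replicate-level seeds are derived from it
#'   hierarchically so single replicates can be reproduced in isolation.
#' @param paramSeed seed for the item parameters; defaults to a test-length
#'   key (77000 + nItems) because the design holds item parameters fixed
#'   across cells of equal test length.
#' @param quadPoints,fitMethod,tol estimation settings for the harness.
#' @param level nominal test level.
#' @param statistic test statistic (default by covariate kind).
#' @param runCutpoint also run the cutpoint search on replicates where the
#'   \code{cutpointParam} test is significant (metric/ordinal designs).
#' @param cutpointParam whose test gates the cutpoint search (default:
#'   alpha_e unless only alpha_nm is shifted, mirroring the study's report).
#' @param minSize,maxCandidates cutpoint-search settings.
#' @return a \code{simConfig} list.
#' @export
simConfig <- function(nItems = 6L, nPersons = 1000L, alphaNm = 0.8,
                      alphaE = 0.8, shift = 0,
                      shiftWhich = c("both", "alpha_nm", "alpha_e"),
                      covariate = c("categorical", "metric", "ordinal"),
                      ordinalProbs = rep(0.2, 5),
                      sigma = defaultLatentCovariance(),
                      replications = 100L, seed = 1L, paramSeed = NULL,
                      quadPoints = 5L, fitMethod = "bfgs", tol = 1e-3,
                      level = 0.05, statistic = NULL, runCutpoint = FALSE,
                      cutpointParam = NULL, minSize = 300L,
                      maxCandidates = 15L) {
  shiftWhich <- match.arg(shiftWhich)
  covariate <- match.arg(covariate)
  if (is.null(paramSeed)) paramSeed <- 77000L + as.integer(nItems)
  if (is.null(cutpointParam))
    cutpointParam <- if (shiftWhich == "alpha_nm") "alpha_nm" else "alpha_e"
  structure(list(nItems = as.integer(nItems), nPersons = as.integer(nPersons),
                 alphaNm = alphaNm, alphaE = alphaE, shift = shift,
                 shiftWhich = shiftWhich, covariate = covariate,
                 ordinalProbs = ordinalProbs, sigma = sigma,
                 replications = as.integer(replications),
                 seed = as.integer(seed), paramSeed = as.integer(paramSeed),
                 quadPoints = as.integer(quadPoints), fitMethod = fitMethod,
                 tol = tol, level = level, statistic = statistic,
                 runCutpoint = isTRUE(runCutpoint),
                 cutpointParam = cutpointParam, minSize = as.integer(minSize),
                 maxCandidates = maxCandidates),
            class = "simConfig")
}

## replicate-level seed streams: cell seed -> replicate seed -> component
## seeds (persons, covariate, responses), all below 2^31
replicateSeeds <- function(config, replicate) {
  base <- withSeed(config$seed, sample.int(2^31 - 2L, config$replications))
  withSeed(base[replicate],
           setNames(sample.int(2^31 - 2L, 3L),
                    c("persons", "covariate", "responses")))
}

#' Generate one replicate of a simulation cell
#'
#' @param config a \code{\link{simConfig}}.
#' @param replicate replicate index in 1..replications.
#' @return list with \code{responses}, \code{covariate} (value vector),
#'   \code{kind}, \code{focal}, \code{model}, \code{itemParams},
#'   \code{latent} and the seeds used.
#' @export
simulateStudyData <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "simConfig"),
            replicate >= 1L, replicate <= config$replications)
  seeds <- replicateSeeds(config, replicate)
  itemParams <- simulateItemParams(config$nItems, config$alphaNm,
                                   config$alphaE, nTraits = 2L,
                                   seed = config$paramSeed)
  latent <- simulateLatent(config$nPersons, config$sigma,
                           seed = seeds[["persons"]])
  cov <- simulateCovariate(config$covariate, config$nPersons,
                           probs = config$ordinalProbs,
                           seed = seeds[["covariate"]])
  responses <- simulateResponses(latent, itemParams, focal = cov$focal,
                                 shift = config$shift,
                                 shiftWhich = config$shiftWhich,
                                 seed = seeds[["responses"]])
  list(responses = responses, covariate = cov$value, kind = cov$kind,
       focal = cov$focal, model = itemParams$model, itemParams = itemParams,
       latent = latent, seeds = seeds)
}

#' Run one simulation cell
#'
#' Per replicate: generate data, fit the two-trait IRTree model, run the two
#' separate score-based subset tests for alpha_nm and alpha_e with the
#' covariate-appropriate statistic, and (when configured) run the cutpoint
#' search on replicates whose gating test is significant.  Non-convergent
#' replicates are recorded and excluded from the aggregates, never dropped
#' silently.
#'
#' @param config a \code{\link{simConfig}}.
#' @param verbose print per-replicate progress.
#' @return an object of class \code{irtreeSimResult}: \code{records} (one
#'   row per replicate), \code{summary} (rejection rates for both tests
#'   among converged replicates, cutpoint mean/SD over significant
#'   replicates, convergence count) and the \code{config}.
#' @export
runSimulationCell <- function(config, verbose = FALSE) {
  opts <- fitOptions(method = config$fitMethod, quadPoints = config$quadPoints,
                     tol = config$tol)
  rows <- vector("list", config$replications)
  for (r in seq_len(config$replications)) {
    dat <- simulateStudyData(config, r)
    row <- data.frame(replicate = r, converged = FALSE, loglik = NA_real_,
                      alphaNmHat = NA_real_, alphaEHat = NA_real_,
                      pNm = NA_real_, pE = NA_real_, cutpoint = NA_real_)
    fit <- tryCatch(suppressWarnings(fitIRTree(dat$responses, dat$model, opts)),
                    error = function(e) e)
    if (!inherits(fit, "error")) {
      row$converged <- fit@converged
      row$loglik <- fit@loglik
      st <- paramStructures(fit@model, fit@psi)
      row$alphaNmHat <- st$alphaNm[1L]
      row$alphaEHat <- st$alphaE[1L]
      if (fit@converged) {
        scores <- scoreContributions(fit)
        tNm <- invarianceTest(fit, dat$covariate, kind = dat$kind,
                              subset = "alpha_nm", statistic = config$statistic,
                              covariateName = "covariate", scores = scores)
        tE <- invarianceTest(fit, dat$covariate, kind = dat$kind,
                             subset = "alpha_e", statistic = config$statistic,
                             covariateName = "covariate", scores = scores)
        row$pNm <- tNm@pValue; row$pE <- tE@pValue
        gateP <- if (config$cutpointParam == "alpha_nm") row$pNm else row$pE
        if (config$runCutpoint && dat$kind != "categorical" &&
            gateP < config$level) {
          fc <- tryCatch(
            findCutpoint(dat$responses, as.numeric(dat$covariate), dat$model,
                         opts, minSize = config$minSize,
                         maxCandidates = config$maxCandidates, init = fit@psi),
            error = function(e) e)
          if (!inherits(fc, "error")) row$cutpoint <- fc$cutpoint
        }
      }
    }
    rows[[r]] <- row
    if (verbose)
      message(sprintf("replicate %d/%d: pNm=%s pE=%s cut=%s", r,
                      config$replications, format(row$pNm, digits = 3),
                      format(row$pE, digits = 3), format(row$cutpoint)))
  }
  records <- do.call(rbind, rows)
  conv <- records[records$converged & !is.na(records$pNm), , drop = FALSE]
  summary <- list(
    nConverged = nrow(conv), nReplications = config$replications,
    rejectNm = mean(conv$pNm < config$level),
    rejectE = mean(conv$pE < config$level),
    cutpointMean = if (any(!is.na(conv$cutpoint)))
      mean(conv$cutpoint, na.rm = TRUE) else NA_real_,
    cutpointSD = if (sum(!is.na(conv$cutpoint)) > 1L)
      sd(conv$cutpoint, na.rm = TRUE) else NA_real_,
    nCutpoints = sum(!is.na(conv$cutpoint)))
  structure(list(records = records, summary = summary, config = config),
            class = "irtreeSimResult")
}

#' @export
print.irtreeSimResult <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Simulation cell: %d items, N = %d, covariate %s, shift %+.2f (%s)\n",
              x$config$nItems, x$config$nPersons, x$config$covariate,
              x$config$shift, x$config$shiftWhich))
  cat(sprintf("  converged replicates: %d / %d\n", s$nConverged, s$nReplications))
  cat(sprintf("  rejection rate alpha_nm test: %.3f\n", s$rejectNm))
  cat(sprintf("  rejection rate alpha_e  test: %.3f\n", s$rejectE))
  if (s$nCutpoints > 0L)
    cat(sprintf("  cutpoint mean (SD) over %d significant replicates: %.2f (%.2f)\n",
                s$nCutpoints, s$cutpointMean, s$cutpointSD))
  invisible(x)
}

#' Write a simulation result as JSON plus a tidy per-replicate CSV
#'
#' @param result an \code{irtreeSimResult}.
#' @param jsonPath,csvPath output paths (either may be NULL).
#' @export
writeSimResult <- function(result, jsonPath = NULL, csvPath = NULL) {
  if (!is.null(jsonPath)) {
    cfg <- unclass(result$config)
    cfg$sigma <- as.vector(cfg$sigma)
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    jsonlite::write_json(list(summary = result$summary, config = cfg),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csvPath))
    write.csv(result$records, csvPath, row.names = FALSE)
  invisible(result)
}
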
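#' Read a Likert response table from delimited text
#'
#' One row per person; item columns plus covariate columns.  Categories must
#' be coded 0..5 or, with \code{categories = "1-6"}, 1..6 (shifted down by
#' one, never silently: the default errors on values outside 0..5).
#'
#' @param path CSV/TSV file.
#' @param items column names or indices holding the item responses.
#' @param categories \code{"0-5"} (native coding) or \code{"1-6"}.
#' @param sep field separator ("," or "\\t"); guessed from the extension.
#' @param na missing-value token.
#' @return list with integer matrix \code{responses} (0..5 coding) and data
#'   frame \code{covariates} (remaining columns).
#' @export
readLikertData <- function(path, items, categories = c("0-5", "1-6"),
                           sep = NULL, na = c("", "NA")) {
  categories <- match.arg(categories)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, na.strings = na, check.names = FALSE)
  if (is.character(items)) {
    missing <- setdiff(items, names(df))
    if (length(missing))
      stop("item column(s) not found: ", paste(missing, collapse = ", "))
  }
  resp <- as.matrix(df[, items, drop = FALSE])
  storage.mode(resp) <- "integer"
  if (categories == "1-6") {
    rng <- range(resp, na.rm = TRUE)
    if (rng[1L] < 1L || rng[2L] > 6L)
      stop("responses outside 1..6 under '1-6' coding (observed ",
           rng[1L], "..", rng[2L], ")")
    resp <- resp - 1L
  } else {
    rng <- range(resp, na.rm = TRUE)
    if (rng[1L] < 0L || rng[2L] > 5L)
      stop("responses outside 0..5; if the data is coded 1..6 pass categories = '1-6'")
  }
  covCols <- if (is.character(items)) setdiff(names(df), items)
             else setdiff(seq_along(df), items)
  list(responses = resp, covariates = df[, covCols, drop = FALSE])
}

#' Serialize a fitted model to JSON
#'
#' Stores the model specification, the named parameter vector, the latent
#' covariance, the log-likelihood and fit metadata; \code{readFitJSON}
#' rebuilds an \code{\linkS4class{IRTreeFit}} (without the response data,
#' which must be supplied again for score computations).
#'
#' @param fit an \code{IRTreeFit}.
#' @param path output file.
#' @export
writeFitJSON <- function(fit, path) {
  m <- fit@model
  obj <- list(
    model = list(nItems = m@nItems, nTraits = m@nTraits,
                 itemTraitMap = m@itemTraitMap, variant = m@variant),
    psi = as.list(fit@psi),
    sigma = fit@sigma,
    loglik = fit@loglik, nPersons = fit@nPersons,
    converged = fit@converged, iterations = fit@iterations,
    method = fit@method, gradNorm = fit@gradNorm,
    quadPointsPerDim = fit@quad$pointsPerDim)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFitJSON
#' @export
readFitJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- irtreeModel(obj$model$nItems, obj$model$nTraits,
                       obj$model$itemTraitMap, obj$model$variant)
  psi <- unlist(obj$psi)
  quad <- ghGrid(latentDims(model), obj$quadPointsPerDim)
  new("IRTreeFit", model = model, psi = psi[paramNames(model)],
      sigma = as.matrix(obj$sigma), loglik = obj$loglik,
      nPersons = as.integer(obj$nPersons), converged = obj$converged,
      iterations = as.integer(obj$iterations), method = obj$method,
      gradNorm = obj$gradNorm, loglikPath = numeric(0),
      quad = c(quad, list(pointsPerDim = obj$quadPointsPerDim)),
      pseudoData = matrix(NA_integer_, 0L, nPseudo(model)))
}

#' Serialize an invariance test to JSON
#'
#' @param test an \code{\linkS4class{InvarianceTest}}.
#' @param path output file.
#' @export
writeTestJSON <- function(test, path) {
  obj <- list(statistic = test@statisticName, value = test@statistic,
              p = test@pValue, pMethod = test@pMethod, subset = test@subset,
              k = test@k, covariate = test@covariateName,
              kind = test@covariateKind)
  if (test@pMethod == "simulated") {
    obj$nsim <- test@nsim; obj$seed <- test@seed
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
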
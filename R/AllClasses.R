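#' @import methods
#' @importFrom stats plogis dnorm pnorm pchisq qchisq rnorm runif optim cov setNames quantile sd p.adjust
#' @importFrom utils head tail read.csv write.csv write.table packageVersion
NULL

#' Decision-tree specification for a Likert rating scale
#'
#' An \code{IRTreeSpec} records how observed rating categories map onto the
#' binary pseudo-items (decision nodes) of an item response tree.  Each
#' category follows exactly one branch; nodes not on the branch are
#' structurally missing and are coded \code{NA} in the branch table.
#'
#' @slot nCategories number of observed categories (6 for the shipped tree).
#' @slot nNodes number of binary decision nodes (5 for the shipped tree).
#' @slot branchTable integer matrix (categories x nodes) with entries 0, 1 or
#'   \code{NA} (structural missing).
#' @slot nodeNames character names of the decision nodes.
#'
#' @seealso \code{\link{sixPointTree}}, \code{\link{expandResponses}}
#' @export
setClass("IRTreeSpec",
  representation(
    nCategories = "integer",
    nNodes      = "integer",
    branchTable = "matrix",
    nodeNames   = "character"
  )
)

setValidity("IRTreeSpec", function(object) {
  bt <- object@branchTable
  msg <- character()
  if (nrow(bt) != object@nCategories) msg <- c(msg, "branchTable must have one row per category")
  if (ncol(bt) != object@nNodes) msg <- c(msg, "branchTable must have one column per node")
  if (!all(bt %in% c(0L, 1L, NA))) msg <- c(msg, "branchTable entries must be 0, 1 or NA")
  ## every pair of categories must be distinguished by at least one shared node
  for (a in seq_len(nrow(bt))) {
    for (b in seq_len(nrow(bt))) {
      if (a >= b) next
      shared <- which(!is.na(bt[a, ]) & !is.na(bt[b, ]))
      if (length(shared) == 0L || all(bt[a, shared] == bt[b, shared]))
        msg <- c(msg, sprintf("categories %d and %d are not separated by any node", a - 1L, b - 1L))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Model specification for an IRTree measurement model
#'
#' Describes the structural side of the model: the tree, the number of rating
#' items, the assignment of items to substantive trait dimensions, and whether
#' trait loadings are shared across items (Rasch-style variant, loading fixed
#' to 1 at the agreement node) or item-specific.
#'
#' The latent space has \code{nTraits + 2} dimensions: the substantive
#' trait(s) theta, the nonmoderate response style eta_nm and the extreme
#' response style eta_e, in that order.  Response-style loadings are fixed to
#' 1 for all items.
#'
#' @slot tree an \code{\linkS4class{IRTreeSpec}}.
#' @slot nItems number of rating items.
#' @slot nTraits number of substantive trait dimensions (1 or 2).
#' @slot itemTraitMap integer vector: trait dimension loading on each item.
#' @slot variant \code{"rasch"} (shared loadings alpha_nm, alpha_e; agreement
#'   loading fixed at 1; latent covariance free) or \code{"itemwise"}
#'   (per-item loadings at all five nodes; trait variance fixed at 1).
#' @slot registry data.frame describing the free parameter vector Psi: one row
#'   per free parameter with its name, type, item/node indices and, for
#'   Cholesky entries, the latent dimensions.
#' @export
setClass("IRTreeModel",
  representation(
    tree         = "IRTreeSpec",
    nItems       = "integer",
    nTraits      = "integer",
    itemTraitMap = "integer",
    variant      = "character",
    registry     = "data.frame"
  )
)

setValidity("IRTreeModel", function(object) {
  msg <- character()
  if (object@nItems < 1L) msg <- c(msg, "nItems must be >= 1")
  if (!object@variant %in% c("rasch", "itemwise")) msg <- c(msg, "variant must be 'rasch' or 'itemwise'")
  if (object@variant == "itemwise" && object@nTraits != 1L)
    msg <- c(msg, "the item-specific loading variant is implemented for a single trait dimension")
  if (length(object@itemTraitMap) != object@nItems)
    msg <- c(msg, "itemTraitMap must have one entry per item")
  if (any(object@itemTraitMap < 1L | object@itemTraitMap > object@nTraits))
    msg <- c(msg, "itemTraitMap entries must be in 1..nTraits")
  if (anyDuplicated(object@registry$name)) msg <- c(msg, "parameter names must be unique")
  if (length(msg)) msg else TRUE
})

#' Fitted IRTree model
#'
#' Result of \code{\link{fitIRTree}}: the marginal maximum-likelihood estimate
#' of the structural parameter vector Psi (item parameters plus the Cholesky
#' factor of the latent covariance), the implied covariance matrix, the
#' log-likelihood, and the quadrature rule used (shared by all downstream
#' score computations so that the score identity holds numerically).
#'
#' @slot model the \code{\linkS4class{IRTreeModel}}.
#' @slot psi named numeric vector of free parameters at the optimum.
#' @slot sigma estimated latent covariance matrix.
#' @slot loglik total marginal log-likelihood.
#' @slot nPersons number of respondents.
#' @slot converged logical convergence flag.
#' @slot iterations iterations used by the outer algorithm.
#' @slot method estimation method ("em" or "bfgs").
#' @slot gradNorm maximum absolute component of the marginal score at psi.
#' @slot loglikPath log-likelihood per EM iteration (empty for "bfgs").
#' @slot quad list with the Gauss-Hermite grid (nodes X, weights w).
#' @slot pseudoData integer matrix of expanded pseudo-item responses
#'   (persons x pseudo-items, NA = missing), kept for score computations.
#' @export
setClass("IRTreeFit",
  representation(
    model      = "IRTreeModel",
    psi        = "numeric",
    sigma      = "matrix",
    loglik     = "numeric",
    nPersons   = "integer",
    converged  = "logical",
    iterations = "integer",
    method     = "character",
    gradNorm   = "numeric",
    loglikPath = "numeric",
    quad       = "list",
    pseudoData = "matrix"
  )
)

#' Decorrelated cumulative score process
#'
#' The empirical fluctuation process B(t, Psi-hat): cumulative sums of
#' per-person score contributions, ordered by a person covariate and
#' decorrelated with the inverse square root of the outer-product-of-gradients
#' covariance of the tested parameter subset.  Under parameter invariance each
#' column behaves asymptotically as an independent Brownian bridge.
#'
#' @slot B numeric matrix (persons x tested parameters) of the process.
#' @slot subset names of the tested parameters.
#' @slot info the OPG covariance block used for decorrelation.
#' @slot ordering the \code{\link{covariateOrdering}} used.
#' @slot nPersons number of respondents.
#' @export
setClass("FluctuationProcess",
  representation(
    B        = "matrix",
    subset   = "character",
    info     = "matrix",
    ordering = "list",
    nPersons = "integer"
  )
)

#' Result of a score-based parameter-invariance test
#'
#' @slot statisticName one of DM, CvM, maxLM, WDMo, maxLMo, LMuo.
#' @slot statistic observed value of the test statistic.
#' @slot pValue p-value for the null hypothesis of parameter invariance.
#' @slot pMethod "analytic" or "simulated".
#' @slot subset names of the tested parameters.
#' @slot k number of tested parameters.
#' @slot covariateName name of the person covariate.
#' @slot covariateKind "metric", "ordinal" or "categorical".
#' @slot nsim number of Monte-Carlo paths (simulated p-values; 0 otherwise).
#' @slot seed RNG seed used for simulated p-values (NA otherwise).
#' @slot process the underlying \code{\linkS4class{FluctuationProcess}}.
#' @export
setClass("InvarianceTest",
  representation(
    statisticName = "character",
    statistic     = "numeric",
    pValue        = "numeric",
    pMethod       = "character",
    subset        = "character",
    k             = "integer",
    covariateName = "character",
    covariateKind = "character",
    nsim          = "integer",
    seed          = "numeric",
    process       = "FluctuationProcess"
  )
)

setValidity("InvarianceTest", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must be in [0, 1]")
  if (!is.na(object@statistic) && object@statistic < 0)
    msg <- c(msg, "statistic must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Node of a score-based partition of the sample
#'
#' Recursive container built by \code{\link{partitionIRTree}}.  Internal nodes
#' carry the selected cutpoint and two children whose subgroups partition the
#' parent's; every node carries its subgroup fit and (when performed) the
#' within-subgroup invariance tests.
#'
#' @slot condition human-readable description of the subgroup.
#' @slot n subgroup size.
#' @slot fit the subgroup \code{\linkS4class{IRTreeFit}}.
#' @slot tests list of \code{\linkS4class{InvarianceTest}} (may be empty at
#'   leaves below the minimum size).
#' @slot cutpoint selected split value (internal nodes; NA at leaves).
#' @slot children list of 0 or 2 \code{PartitionNode} objects.
#' @slot note diagnostic note (e.g. "no admissible split").
#' @export
setClass("PartitionNode",
  representation(
    condition = "character",
    n         = "integer",
    fit       = "ANY",
    tests     = "list",
    cutpoint  = "numeric",
    children  = "list",
    note      = "character"
  )
)

setValidity("PartitionNode", function(object) {
  if (!length(object@children) %in% c(0L, 2L))
    return("a partition node has 0 or 2 children")
  TRUE
})
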
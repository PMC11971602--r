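#' Specify an IRTree measurement model
#'
#' Sets up the structural model for six-point Likert items with nonmoderate
#' and extreme response styles.  The latent space is
#' (theta_1, ..., theta_nTraits, eta_nm, eta_e) with mean zero; response-style
#' loadings are fixed at 1 for all items.
#'
#' Identification: in the \code{"rasch"} variant the trait loading at the
#' agreement node is fixed at 1 per item, alpha_nm and alpha_e are shared
#' across items, and the latent covariance is free (parameterized by its
#' Cholesky factor with log-diagonal).  In the \code{"itemwise"} variant
#' (single trait only) each item gets free loadings at all five nodes and the
#' trait variance is fixed at 1.
#'
#' @param nItems number of rating items.
#' @param nTraits number of substantive traits (1 or 2).
#' @param itemTraitMap integer vector assigning each item to a trait
#'   dimension; default: first half of the items on trait 1, second half on
#'   trait 2 (all on trait 1 if \code{nTraits == 1}).
#' @param variant \code{"rasch"} or \code{"itemwise"}.
#' @return an \code{\linkS4class{IRTreeModel}}.
#' @examples
#' m <- irtreeModel(6, nTraits = 2)
#' nParams(m)
#' @export
irtreeModel <- function(nItems, nTraits = 1L, itemTraitMap = NULL,
                        variant = c("rasch", "itemwise")) {
  variant <- match.arg(variant)
  nItems <- as.integer(nItems); nTraits <- as.integer(nTraits)
  if (is.null(itemTraitMap)) {
    itemTraitMap <- if (nTraits == 1L) rep(1L, nItems)
    else rep(seq_len(nTraits), each = ceiling(nItems / nTraits))[seq_len(nItems)]
  }
  itemTraitMap <- as.integer(itemTraitMap)
  D <- nTraits + 2L
  reg <- list()
  add <- function(name, type, item = NA_integer_, node = NA_integer_,
                  dim1 = NA_integer_, dim2 = NA_integer_, logScale = FALSE) {
    reg[[length(reg) + 1L]] <<- data.frame(
      name = name, type = type, item = item, node = node,
      dim1 = dim1, dim2 = dim2, logScale = logScale, stringsAsFactors = FALSE)
  }
  if (variant == "rasch") {
    add("alpha_nm", "alpha_nm")
    add("alpha_e", "alpha_e")
    for (i in seq_len(nItems))
      for (n in 1:5) add(sprintf("d%d_i%d", n, i), "delta", item = i, node = n)
    for (d in seq_len(D))
      for (e in seq_len(d))
        add(sprintf("L%d%d", d, e), "chol", dim1 = d, dim2 = e, logScale = d == e)
  } else {
    for (i in seq_len(nItems)) {
      add(sprintf("a1_i%d", i), "alpha1", item = i)
      add(sprintf("anm_i%d", i), "alpha_nm", item = i)
      add(sprintf("ae_i%d", i), "alpha_e", item = i)
    }
    for (i in seq_len(nItems))
      for (n in 1:5) add(sprintf("d%d_i%d", n, i), "delta", item = i, node = n)
    ## trait variance fixed at 1: L11 is not a free parameter
    for (d in seq_len(D))
      for (e in seq_len(d))
        if (!(d == 1L && e == 1L))
          add(sprintf("L%d%d", d, e), "chol", dim1 = d, dim2 = e, logScale = d == e)
  }
  registry <- do.call(rbind, reg)
  rownames(registry) <- NULL
  new("IRTreeModel", tree = sixPointTree(), nItems = nItems, nTraits = nTraits,
      itemTraitMap = itemTraitMap, variant = variant, registry = registry)
}

#' @describeIn irtreeModel number of free parameters.
#' @param model an \code{IRTreeModel}.
#' @export
nParams <- function(model) nrow(model@registry)

#' @describeIn irtreeModel names of the free parameters (the registry of Psi).
#' @export
paramNames <- function(model) model@registry$name

latentDims <- function(model) model@nTraits + 2L

## number of pseudo-items
nPseudo <- function(model) model@nItems * 5L

pseudoItemOf <- function(model) rep(seq_len(model@nItems), each = 5L)
pseudoNodeOf <- function(model) rep(1:5, model@nItems)

#' Default starting values for Psi
#'
#' Intercepts start near the marginal logits implied by a flat response
#' distribution, loadings at 0.5 (agreement loadings at 1) and the latent
#' Cholesky factor at the identity.
#'
#' @param model an \code{IRTreeModel}.
#' @return named numeric vector.
#' @export
defaultPsi <- function(model) {
  reg <- model@registry
  psi <- numeric(nrow(reg))
  psi[reg$type %in% c("alpha_nm", "alpha_e")] <- 0.5
  psi[reg$type == "alpha1"] <- 1
  psi[reg$type == "delta" & reg$node %in% 4:5] <- -2
  names(psi) <- reg$name
  psi
}

#' Structured view of a parameter vector
#'
#' Converts the flat vector Psi into the structures the likelihood uses: the
#' loading matrix A (latent dims x pseudo-items), the intercept vector delta
#' (one per pseudo-item), the latent Cholesky factor L and the covariance
#' Sigma = L L'.  The mapping is lossless: \code{structuresToPsi} inverts it.
#'
#' @param model an \code{IRTreeModel}.
#' @param psi numeric vector in registry order.
#' @return list with elements \code{A}, \code{delta}, \code{L}, \code{Sigma},
#'   \code{alphaNm}, \code{alphaE}, \code{alpha1}.
#' @export
paramStructures <- function(model, psi) {
  reg <- model@registry
  stopifnot(length(psi) == nrow(reg))
  I <- model@nItems; D <- latentDims(model); J <- nPseudo(model)
  dimNm <- model@nTraits + 1L; dimE <- model@nTraits + 2L
  if (model@variant == "rasch") {
    aNm <- rep(psi[reg$type == "alpha_nm"], I)
    aE  <- rep(psi[reg$type == "alpha_e"], I)
    a1  <- rep(1, I)
  } else {
    a1  <- psi[reg$type == "alpha1"]
    aNm <- psi[reg$type == "alpha_nm"]
    aE  <- psi[reg$type == "alpha_e"]
  }
  delta <- psi[reg$type == "delta"]  # ordered item-major, node within item
  A <- matrix(0, D, J)
  item <- pseudoItemOf(model); node <- pseudoNodeOf(model)
  td <- model@itemTraitMap[item]
  sgn <- c(1, -1, 1, -1, 1)[node]
  aj <- ifelse(node == 1L, a1[item], ifelse(node %in% 2:3, aNm[item], aE[item]))
  A[cbind(td, seq_len(J))] <- sgn * aj
  A[dimNm, node %in% 2:3] <- 1
  A[dimE, node %in% 4:5] <- 1
  L <- diag(D)
  ch <- reg$type == "chol"
  v <- psi[ch]
  v[reg$logScale[ch]] <- exp(v[reg$logScale[ch]])
  L[cbind(reg$dim1[ch], reg$dim2[ch])] <- v
  list(A = A, delta = unname(delta), L = L, Sigma = L %*% t(L),
       alphaNm = unname(aNm), alphaE = unname(aE), alpha1 = unname(a1))
}

#' @rdname paramStructures
#' @param str a list as returned by \code{paramStructures} (fields
#'   \code{delta}, \code{L} and the loadings relevant for the variant).
#' @export
structuresToPsi <- function(model, str) {
  reg <- model@registry
  psi <- numeric(nrow(reg))
  if (model@variant == "rasch") {
    psi[reg$type == "alpha_nm"] <- str$alphaNm[1L]
    psi[reg$type == "alpha_e"]  <- str$alphaE[1L]
  } else {
    psi[reg$type == "alpha1"]   <- str$alpha1
    psi[reg$type == "alpha_nm"] <- str$alphaNm
    psi[reg$type == "alpha_e"]  <- str$alphaE
  }
  psi[reg$type == "delta"] <- str$delta
  ch <- which(reg$type == "chol")
  v <- str$L[cbind(reg$dim1[ch], reg$dim2[ch])]
  v[reg$logScale[ch]] <- log(v[reg$logScale[ch]])
  psi[ch] <- v
  names(psi) <- reg$name
  psi
}

#' Map a latent covariance matrix to Cholesky parameters
#'
#' @param model an \code{IRTreeModel}.
#' @param psi parameter vector whose Cholesky entries are to be replaced.
#' @param sigma positive-definite latent covariance (its Cholesky factor is
#'   written into psi; for the itemwise variant sigma must have unit trait
#'   variance).
#' @return updated psi.
#' @export
setSigma <- function(model, psi, sigma) {
  L <- t(chol(sigma))
  reg <- model@registry
  ch <- which(reg$type == "chol")
  v <- L[cbind(reg$dim1[ch], reg$dim2[ch])]
  v[reg$logScale[ch]] <- log(v[reg$logScale[ch]])
  psi[ch] <- v
  psi
}

#' Resolve a parameter subset against the registry
#'
#' Named subsets: \code{"alpha_nm"} / \code{"loadings_nm"} (trait loadings at
#' the nonmoderate nodes), \code{"alpha_e"} / \code{"loadings_e"},
#' \code{"intercepts"} (all delta), or a character vector of registry names
#' (custom subset).
#'
#' @param model an \code{IRTreeModel}.
#' @param subset subset specifier.
#' @return character vector of parameter names.
#' @export
resolveSubset <- function(model, subset) {
  reg <- model@registry
  if (length(subset) == 1L && subset %in%
      c("alpha_nm", "alpha_e", "loadings_nm", "loadings_e", "intercepts")) {
    type <- switch(subset,
      alpha_nm = , loadings_nm = "alpha_nm",
      alpha_e = , loadings_e = "alpha_e",
      intercepts = "delta")
    return(reg$name[reg$type == type])
  }
  missing <- setdiff(subset, reg$name)
  if (length(missing))
    stop("unknown parameter(s) in subset: ", paste(missing, collapse = ", "))
  subset
}
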
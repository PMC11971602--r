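#' The six-category IRTree for Likert items
#'
#' Builds the decision tree used throughout the package for six-point rating
#' scales (categories coded 0--5).  The first node Y1 separates disagreement
#' (0, 1, 2) from agreement (3, 4, 5); conditional on that, Y2/Y3 separate
#' nonmoderate (0, 1 resp. 4, 5) from moderate (2 resp. 3) responses; given a
#' nonmoderate response, Y4/Y5 separate extreme (0 resp. 5) from nonextreme
#' (1 resp. 4) responses.  Nodes not on a category's branch are structurally
#' missing.
#'
#' @return an \code{\linkS4class{IRTreeSpec}}.
#' @examples
#' tr <- sixPointTree()
#' branchTable(tr)
#' @export
sixPointTree <- function() {
  bt <- rbind(
    c(0L, 1L, NA, 1L, NA),  # category 0: disagree, nonmoderate, extreme
    c(0L, 1L, NA, 0L, NA),  # category 1: disagree, nonmoderate, nonextreme
    c(0L, 0L, NA, NA, NA),  # category 2: disagree, moderate
    c(1L, NA, 0L, NA, NA),  # category 3: agree, moderate
    c(1L, NA, 1L, NA, 0L),  # category 4: agree, nonmoderate, nonextreme
    c(1L, NA, 1L, NA, 1L)   # category 5: agree, nonmoderate, extreme
  )
  rownames(bt) <- paste0("cat", 0:5)
  colnames(bt) <- paste0("Y", 1:5)
  new("IRTreeSpec", nCategories = 6L, nNodes = 5L, branchTable = bt,
      nodeNames = c("agree", "nonmoderate|disagree", "nonmoderate|agree",
                    "extreme|disagree", "extreme|agree"))
}

#' @describeIn sixPointTree accessor for the category-to-node branch table.
#' @param object an \code{IRTreeSpec}.
#' @export
branchTable <- function(object) {
  stopifnot(is(object, "IRTreeSpec"))
  object@branchTable
}

#' Register an alternative tree
#'
#' Alternative rating-scale trees (e.g. 4-, 5- or 7-point scales) can be
#' specified by their branch table; the table is validated for the structural
#' invariants (every category on exactly one branch, all pairs of categories
#' separated).  Only the six-category tree ships with validated model code;
#' alternative trees are supported by \code{\link{expandResponses}} only.
#'
#' @param branchTable integer matrix (categories x nodes) with entries 0, 1
#'   or NA.
#' @param nodeNames optional node labels.
#' @return an \code{\linkS4class{IRTreeSpec}}.
#' @export
irtreeSpec <- function(branchTable, nodeNames = colnames(branchTable)) {
  branchTable <- as.matrix(branchTable)
  storage.mode(branchTable) <- "integer"
  if (is.null(nodeNames)) nodeNames <- paste0("Y", seq_len(ncol(branchTable)))
  new("IRTreeSpec", nCategories = nrow(branchTable), nNodes = ncol(branchTable),
      branchTable = branchTable, nodeNames = nodeNames)
}

#' Serialize / deserialize a tree specification as JSON
#'
#' @param tree an \code{IRTreeSpec}.
#' @param path file path.
#' @return \code{readTreeJSON} returns an \code{IRTreeSpec}.
#' @export
writeTreeJSON <- function(tree, path) {
  stopifnot(is(tree, "IRTreeSpec"))
  bt <- tree@branchTable
  lst <- lapply(seq_len(nrow(bt)), function(r) {
    v <- bt[r, ]
    lapply(as.list(v), function(x) if (is.na(x)) NULL else x)
  })
  names(lst) <- rownames(bt)
  jsonlite::write_json(list(nodeNames = tree@nodeNames, branches = lst),
                       path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeTreeJSON
#' @export
readTreeJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  nodes <- unlist(obj$nodeNames)
  bt <- t(vapply(obj$branches, function(br) {
    vapply(br, function(x) if (is.null(x)) NA_integer_ else as.integer(x), integer(1))
  }, integer(length(nodes))))
  colnames(bt) <- names(obj$branches[[1]])
  rownames(bt) <- names(obj$branches)
  irtreeSpec(bt, nodeNames = nodes)
}

#' Expand observed rating categories into pseudo-item responses
#'
#' Maps an N x I matrix of observed categories onto the binary pseudo-items of
#' the tree.  For each response the nodes on the category's branch receive
#' their branch outcomes; nodes off the branch are structurally missing (NA).
#' A person-missing response (NA in the input) yields NA on all of the item's
#' pseudo-items.
#'
#' @param responses integer matrix or data.frame, categories in
#'   \code{0:(nCategories-1)}, NA allowed.
#' @param tree an \code{\linkS4class{IRTreeSpec}} (default: six-point tree).
#' @return integer matrix with \code{nItems * nNodes} columns named
#'   \code{i<item>_n<node>}, pseudo-items grouped by item.
#' @examples
#' expandResponses(matrix(c(2L, 5L, 0L), ncol = 1))
#' @export
expandResponses <- function(responses, tree = sixPointTree()) {
  responses <- as.matrix(responses)
  if (!is.numeric(responses)) stop("responses must be numeric category codes")
  storage.mode(responses) <- "integer"
  bad <- which(!is.na(responses) & (responses < 0L | responses >= tree@nCategories))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(responses))
    stop(sprintf("response out of range 0..%d at row %d, column %d (value %d)",
                 tree@nCategories - 1L, rc[1L], rc[2L], responses[bad[1L]]))
  }
  N <- nrow(responses); I <- ncol(responses); K <- tree@nNodes
  bt <- tree@branchTable
  out <- matrix(NA_integer_, N, I * K)
  for (i in seq_len(I)) {
    cat <- responses[, i]
    idx <- !is.na(cat)
    block <- matrix(NA_integer_, N, K)
    block[idx, ] <- bt[cat[idx] + 1L, , drop = FALSE]
    out[, (i - 1L) * K + seq_len(K)] <- block
  }
  colnames(out) <- as.vector(t(outer(seq_len(I), seq_len(K),
                                     function(i, n) sprintf("i%d_n%d", i, n))))
  out
}

#' Pseudo-item success probabilities for one item
#'
#' Evaluates the five node probabilities of the six-point tree for a single
#' person and item.  Node 1 uses the linear predictor \code{a1 * theta + d1};
#' nodes 2/3 use \code{eta_nm -/+ alpha_nm * theta + d2/d3}; nodes 4/5 use
#' \code{eta_e -/+ alpha_e * theta + d4/d5}: the trait enters the disagree and
#' agree branches with opposite signs by construction.
#'
#' @param theta substantive trait value of the person (scalar: the trait
#'   loading on this item).
#' @param etaNm,etaE response-style values of the person.
#' @param alphaNm,alphaE trait loadings at the nonmoderate and extremity
#'   nodes.
#' @param delta numeric length-5 intercept vector (d1..d5) for the item.
#' @param alpha1 trait loading at the agreement node (1 in the Rasch-style
#'   variant).
#' @return numeric length-5 vector of success probabilities.
#' @examples
#' nodeProbabilities(0, 0, 0, 0.8, 0.8, rep(0, 5))  # all 0.5
#' @export
nodeProbabilities <- function(theta, etaNm, etaE, alphaNm, alphaE, delta,
                              alpha1 = 1) {
  stopifnot(length(delta) == 5L)
  lp <- c(alpha1 * theta + delta[1L],
          etaNm - alphaNm * theta + delta[2L],
          etaNm + alphaNm * theta + delta[3L],
          etaE  - alphaE  * theta + delta[4L],
          etaE  + alphaE  * theta + delta[5L])
  plogis(lp)
}

#' Category probabilities for one item
#'
#' The probability of each rating category is the product of node success
#' probabilities (or their complements) along the category's branch of the
#' tree; the six probabilities sum to one because the branches partition the
#' outcome space.
#'
#' @inheritParams nodeProbabilities
#' @param tree the tree specification (default six-point).
#' @return numeric length-\code{nCategories} probability vector.
#' @examples
#' sum(categoryProbabilities(1, 0.2, -0.1, 0.8, 0.6, runif(5, -1, 1)))  # 1
#' @export
categoryProbabilities <- function(theta, etaNm, etaE, alphaNm, alphaE, delta,
                                  alpha1 = 1, tree = sixPointTree()) {
  p <- nodeProbabilities(theta, etaNm, etaE, alphaNm, alphaE, delta, alpha1)
  bt <- tree@branchTable
  out <- apply(bt, 1L, function(br) {
    on <- !is.na(br)
    prod(ifelse(br[on] == 1L, p[on], 1 - p[on]))
  })
  names(out) <- rownames(bt)
  out
}
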
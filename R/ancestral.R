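#' Maximum-likelihood ancestral state at a tree node (Brownian motion)
#'
#' Under Brownian motion the ML estimate of the state at an internal node is
#' the generalized-least-squares mean of the tip values,
#' \eqn{\hat x = (1' C^{-1} x) / (1' C^{-1} 1)}, where \eqn{C} is the BM
#' covariance of the tree rerooted at that node: \eqn{C_{ij}} is the shared
#' path length from the node to tips i and j. The BM rate \eqn{\sigma^2}
#' cancels and never needs to be estimated. Polytomies are handled directly
#' (only path lengths enter the computation).
#'
#' @param tree A dated \code{phylo} tree whose tips all carry observations.
#' @param tip_values Named numeric vector, names = \code{tree$tip.label}
#'   (any order; must cover all tips).
#' @param node Internal node: either an integer node id (\code{ape}
#'   numbering), a node label, or a character vector of >= 2 tip labels whose
#'   MRCA is used.
#' @return List with \code{estimate}, \code{node} (id), \code{n_tips}.
#' @export
ml_ancestral_state <- function(tree, tip_values, node) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need at least 2 tips")
  if (is.null(names(tip_values)) || !all(tree$tip.label %in% names(tip_values))) {
    stop("tip_values must be named and cover every tip of the tree")
  }
  x <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(x)) stop("NA tip value")
  nd <- .resolve_node(tree, node)
  if (nd <= ntip) stop("ancestor not reconstructible: node is a tip")
  w <- .gls_weights(tree, nd)
  list(estimate = sum(w * x), node = nd, n_tips = ntip)
}

## node argument -> internal node id
.resolve_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (is.numeric(node) && length(node) == 1L) return(as.integer(node))
  node <- as.character(node)
  if (length(node) == 1L) {
    if (!is.null(tree$node.label)) {
      hit <- match(node, tree$node.label)
      if (!is.na(hit)) return(ntip + hit)
    }
    if (node %in% tree$tip.label) return(match(node, tree$tip.label))
    stop("node label not found: ", node)
  }
  tips <- match(node, tree$tip.label)
  if (anyNA(tips)) stop("ancestor not reconstructible: tip(s) absent after pruning: ",
                        paste(node[is.na(tips)], collapse = ", "))
  if (length(unique(tips)) == 1L) return(tips[1])
  ape::getMRCA(tree, unique(tips))
}

## normalized GLS weights for the tips, for the estimate at `node`
.gls_weights <- function(tree, node) {
  ntip <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  d <- D[node, seq_len(ntip)]
  C <- (outer(d, d, `+`) - D[seq_len(ntip), seq_len(ntip)]) / 2
  w <- tryCatch(solve(C, rep(1, ntip)),
                error = function(e) stop("ancestor not reconstructible: singular BM covariance (duplicated zero-length tips?)"))
  w / sum(w)
}

#' Reconstruct ancestral inter-CNE distances for a set of pairs
#'
#' For each pair, prunes the tree to the species with an ortholog-distance
#' observation and estimates the state at the MRCA of the observed mammals
#' (the common mammalian ancestor). Because the state at a node can only be
#' inferred when the node subtends the observed data on both sides, pairs
#' without an observation in the key outgroup mammal (platypus by default)
#' are skipped and flagged, as are pairs with fewer than two mammalian
#' observations.
#'
#' @param dist_mat Numeric matrix, pairs x species (rownames = pair ids,
#'   colnames = species); NA where a species has no ortholog distance.
#' @param tree Dated phylogeny containing all species columns.
#' @param mammals Character vector of mammalian species.
#' @param key_species Species whose observation is required for the mammalian
#'   MRCA to be reconstructible (default \code{"platypus"}).
#' @return data.frame \code{pair_id, d_r, n_tips, flag} (\code{flag} is
#'   \code{""}, \code{"no_platypus"} or \code{"too_few_mammals"}; skipped
#'   pairs have \code{d_r = NA}).
#' @export
reconstruct_pair_ancestors <- function(dist_mat, tree, mammals,
                                       key_species = "platypus") {
  stopifnot(is.matrix(dist_mat), !is.null(colnames(dist_mat)))
  species <- colnames(dist_mat)
  if (!all(species %in% tree$tip.label)) {
    stop("species missing from tree: ",
         paste(setdiff(species, tree$tip.label), collapse = ", "))
  }
  n <- nrow(dist_mat)
  out <- data.frame(pair_id = rownames(dist_mat), d_r = NA_real_,
                    n_tips = 0L, flag = "", stringsAsFactors = FALSE)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    obs <- species[!is.na(dist_mat[i, ])]
    mam_obs <- intersect(obs, mammals)
    if (!(key_species %in% obs)) { out$flag[i] <- "no_platypus"; next }
    if (length(mam_obs) < 2L) { out$flag[i] <- "too_few_mammals"; next }
    key <- paste(sort(obs), collapse = ",")
    w <- cache[[key]]
    if (is.null(w)) {
      sub <- ape::keep.tip(tree, obs)
      nd <- if (length(mam_obs) == length(sub$tip.label)) {
        length(sub$tip.label) + 1L  # root
      } else {
        ape::getMRCA(sub, mam_obs)
      }
      wts <- .gls_weights(sub, nd)
      w <- wts[match(obs, sub$tip.label)]
      names(w) <- obs
      cache[[key]] <- w
    }
    out$d_r[i] <- sum(w * dist_mat[i, obs])
    out$n_tips[i] <- length(obs)
  }
  out
}

#' Reconstruct ancestral transposon lengths per class
#'
#' Applies the same BM machinery to per-species transposon-covered lengths
#' within each pair's inter-CNE span, one reconstruction per transposon class.
#' Negative GLS estimates (possible since the estimator is a signed weighted
#' mean) are floored at 0 and flagged \code{"clamped"}.
#'
#' @param t_arrays Named list (one element per transposon class) of matrices
#'   pairs x species, as for \code{\link{reconstruct_pair_ancestors}}.
#' @param tree,mammals,key_species See \code{\link{reconstruct_pair_ancestors}}.
#' @return data.frame \code{pair_id, class, T_r, n_tips, flag}.
#' @export
reconstruct_transposon_ancestors <- function(t_arrays, tree, mammals,
                                             key_species = "platypus") {
  stopifnot(is.list(t_arrays), length(names(t_arrays)) == length(t_arrays))
  res <- lapply(names(t_arrays), function(cl) {
    r <- reconstruct_pair_ancestors(t_arrays[[cl]], tree, mammals, key_species)
    names(r)[names(r) == "d_r"] <- "T_r"
    clamp <- !is.na(r$T_r) & r$T_r < 0
    r$T_r[clamp] <- 0
    r$flag[clamp] <- ifelse(nzchar(r$flag[clamp]), paste0(r$flag[clamp], ";clamped"), "clamped")
    r$class <- cl
    r[, c("pair_id", "class", "T_r", "n_tips", "flag")]
  })
  do.call(rbind, res)
}
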
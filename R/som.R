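## hexagonal grid unit coordinates for an ncol x nrow layout:
## odd rows are offset by half a unit, rows are sqrt(3)/2 apart
.hex_grid <- function(grid_dim) {
  ncol_ <- grid_dim[1]; nrow_ <- grid_dim[2]
  rows <- rep(seq_len(nrow_) - 1L, each = ncol_)
  cols <- rep(seq_len(ncol_) - 1L, times = nrow_)
  data.frame(unit = seq_len(ncol_ * nrow_),
             x = cols + 0.5 * (rows %% 2L),
             y = rows * sqrt(3) / 2)
}

#' Train a Kohonen self-organizing map
#'
#' Online SOM training with the bubble neighborhood: codebook vectors are
#' initialized to a random sample of input rows; at each of \code{t_max}
#' iterations a row x(t) is drawn uniformly at random, its best-matching
#' unit c (smallest Euclidean distance, ties to the lowest unit id) is found,
#' and every codebook within grid radius r(t) of c is updated as
#' m_i(t+1) = m_i(t) + alpha(t) (x(t) - m_i(t)). The bubble neighborhood is
#' constant (= alpha) inside the radius and zero outside. The learning rate
#' decreases linearly from \code{alpha[1]} to \code{alpha[2]}, and the radius
#' from half the grid diameter to 0 over t_max, so the map anneals from
#' coarse topological ordering to winner-only fine tuning.
#'
#' @param x Numeric matrix, rows = observations (>= n units), no NAs.
#' @param n_units Number of map units (default 12).
#' @param grid_dim Grid columns x rows (default c(4, 3), hexagonal).
#' @param t_max Training iterations (default 1000).
#' @param alpha Learning rate start/end (default c(0.05, 0.01)).
#' @param radius Neighborhood radius start/end; default half the grid
#'   diameter shrinking to 0, so late iterations update the winner only.
#' @param seed Integer seed for initialization and sampling.
#' @return Object of class \code{som_model}: \code{codebook} (units x
#'   features), \code{grid}, \code{params}, \code{qe} (final mean
#'   quantization error), \code{qe_init} (at initialization).
#' @export
train_som <- function(x, n_units = 12L, grid_dim = c(4L, 3L), t_max = 1000L,
                      alpha = c(0.05, 0.01), radius = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("train_som: NA in input matrix")
  if (nrow(x) < n_units) stop("train_som: fewer rows than units")
  if (prod(grid_dim) != n_units) stop("train_som: grid_dim must give n_units cells")
  grid <- .hex_grid(grid_dim)
  gd <- as.matrix(stats::dist(grid[, c("x", "y")]))
  if (is.null(radius)) radius <- c(max(gd) / 2, 0)
  set.seed(seed)
  cb <- x[sample.int(nrow(x), n_units), , drop = FALSE]
  rownames(cb) <- NULL
  qe_init <- mean(sqrt(.min_dist2(x, cb)$d2))
  frac <- if (t_max > 1L) (seq_len(t_max) - 1) / (t_max - 1) else 0
  a_t <- alpha[1] - (alpha[1] - alpha[2]) * frac
  r_t <- radius[1] - (radius[1] - radius[2]) * frac
  idx <- sample.int(nrow(x), t_max, replace = TRUE)
  for (t in seq_len(t_max)) {
    xi <- x[idx[t], ]
    d2 <- rowSums(sweep(cb, 2L, xi)^2)
    bmu <- which.min(d2)
    nb <- which(gd[bmu, ] <= r_t[t] + 1e-9)
    cb[nb, ] <- cb[nb, , drop = FALSE] +
      a_t[t] * (rep(xi, each = length(nb)) - cb[nb, , drop = FALSE])
  }
  qe <- mean(sqrt(.min_dist2(x, cb)$d2))
  structure(list(codebook = cb, grid = grid,
                 params = list(n_units = n_units, grid_dim = grid_dim,
                               t_max = t_max, alpha = alpha, radius = radius,
                               topology = "hexagonal"),
                 seed = seed, qe = qe, qe_init = qe_init),
            class = "som_model")
}

## squared distance from each row of x to its nearest codebook row
.min_dist2 <- function(x, cb) {
  cross <- x %*% t(cb)
  d2 <- outer(rowSums(x^2), rowSums(cb^2), `+`) - 2 * cross
  d2[d2 < 0] <- 0
  unit <- max.col(-d2, ties.method = "first")
  list(unit = unit, d2 = d2[cbind(seq_len(nrow(x)), unit)])
}

#' Assign observations to SOM units
#'
#' Best-matching unit by Euclidean distance; ties broken by the lowest unit
#' id. Assignment is invariant to adding a constant column shift to both the
#' data and the codebook.
#'
#' @param model A \code{som_model}.
#' @param x Matrix with the same feature columns as the training data.
#' @return Integer vector of unit ids (named by rownames of x, if any).
#' @export
som_assign <- function(model, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == ncol(model$codebook))
  u <- .min_dist2(x, model$codebook)$unit
  names(u) <- rownames(x)
  u
}

#' Per-unit mean enrichment summaries
#'
#' For each unit, the mean enrichment level across all tissues and member
#' pairs for each (region, mark) combination — the representation used to
#' match and cluster units across maps. Feature columns must be named
#' \code{tissue.region.mark} as produced by \code{\link{build_feature_matrix}}.
#'
#' @param features Feature matrix (pairs x columns).
#' @param assignments Unit id per pair (same order as rows).
#' @param n_units Total number of units.
#' @return Matrix units x (region.mark); rows of empty units are NA.
#' @export
unit_summaries <- function(features, assignments, n_units = 12L) {
  parts <- strsplit(colnames(features), ".", fixed = TRUE)
  rm_key <- vapply(parts, function(p) paste(p[-1L], collapse = "."), character(1))
  keys <- sort(unique(rm_key))
  out <- matrix(NA_real_, n_units, length(keys),
                dimnames = list(paste0("unit", seq_len(n_units)), keys))
  for (u in seq_len(n_units)) {
    rows <- which(assignments == u)
    if (!length(rows)) next
    cm <- colMeans(features[rows, , drop = FALSE])
    out[u, ] <- as.numeric(tapply(cm, rm_key, mean)[keys])
  }
  out
}

#' Reciprocally most similar unit pairs between two maps
#'
#' Unit a of map A matches unit b of map B iff b is the Euclidean-nearest
#' B-unit to a AND a is the nearest A-unit to b. Empty (all-NA) units do not
#' participate. The matching is symmetric: matching(A,B) is the transpose of
#' matching(B,A).
#'
#' @param summaries_a,summaries_b Unit-summary matrices on identical columns.
#' @return List: \code{matches} (data.frame \code{unit_a, unit_b}),
#'   \code{unmatched_a}, \code{unmatched_b} (integer unit ids).
#' @export
reciprocal_unit_matching <- function(summaries_a, summaries_b) {
  stopifnot(ncol(summaries_a) == ncol(summaries_b))
  va <- which(stats::complete.cases(summaries_a))
  vb <- which(stats::complete.cases(summaries_b))
  A <- summaries_a[va, , drop = FALSE]
  B <- summaries_b[vb, , drop = FALSE]
  d <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  best_b <- apply(d, 1L, which.min)   # per A-unit
  best_a <- apply(d, 2L, which.min)   # per B-unit
  mutual <- which(best_a[best_b] == seq_along(best_b))
  matches <- data.frame(unit_a = va[mutual], unit_b = vb[best_b[mutual]])
  list(matches = matches,
       unmatched_a = setdiff(va, matches$unit_a),
       unmatched_b = setdiff(vb, matches$unit_b))
}

#' Cluster SOM units by their mean enrichment summaries
#'
#' Complete-linkage hierarchical clustering of the unit summaries (Euclidean
#' distance), cut at \code{k} clusters. Empty units get NA.
#'
#' @param summaries Unit-summary matrix.
#' @param k Number of clusters (default 4).
#' @return Integer vector of cluster ids per unit (NA for empty units).
#' @export
cluster_units <- function(summaries, k = 4L) {
  valid <- which(stats::complete.cases(summaries))
  if (length(valid) < k) stop("fewer nonempty units than clusters")
  hc <- stats::hclust(stats::dist(summaries[valid, , drop = FALSE]),
                      method = "complete")
  cl <- stats::cutree(hc, k = k)
  out <- rep(NA_integer_, nrow(summaries))
  out[valid] <- cl
  out
}

#' Transfer unit clusters across maps via reciprocal matches
#'
#' Units of map B matched to an A-unit inherit that unit's cluster; unmatched
#' B-units are assigned the cluster of their Euclidean-nearest matched B-unit
#' (the treatment used for units with no unambiguous counterpart).
#'
#' @param matching Output of \code{\link{reciprocal_unit_matching}}.
#' @param clusters_a Cluster id per A-unit.
#' @param summaries_b B unit summaries (for the nearest-matched-unit rule).
#' @return Integer vector of cluster ids per B-unit.
#' @export
transfer_unit_clusters <- function(matching, clusters_a, summaries_b) {
  out <- rep(NA_integer_, nrow(summaries_b))
  m <- matching$matches
  out[m$unit_b] <- clusters_a[m$unit_a]
  todo <- setdiff(which(stats::complete.cases(summaries_b)), m$unit_b)
  for (u in todo) {
    d <- colSums((t(summaries_b[m$unit_b, , drop = FALSE]) - summaries_b[u, ])^2)
    out[u] <- out[m$unit_b[which.min(d)]]
  }
  out
}
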
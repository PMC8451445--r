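## Distance-based Moran eigenvector maps (dbMEM / PCNM): spatial
## eigenfunctions of the truncated inter-site distance matrix, used to check
## whether community responses carry spatial structure that could confound
## the establishment-year chronosequence.

#' Spatial eigenvectors of site coordinates
#'
#' Builds dbMEM/PCNM eigenvectors: inter-site Euclidean distances are
#' truncated at the longest edge of their minimum spanning tree (distances
#' above the threshold replaced by 4x threshold), the truncated matrix is
#' double-centred and eigen-decomposed, and eigenvectors with positive
#' eigenvalues are retained (via `vegan::pcnm`).
#'
#' @param coords n x 2 matrix or data frame of planar coordinates (km).
#' @param threshold optional truncation distance; default is the longest
#'   minimum-spanning-tree edge.
#' @return list of class `bv_dbmem` with `vectors` (n x m matrix),
#'   `values` (positive eigenvalues) and `threshold`.
#' @export
dbmem <- function(coords, threshold = NULL) {
  coords <- as.matrix(coords[, c(1, 2)])
  if (nrow(coords) < 3L) stop("dbmem: need at least 3 sites")
  d <- dist(coords)
  if (any(d == 0)) stop("dbmem: duplicate coordinates")
  if (is.null(threshold)) threshold <- max(vegan::spantree(d)$dist)
  fit <- vegan::pcnm(d, threshold = threshold)
  vec <- as.matrix(vegan::scores(fit))
  structure(list(vectors = vec, values = fit$values[seq_len(ncol(vec))],
                 threshold = threshold),
            class = "bv_dbmem")
}

#' @export
print.bv_dbmem <- function(x, ...) {
  cat(sprintf("dbMEM: %d spatial eigenvectors (truncation %.2f)\n",
              ncol(x$vectors), x$threshold))
  invisible(x)
}

#' Permutation tests of spatial eigenvectors against a response
#'
#' Tests each dbMEM vector marginally.  A numeric response is first
#' detrended (residuals of a linear regression on the x, y coordinates),
#' then each vector's R-squared against the detrended response is compared
#' with its permutation distribution.  A multivariate response (items x
#' variables matrix) is detrended column-wise and converted to Euclidean
#' distances; a `dist` response is used as is.  Distance responses are
#' tested with one-factor [permanova()]-style partitioning per vector.
#'
#' @param mem a `bv_dbmem` object.
#' @param response numeric vector, items x variables matrix, or `dist`.
#' @param coords the site coordinates used to build `mem` (needed for
#'   detrending numeric/matrix responses).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return data frame with one row per eigenvector: `vector`, `r2`,
#'   `p_value`.
#' @export
dbmem_test <- function(mem, response, coords = NULL, n_perm = 999L,
                       seed = 1L) {
  vec <- mem$vectors
  n <- nrow(vec)

  detrend <- function(y) {
    if (is.null(coords)) stop("dbmem_test: coords needed for detrending")
    xy <- as.matrix(coords[, c(1, 2)])
    resid(lm(y ~ xy))
  }

  if (inherits(response, "dist") || is.matrix(response) ||
      is.data.frame(response)) {
    d <- if (inherits(response, "dist")) {
      response
    } else {
      dist(apply(as.matrix(response), 2, detrend))
    }
    if (attr(d, "Size") != n) stop("dbmem_test: response size mismatch")
    rows <- lapply(seq_len(ncol(vec)), function(j) {
      fit <- permanova_numeric(d, vec[, j], n_perm = n_perm,
                               seed = seed + j)
      data.frame(vector = colnames(vec)[j], r2 = fit$r2,
                 p_value = fit$p_value)
    })
    return(do.call(rbind, rows))
  }

  y <- detrend(as.numeric(response))
  if (length(y) != n) stop("dbmem_test: response length mismatch")
  rows <- lapply(seq_len(ncol(vec)), function(j) {
    v <- vec[, j]
    r2_obs <- cor(v, y)^2
    pm <- permutation_matrix(n, n_perm = n_perm, seed = seed + j)
    r2_perm <- apply(pm, 1, function(p) cor(v, y[p])^2)
    data.frame(vector = colnames(vec)[j], r2 = r2_obs,
               p_value = (1 + sum(r2_perm >= r2_obs)) / (1 + nrow(pm)))
  })
  do.call(rbind, rows)
}

## One-quantitative-predictor partitioning of a distance matrix (dbRDA-style
## marginal test of a single dbMEM vector), via adonis2 with a seeded
## permutation matrix.
permanova_numeric <- function(d, x, n_perm = 999L, seed = 1L) {
  pm <- permutation_matrix(attr(d, "Size"), n_perm = n_perm, seed = seed)
  fit <- vegan::adonis2(d ~ x, data = data.frame(x = x), permutations = pm,
                        by = "terms")
  list(r2 = fit$R2[1L], p_value = fit[["Pr(>F)"]][1L])
}
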
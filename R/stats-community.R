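## Community statistics used by all three analysis arms.  The heavy lifting
## (dissimilarities, pseudo-F, dispersion, ordination, spatial eigenvectors)
## is delegated to vegan; this layer fixes the permutation scheme (seeded,
## optionally restricted to strata, optionally exhaustive) so every p-value
## is reproducible and block structure is honoured.

#' Site-level abundance matrix from a coverage table
#'
#' Sums the per-plot coverages of each species over the plots of a site
#' (the site-level aggregation used before Bray-Curtis in the vegetation
#' analyses).
#'
#' @param coverage validated coverage table.
#' @return sites x species numeric matrix.
#' @export
site_matrix <- function(coverage) {
  coverage <- as_coverage_table(coverage)
  tab <- tapply(coverage$coverage,
                list(coverage$site, coverage$species), sum, default = 0)
  m <- as.matrix(tab)
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Species richness and Shannon-Wiener diversity per site
#'
#' Richness is the number of species with at least one coverage record at
#' the site.  Shannon H' = -sum p_i log p_i, with p_i the species' share of
#' the site's summed coverage (natural log).
#'
#' @param coverage validated coverage table.
#' @param site optional single site id; default returns all sites.
#' @return named numeric vector (one value per site).
#' @export
richness <- function(coverage, site = NULL) {
  m <- site_matrix(coverage)
  r <- rowSums(m > 0)
  if (is.null(site)) return(r)
  if (!site %in% names(r)) return(setNames(0L, site))
  r[site]
}

#' @rdname richness
#' @export
shannon <- function(coverage, site = NULL) {
  m <- site_matrix(coverage)
  h <- vegan::diversity(m, index = "shannon")
  if (is.null(site)) return(h)
  if (!site %in% names(h)) stop("shannon: site ", site, " has no records")
  h[site]
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) on non-negative abundance
#' rows; 0 for identical rows, 1 for disjoint supports.
#'
#' @param m items x variables non-negative matrix.
#' @return `dist` object with item labels.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("bray_curtis: negative abundances")
  if (sum(rowSums(m) == 0) > 1L) {
    stop("bray_curtis: more than one all-zero row; ",
         "their pairwise dissimilarity is undefined")
  }
  vegan::vegdist(m, method = "bray")
}

#' Seeded permutation matrix, optionally restricted to strata
#'
#' Generates the permutations used by [permanova()] and [permdisp()]: each
#' row is a permutation of `1:n`.  With `strata`, indices are shuffled only
#' within their stratum, so labels are never exchanged across blocks.  With
#' `exhaustive = TRUE` all `n! - 1` non-identity permutations are returned
#' (for exact tests on small instances).
#'
#' @param n number of items.
#' @param n_perm number of random permutations.
#' @param strata optional factor of length `n` defining exchangeability
#'   blocks.
#' @param seed integer seed (mandatory for random permutations).
#' @param exhaustive enumerate all permutations instead of sampling
#'   (requires `n <= 8` and no strata).
#' @return integer matrix, one permutation per row.
#' @export
permutation_matrix <- function(n, n_perm = 999L, strata = NULL, seed = NULL,
                               exhaustive = FALSE) {
  if (exhaustive) {
    if (!is.null(strata)) stop("exhaustive enumeration with strata not supported")
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    keep <- rowSums(perms != matrix(1:n, nrow(perms), n, byrow = TRUE)) > 0L
    return(perms[keep, , drop = FALSE])
  }
  if (n_perm < 1L) stop("permutation_matrix: n_perm must be >= 1")
  if (is.null(seed)) stop("permutation_matrix: seed is required")
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    if (length(strata) != n) stop("permutation_matrix: strata length != n")
    idx <- split(seq_len(n), strata)
  }
  with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      p <- seq_len(n)
      if (is.null(strata)) {
        p <- sample(n)
      } else {
        for (block in idx) p[block] <- block[sample(length(block))]
      }
      p
    }, integer(n)))
  })
}

## All n! permutations of 1:n by recursive insertion (n small).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = nrow(sub) * n, ncol = n)
  r <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
      r <- r + 1L
    }
  }
  out
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the sums of squares of a dissimilarity matrix between and
#' within the levels of one grouping factor (Gower-centred -D^2/2 matrix,
#' pseudo-F = (SS_A/(a-1)) / (SS_W/(n-a))) and assesses it against
#' permutations of the group labels.  With `strata`, permutations are
#' restricted to within-stratum shuffles (block design, e.g. site as block
#' for repeated fecal samples).  p = (1 + #\{F_perm >= F_obs\}) /
#' (1 + n_perm).
#'
#' @param d `dist` object or symmetric dissimilarity matrix.
#' @param groups factor (or coercible) of group labels, length n.
#' @param strata optional blocking factor of length n.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed (required unless `exhaustive`).
#' @param exhaustive use all non-identity permutations (small n only).
#' @return object of class `bv_permanova`: list with `f`, `r2`, `p_value`,
#'   `df`, `n_perm`, `scheme` and the underlying `vegan::adonis2` table.
#' @export
permanova <- function(d, groups, strata = NULL, n_perm = 999L, seed = NULL,
                      exhaustive = FALSE) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  groups <- as.factor(groups)
  if (length(groups) != n) stop("permanova: length(groups) != n")
  if (nlevels(droplevels(groups)) < 2L) {
    stop("permanova: need at least two groups")
  }
  pm <- permutation_matrix(n, n_perm = n_perm, strata = strata, seed = seed,
                           exhaustive = exhaustive)
  dat <- data.frame(groups = groups)
  fit <- vegan::adonis2(d ~ groups, data = dat, permutations = pm,
                        by = "terms")
  scheme <- if (exhaustive) {
    "exhaustive enumeration"
  } else if (is.null(strata)) {
    sprintf("%d free permutations, seed %d", nrow(pm), as.integer(seed))
  } else {
    sprintf("%d permutations within %d strata, seed %d", nrow(pm),
            nlevels(as.factor(strata)), as.integer(seed))
  }
  structure(list(f = fit$F[1L], r2 = fit$R2[1L],
                 p_value = fit[["Pr(>F)"]][1L],
                 df = c(fit$Df[1L], fit$Df[2L]),
                 n_perm = nrow(pm), scheme = scheme, table = fit),
            class = "bv_permanova")
}

#' @export
print.bv_permanova <- function(x, ...) {
  cat("PERMANOVA (", x$scheme, ")\n", sep = "")
  cat(sprintf("  pseudo-F = %.4f on %d, %d df;  R2 = %.4f;  p = %.4g\n",
              x$f, x$df[1], x$df[2], x$r2, x$p_value))
  invisible(x)
}

#' Homogeneity of multivariate dispersion
#'
#' Distances to group centroids in principal-coordinate space (negative
#' eigenvalues handled by the standard corrected-distance formula of
#' `vegan::betadisper`), one-way F on those distances, permutation p with
#' the same seeded scheme as [permanova()].
#'
#' @inheritParams permanova
#' @return list of class `bv_permdisp` with `f`, `p_value`, `n_perm` and
#'   the `betadisper` fit.
#' @export
permdisp <- function(d, groups, n_perm = 999L, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (any(table(groups) == 1L)) {
    warning("permdisp: group(s) of size 1 contribute zero dispersion")
  }
  bd <- vegan::betadisper(d, groups, type = "centroid")
  pm <- permutation_matrix(attr(d, "Size"), n_perm = n_perm, seed = seed)
  pt <- vegan::permutest(bd, permutations = pm)
  structure(list(f = pt$tab$F[1L], p_value = pt$tab[1L, "Pr(>F)"],
                 n_perm = nrow(pm), betadisper = bd),
            class = "bv_permdisp")
}

#' @export
print.bv_permdisp <- function(x, ...) {
  cat(sprintf("Multivariate dispersion: F = %.4f, p = %.4g (%d permutations)\n",
              x$f, x$p_value, x$n_perm))
  invisible(x)
}
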
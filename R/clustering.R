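## Per-species establishment-year profiles and their K-means clustering.
## A profile is a 4-vector over the establishment classes (Y1978, Y2003,
## Y2011, Y2014): the class mean of a species' site-level statistic
## (summed coverage, MDG, or per-sample read proportion averaged within and
## then over sites).  The number of clusters is chosen with the gap
## statistic against a uniform reference distribution.

#' Build per-species establishment-year profiles
#'
#' For each species, the site-level statistic is averaged over the sites of
#' each establishment class, yielding one 4-vector per species.
#'
#' * `source = "coverage"`: site-level value is the coverage summed over
#'   the site's plots.
#' * `source = "mdg"`: site-level value is the mean damage grade; sites
#'   without a damage record for the species are excluded from the class
#'   mean (absence is not zero damage).
#' * `source = "reads"`: per-sample read proportions are averaged within
#'   each site, then over the sites of the class.
#'
#' With `presence_filter = TRUE` (the default for coverage and MDG
#' profiles) only species present in at least one site of every
#' establishment class are kept, so all four class means rest on data.
#' Read profiles keep every detected taxon (`presence_filter = FALSE`).
#'
#' @param x source data: a coverage table (`source = "coverage"`), an MDG
#'   matrix from [mdg_matrix()] (`source = "mdg"`), or a samples x taxa
#'   proportion matrix (`source = "reads"`).
#' @param sites validated site table (site to class mapping); every class
#'   must have at least one site.
#' @param source one of `"coverage"`, `"mdg"`, `"reads"`.
#' @param presence_filter keep only species observed in every class;
#'   defaults to `TRUE` except for `source = "reads"`.
#' @param sample_sites for `source = "reads"`: character vector mapping the
#'   rows of `x` (samples) to site ids.
#' @return species x 4 matrix (columns `Y1978`, `Y2003`, `Y2011`, `Y2014`)
#'   with attribute `source`.
#' @export
build_profiles <- function(x, sites, source = c("coverage", "mdg", "reads"),
                           presence_filter = NULL, sample_sites = NULL) {
  source <- match.arg(source)
  sites <- as_site_table(sites)
  if (!all(CLASS_LABELS %in% sites$class)) {
    stop("build_profiles: every establishment class needs at least one site")
  }
  if (is.null(presence_filter)) presence_filter <- source != "reads"
  site_class <- setNames(sites$class, sites$site)

  if (source == "coverage") {
    m <- site_matrix(x)                    # sites x species
    values <- t(m)                         # species x sites
  } else if (source == "mdg") {
    values <- as.matrix(x)                 # species x sites, NA = absent
  } else {
    if (is.null(sample_sites)) {
      stop("build_profiles: sample_sites required for read profiles")
    }
    p <- as.matrix(x)                      # samples x taxa
    if (length(sample_sites) != nrow(p)) {
      stop("build_profiles: sample_sites length != number of samples")
    }
    ## mean proportion per site, then species x sites
    by_site <- apply(p, 2, function(col) tapply(col, sample_sites, mean))
    values <- t(as.matrix(by_site))
  }

  cls <- site_class[colnames(values)]
  if (any(is.na(cls))) {
    stop("build_profiles: unknown site(s): ",
         paste(colnames(values)[is.na(cls)], collapse = ", "))
  }
  prof <- t(apply(values, 1, function(v) {
    tapply(v, factor(cls, levels = CLASS_LABELS), mean, na.rm = TRUE)
  }))
  colnames(prof) <- CLASS_LABELS
  prof[is.nan(prof)] <- NA_real_

  if (presence_filter) {
    present <- t(apply(values, 1, function(v) {
      tapply(!is.na(v) & v > 0, factor(cls, levels = CLASS_LABELS), any)
    }))
    prof <- prof[rowSums(present) == 4L, , drop = FALSE]
  } else {
    prof[is.na(prof)] <- 0
  }
  attr(prof, "source") <- source
  prof
}

#' Scale species profiles before clustering
#'
#' @param x species x 4 profile matrix.
#' @param scale `"max"` (default: each profile divided by its own maximum,
#'   so clustering sees the pattern of variation rather than the
#'   magnitude), `"raw"` (no scaling) or `"z"` (row z-scores).  All-zero
#'   (or constant, for `"z"`) profiles are left at zero.
#' @return scaled matrix with attribute `scaling`.
#' @export
scale_profiles <- function(x, scale = c("max", "raw", "z")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  out <- switch(scale,
    raw = x,
    max = {
      mx <- apply(x, 1, max)
      sweep(x, 1, ifelse(mx > 0, mx, 1), "/")
    },
    z = {
      mu <- rowMeans(x)
      sdv <- apply(x, 1, sd)
      sweep(sweep(x, 1, mu, "-"), 1, ifelse(sdv > 0, sdv, 1), "/")
    })
  attr(out, "scaling") <- scale
  out
}

#' K-means clustering (seeded multistart)
#'
#' @param x numeric matrix (rows = items).
#' @param k number of clusters, `1 <= k <= nrow(x)`.
#' @param seed integer seed.
#' @param n_init number of random initializations; the solution with the
#'   lowest total within-cluster sum of squares is kept.
#' @return list with `labels`, `centers` and `w` (total within-cluster SS).
#' @export
bv_kmeans <- function(x, k, seed = 1L, n_init = 25L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("bv_kmeans: k > number of items")
  if (k < 1L) stop("bv_kmeans: k must be >= 1")
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1, ncol(x),
                  dimnames = list(NULL, colnames(x)))
    return(list(labels = setNames(rep(1L, nrow(x)), rownames(x)),
                centers = ctr,
                w = sum(sweep(x, 2, ctr[1L, ])^2)))
  }
  if (k == nrow(x)) {
    ## every point its own cluster (stats::kmeans refuses k == n)
    return(list(labels = setNames(seq_len(nrow(x)), rownames(x)),
                centers = x, w = 0))
  }
  fit <- with_seed(seed, suppressWarnings(
    kmeans(x, centers = k, nstart = n_init, iter.max = 100L)))
  list(labels = setNames(fit$cluster, rownames(x)), centers = fit$centers,
       w = fit$tot.withinss)
}

#' Gap-statistic choice of the number of clusters
#'
#' Computes `Gap(k) = mean_b log(W*_kb) - log(W_k)` for `k = 1..kmax`,
#' where the `B` reference data sets are drawn uniformly over the observed
#' per-dimension ranges, with simulation error
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`, and picks the smallest `k`
#' with `Gap(k) >= Gap(k+1) - s_(k+1)` (computed by `cluster::clusGap`
#' with `spaceH0 = "original"` and `cluster::maxSE`).  The data are then
#' clustered at the chosen `k`.
#'
#' @param x numeric matrix (rows = items).
#' @param kmax maximum number of clusters considered (`< nrow(x)`).
#' @param b number of reference data sets (`>= 10`).
#' @param seed integer seed (controls both the reference draws and the
#'   final clustering).
#' @param n_init K-means initializations per fit.
#' @return object of class `bv_clustering`: list with `chosen_k`, `labels`,
#'   `centers`, `w` (within-cluster dispersion at each k), `gap`, `se` and
#'   the `clusGap` table.
#' @export
gap_statistic <- function(x, kmax = 6L, b = 50L, seed = 1L, n_init = 10L) {
  x <- as.matrix(x)
  if (kmax >= nrow(x)) stop("gap_statistic: kmax must be < number of items")
  if (b < 10L) stop("gap_statistic: need at least 10 reference sets")

  if (kmax < 2L || all(apply(x, 2, function(col) diff(range(col)) == 0))) {
    ## degenerate: all points identical, or too few for a gap curve
    fit <- bv_kmeans(x, 1L)
    return(structure(list(chosen_k = 1L, labels = fit$labels,
                          centers = fit$centers, w = fit$w,
                          gap = NA_real_, se = NA_real_, table = NULL),
                     class = "bv_clustering"))
  }

  fun <- function(xx, k) {
    list(cluster = bv_kmeans(xx, k, seed = NULL, n_init = n_init)$labels)
  }
  cg <- with_seed(seed, cluster::clusGap(x, FUNcluster = fun, K.max = kmax,
                                         B = b, spaceH0 = "original",
                                         verbose = FALSE))
  tab <- cg$Tab
  chosen_k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                             method = "Tibs2001SEmax")
  fit <- bv_kmeans(x, chosen_k, seed = seed + 1L, n_init = 25L)
  structure(list(chosen_k = as.integer(chosen_k), labels = fit$labels,
                 centers = fit$centers, w = exp(tab[, "logW"]),
                 gap = tab[, "gap"], se = tab[, "SE.sim"], table = tab),
            class = "bv_clustering")
}

#' @export
plot.bv_clustering <- function(x, main = NULL, ...) {
  ctr <- x$centers
  graphics::matplot(t(ctr), type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "establishment class",
                    ylab = "cluster centroid",
                    main = if (is.null(main)) {
                      sprintf("K-means centroids (k = %d)", x$chosen_k)
                    } else main, ...)
  graphics::axis(1, at = seq_len(ncol(ctr)),
                 labels = colnames(ctr) %||% CLASS_LABELS)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bv_clustering <- function(x, ...) {
  cat(sprintf("Gap-statistic K-means: chosen k = %d (%d items)\n",
              x$chosen_k, length(x$labels)))
  sizes <- table(x$labels)
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster species profiles
#'
#' Convenience wrapper: scales the profiles (see [scale_profiles()]),
#' chooses the number of clusters with [gap_statistic()] and attaches the
#' scaling and source metadata the vulnerability classifier needs.
#'
#' @param profiles species x 4 profile matrix from [build_profiles()].
#' @param kmax,b,seed,n_init passed to [gap_statistic()].
#' @param scale profile scaling mode (see [scale_profiles()]).
#' @return `bv_clustering` object with extra fields `scale` and `source`.
#' @export
cluster_profiles <- function(profiles, kmax = 6L, b = 50L, seed = 1L,
                             scale = c("max", "raw", "z"), n_init = 10L) {
  scale <- match.arg(scale)
  scaled <- scale_profiles(profiles, scale)
  kmax <- min(kmax, nrow(scaled) - 1L)
  out <- gap_statistic(scaled, kmax = kmax, b = b, seed = seed,
                       n_init = n_init)
  out$scale <- scale
  out$source <- attr(profiles, "source")
  out
}
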
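## Non-metric multidimensional scaling on a dissimilarity matrix, with a
## multistart strategy: the first start is the metric principal-coordinate
## configuration, the remaining starts are that configuration plus
## increasing jitter.  The best (lowest Kruskal stress-1) solution is kept.

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1,
#' `sqrt(sum((dhat - dstar)^2) / sum(dhat^2))`, where `dstar` is the
#' monotone (isotonic) regression of configuration distances on the ranks
#' of the observed dissimilarities (ties treated by within-tie averaging,
#' the primary approach).  The optimizer is `vegan::monoMDS`; this wrapper
#' adds seeded multistart and returns the best configuration.
#'
#' @param d `dist` or symmetric dissimilarity matrix.
#' @param k number of ordination axes (default 2).
#' @param n_starts number of starting configurations (default 20): metric
#'   PCoA plus jittered copies.
#' @param max_iter maximum iterations per start.
#' @param tol stress convergence tolerance.
#' @param seed integer seed for the jitter.
#' @return object of class `bv_nmds`: list with `points` (n x k matrix),
#'   `stress` (Kruskal stress-1, fraction in `[0, 1]`), `converged`,
#'   `n_starts`.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, max_iter = 200L, tol = 1e-7,
                 seed = 1L) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 1L) stop("nmds: need at least k + 1 items")
  base <- cmdscale(d, k = k, add = TRUE)$points
  scale0 <- max(apply(base, 2, sd), 1e-8)
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      y0 <- if (s == 1L) base else base + rnorm(length(base),
                                                sd = scale0 * 0.25 * s)
      fit <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                            maxit = max_iter, sratmax = 1 - tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    structure(list(points = best$points, stress = best$stress,
                   converged = best$icause %in% c(2L, 3L),
                   n_starts = n_starts, monoMDS = best),
              class = "bv_nmds")
  })
}

#' @export
print.bv_nmds <- function(x, ...) {
  cat(sprintf("NMDS: %d points, %d axes, stress = %.5f (%s, best of %d starts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged", x$n_starts))
  invisible(x)
}

#' @export
plot.bv_nmds <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1L else as.integer(as.factor(groups))
  plot(x$points[, 1:2], col = col, pch = 19,
       xlab = "NMDS1", ylab = "NMDS2",
       main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}

#' Kruskal stress-1 of a configuration
#'
#' Direct evaluation of stress-1 for a given configuration against observed
#' dissimilarities, using isotonic regression (`stats::isoreg`) of the
#' configuration distances on the rank order of `d`.  Useful as an
#' independent check of an ordination result; rigid motions of the
#' configuration leave it unchanged.
#'
#' @param d observed dissimilarities (`dist` or matrix).
#' @param config n x k coordinate matrix.
#' @return stress-1 value.
#' @export
kruskal_stress <- function(d, config) {
  d <- as.vector(stats::as.dist(d))
  dhat <- as.vector(dist(config))
  ## average within ties of the observed dissimilarities (primary treatment)
  ord <- order(d)
  fit <- stats::isoreg(d[ord], dhat[ord])$yf
  ## isoreg fits monotone in the order given; map back
  dstar <- numeric(length(d))
  dstar[ord] <- fit
  ## primary tie treatment: within tied d, dstar is free; replace by the
  ## within-tie isotonic fit already produced, then average residuals
  sqrt(sum((dhat - dstar)^2) / sum(dhat^2))
}
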
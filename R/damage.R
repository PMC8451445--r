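## Mean damage grade (MDG): the weighted mean of the four ordinal browsing
## damage classes scored on N sampled plant units,
##   MDG = (0*CL1 + 5*CL2 + 30*CL3 + 75*CL4) / N,
## so MDG ranges from 0 (no unit damaged) to 75 (every unit >50% damaged).

MDG_WEIGHTS <- c(0, 5, 30, 75)

#' Mean damage grade of a damage record
#'
#' @param n_cl1,n_cl2,n_cl3,n_cl4 counts of sampled plant units in damage
#'   classes CL1 (no damage), CL2 (1--10%), CL3 (11--50%), CL4 (51--100%).
#'   Vectorized.
#' @return numeric MDG value(s) in `[0, 75]`.
#' @export
#' @examples
#' mdg(2, 3, 4, 1)  # (0 + 15 + 120 + 75) / 10 = 21
mdg <- function(n_cl1, n_cl2, n_cl3, n_cl4) {
  counts <- cbind(n_cl1, n_cl2, n_cl3, n_cl4)
  if (any(counts < 0)) stop("mdg: negative class counts")
  n <- rowSums(counts)
  if (any(n < 1)) stop("mdg: N must be >= 1")
  as.vector(counts %*% MDG_WEIGHTS) / n
}

#' Species x site matrix of mean damage grades
#'
#' Cells where a species was not surveyed at a site stay `NA`: absence of a
#' damage record is not evidence of zero damage, and `NA` cells are excluded
#' from all downstream means.
#'
#' @param damage validated damage table (see [as_damage_table()]).
#' @return numeric matrix, rows = species, cols = sites, `NA` where missing.
#' @export
mdg_matrix <- function(damage) {
  damage <- as_damage_table(damage)
  species <- sort(unique(damage$species))
  sites <- sort(unique(damage$site))
  m <- matrix(NA_real_, nrow = length(species), ncol = length(sites),
              dimnames = list(species, sites))
  m[cbind(match(damage$species, species), match(damage$site, sites))] <-
    mdg(damage$n_cl1, damage$n_cl2, damage$n_cl3, damage$n_cl4)
  m
}

#' Species absent where deer are long established but browsed elsewhere
#'
#' Lists species with zero occurrence in the coverage survey of every site
#' of the oldest establishment class (Y1978) but browsing evidence
#' (MDG > 0) in the other establishment classes.  Such species may have
#' been eliminated from the long-established sites by browsing; they form
#' the supplementary damage group G4 feeding the vulnerability
#' classification.
#'
#' @param coverage validated coverage table.
#' @param mdg_mat species x site MDG matrix from [mdg_matrix()].
#' @param sites validated site table mapping sites to establishment classes.
#' @param strict if `FALSE` (default, the weak reading), browsing evidence
#'   in at least one site of at least one other class suffices; if `TRUE`,
#'   evidence is required in at least one site of each of the three other
#'   classes.
#' @return sorted character vector of species ids.
#' @export
g4_species <- function(coverage, mdg_mat, sites, strict = FALSE) {
  coverage <- as_coverage_table(coverage)
  sites <- as_site_table(sites)
  old_sites <- sites$site[sites$class == "Y1978"]
  other_classes <- setdiff(CLASS_LABELS, "Y1978")

  present_old <- unique(coverage$species[coverage$site %in% old_sites])
  candidates <- setdiff(rownames(mdg_mat), present_old)

  keep <- vapply(candidates, function(sp) {
    browsed_in <- vapply(other_classes, function(cl) {
      s <- intersect(sites$site[sites$class == cl], colnames(mdg_mat))
      any(mdg_mat[sp, s] > 0, na.rm = TRUE)
    }, TRUE)
    if (strict) all(browsed_in) else any(browsed_in)
  }, TRUE)
  sort(candidates[keep])
}
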
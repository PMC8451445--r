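# Independent oracles, deliberately implemented from the textbook
# definitions rather than through the package or vegan, so the tests check
# two routes against each other.

# One-factor PERMANOVA sums of squares straight from squared
# dissimilarities: SS_total = sum(d_ij^2)/n over all pairs, SS_within =
# sum over groups of within-group d_ij^2 / n_g (Anderson's direct formula).
oracle_permanova_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- as.factor(groups)
  sst <- sum(d[upper.tri(d)]^2) / n
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      dg <- d[idx, idx]
      ssw <- ssw + sum(dg[upper.tri(dg)]^2) / length(idx)
    }
  }
  ssa <- sst - ssw
  a <- nlevels(groups)
  (ssa / (a - 1)) / (ssw / (n - a))
}

# Exact permutation p-value by enumerating every distinct assignment of the
# observed group sizes to the items.
oracle_permanova_exact_p <- function(d, groups) {
  groups <- as.factor(groups)
  n <- length(groups)
  f_obs <- oracle_permanova_f(d, groups)
  perms <- deervuln:::all_permutations(n)
  f_all <- apply(perms, 1, function(p) oracle_permanova_f(d, groups[p]))
  mean(f_all >= f_obs - 1e-12)
}

# Total within-cluster sum of squares of a labelled partition.
oracle_wss <- function(x, labels) {
  sum(vapply(unique(labels), function(l) {
    xs <- x[labels == l, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, 0))
}

# Best (minimum-W) 2-partition of a small point set by brute force over all
# bipartitions.
oracle_best_two_partition <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(0L, as.integer(intToBits(code)[1:(n - 1)]))
    if (length(unique(lab)) < 2) next
    w <- oracle_wss(x, lab)
    if (w < best) {
      best <- w
      best_lab <- lab
    }
  }
  list(w = best, labels = best_lab)
}

# A tiny hand-rolled reference database for barcoding tests.
tiny_db <- function() {
  as_reference_db(data.frame(
    taxon = c("Quercus crispula", "Acer pictum", "Sasa sp", "Viola vaginata"),
    family = c("Fagaceae", "Sapindaceae", "Poaceae", "Violaceae"),
    sequence = c(
      "ATCCTGTTTTCCGAAAACAAACAAAGGTTCAGAAAGCGAG",
      "ATCCGGTTTTCCGAAAACAAACAAAGGTTCAGAAAGCGAA",
      "GGTTCAGAAAGCGAGAATCCTGTTTTCCGAAAACAAACAA",
      "ATCCTGTTTTCCGAAAACAAACAAAGGTTCAGAAAGCGAG"),  # == Quercus
    stringsAsFactors = FALSE))
}
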
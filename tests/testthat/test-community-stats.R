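make_cov <- function(site, species, coverage) {
  data.frame(site = site, plot = ave(seq_along(site), site, species,
                                     FUN = seq_along),
             species = species, coverage = coverage)
}

test_that("richness and Shannon diversity follow their definitions", {
  # one species only -> H' = 0
  cov1 <- make_cov("S1", "a", 10)
  expect_equal(unname(shannon(cov1)), 0)
  expect_equal(unname(richness(cov1)), 1L)

  # two species with equal summed cover -> H' = ln 2
  cov2 <- make_cov(rep("S1", 2), c("a", "b"), c(20, 20))
  expect_equal(unname(shannon(cov2)), log(2), tolerance = 1e-12)

  # shares (0.5, 0.25, 0.25): hand-computed -sum p log p
  cov3 <- make_cov(rep("S1", 3), c("a", "b", "c"), c(50, 25, 25))
  h_hand <- -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25)))
  expect_equal(unname(shannon(cov3)), h_hand, tolerance = 1e-12)
  expect_equal(round(h_hand, 4), 1.0397)

  # invariance to plot order (records split across plots)
  cov4 <- data.frame(site = "S1", plot = c(1, 2, 3, 1),
                     species = c("a", "a", "b", "b"),
                     coverage = c(10, 10, 15, 5))
  cov5 <- cov4[c(3, 1, 4, 2), ]
  expect_equal(shannon(cov4), shannon(cov5))
  expect_equal(richness(cov4), richness(cov5))
  expect_equal(richness(cov4, "missing_site"), c(missing_site = 0L))
  expect_error(shannon(cov4, "missing_site"), "no records")
})

test_that("Bray-Curtis matches the definitional formula", {
  expect_equal(as.vector(bray_curtis(rbind(c(1, 2), c(1, 2)))), 0)
  expect_equal(as.vector(bray_curtis(rbind(c(3, 0), c(0, 4)))), 1)
  expect_equal(as.vector(bray_curtis(rbind(c(1, 2), c(2, 0)))), 0.6)

  # column-order invariance
  m <- matrix(rpois(40, 5), 8, 5)
  expect_equal(as.vector(bray_curtis(m)), as.vector(bray_curtis(m[, 5:1])))

  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 1))), "all-zero")
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "negative")
})

test_that("PERMANOVA matches the exhaustive enumeration oracle", {
  set.seed(21)
  # balanced 3 + 3 with real group structure
  x <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 2), 3, 2))
  g <- rep(c("a", "b"), each = 3)
  d <- dist(x)
  fit <- permanova(d, g, exhaustive = TRUE)
  expect_equal(fit$p_value, oracle_permanova_exact_p(d, g), tolerance = 1e-12)
  expect_equal(fit$f, oracle_permanova_f(d, g), tolerance = 1e-8)

  # unbalanced groups and three levels
  g2 <- c("a", "a", "b", "b", "b", "c")
  fit2 <- permanova(d, g2, exhaustive = TRUE)
  expect_equal(fit2$p_value, oracle_permanova_exact_p(d, g2),
               tolerance = 1e-12)
})

test_that("PERMANOVA degenerate and error cases behave", {
  # two groups of two identical points each, groups separated -> R2 = 1
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  fit <- permanova(dist(x), c("a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_equal(fit$r2, 1)
  expect_error(permanova(dist(x), rep("a", 4), n_perm = 9, seed = 1),
               "two groups")
  expect_error(permutation_matrix(5, n_perm = 0, seed = 1), "n_perm")
  # determinism under a fixed seed
  set.seed(5)
  y <- matrix(rnorm(40), 10, 4)
  g <- rep(c("a", "b"), 5)
  f1 <- permanova(dist(y), g, n_perm = 199, seed = 42)
  f2 <- permanova(dist(y), g, n_perm = 199, seed = 42)
  expect_identical(f1$p_value, f2$p_value)
})

test_that("stratified permutations stay within their blocks", {
  strata <- rep(1:8, each = 3)
  pm <- permutation_matrix(24, n_perm = 500, strata = strata, seed = 9)
  expect_equal(dim(pm), c(500L, 24L))
  # every permuted index keeps its stratum
  for (r in seq_len(nrow(pm))) {
    expect_identical(strata[pm[r, ]], strata)
  }
  # and rows are genuine permutations
  expect_true(all(apply(pm, 1, function(p) identical(sort(p), 1:24))))
})

test_that("multivariate dispersion test detects planted dispersion differences", {
  set.seed(31)
  # identical internal geometry -> no dispersion difference
  base <- matrix(rnorm(40), 20, 2)
  x <- rbind(base, base + 50)
  g <- rep(c("a", "b"), each = 20)
  fit <- permdisp(dist(x), g, n_perm = 199, seed = 3)
  expect_gt(fit$p_value, 0.2)

  # planted dispersion ratio 4 at n = 20/group
  y <- rbind(matrix(rnorm(40, sd = 1), 20, 2),
             matrix(rnorm(40, sd = 4), 20, 2))
  fit2 <- permdisp(dist(y), g, n_perm = 199, seed = 3)
  expect_lt(fit2$p_value, 0.05)
})

test_that("GLM likelihood-ratio test matches the Poisson deviance difference", {
  # identical group means -> chi2 = 0
  fit0 <- glm_lrt(c(4, 4, 4, 4), c("a", "a", "b", "b"), family = "poisson")
  expect_equal(fit0$chi2, 0, tolerance = 1e-10)

  # hand-computable saturated designs: chi2 = 2 sum y log(mu_g / mu_0)
  set.seed(41)
  for (i in 1:5) {
    y <- rpois(12, lambda = sample(2:10, 1))
    g <- rep(c("a", "b", "c"), each = 4)
    mu_g <- ave(y, g)
    mu_0 <- mean(y)
    hand <- 2 * sum(ifelse(y == 0, 0, y * log(mu_g / mu_0)) - (mu_g - mu_0))
    fit <- glm_lrt(y, g, family = "poisson")
    expect_equal(fit$chi2, hand, tolerance = 1e-8)
  }

  # zero-count group under the log link: deviance limit, no pseudo-counts
  yz <- c(0, 0, 3, 5)
  fitz <- suppressWarnings(glm_lrt(yz, c("a", "a", "b", "b"),
                                   family = "poisson"))
  mu_g <- ave(yz, c("a", "a", "b", "b"))
  hand <- 2 * sum(ifelse(yz == 0, 0, yz * log(mu_g / mean(yz))) -
                    (mu_g - mean(yz)))
  expect_equal(fitz$chi2, hand, tolerance = 1e-8)

  # gaussian family and covariate adjustment run end to end
  fg <- glm_lrt(rnorm(12), rep(c("a", "b"), 6), covariate = runif(12),
                family = "gaussian")
  expect_gte(fg$chi2, 0)
  expect_equal(fg$df, 1L)
})

test_that("Poisson GLMM shrinks to the GLM when site variance is zero", {
  set.seed(51)
  g <- rep(c("a", "b"), each = 40)
  site <- rep(sprintf("S%d", 1:8), each = 10)
  y <- rpois(80, lambda = ifelse(g == "a", 4, 8))   # no site effect
  fit <- suppressMessages(glmm_poisson(y, g, site))
  expect_lt(fit$site_variance, 0.05)
  # with no site variance the fixed effects match the plain GLM
  ref <- glm_lrt(y, g, family = "poisson")
  expect_equal(unname(lme4::fixef(fit$full)), unname(ref$coefficients),
               tolerance = 1e-3)
  expect_gte(fit$chi2, 0)
  expect_lt(fit$p_value, 0.05)
})

test_that("dbMEM eigenvectors use the spanning-tree truncation", {
  # 4 equally spaced points on a line: MST edge = spacing
  coords <- cbind(c(0, 1, 2, 3), rep(0, 4))
  mem <- dbmem(coords)
  expect_equal(mem$threshold, 1)
  expect_lte(ncol(mem$vectors), 3L)
  expect_true(all(mem$values > 0))
  expect_error(dbmem(coords[c(1, 1, 2), ]), "duplicate")
  expect_error(dbmem(coords[1:2, ]), "at least 3")
})

test_that("dbMEM tests are calibrated on spatially unstructured responses", {
  set.seed(61)
  coords <- cbind(runif(20, 0, 300), runif(20, 0, 200))
  mem <- dbmem(coords)
  # aggregate type-I error over replicates of a spatially independent response
  ps <- unlist(lapply(1:15, function(i) {
    dbmem_test(mem, rnorm(20), coords = coords, n_perm = 99,
               seed = 100 + i)$p_value
  }))
  expect_lt(mean(ps < 0.05), 0.15)  # near the nominal 5% rate

  # a strongly spatial response is detected (fine-scale vector: detrending
  # removes little of it, unlike the broad-scale first vector)
  j <- ncol(mem$vectors)
  resp <- mem$vectors[, j] * 3 + rnorm(20, sd = 0.1)
  p1 <- dbmem_test(mem, resp, coords = coords, n_perm = 199, seed = 1)
  expect_lt(p1$p_value[j], 0.05)

  # multivariate (distance) responses run through the PERMANOVA route
  comm <- matrix(rpois(20 * 6, 10), 20, 6)
  tab <- dbmem_test(mem, comm, coords = coords, n_perm = 99, seed = 2)
  expect_equal(nrow(tab), ncol(mem$vectors))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
})
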
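four_sites <- function() {
  data.frame(site = c("S1", "S2", "S3", "S4", "S5"),
             class = c("Y1978", "Y2003", "Y2011", "Y2014", "Y2014"),
             x = 1:5, y = rep(0, 5))
}

test_that("profiles average site-level values within establishment classes", {
  sites <- four_sites()
  cov <- data.frame(
    site = c("S1", "S1", "S2", "S3", "S4", "S5", "S2", "S3", "S4"),
    plot = c(1, 2, 1, 1, 1, 1, 1, 1, 1),
    species = c("a", "a", "a", "a", "a", "a", "b", "b", "b"),
    coverage = c(5, 10, 20, 30, 40, 20, 5, 5, 5))
  prof <- build_profiles(cov, sites, source = "coverage")
  # species a: class values 15, 20, 30, mean(40, 20) = 30
  expect_equal(unname(prof["a", ]), c(15, 20, 30, 30))
  # species b absent from Y1978 -> removed by the presence filter
  expect_false("b" %in% rownames(prof))
  prof_all <- build_profiles(cov, sites, source = "coverage",
                             presence_filter = FALSE)
  expect_true("b" %in% rownames(prof_all))

  # constant species: profile (v, v, v, v)
  cov_c <- data.frame(site = c("S1", "S2", "S3", "S4"), plot = 1,
                      species = "c", coverage = 10)
  expect_equal(unname(build_profiles(cov_c, sites, source = "coverage")["c", ]),
               rep(10, 4))
})

test_that("MDG profiles exclude missing cells from class means", {
  sites <- four_sites()
  m <- matrix(NA_real_, 1, 5, dimnames = list("a", sites$site))
  m["a", ] <- c(30, 20, 10, 5, NA)   # not surveyed at S5
  prof <- build_profiles(m, sites, source = "mdg")
  expect_equal(unname(prof["a", ]), c(30, 20, 10, 5))
})

test_that("read profiles average within sites before classes", {
  sites <- four_sites()
  # two samples at S4, one at S5 (both Y2014): site means first
  props <- rbind(F1 = c(0.2, 0.8), F2 = c(0.4, 0.6), F3 = c(1.0, 0.0),
                 F4 = c(0.5, 0.5), F5 = c(0.1, 0.9), F6 = c(0.3, 0.7))
  colnames(props) <- c("t1", "t2")
  samp_sites <- c(F1 = "S1", F2 = "S2", F3 = "S3",
                  F4 = "S4", F5 = "S4", F6 = "S5")
  prof <- build_profiles(props, sites, source = "reads",
                         sample_sites = samp_sites)
  # Y2014 value for t1: mean(site S4 = mean(0.5, 0.1) = 0.3, site S5 = 0.3)
  expect_equal(unname(prof["t1", "Y2014"]), 0.3)
  expect_equal(unname(prof["t1", c("Y1978", "Y2003", "Y2011")]),
               c(0.2, 0.4, 1.0))
  # no presence filter for reads: both taxa retained
  expect_equal(nrow(prof), 2L)
})

test_that("profile scaling modes behave", {
  x <- rbind(a = c(2, 4, 8, 8), b = c(0, 0, 0, 0), c = c(3, 3, 3, 3))
  mx <- scale_profiles(x, "max")
  expect_equal(unname(mx["a", ]), c(0.25, 0.5, 1, 1))
  expect_equal(unname(mx["b", ]), rep(0, 4))   # all-zero stays zero
  expect_equal(unname(mx["c", ]), rep(1, 4))
  expect_identical(scale_profiles(x, "raw")[, ], x[, ])
  z <- scale_profiles(x, "z")
  expect_equal(unname(rowMeans(z)), rep(0, 3), tolerance = 1e-12)
})

test_that("k-means reaches the brute-force optimum on small instances", {
  set.seed(81)
  # two well-separated planted blobs of 4 points each
  x <- rbind(matrix(rnorm(8), 4, 2), matrix(rnorm(8, mean = 10), 4, 2))
  fit <- bv_kmeans(x, 2, seed = 1)
  oracle <- oracle_best_two_partition(x)
  expect_equal(fit$w, oracle$w, tolerance = 1e-8)
  # exact label recovery up to permutation
  expect_equal(length(unique(fit$labels[1:4])), 1L)
  expect_equal(length(unique(fit$labels[5:8])), 1L)
  expect_false(fit$labels[1] == fit$labels[5])

  # k = n -> W = 0; duplicates co-clustered
  expect_equal(bv_kmeans(x, nrow(x), seed = 1)$w, 0)
  dup <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9))
  labs <- bv_kmeans(dup, 2, seed = 1)$labels
  expect_equal(labs[1], labs[2])
  expect_equal(labs[3], labs[4])
  expect_error(bv_kmeans(x, 9, seed = 1), "k > number")
})

test_that("gap statistic picks one cluster for a single blob", {
  set.seed(82)
  x <- matrix(rnorm(40 * 4), 40, 4)
  out <- gap_statistic(x, kmax = 5, b = 25, seed = 7)
  expect_equal(out$chosen_k, 1L)
  # within-cluster dispersion is non-increasing in k
  expect_true(all(diff(out$w) <= 1e-8))

  # degenerate: all points identical
  xx <- matrix(1, 10, 3)
  expect_equal(gap_statistic(xx, kmax = 3, b = 10, seed = 1)$chosen_k, 1L)
})

test_that("gap statistic is invariant to coordinate permutation", {
  set.seed(83)
  x <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 6), 20, 3),
             sweep(matrix(rnorm(60), 20, 3), 2, c(6, -6, 0), "+"))
  out1 <- gap_statistic(x, kmax = 5, b = 25, seed = 11)
  out2 <- gap_statistic(x[, c(3, 1, 2)], kmax = 5, b = 25, seed = 11)
  expect_equal(out1$chosen_k, out2$chosen_k)
  # same partition (cluster indices may differ)
  expect_equal(length(unique(paste(out1$labels, out2$labels))),
               length(unique(out1$labels)))
})

test_that("cluster_profiles records scaling and source metadata", {
  set.seed(84)
  prof <- rbind(matrix(runif(40, 0, 5), 10, 4),
                matrix(runif(40, 20, 30), 10, 4))
  rownames(prof) <- sprintf("sp%02d", 1:20)
  colnames(prof) <- c("Y1978", "Y2003", "Y2011", "Y2014")
  attr(prof, "source") <- "coverage"
  out <- cluster_profiles(prof, kmax = 4, b = 15, seed = 2, scale = "raw")
  expect_equal(out$scale, "raw")
  expect_equal(out$source, "coverage")
  expect_setequal(names(out$labels), rownames(prof))
})
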
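test_that("coverage tables parse, validate the survey grid, and canonicalize", {
  df <- data.frame(site = "S1", plot = 3, species = "Quercus crispula",
                   coverage = 5)
  out <- as_coverage_table(df)
  expect_equal(nrow(out), 1L)
  expect_equal(out$coverage, 5)

  expect_error(as_coverage_table(transform(df, coverage = 3)),
               "not in the permitted set")
  expect_error(as_coverage_table(rbind(df, df)), "duplicate record")
  expect_error(as_coverage_table(transform(df, plot = 21)), "20 plots")

  # permuting input rows yields the identical canonical table
  big <- data.frame(site = rep(c("S1", "S2"), each = 6),
                    plot = rep(1:3, 4),
                    species = rep(c("a", "b"), 6),
                    coverage = rep(c(1, 10, 45), 4))
  shuffled <- big[sample(nrow(big)), ]
  expect_identical(as_coverage_table(big), as_coverage_table(shuffled))
})

test_that("damage tables enforce count invariants", {
  df <- data.frame(site = "S1", species = "sp1",
                   n_cl1 = 2, n_cl2 = 3, n_cl3 = 4, n_cl4 = 1)
  out <- as_damage_table(df)
  expect_equal(out$n, 10L)
  expect_error(as_damage_table(transform(df, n_cl1 = -1)), "non-negative")
  expect_error(as_damage_table(transform(df, n = 9)), "does not equal")
  zero <- transform(df, n_cl1 = 0, n_cl2 = 0, n_cl3 = 0, n_cl4 = 0)
  expect_error(as_damage_table(zero), "N >= 1")
  expect_error(as_damage_table(rbind(df, df)), "duplicate")
})

test_that("trait table ties architecture to woodiness", {
  df <- data.frame(species = c("t1", "f1"), family = "x",
                   life_form = c("tree", "perennial"),
                   architecture = c(NA, "erect"))
  expect_silent(as_trait_table(df))
  df$architecture <- c("erect", "erect")
  expect_error(as_trait_table(df), "woody")
  df$architecture <- c(NA, NA)
  expect_warning(as_trait_table(df), "without an architecture")
})

test_that("reference database merges identical sequences into taxon groups", {
  db <- tiny_db()
  expect_equal(nrow(db), 4L)
  grp <- db$group[db$taxon == "Quercus crispula"]
  expect_equal(grp, "Quercus crispula|Viola vaginata")
  expect_equal(grp, db$group[db$taxon == "Viola vaginata"])
  expect_equal(length(unique(db$group)), 3L)

  # lowercase input is normalized
  low <- as_reference_db(data.frame(taxon = "x", sequence = "acgt"))
  expect_equal(low$sequence, "ACGT")

  # same taxon, conflicting sequences
  expect_error(as_reference_db(data.frame(taxon = c("x", "x"),
                                          sequence = c("AAAA", "CCCC"))),
               "conflicting")
  expect_error(as_reference_db(data.frame(taxon = "x", sequence = "AXGT")),
               "non-ACGTN")
})

test_that("reference database round-trips through FASTA", {
  db <- tiny_db()
  path <- tempfile(fileext = ".fasta")
  write_reference_db(db, path)
  back <- read_reference_db(path)
  expect_equal(back$taxon, db$taxon)
  expect_equal(back$sequence, db$sequence)
  expect_equal(back$group, db$group)
  expect_equal(back$family, db$family)
})

test_that("matrix CSV round-trip is exact for integers and 12-digit for reals", {
  path <- tempfile(fileext = ".csv")

  m_int <- matrix(c(1, 2, 3, 4), 2, 2,
                  dimnames = list(c("r1", "r2"), c("c1", "c2")))
  write_matrix(m_int, path)
  expect_identical(read_matrix(path), m_int)

  expect_error(write_matrix(matrix(numeric(0), 0, 0), path), "empty")
  expect_error(write_matrix(1:3, path), "not a matrix")

  # property: random real matrices at the read-table scale
  set.seed(1)
  for (i in 1:3) {
    m <- matrix(rnorm(63 * 98) * 10^sample(-6:6, 1), 63, 98,
                dimnames = list(sprintf("F%02d", 1:63),
                                sprintf("sp%03d", 1:98)))
    write_matrix(m, path)
    expect_equal(read_matrix(path), m, tolerance = 1e-12)
  }
  # integer counts round-trip exactly
  m <- matrix(as.numeric(rpois(63 * 98, 50)), 63, 98,
              dimnames = list(sprintf("F%02d", 1:63), sprintf("sp%03d", 1:98)))
  write_matrix(m, path)
  expect_identical(read_matrix(path), m)
})

test_that("site table validates classes and coordinates", {
  df <- data.frame(site = c("S1", "S2", "S3"),
                   class = c("Y1978", "Y2003", "Y2014"),
                   x = c(0, 10, 20), y = c(0, 5, 2))
  expect_silent(as_site_table(df))
  expect_error(as_site_table(transform(df, class = "Y1999")), "unknown")
  expect_error(as_site_table(transform(df, x = c(0, Inf, 1))), "finite")
  expect_error(as_site_table(df[c(1, 1, 2), ]), "duplicate site")
  expect_equal(levels(establishment_factor(df$class)),
               c("Y1978", "Y2003", "Y2011", "Y2014"))
})
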
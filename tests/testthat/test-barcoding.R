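test_that("dereplication counts and orders unique sequences", {
  d <- dereplicate_reads(c("AAA", "aaa", "AAC"))
  expect_equal(d$sequence, c("AAA", "AAC"))
  expect_equal(d$count, c(2L, 1L))

  empty <- dereplicate_reads(character(0))
  expect_equal(nrow(empty), 0L)

  # error-free simulation from 5 templates collapses back to 5 pairs
  set.seed(7)
  templates <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, "")
  reads <- sample(templates, 10000, replace = TRUE,
                  prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  d <- dereplicate_reads(reads)
  expect_equal(nrow(d), 5L)
  expect_equal(sum(d$count), 10000L)
  expect_false(is.unsorted(rev(d$count)))
})

test_that("assignment is exact-match with merged taxon groups", {
  db <- tiny_db()
  qseq <- db$sequence[db$taxon == "Quercus crispula"]
  aseq <- db$sequence[db$taxon == "Acer pictum"]
  res <- assign_reads(list(s1 = c(qseq, qseq, aseq)), db, min_prop = 0)
  expect_equal(unname(res$counts["s1", "Quercus crispula|Viola vaginata"]), 2L)
  expect_equal(unname(res$counts["s1", "Acer pictum"]), 1L)
  expect_equal(sum(res$unassigned), 0L)
})

test_that("unassigned reads are tallied by reason and conserved", {
  db <- tiny_db()
  qseq <- db$sequence[db$taxon == "Quercus crispula"]
  reads <- list(s1 = c(rep(qseq, 5),
                       "ACGT",                # shorter than min_len
                       paste(rep("T", 40), collapse = ""),  # no match
                       "NNNNNNNNNNNNNNNNNNNNNNNNNNNNNN"))   # no match
  res <- assign_reads(reads, db, min_len = 20, min_prop = 0)
  expect_equal(unname(res$unassigned["s1", "too_short"]), 1L)
  expect_equal(unname(res$unassigned["s1", "no_match"]), 2L)
  expect_equal(sum(res$counts["s1", ]) + sum(res$unassigned["s1", ]),
               unname(res$totals["s1"]))

  # low-frequency zeroing: 1 read in 2000 at min_prop 0.001 stays, at 0.01 goes
  aseq <- db$sequence[db$taxon == "Acer pictum"]
  many <- list(s1 = data.frame(sequence = c(qseq, aseq),
                               count = c(1999L, 1L)))
  keep <- assign_reads(many, db, min_prop = 0)
  drop <- assign_reads(many, db, min_prop = 0.01)
  expect_equal(unname(keep$counts["s1", "Acer pictum"]), 1L)
  expect_equal(unname(drop$counts["s1", "Acer pictum"]), 0L)
  expect_equal(unname(drop$unassigned["s1", "low_frequency"]), 1L)
  # monotonicity: raising min_prop never increases any count
  expect_true(all(drop$counts <= keep$counts))
  # conservation still holds after filtering
  expect_equal(rowSums(drop$counts) + rowSums(drop$unassigned),
               drop$totals)
})

test_that("assignment is invariant to read order and warns when nothing matches", {
  db <- tiny_db()
  qseq <- db$sequence[db$taxon == "Quercus crispula"]
  aseq <- db$sequence[db$taxon == "Acer pictum"]
  reads <- c(rep(qseq, 3), rep(aseq, 2), "ACGTACGTACGTACGTACGTACGT")
  r1 <- assign_reads(list(s = reads), db)
  r2 <- assign_reads(list(s = rev(reads)), db)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$unassigned, r2$unassigned)

  expect_warning(assign_reads(list(s = "ACGTACGTACGTACGTACGTACGT"), db),
                 "no read")
})

test_that("read proportions sum to one and drop empty samples", {
  m <- matrix(c(30, 70, 0, 0, 5, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  expect_warning(p <- read_proportions(m), "zero assigned")
  expect_equal(nrow(p), 2L)
  expect_equal(unname(p["a", ]), c(0.3, 0.7))
  expect_equal(unname(p["c", ]), c(1, 0))
  expect_equal(unname(rowSums(p)), rep(1, 2), tolerance = 1e-12)
})

test_that("planted multinomial compositions are recovered", {
  # 2000 reads over 10 taxa at known proportions: chi-square goodness of fit
  set.seed(11)
  seqs <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  }, "")
  db <- as_reference_db(data.frame(taxon = sprintf("t%02d", 1:10),
                                   sequence = seqs))
  p_true <- c(30, 20, 15, 10, 8, 6, 5, 3, 2, 1) / 100
  counts <- as.integer(rmultinom(1, 2000, p_true))
  reads <- data.frame(sequence = seqs, count = counts)
  res <- assign_reads(list(s1 = reads), db, min_prop = 0)
  obs <- res$counts["s1", sprintf("t%02d", 1:10)]
  expect_equal(sum(obs), 2000L)
  gof <- suppressWarnings(chisq.test(obs, p = p_true))
  expect_gt(gof$p.value, 0.001)
})

test_that("per-sample reads round-trip through FASTA", {
  st <- fixture_small(seed = 5)
  path <- tempfile(fileext = ".fasta")
  write_sample_fasta(st$reads, path)
  back <- read_sample_fasta(path)
  expect_setequal(names(back), names(st$reads))
  for (s in names(st$reads)) {
    orig <- st$reads[[s]][order(st$reads[[s]]$sequence), ]
    got <- back[[s]][order(back[[s]]$sequence), ]
    expect_equal(got$sequence, orig$sequence)
    expect_equal(got$count, orig$count)
  }
})
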
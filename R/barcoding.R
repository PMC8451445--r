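## Fecal amplicon read assignment against the trnL P6-loop reference
## database.  Assignment is by exact sequence identity: the P6 loop is a
## short marker (~75 bp mean read length in deer feces) and exact matching
## is reproducible and conservative.  Taxa whose reference sequences are
## byte-identical are indistinguishable and receive one merged taxon-group
## column.

#' Dereplicate a collection of reads
#'
#' Collapses identical sequences (after upper-casing) into
#' (sequence, multiplicity) pairs, sorted by descending multiplicity and
#' then lexicographically, so results are independent of read order.
#'
#' @param reads character vector of nucleotide reads.
#' @return data frame with columns `sequence` and `count`;
#'   `sum(count) == length(reads)`.
#' @export
#' @examples
#' dereplicate_reads(c("AAA", "aaa", "AAC"))
dereplicate_reads <- function(reads) {
  reads <- toupper(as.character(reads))
  if (length(reads) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Accept either raw reads (character vector) or a dereplicated
## data.frame(sequence, count); always return the dereplicated form.
as_derep <- function(x) {
  if (is.data.frame(x)) {
    need_cols(x, c("sequence", "count"), "dereplicated reads")
    x$sequence <- toupper(as.character(x$sequence))
    x$count <- as.integer(x$count)
    if (any(x$count < 0L)) stop("dereplicated reads: negative count")
    return(x)
  }
  dereplicate_reads(x)
}

#' Read per-sample fecal reads from FASTA
#'
#' Headers follow the convention `sample_id|read_id`; reads are grouped by
#' `sample_id` and returned dereplicated.
#'
#' @param path FASTA path.
#' @return named list of dereplicated read data frames, one per sample.
#' @export
read_sample_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("read FASTA: empty file")
  sample <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[`, "", 1L)
  lapply(split(as.character(seqs), sample), dereplicate_reads)
}

#' Write per-sample reads to FASTA
#'
#' Expands dereplicated reads back to one record per read, headers
#' `sample_id|n`.
#'
#' @param samples named list of reads (character vectors or dereplicated
#'   data frames).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sample_fasta <- function(samples, path) {
  seqs <- character(0)
  heads <- character(0)
  for (s in names(samples)) {
    d <- as_derep(samples[[s]])
    expanded <- rep(d$sequence, d$count)
    seqs <- c(seqs, expanded)
    heads <- c(heads, paste(s, seq_along(expanded), sep = "|"))
  }
  x <- Biostrings::BStringSet(seqs)
  names(x) <- heads
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Assign fecal reads to plant taxa
#'
#' A read is assigned to a reference taxon if and only if its sequence
#' exactly equals that taxon's reference sequence; taxa sharing a sequence
#' are credited as one merged taxon group.  Unassigned reads are tallied by
#' reason: `too_short` (shorter than `min_len`), `no_match` (no identical
#' reference sequence, including reads with non-nucleotide characters), and
#' `low_frequency` (assigned taxa whose within-sample read proportion falls
#' below `min_prop` are zeroed and their reads moved here).
#'
#' @param samples named list of per-sample reads: character vectors or
#'   dereplicated `data.frame(sequence, count)` as returned by
#'   [dereplicate_reads()].
#' @param db a `reference_db` (see [read_reference_db()]).
#' @param min_len minimum read length retained (default 20 nt).
#' @param min_prop minimum within-sample proportion, relative to the
#'   sample's total reads, for a taxon to be retained (default 0.001).
#' @return object of class `assignment_result`: list with `counts`
#'   (sample x taxon-group integer matrix), `unassigned` (sample x reason
#'   matrix with columns `no_match`, `too_short`, `low_frequency`) and
#'   `totals` (input reads per sample).  Conservation holds per sample:
#'   `rowSums(counts) + rowSums(unassigned) == totals`.
#' @export
assign_reads <- function(samples, db, min_len = 20L, min_prop = 0.001) {
  if (!inherits(db, "reference_db")) db <- as_reference_db(db)
  if (nrow(db) == 0L) stop("assign_reads: empty reference database")
  if (min_len < 1L) stop("assign_reads: min_len must be >= 1")
  if (min_prop < 0 || min_prop >= 1) stop("assign_reads: need 0 <= min_prop < 1")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("assign_reads: samples must be a named list")
  }
  groups <- sort(unique(db$group))
  seq2group <- setNames(db$group, db$sequence)

  counts <- matrix(0L, nrow = length(samples), ncol = length(groups),
                   dimnames = list(names(samples), groups))
  unassigned <- matrix(0L, nrow = length(samples), ncol = 3L,
                       dimnames = list(names(samples),
                                       c("no_match", "too_short",
                                         "low_frequency")))
  totals <- integer(length(samples))
  names(totals) <- names(samples)

  for (i in seq_along(samples)) {
    d <- as_derep(samples[[i]])
    total <- sum(d$count)
    totals[i] <- total
    if (total == 0L) next
    short <- nchar(d$sequence) < min_len
    unassigned[i, "too_short"] <- sum(d$count[short])
    d <- d[!short, , drop = FALSE]
    hit <- seq2group[d$sequence]
    unassigned[i, "no_match"] <- sum(d$count[is.na(hit)])
    if (any(!is.na(hit))) {
      agg <- tapply(d$count[!is.na(hit)], hit[!is.na(hit)], sum)
      counts[i, names(agg)] <- as.integer(agg)
    }
    ## low-frequency filter: proportion relative to the sample's total reads
    low <- counts[i, ] > 0L & counts[i, ] / total < min_prop
    if (any(low)) {
      unassigned[i, "low_frequency"] <- sum(counts[i, low])
      counts[i, low] <- 0L
    }
  }
  if (all(rowSums(counts) == 0L)) {
    warning("assign_reads: no read in any sample matched the reference database")
  }
  structure(list(counts = counts, unassigned = unassigned, totals = totals,
                 min_len = min_len, min_prop = min_prop),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  assigned <- sum(x$counts)
  total <- sum(x$totals)
  cat("Read assignment:", nrow(x$counts), "samples,",
      ncol(x$counts), "taxon groups\n")
  cat(sprintf("  assigned %d / %d reads (%.1f%%)\n", assigned, total,
              if (total > 0) 100 * assigned / total else 0))
  ua <- colSums(x$unassigned)
  cat("  unassigned:", paste(names(ua), ua, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample read proportions
#'
#' Divides each sample's taxon counts by its assigned-read total, the
#' relative read abundance used for all diet analyses.  Samples with zero
#' assigned reads are dropped with a warning.
#'
#' @param x an `assignment_result` or a sample x taxon count matrix.
#' @return matrix of proportions; rows sum to 1.
#' @export
read_proportions <- function(x) {
  counts <- if (inherits(x, "assignment_result")) x$counts else as.matrix(x)
  if (any(counts < 0)) stop("read_proportions: negative counts")
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning("read_proportions: dropping ", sum(tot == 0),
            " sample(s) with zero assigned reads: ",
            paste(rownames(counts)[tot == 0], collapse = ", "))
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(counts, 1, tot, "/")
}
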
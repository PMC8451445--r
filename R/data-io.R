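## Tabular readers and validators for the shared domain tables.
##
## All tables travel as plain data frames with fixed column names; every
## reader enforces the table's invariants so downstream stages can assume
## clean input.  Dialect: comma-separated, UTF-8, mandatory header row.

## The permitted coverage value set: trace cover is scored 1%, everything
## above 5% on a 5%-step grid.
COVERAGE_GRID <- c(1, seq(5, 100, by = 5))

norm_species <- function(x) {
  x <- trimws(as.character(x))
  gsub("[[:space:]]+", " ", x)
}

need_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "))
  }
}

#' Validate a plot-level coverage table
#'
#' A coverage table records the percent cover of each understory species in
#' each 2x2 m plot: trace occurrences (<5%) are scored 1%, everything else
#' on a 5%-step grid up to 100%.
#'
#' @param df data frame with columns `site`, `plot`, `species`, `coverage`.
#' @return the validated data frame (species names normalized).
#' @export
as_coverage_table <- function(df) {
  need_cols(df, c("site", "plot", "species", "coverage"), "coverage table")
  df$site <- as.character(df$site)
  df$species <- norm_species(df$species)
  df$plot <- as.integer(df$plot)
  df$coverage <- as.numeric(df$coverage)
  bad <- which(!(df$coverage %in% COVERAGE_GRID))
  if (length(bad) > 0L) {
    stop("coverage table: coverage value ", df$coverage[bad[1]],
         " at row ", bad[1],
         " not in the permitted set {1, 5, 10, ..., 100}")
  }
  if (any(is.na(df$plot)) || any(df$plot < 1L)) {
    stop("coverage table: plot ids must be positive integers")
  }
  if (any(df$plot > 20L)) {
    stop("coverage table: more than 20 plots per site are not supported")
  }
  key <- paste(df$site, df$plot, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("coverage table: duplicate record for site ", d$site,
         ", plot ", d$plot, ", species ", d$species)
  }
  ## canonical row order so parsing is independent of input order
  df <- df[order(df$site, df$plot, df$species), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a coverage table from CSV
#'
#' @param path path to a CSV file with columns `site`, `plot`, `species`,
#'   `coverage`.
#' @return validated coverage data frame (see [as_coverage_table()]).
#' @export
read_coverage_table <- function(path) {
  as_coverage_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a browsing-damage table
#'
#' Each row counts the sampled plant units (10 in the study design) of one
#' species at one site across the four damage classes: CL1 no damage, CL2
#' 1--10% of the plant damaged, CL3 11--50%, CL4 51--100%.
#'
#' @param df data frame with columns `site`, `species`, `n_cl1` .. `n_cl4`
#'   (an optional `n` column is checked against the class-count sum).
#' @return validated data frame with a recomputed `n` column.
#' @export
as_damage_table <- function(df) {
  cls <- paste0("n_cl", 1:4)
  need_cols(df, c("site", "species", cls), "damage table")
  df$site <- as.character(df$site)
  df$species <- norm_species(df$species)
  for (cl in cls) {
    df[[cl]] <- as.integer(df[[cl]])
    if (any(is.na(df[[cl]])) || any(df[[cl]] < 0L)) {
      stop("damage table: ", cl, " must be non-negative integers")
    }
  }
  total <- df$n_cl1 + df$n_cl2 + df$n_cl3 + df$n_cl4
  if (any(total < 1L)) {
    stop("damage table: every record needs at least one sampled unit (N >= 1)")
  }
  if ("n" %in% names(df) && any(as.integer(df$n) != total)) {
    stop("damage table: declared N does not equal the class-count sum")
  }
  df$n <- total
  key <- paste(df$site, df$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("damage table: duplicate record for site ", d$site,
         ", species ", d$species)
  }
  df <- df[order(df$site, df$species), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a browsing-damage table from CSV
#' @param path CSV path.
#' @return validated damage data frame (see [as_damage_table()]).
#' @export
read_damage_table <- function(path) {
  as_damage_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a site metadata table
#'
#' @param df data frame with columns `site`, `class` (establishment-year
#'   class label), `surveyed_year`, `x`, `y` (planar coordinates in km;
#'   geographic to planar projection is the caller's responsibility) and an
#'   optional `region`.
#' @return validated data frame.
#' @export
as_site_table <- function(df) {
  need_cols(df, c("site", "class", "x", "y"), "site table")
  df$site <- as.character(df$site)
  if (anyDuplicated(df$site)) {
    stop("site table: duplicate site id ", df$site[duplicated(df$site)][1])
  }
  df$class <- as.character(establishment_factor(df$class))
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("site table: coordinates must be finite")
  }
  if ("surveyed_year" %in% names(df)) {
    df$surveyed_year <- as.integer(df$surveyed_year)
  }
  rownames(df) <- NULL
  df
}

#' Read a site metadata table from CSV
#' @param path CSV path.
#' @return validated site data frame (see [as_site_table()]).
#' @export
read_site_table <- function(path) {
  as_site_table(read.csv(path, stringsAsFactors = FALSE))
}

LIFE_FORMS <- c("annual/biennial", "perennial", "vine", "tree", "shrub")
ARCHITECTURES <- c("prostrate", "erect", "rosette", "rosette_seasonal",
                   "tussock")

#' Validate a species-trait table
#'
#' Life form is one of annual/biennial, perennial, vine, tree, shrub.
#' Plant architecture (prostrate, erect, rosette, rosette_seasonal, tussock)
#' applies to forbs only; for woody species (tree, shrub) the architecture
#' category coincides with the life form, so the column must be `NA` there.
#'
#' @param df data frame with columns `species`, `family`, `life_form`,
#'   `architecture`.
#' @return validated data frame.
#' @export
as_trait_table <- function(df) {
  need_cols(df, c("species", "life_form"), "trait table")
  df$species <- norm_species(df$species)
  if (anyDuplicated(df$species)) {
    stop("trait table: duplicate species ",
         df$species[duplicated(df$species)][1])
  }
  bad <- setdiff(unique(df$life_form), LIFE_FORMS)
  if (length(bad) > 0L) {
    stop("trait table: unknown life form(s): ", paste(bad, collapse = ", "))
  }
  if (!"architecture" %in% names(df)) df$architecture <- NA_character_
  df$architecture[df$architecture %in% c("", "NA")] <- NA_character_
  bad <- setdiff(unique(df$architecture[!is.na(df$architecture)]),
                 ARCHITECTURES)
  if (length(bad) > 0L) {
    stop("trait table: unknown architecture(s): ", paste(bad, collapse = ", "))
  }
  woody <- df$life_form %in% c("tree", "shrub")
  if (any(woody & !is.na(df$architecture))) {
    stop("trait table: woody species must have NA architecture ",
         "(their architecture category equals the life form)")
  }
  if (any(!woody & is.na(df$architecture))) {
    warning("trait table: ", sum(!woody & is.na(df$architecture)),
            " non-woody species without an architecture category")
  }
  rownames(df) <- NULL
  df
}

#' Read a species-trait table from CSV
#' @param path CSV path.
#' @return validated trait data frame (see [as_trait_table()]).
#' @export
read_trait_table <- function(path) {
  as_trait_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a trnL P6-loop reference database from FASTA
#'
#' Headers follow the convention `taxon_id|family` (the family part is
#' optional).  Sequences are upper-cased and checked against the IUPAC
#' nucleotide alphabet actually used for the P6 loop (A, C, G, T, N).
#' Taxa sharing a byte-identical sequence cannot be told apart by the
#' marker and are linked into one `taxon_group`; read assignment later
#' credits such reads to the merged group.
#'
#' @param path FASTA file.
#' @return data frame of class `reference_db` with columns `taxon`,
#'   `family`, `sequence` and `group` (the merged taxon-group id; equals
#'   `taxon` when the sequence is unique).
#' @export
read_reference_db <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("reference database: empty FASTA file")
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  taxon <- norm_species(vapply(parts, `[`, "", 1L))
  family <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, "")
  sequence <- toupper(as.character(seqs))
  as_reference_db(data.frame(taxon = taxon, family = family,
                             sequence = sequence, stringsAsFactors = FALSE))
}

#' Build a reference database from a data frame
#'
#' @param df data frame with columns `taxon`, `sequence` and optionally
#'   `family`.
#' @return validated `reference_db` data frame (see [read_reference_db()]).
#' @export
as_reference_db <- function(df) {
  need_cols(df, c("taxon", "sequence"), "reference database")
  df$taxon <- norm_species(df$taxon)
  if (!"family" %in% names(df)) df$family <- NA_character_
  df$sequence <- toupper(as.character(df$sequence))
  if (any(nchar(df$sequence) == 0L)) {
    stop("reference database: empty sequence for taxon ",
         df$taxon[nchar(df$sequence) == 0L][1])
  }
  if (any(grepl("[^ACGTN]", df$sequence))) {
    stop("reference database: sequence with non-ACGTN characters for taxon ",
         df$taxon[grepl("[^ACGTN]", df$sequence)][1])
  }
  ## exact duplicate records collapse; same taxon with different sequences
  ## is a curation error we refuse to guess about
  df <- unique(df[, c("taxon", "family", "sequence")])
  if (anyDuplicated(df$taxon)) {
    stop("reference database: taxon ", df$taxon[duplicated(df$taxon)][1],
         " has conflicting sequences")
  }
  grp <- vapply(split(df$taxon, df$sequence),
                function(t) paste(sort(t), collapse = "|"), "")
  df$group <- unname(grp[df$sequence])
  df <- df[order(df$taxon), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("reference_db", "data.frame")
  df
}

#' Write a reference database to FASTA
#' @param db a `reference_db` data frame.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(db, path) {
  x <- Biostrings::BStringSet(db$sequence)
  names(x) <- ifelse(is.na(db$family), db$taxon,
                     paste(db$taxon, db$family, sep = "|"))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read a labelled numeric matrix as CSV
#'
#' Round-trip identity: integers are reproduced exactly, reals to at least
#' 12 significant digits.  Row names go into a leading `id` column.
#'
#' @param m numeric matrix with dimnames.
#' @param path CSV path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()`
#'   returns the matrix.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m)) stop("write_matrix: not a matrix")
  if (nrow(m) == 0L || ncol(m) == 0L) stop("write_matrix: empty matrix")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ## format() at 15 significant digits keeps doubles well past the 12-digit
  ## round-trip contract
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) {
    out <- format(col, digits = 15, scientific = TRUE, trim = TRUE)
    out[is.na(col)] <- NA
    out
  })
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("read_matrix: no 'id' column in ", path)
  rn <- as.character(df$id)
  df$id <- NULL
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}
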
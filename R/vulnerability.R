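## Integration of the three clusterings (coverage, damage, diet) plus the
## absent-where-established species list into six vulnerability groups:
##   A: browsed from the initial stage of deer establishment, coverage
##      lower where deer have been established longest;
##   B: browsed from the initial stage, coverage response unknown;
##   C: browsed mainly after the first decade, coverage lower where deer
##      have been established longest;
##   D: browsed later, coverage response unknown;
##   E: selected in the diet only (no visible damage), coverage unaffected;
##   F: visibly browsed, coverage unaffected.
## Cluster indices from K-means are arbitrary, so clusters are mapped to
## semantics by the shape of their centroid profile, never by index.

#' Semantic label of coverage cluster centroids
#'
#' A coverage cluster means "decline" when its centroid is lowest in the
#' oldest establishment class (Y1978) and that value falls at least
#' `margin` below the centroid's maximum -- the relative margin keeps a
#' flat centroid whose smallest coordinate lands on Y1978 by noise from
#' being read as a decline.
#'
#' @param centers cluster centroid matrix (clusters x 4, columns in
#'   establishment order `Y1978..Y2014`).
#' @param margin minimum relative drop of the Y1978 value below the
#'   centroid maximum (default 0.2).
#' @return character vector, `"decline"` or `"no_decline"` per cluster.
#' @export
coverage_semantics <- function(centers, margin = 0.2) {
  apply(as.matrix(centers), 1, function(v) {
    if (max(v) <= 0) return("no_decline")
    if (which.min(v) == 1L && v[1L] <= (1 - margin) * max(v)) "decline"
    else "no_decline"
  })
}

#' Semantic label of damage / diet cluster centroids
#'
#' Timing of browse selection read off the centroid profile (columns in
#' establishment order `Y1978..Y2014`):
#' * `"early"` -- the signal is already substantial (at least half the
#'   centroid maximum) in the youngest class `Y2014`, i.e. the species is
#'   selected from the initial stage of deer establishment;
#' * `"late"` -- the signal peaks in the oldest class `Y1978` and is weak
#'   in `Y2014`: selection builds up only after years of establishment;
#' * `"other"` -- mid-peaking profiles (e.g. highest at `Y2011`/`Y2003`);
#' * `"none"` -- all-zero centroid (no signal).
#'
#' @param centers cluster centroid matrix (clusters x 4).
#' @return character vector per cluster.
#' @export
timing_semantics <- function(centers) {
  apply(as.matrix(centers), 1, function(v) {
    if (max(v) <= 0) return("none")
    u <- v / max(v)
    if (u[4L] >= 0.5) "early"
    else if (which.max(u) == 1L) "late"
    else "other"
  })
}

#' Default vulnerability rule table
#'
#' The editable rule table consumed by [classify_vulnerability()].  Rules
#' are applied in order; the first match fires.  Columns: `rule` (id),
#' `coverage` (required coverage evidence: `decline`, `unknown`,
#' `no_decline` or `any`), `timing` (required selection timing: `early`,
#' `late` or `any`), `requires_damage` / `requires_dna` (`yes`, `no` or
#' `any` -- whether visible-damage / diet-DNA evidence must be present or
#' absent), and `group` (assigned group).  Mid-peaking ("other") timing is
#' routed with the late branch.  Species matching no rule stay
#' `unclassified`.
#'
#' @return the rule data frame.
#' @seealso [read_rule_table()], [write_rule_table()]
#' @export
default_rule_table <- function() {
  df <- read.csv(text = "
rule,coverage,timing,requires_damage,requires_dna,group
A,decline,early,any,any,A
B,unknown,early,any,any,B
C,decline,late,any,any,C
D,unknown,late,any,any,D
E,no_decline,any,no,yes,E
F,no_decline,any,yes,any,F
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

#' Read / write a vulnerability rule table
#'
#' Plain CSV with the columns of [default_rule_table()], so the integration
#' rule can be overridden without code changes.
#'
#' @param path CSV path.
#' @param rules rule data frame.
#' @return the rule data frame (`read_rule_table`) or `path` invisibly.
#' @export
read_rule_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need_cols(df, c("rule", "coverage", "timing", "requires_damage",
                  "requires_dna", "group"), "rule table")
  df
}

#' @rdname read_rule_table
#' @export
write_rule_table <- function(rules, path) {
  write.csv(rules, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Per-species semantic evidence from a clustering outcome.
cluster_evidence <- function(outcome, semantics_fun) {
  if (is.null(outcome)) return(character(0))
  sem <- semantics_fun(outcome$centers)
  setNames(unname(sem[outcome$labels]), names(outcome$labels))
}

#' Integrate the evidence streams into vulnerability groups
#'
#' Combines the coverage clustering, the damage (MDG) clustering, the diet
#' (read-profile) clustering, and the absent-where-established list
#' ([g4_species()]) into one group per species via the rule table.
#'
#' Evidence per species:
#' * coverage: `decline` / `no_decline` from its coverage cluster's
#'   centroid ([coverage_semantics()]); `unknown` when the species did not
#'   pass the coverage presence filter;
#' * timing: `early` if any stream (damage cluster, diet cluster, or G4
#'   membership) signals early selection; otherwise `late` if any stream
#'   signals late or mid-peaking selection; `none` otherwise
#'   ([timing_semantics()]);
#' * `damage_present`: MDG > 0 somewhere (damage cluster with non-zero
#'   centroid, or G4 membership, or listed in `damage_detected`);
#' * `dna_present`: detected in the diet clustering with a non-zero signal.
#'
#' The species universe is the union of the damage and diet evidence
#' streams (species in neither are excluded upstream).  Species matching no
#' rule are returned as `unclassified`, never dropped.
#'
#' @param coverage_outcome `bv_clustering` of coverage profiles, or `NULL`.
#' @param mdg_outcome `bv_clustering` of MDG profiles, or `NULL`.
#' @param dna_outcome `bv_clustering` of read profiles, or `NULL`.
#' @param g4 character vector from [g4_species()].
#' @param rule_table rule data frame (default [default_rule_table()]).
#' @param damage_detected optional character vector of additional species
#'   with browsing damage (MDG > 0) that did not enter the MDG clustering.
#' @return object of class `bv_vulnerability`: data frame with columns
#'   `species`, `group`, `coverage_evidence`, `timing`, `mdg_evidence`,
#'   `dna_evidence`, `g4`, `damage_present`, `dna_present`,
#'   `detected_in_both`, `rule`.
#' @export
classify_vulnerability <- function(coverage_outcome = NULL,
                                   mdg_outcome = NULL,
                                   dna_outcome = NULL,
                                   g4 = character(0),
                                   rule_table = default_rule_table(),
                                   damage_detected = character(0)) {
  cov_ev <- cluster_evidence(coverage_outcome, coverage_semantics)
  mdg_ev <- cluster_evidence(mdg_outcome, timing_semantics)
  dna_ev <- cluster_evidence(dna_outcome, timing_semantics)

  species <- sort(unique(c(names(mdg_ev), names(dna_ev), g4,
                           damage_detected)))
  if (length(species) == 0L) {
    out <- data.frame(species = character(0), group = character(0))
    class(out) <- c("bv_vulnerability", "data.frame")
    return(out)
  }

  ev <- function(map, sp, default) {
    v <- unname(map[sp])
    ifelse(is.na(v), default, v)
  }
  cov <- ev(cov_ev, species, "unknown")
  mdg_t <- ev(mdg_ev, species, "absent")
  dna_t <- ev(dna_ev, species, "absent")
  in_g4 <- species %in% g4

  timing <- ifelse(mdg_t == "early" | dna_t == "early" | in_g4, "early",
            ifelse(mdg_t %in% c("late", "other") |
                   dna_t %in% c("late", "other"), "late", "none"))
  damage_present <- (mdg_t %in% c("early", "late", "other")) | in_g4 |
    species %in% damage_detected
  dna_present <- dna_t %in% c("early", "late", "other")

  group <- rep("unclassified", length(species))
  rule_id <- rep(NA_character_, length(species))
  for (r in seq_len(nrow(rule_table))) {
    rr <- rule_table[r, ]
    hit <- group == "unclassified" &
      (rr$coverage == "any" | cov == rr$coverage) &
      (rr$timing == "any" | timing == rr$timing) &
      (rr$requires_damage == "any" |
         (rr$requires_damage == "yes") == damage_present) &
      (rr$requires_dna == "any" |
         (rr$requires_dna == "yes") == dna_present)
    group[hit] <- rr$group
    rule_id[hit] <- rr$rule
  }

  out <- data.frame(species = species, group = group,
                    coverage_evidence = cov, timing = timing,
                    mdg_evidence = mdg_t, dna_evidence = dna_t,
                    g4 = in_g4, damage_present = damage_present,
                    dna_present = dna_present,
                    detected_in_both = damage_present & dna_present,
                    rule = rule_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bv_vulnerability", "data.frame")
  out
}

#' @export
print.bv_vulnerability <- function(x, ...) {
  cat("Vulnerability classification:", nrow(x), "species\n")
  if (nrow(x) > 0L) {
    print(table(factor(x$group,
                       levels = c("A", "B", "C", "D", "E", "F",
                                  "unclassified"))))
  }
  invisible(x)
}

#' @export
summary.bv_vulnerability <- function(object, ...) {
  tab <- table(group = object$group, both = object$detected_in_both)
  print(tab)
  invisible(tab)
}

#' Overlap between the damage and diet evidence streams
#'
#' Flags species detected both in the browsing-damage survey and in the
#' DNA barcoding of feces.
#'
#' @param damage_species character vector (or `bv_clustering`) of species
#'   with damage evidence.
#' @param dna_species character vector (or `bv_clustering`) of taxa
#'   detected in feces.
#' @return data frame with `species`, `in_damage`, `in_dna`, `both`.
#' @export
detection_overlap <- function(damage_species, dna_species) {
  as_sp <- function(x) {
    if (inherits(x, "bv_clustering")) names(x$labels) else as.character(x)
  }
  damage_species <- as_sp(damage_species)
  dna_species <- as_sp(dna_species)
  species <- sort(unique(c(damage_species, dna_species)))
  data.frame(species = species,
             in_damage = species %in% damage_species,
             in_dna = species %in% dna_species,
             both = species %in% damage_species & species %in% dna_species,
             stringsAsFactors = FALSE)
}
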
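## End-to-end orchestration: ingest (or take a simulated study), assign
## reads, score damage, run the community statistics, cluster the three
## profile streams, and integrate them into the vulnerability groups.
## Stage seeds are derived deterministically from the pipeline seed, so one
## (inputs, seed) pair fixes every numeric output.

#' Read a study from a directory of input files
#'
#' Expects the layout written by [write_study()]: `sites.csv`,
#' `coverage.csv`, `damage.csv`, `traits.csv` (optional),
#' `reference_db.fasta`, `reads.fasta`.
#'
#' @param dir input directory.
#' @return list with the validated tables, reference database and
#'   per-sample reads, suitable for [run_pipeline()].
#' @export
read_study <- function(dir) {
  req <- c("sites.csv", "coverage.csv", "damage.csv", "reference_db.fasta",
           "reads.fasta")
  missing <- req[!file.exists(file.path(dir, req))]
  if (length(missing) > 0L) {
    stop("read_study: missing input file(s): ", paste(missing, collapse = ", "))
  }
  reads <- read_sample_fasta(file.path(dir, "reads.fasta"))
  ## sample -> site map: sample ids of the form <site>. or a sample_sites.csv
  ss_path <- file.path(dir, "sample_sites.csv")
  sample_sites <- if (file.exists(ss_path)) {
    ss <- read.csv(ss_path, stringsAsFactors = FALSE)
    setNames(ss$site, ss$sample)[names(reads)]
  } else NULL
  traits_path <- file.path(dir, "traits.csv")
  list(sites = read_site_table(file.path(dir, "sites.csv")),
       coverage = read_coverage_table(file.path(dir, "coverage.csv")),
       damage = read_damage_table(file.path(dir, "damage.csv")),
       traits = if (file.exists(traits_path)) read_trait_table(traits_path),
       ref_db = read_reference_db(file.path(dir, "reference_db.fasta")),
       reads = reads, sample_sites = sample_sites)
}

#' Run the full vulnerability analysis
#'
#' Pipeline stages: (1) assign fecal reads to taxa and form read
#' proportions; (2) compute the MDG matrix and the absent-where-established
#' (G4) species list; (3) vegetation statistics -- richness and Shannon GLM
#' likelihood-ratio tests against establishment class, site-level
#' Bray-Curtis PERMANOVA, dispersion, NMDS and the dbMEM spatial check;
#' (4) diet statistics -- PERMANOVA of read proportions with and without
#' site as permutation blocks, and NMDS; (5) gap-statistic K-means on the
#' three profile streams; (6) the rule-table classification.
#'
#' @param study a `sim_study` from [simulate_study()] or the list returned
#'   by [read_study()] (needs a `sample_sites` map when fecal samples are
#'   present).
#' @param seed integer pipeline seed (mandatory; stage seeds are derived
#'   from it).
#' @param n_perm permutations for all permutation tests (default 999).
#' @param kmax,b gap-statistic settings (default 6 and 50).
#' @param scale profile scaling before clustering (see [scale_profiles()]).
#' @param rule_table vulnerability rule table.
#' @param min_len,min_prop read-assignment thresholds (see
#'   [assign_reads()]).
#' @param strict_g4 strict reading of the G4 rule (see [g4_species()]).
#' @param ordination run NMDS stages (default `TRUE`).
#' @param spatial run dbMEM stages (default `TRUE`).
#' @param out_dir optional directory: per-stage CSV artifacts plus a
#'   markdown report are written there.
#' @return object of class `deer_vulnerability` with elements `assignment`,
#'   `proportions`, `mdg`, `g4`, `vegetation` (GLM/PERMANOVA/NMDS/dbMEM
#'   results), `diet`, `clusterings` (coverage/mdg/reads), `classification`
#'   and a flat `summary` list of the headline numbers.
#' @export
run_pipeline <- function(study, seed, n_perm = 999L, kmax = 6L, b = 50L,
                         scale = c("max", "raw", "z"),
                         rule_table = default_rule_table(),
                         min_len = 20L, min_prop = 0.001,
                         strict_g4 = FALSE,
                         ordination = TRUE, spatial = TRUE,
                         out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("run_pipeline: seed is required")
  scale <- match.arg(scale)
  for (el in c("sites", "coverage", "damage", "ref_db", "reads")) {
    if (is.null(study[[el]])) stop("run_pipeline: study lacks '", el, "'")
  }
  sites <- as_site_table(study$sites)
  site_class <- setNames(sites$class, sites$site)
  seed <- as.integer(seed)

  ## --- barcoding ----------------------------------------------------------
  assignment <- assign_reads(study$reads, study$ref_db,
                             min_len = min_len, min_prop = min_prop)
  props <- read_proportions(assignment)
  sample_sites <- study$sample_sites[rownames(props)]
  if (any(is.na(sample_sites))) {
    stop("run_pipeline: no site mapping for sample(s): ",
         paste(rownames(props)[is.na(sample_sites)], collapse = ", "))
  }

  ## --- damage -------------------------------------------------------------
  mdg_mat <- mdg_matrix(study$damage)
  g4 <- g4_species(study$coverage, mdg_mat, sites, strict = strict_g4)
  ## the damage analyses cover species with detected browsing only;
  ## surveyed-but-undamaged species carry no damage evidence
  damage_detected <- rownames(mdg_mat)[apply(mdg_mat > 0, 1, any,
                                             na.rm = TRUE)]

  ## --- vegetation statistics ----------------------------------------------
  m_site <- site_matrix(study$coverage)
  cls_sites <- establishment_factor(site_class[rownames(m_site)])
  rich <- richness(study$coverage)
  shan <- shannon(study$coverage)
  veg <- list(
    richness_lrt = glm_lrt(rich, cls_sites, family = "poisson"),
    shannon_lrt = glm_lrt(shan, cls_sites, family = "gaussian"),
    permanova = permanova(bray_curtis(m_site), cls_sites,
                          n_perm = n_perm, seed = seed + 11L),
    permdisp = permdisp(bray_curtis(m_site), cls_sites,
                        n_perm = n_perm, seed = seed + 12L))
  if (ordination) {
    veg$nmds <- nmds(bray_curtis(m_site), seed = seed + 13L)
  }
  if (spatial) {
    coords <- sites[match(rownames(m_site), sites$site), c("x", "y")]
    veg$dbmem <- dbmem(coords)
    veg$dbmem_test <- dbmem_test(veg$dbmem, m_site, coords = coords,
                                 n_perm = n_perm, seed = seed + 14L)
  }

  ## --- diet statistics ------------------------------------------------------
  cls_samples <- establishment_factor(site_class[sample_sites])
  d_diet <- bray_curtis(props)
  diet <- list(
    permanova = permanova(d_diet, cls_samples, n_perm = n_perm,
                          seed = seed + 21L),
    permanova_blocked = permanova(d_diet, cls_samples,
                                  strata = sample_sites,
                                  n_perm = n_perm, seed = seed + 22L))
  if (ordination) diet$nmds <- nmds(d_diet, seed = seed + 23L)

  ## --- profile clustering ---------------------------------------------------
  prof_cov <- build_profiles(study$coverage, sites, source = "coverage")
  prof_mdg <- build_profiles(mdg_mat[rownames(mdg_mat) %in% damage_detected,
                                     , drop = FALSE],
                             sites, source = "mdg")
  ## diet analyses cover detected taxa only (columns with at least one read)
  detected_taxa <- colnames(props)[colSums(props) > 0]
  prof_dna <- build_profiles(props[, detected_taxa, drop = FALSE], sites,
                             source = "reads", sample_sites = sample_sites)
  clusterings <- list(
    coverage = cluster_profiles(prof_cov, kmax = kmax, b = b,
                                seed = seed + 31L, scale = scale),
    mdg = cluster_profiles(prof_mdg, kmax = kmax, b = b,
                           seed = seed + 32L, scale = scale),
    reads = cluster_profiles(prof_dna, kmax = kmax, b = b,
                             seed = seed + 33L, scale = scale))

  ## --- integration ----------------------------------------------------------
  classification <- classify_vulnerability(
    coverage_outcome = clusterings$coverage,
    mdg_outcome = clusterings$mdg,
    dna_outcome = clusterings$reads,
    g4 = g4, rule_table = rule_table,
    damage_detected = intersect(damage_detected,
                                c(names(clusterings$reads$labels), g4,
                                  names(clusterings$mdg$labels))))

  group_sizes <- table(factor(classification$group,
                              levels = c("A", "B", "C", "D", "E", "F",
                                         "unclassified")))
  summary <- list(
    n_sites = nrow(sites),
    n_species_vegetation = ncol(m_site),
    n_taxa_detected = sum(colSums(assignment$counts) > 0),
    reads_total = sum(assignment$totals),
    reads_assigned = sum(assignment$counts),
    richness_chi2 = veg$richness_lrt$chi2,
    shannon_chi2 = veg$shannon_lrt$chi2,
    vegetation_permanova_r2 = veg$permanova$r2,
    vegetation_permanova_p = veg$permanova$p_value,
    diet_permanova_r2 = diet$permanova$r2,
    diet_permanova_p = diet$permanova$p_value,
    diet_permanova_blocked_p = diet$permanova_blocked$p_value,
    chosen_k_coverage = clusterings$coverage$chosen_k,
    chosen_k_mdg = clusterings$mdg$chosen_k,
    chosen_k_reads = clusterings$reads$chosen_k,
    n_g4 = length(g4),
    group_sizes = as.list(setNames(as.integer(group_sizes),
                                   names(group_sizes))))
  if (ordination) {
    summary$vegetation_nmds_stress <- veg$nmds$stress
    summary$diet_nmds_stress <- diet$nmds$stress
  }

  out <- structure(list(assignment = assignment, proportions = props,
                        mdg = mdg_mat, g4 = g4, vegetation = veg,
                        diet = diet, profiles = list(coverage = prof_cov,
                                                     mdg = prof_mdg,
                                                     reads = prof_dna),
                        clusterings = clusterings,
                        classification = classification,
                        summary = summary, seed = seed),
                   class = "deer_vulnerability")
  if (!is.null(out_dir)) write_artifacts(out, out_dir)
  out
}

#' @export
print.deer_vulnerability <- function(x, ...) {
  s <- x$summary
  cat("Deer-browsing vulnerability analysis (seed", x$seed, ")\n")
  cat(sprintf("  vegetation: %d species, PERMANOVA R2 = %.3f (p = %.3g), richness chi2 = %.2f\n",
              s$n_species_vegetation, s$vegetation_permanova_r2,
              s$vegetation_permanova_p, s$richness_chi2))
  cat(sprintf("  diet: %d taxa from %d/%d reads, PERMANOVA R2 = %.3f (p = %.3g; blocked p = %.3g)\n",
              s$n_taxa_detected, s$reads_assigned, s$reads_total,
              s$diet_permanova_r2, s$diet_permanova_p,
              s$diet_permanova_blocked_p))
  cat(sprintf("  clusters chosen (coverage/MDG/reads): %d / %d / %d;  G4 species: %d\n",
              s$chosen_k_coverage, s$chosen_k_mdg, s$chosen_k_reads, s$n_g4))
  cat("  vulnerability groups:",
      paste(names(s$group_sizes), unlist(s$group_sizes), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.deer_vulnerability <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (src in names(x$clusterings)) {
    plot(x$clusterings[[src]], main = sprintf("%s profiles (k = %d)", src,
                                              x$clusterings[[src]]$chosen_k))
  }
  invisible(x)
}

#' @export
summary.deer_vulnerability <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$classification)
  invisible(object$summary)
}

#' Markdown report of a vulnerability analysis
#'
#' Tabulates the group membership with its evidence, one row per species,
#' plus the headline statistics.
#'
#' @param x a `deer_vulnerability` object.
#' @param path optional file to write the report to.
#' @return character vector of markdown lines, invisibly when `path` is
#'   given.
#' @export
report <- function(x, path = NULL) {
  stopifnot(inherits(x, "deer_vulnerability"))
  s <- x$summary
  cl <- x$classification
  lines <- c(
    "# Plant vulnerability to deer browsing",
    "",
    sprintf("- Sites: %d; vegetation species: %d; diet taxa: %d",
            s$n_sites, s$n_species_vegetation, s$n_taxa_detected),
    sprintf("- Vegetation composition PERMANOVA: R2 = %.3f, p = %.3g",
            s$vegetation_permanova_r2, s$vegetation_permanova_p),
    sprintf("- Diet composition PERMANOVA: R2 = %.3f, p = %.3g (site-blocked p = %.3g)",
            s$diet_permanova_r2, s$diet_permanova_p,
            s$diet_permanova_blocked_p),
    sprintf("- Clusters chosen (coverage / MDG / reads): %d / %d / %d",
            s$chosen_k_coverage, s$chosen_k_mdg, s$chosen_k_reads),
    "")
  if (nrow(cl) == 0L) {
    lines <- c(lines, "No species classified.")
  } else {
    lines <- c(lines,
               "| Species | Group | Coverage | Timing | Damage | DNA | Both |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %s | %s | %s | %s |",
                       cl$species, cl$group, cl$coverage_evidence, cl$timing,
                       cl$mdg_evidence, cl$dna_evidence,
                       ifelse(cl$detected_in_both, "yes", "no")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

## Per-stage CSV artifacts plus the markdown report (write-once outputs).
write_artifacts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(x$assignment$counts, file.path(dir, "read_counts.csv"))
  write_matrix(x$proportions, file.path(dir, "read_proportions.csv"))
  write_matrix(x$mdg, file.path(dir, "mdg_matrix.csv"))
  for (src in names(x$profiles)) {
    write_matrix(x$profiles[[src]],
                 file.path(dir, paste0("profiles_", src, ".csv")))
  }
  write.csv(as.data.frame(x$classification),
            file.path(dir, "classification.csv"), row.names = FALSE)
  report(x, file.path(dir, "report.md"))
  ## flat machine-readable summary
  s <- x$summary
  flat <- c(s[names(s) != "group_sizes"],
            setNames(s$group_sizes, paste0("n_group_", names(s$group_sizes))))
  write.csv(data.frame(quantity = names(flat),
                       value = unlist(flat, use.names = FALSE)),
            file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Recovery of planted archetypes by the pipeline
#'
#' Compares a classification against a synthetic study's ground truth:
#' a species counts as recovered when its assigned group equals its planted
#' archetype (`neutral` species are excluded -- they carry no browsing
#' evidence and are excluded upstream by design).
#'
#' @param classification `bv_vulnerability` data frame.
#' @param truth ground-truth data frame with `species` and `archetype`.
#' @return list with `n`, `n_recovered`, `rate` and the merged table.
#' @export
archetype_recovery <- function(classification, truth) {
  truth <- truth[truth$archetype %in% c("A", "B", "C", "D", "E", "F"), ]
  merged <- merge(truth[, c("species", "archetype")],
                  as.data.frame(classification)[, c("species", "group")],
                  by = "species", all.x = TRUE)
  merged$group[is.na(merged$group)] <- "unclassified"
  list(n = nrow(merged),
       n_recovered = sum(merged$group == merged$archetype),
       rate = mean(merged$group == merged$archetype),
       table = merged)
}
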
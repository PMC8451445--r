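## Synthetic-study generator.  Emulates the field design: 22 sites in four
## deer establishment-year classes (5/4/4/9), 20 understory plots per site
## on the 1%/5%-step coverage grid, 10-unit damage samples per species and
## site, and 63 fecal samples (spread over 16 sites) of trnL P6-loop reads
## with negative-binomial depth.  Species are planted as vulnerability
## archetypes A-F plus neutral, so the pipeline's output can be checked
## against known truth:
##   A  early-selected, coverage declining with establishment age;
##   B  early-selected, eliminated from the oldest (Y1978) sites, so its
##      coverage response is unknowable (feeds the G4 list);
##   C  late-selected, coverage declining;
##   D  late-selected, absent from the Y2003 sites (coverage unknown,
##      without triggering the G4 rule);
##   E  diet-detected only, never visibly damaged, coverage flat;
##   F  visibly browsed at a moderate level everywhere, never amplified in
##      the fecal DNA (PCR dropout), coverage flat;
##   neutral  no browsing evidence at all (excluded upstream).

#' Configuration of a synthetic browsing study
#'
#' Defaults mirror the study design the generator emulates; effect sizes
#' (availability decline, palatability shifts, diet selection weights) are
#' chosen so planted archetypes are recoverable but noisy at realistic
#' sample sizes.
#'
#' @param n_sites_per_class sites per establishment class, oldest first
#'   (default `c(5, 4, 4, 9)`, 22 sites).
#' @param n_plots understory plots per site (default 20).
#' @param archetype_counts named integer vector of species counts per
#'   archetype (`A`, `B`, `C`, `D`, `E`, `F`, `neutral`).
#' @param damage_n plant units sampled per species and site (default 10).
#' @param n_fecal_samples total fecal samples (default 63).
#' @param n_fecal_sites number of sites with feces (default 16; all sites
#'   of the three older classes plus the first Y2014 sites).
#' @param depth_mean,depth_dispersion negative-binomial read depth per
#'   sample (default mean 6700, dispersion 2).
#' @param junk_read_rate fraction of short junk reads per sample
#'   (default 0.02), exercising the `too_short` route.
#' @param base_occupancy per-plot occupancy probability of a fully
#'   available species (default 0.25).
#' @param base_cover median percent cover of an occupied plot before
#'   grid-snapping (default 20).
#' @param cover_sd_log lognormal sd of plot cover (default 0.5).
#' @param decline_mult availability multiplier per class (oldest first) for
#'   declining archetypes (default `c(0.15, 0.4, 0.7, 1)`).
#' @param thresholds ordinal-logit cutpoints of the damage-class model;
#'   the defaults give a neutral species (linear predictor 0) an expected
#'   MDG of about 6.
#' @param dirichlet_conc total Dirichlet concentration of per-sample diet
#'   composition (default 30; smaller = noisier samples).
#' @param zero_effects if `TRUE`, every species behaves identically in
#'   every class (availability 1, common palatability, equal diet weights):
#'   a permutation-null dataset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites_per_class = c(5L, 4L, 4L, 9L),
                       n_plots = 20L,
                       archetype_counts = c(A = 8L, B = 6L, C = 8L, D = 6L,
                                            E = 5L, F = 5L, neutral = 22L),
                       damage_n = 10L,
                       n_fecal_samples = 63L,
                       n_fecal_sites = 16L,
                       depth_mean = 6700,
                       depth_dispersion = 2,
                       junk_read_rate = 0.02,
                       base_occupancy = 0.25,
                       base_cover = 20,
                       cover_sd_log = 0.5,
                       decline_mult = c(0.15, 0.4, 0.7, 1),
                       thresholds = c(1, 2, 3.5),
                       dirichlet_conc = 30,
                       zero_effects = FALSE) {
  cfg <- as.list(environment())
  if (any(n_sites_per_class < 1L) || length(n_sites_per_class) != 4L) {
    stop("sim_config: need at least one site in each of the four classes")
  }
  if (sum(archetype_counts) < 1L) stop("sim_config: zero species")
  bad <- setdiff(names(archetype_counts),
                 c("A", "B", "C", "D", "E", "F", "neutral"))
  if (length(bad) > 0L) stop("sim_config: unknown archetype(s): ",
                             paste(bad, collapse = ", "))
  if (junk_read_rate < 0 || junk_read_rate >= 1) {
    stop("sim_config: junk_read_rate must be in [0, 1)")
  }
  class(cfg) <- "sim_config"
  cfg
}

## Archetype parameter tables: one row per archetype, columns = classes
## oldest (Y1978) first.
archetype_params <- function(cfg) {
  dm <- cfg$decline_mult
  flat <- rep(1, 4)
  avail <- rbind(A = dm, B = c(0, 1, 1, 1), C = dm, D = c(1, 0, 1, 1),
                 E = flat, F = flat, neutral = flat)
  ## ordinal-logit linear predictor of visible damage
  eta <- rbind(A = c(4, 3, 3, 3), B = c(-Inf, 3, 3, 3),
               C = c(3, 2.5, 0.5, -2), D = c(3, -Inf, 0.5, -2),
               E = rep(-Inf, 4), F = rep(2, 4), neutral = rep(-Inf, 4))
  ## diet selection weight (multiplied by availability)
  wt <- rbind(A = flat, B = flat, C = c(1, 0.8, 0.3, 0.05),
              D = c(1, 0.8, 0.3, 0.05), E = rep(0.8, 4),
              F = rep(0, 4), neutral = rep(0, 4))
  if (isTRUE(cfg$zero_effects)) {
    avail[] <- 1
    eta[] <- 1
    wt[] <- 1
  }
  colnames(avail) <- colnames(eta) <- colnames(wt) <- CLASS_LABELS
  list(avail = avail, eta = eta, wt = wt)
}

## Snap a raw percent cover onto the survey grid: trace (< 3) scores 1%,
## everything else to the nearest 5% step in [5, 100].
snap_cover <- function(x) {
  out <- pmin(100, pmax(5, round(x / 5) * 5))
  out[x < 3] <- 1
  out
}

random_p6_sequences <- function(n) {
  repeat {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(40:90, 1), replace = TRUE),
            collapse = "")
    }, "")
    if (!anyDuplicated(seqs)) return(seqs)
  }
}

#' Simulate a complete synthetic browsing study
#'
#' Draws all pipeline inputs from a [sim_config()]: site metadata with a
#' class-longitude gradient on a 300 x 200 km box, plot-level coverage
#' (Bernoulli occupancy x lognormal magnitude snapped to the survey grid),
#' damage-class counts from an ordinal-logit palatability model, a
#' reference database of unique P6-loop-like sequences, and per-sample
#' fecal reads (Dirichlet-multinomial composition with concentration
#' proportional to selection weight x availability, negative-binomial
#' depth, plus a small fraction of short junk reads).  Fully reproducible
#' given the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory).
#' @return list of class `sim_study` with elements `sites`, `coverage`,
#'   `damage`, `traits`, `ref_db`, `reads` (named list of dereplicated
#'   per-sample reads), `sample_sites` (sample to site map), `depths`
#'   (planted reads per sample) and `truth` (archetype per species plus
#'   the planted availability/palatability/diet-weight matrices).
#' @export
simulate_study <- function(config = sim_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("simulate_study: seed is required")
  if (!inherits(config, "sim_config")) stop("simulate_study: invalid config")
  par <- archetype_params(config)

  with_seed(seed, {
    ## --- sites -----------------------------------------------------------
    n_sites <- sum(config$n_sites_per_class)
    cls <- rep(CLASS_LABELS, config$n_sites_per_class)
    sites <- data.frame(
      site = sprintf("S%02d", seq_len(n_sites)),
      class = cls,
      surveyed_year = sample(c(2016L, 2017L), n_sites, replace = TRUE),
      ## longitude gradient by class age: the spatial-confounding structure
      ## of a range-expansion chronosequence
      x = (match(cls, CLASS_LABELS) - 1) * 75 + runif(n_sites, 0, 75),
      y = runif(n_sites, 0, 200),
      stringsAsFactors = FALSE)

    ## --- species ---------------------------------------------------------
    counts <- config$archetype_counts
    arch <- rep(names(counts), counts)
    n_sp <- length(arch)
    species <- sprintf("sp%03d", seq_len(n_sp))
    truth <- data.frame(species = species, archetype = arch,
                        stringsAsFactors = FALSE)

    life_form <- sample(LIFE_FORMS, n_sp, replace = TRUE)
    woody <- life_form %in% c("tree", "shrub")
    architecture <- ifelse(woody, NA_character_,
                           sample(ARCHITECTURES, n_sp, replace = TRUE))
    traits <- data.frame(species = species,
                         family = sprintf("fam%02d", 1L + (seq_len(n_sp) %% 12L)),
                         life_form = life_form, architecture = architecture,
                         stringsAsFactors = FALSE)

    avail <- par$avail[arch, , drop = FALSE]   # species x class
    eta <- par$eta[arch, , drop = FALSE]
    wt <- par$wt[arch, , drop = FALSE]
    rownames(avail) <- rownames(eta) <- rownames(wt) <- species

    ## --- plot-level coverage ---------------------------------------------
    cov_rows <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      mult <- avail[, sites$class[i]]
      p_occ <- pmin(1, config$base_occupancy * mult)
      occ <- matrix(rbinom(config$n_plots * n_sp, 1L,
                           rep(p_occ, each = config$n_plots)),
                    nrow = config$n_plots)
      idx <- which(occ == 1L, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      raw <- config$base_cover * mult[idx[, 2L]] *
        exp(rnorm(nrow(idx), 0, config$cover_sd_log))
      cov_rows[[i]] <- data.frame(site = sites$site[i], plot = idx[, 1L],
                                  species = species[idx[, 2L]],
                                  coverage = snap_cover(raw),
                                  stringsAsFactors = FALSE)
    }
    coverage <- as_coverage_table(do.call(rbind, cov_rows))

    ## --- browsing damage ---------------------------------------------------
    ## a species is surveyed for damage at every site where the vegetation
    ## survey found it
    present <- unique(coverage[, c("site", "species")])
    t1 <- config$thresholds
    dmg <- present
    probs <- function(e) {
      c1 <- plogis(t1[1] - e); c2 <- plogis(t1[2] - e); c3 <- plogis(t1[3] - e)
      c(c1, c2 - c1, c3 - c2, 1 - c3)
    }
    cls_of_site <- setNames(sites$class, sites$site)
    cl_counts <- t(vapply(seq_len(nrow(dmg)), function(r) {
      e <- eta[dmg$species[r], cls_of_site[dmg$site[r]]]
      as.integer(rmultinom(1L, config$damage_n, probs(e)))
    }, integer(4L)))
    dmg$n_cl1 <- cl_counts[, 1L]; dmg$n_cl2 <- cl_counts[, 2L]
    dmg$n_cl3 <- cl_counts[, 3L]; dmg$n_cl4 <- cl_counts[, 4L]
    damage <- as_damage_table(dmg)

    ## --- reference database ------------------------------------------------
    ref_db <- as_reference_db(data.frame(taxon = species,
                                         family = traits$family,
                                         sequence = random_p6_sequences(n_sp),
                                         stringsAsFactors = FALSE))

    ## --- fecal reads -------------------------------------------------------
    fecal_sites <- head(sites$site, config$n_fecal_sites)
    samp_sites <- rep(fecal_sites,
                      length.out = config$n_fecal_samples)
    samp_sites <- sort(samp_sites)
    samp_ids <- sprintf("F%02d", seq_len(config$n_fecal_samples))
    taxon_seq <- setNames(ref_db$sequence[match(species, ref_db$taxon)],
                          species)

    depths <- pmax(100L, rnbinom(config$n_fecal_samples,
                                 mu = config$depth_mean,
                                 size = config$depth_dispersion))
    reads <- vector("list", config$n_fecal_samples)
    names(reads) <- samp_ids
    for (i in seq_len(config$n_fecal_samples)) {
      cl <- cls_of_site[samp_sites[i]]
      w <- wt[, cl] * avail[, cl]
      keep <- which(w > 0)
      n_junk <- as.integer(round(config$junk_read_rate * depths[i]))
      n_assignable <- depths[i] - n_junk
      alpha <- config$dirichlet_conc * w[keep] / sum(w[keep])
      g <- rgamma(length(alpha), shape = alpha)
      if (sum(g) == 0) g[] <- 1
      cnt <- as.integer(rmultinom(1L, n_assignable, g / sum(g)))
      d <- data.frame(sequence = unname(taxon_seq[names(keep)]), count = cnt,
                      stringsAsFactors = FALSE)
      if (n_junk > 0L) {
        junk <- vapply(seq_len(n_junk), function(j) {
          paste(sample(c("A", "C", "G", "T"), sample(8:15, 1),
                       replace = TRUE), collapse = "")
        }, "")
        d <- rbind(d, data.frame(sequence = junk, count = 1L,
                                 stringsAsFactors = FALSE))
      }
      d <- d[d$count > 0L, , drop = FALSE]
      d <- stats::aggregate(count ~ sequence, d, sum)
      reads[[i]] <- d[order(-d$count, d$sequence), , drop = FALSE]
    }

    truth$availability <- I(lapply(seq_len(n_sp), function(i) avail[i, ]))
    structure(list(sites = as_site_table(sites), coverage = coverage,
                   damage = damage, traits = as_trait_table(traits),
                   ref_db = ref_db, reads = reads,
                   sample_sites = setNames(samp_sites, samp_ids),
                   depths = setNames(as.integer(depths), samp_ids),
                   truth = truth, availability = avail, palatability = eta,
                   diet_weight = wt, config = config, seed = seed),
              class = "sim_study")
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic browsing study (seed", x$seed, ")\n")
  cat("  sites:", nrow(x$sites), "in classes",
      paste(table(establishment_factor(x$sites$class)), collapse = "/"), "\n")
  cat("  species:", nrow(x$truth), "(",
      paste(names(table(x$truth$archetype)),
            table(x$truth$archetype), sep = "=", collapse = ", "), ")\n")
  cat("  coverage records:", nrow(x$coverage),
      "; damage records:", nrow(x$damage), "\n")
  cat("  fecal samples:", length(x$reads), "totalling", sum(x$depths),
      "reads\n")
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Emits `sites.csv`, `coverage.csv`, `damage.csv`, `traits.csv`,
#' `ground_truth.csv`, `reference_db.fasta` and `reads.fasta` (one record
#' per read, headers `sample|n`).
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(study$coverage, file.path(dir, "coverage.csv"), row.names = FALSE)
  write.csv(study$damage, file.path(dir, "damage.csv"), row.names = FALSE)
  write.csv(study$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(study$truth[, c("species", "archetype")],
            file.path(dir, "ground_truth.csv"), row.names = FALSE)
  write_reference_db(study$ref_db, file.path(dir, "reference_db.fasta"))
  write_sample_fasta(study$reads, file.path(dir, "reads.fasta"))
  invisible(dir)
}

#' Miniature synthetic study for examples and tests
#'
#' Four sites (one per establishment class), 12 species covering every
#' archetype, 8 fecal samples with small read depth; generates in well
#' under a second.
#'
#' @param seed integer seed (default 42).
#' @return a `sim_study`.
#' @export
fixture_small <- function(seed = 42L) {
  cfg <- sim_config(n_sites_per_class = c(1L, 1L, 1L, 1L),
                    archetype_counts = c(A = 2L, B = 2L, C = 2L, D = 2L,
                                         E = 1L, F = 1L, neutral = 2L),
                    n_fecal_samples = 8L, n_fecal_sites = 4L,
                    depth_mean = 500, depth_dispersion = 5)
  simulate_study(cfg, seed = seed)
}
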
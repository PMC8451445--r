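# deervuln

Assessing understory plant vulnerability to sika deer (*Cervus nippon*)
browsing across forests that differ in how long deer have been established.

## The problem

When deer colonize a forest, they do not strip the understory at random:
some plants are selected from the first years of establishment and collapse
within a decade, others are ignored until preferred forage is gone, and
others are browsed without ever losing ground.  Telling these apart needs
three complementary evidence streams, collected across a chronosequence of
deer *establishment-year classes* (deer present since before 1978, since
1979–2003, 2004–2011, or 2012–2014):

1. **Vegetation surveys** — percent cover of every understory species in
   20 plots per site (trace cover scored 1%, otherwise 5% steps);
2. **Browsing-damage surveys** — for each species at each site, 10 plant
   units scored into four damage classes, summarized as the
   **mean damage grade**

   `MDG = (0·CL1 + 5·CL2 + 30·CL3 + 75·CL4) / N`,

   where CL1 is no damage and CL4 is 51–100% of the plant damaged
   (MDG ranges 0–75);
3. **Diet DNA metabarcoding** — trnL P6-loop amplicons from deer fecal
   pellets, assigned to plant taxa by exact match against a reference
   database and summarized as per-sample relative read abundances.

For each stream the package builds one 4-vector per species (its class-wise
mean coverage, MDG, or read proportion), clusters those profiles with
K-means — choosing the number of clusters by the gap statistic — reads each
cluster's meaning off its centroid shape (coverage *decline* vs *no
decline*; browse selection *early* vs *late*), and integrates the streams
through an editable rule table into six vulnerability groups:

| Group | Selection timing | Coverage response |
|---|---|---|
| A | early (from initial establishment) | declines with establishment age |
| B | early | unknown (absent where deer are oldest) |
| C | late (after the first decade) | declines |
| D | late | unknown |
| E | diet evidence only, no visible damage | no difference |
| F | visible damage only | no difference |

Around this core, the package provides the community statistics these
studies rely on: species richness and Shannon diversity with Poisson /
Gaussian GLM likelihood-ratio tests, Bray–Curtis PERMANOVA with seeded and
optionally site-blocked (strata-restricted) permutations, multivariate
dispersion tests, NMDS ordination, and dbMEM spatial eigenvector checks.
A synthetic-study generator plants known vulnerability archetypes so the
entire pipeline can be exercised and validated without field data.

## Worked example

```r
library(deervuln)

study <- simulate_study(sim_config(), seed = 42)
study
#> Synthetic browsing study (seed 42 )
#>   sites: 22 in classes 5/4/4/9
#>   species: 60 ( A=8, B=6, C=8, D=6, E=5, F=5, neutral=22 )
#>   coverage records: 5707 ; damage records: 1223
#>   fecal samples: 63 totalling 440736 reads

result <- run_pipeline(study, seed = 1, n_perm = 999, b = 50)
result
#> Deer-browsing vulnerability analysis (seed 1 )
#>   vegetation: 60 species, PERMANOVA R2 = 0.508 (p = 0.001), richness chi2 = 10.53
#>   diet: 33 taxa from 431530/440736 reads, PERMANOVA R2 = 0.442 (p = 0.001; blocked p = 1)
#>   clusters chosen (coverage/MDG/reads): 2 / 3 / 6;  G4 species: 6
#>   vulnerability groups: A=8, B=6, C=8, D=6, E=5, F=5, unclassified=0
```

Reading the output: understory composition differs strongly among
establishment classes (R² = 0.508); diet composition also differs
(R² = 0.442), but once permutations are restricted to within-site blocks the
class effect is untestable (p = 1) because establishment class is constant
within a site — diet varies mostly among sites, exactly the behaviour such
block designs are meant to expose.  The gap statistic chose 2 coverage
clusters (decline vs no decline), 3 damage clusters and 6 diet clusters, and
every planted archetype was recovered in its own group.

Per-species evidence travels with each assignment:

```r
head(as.data.frame(result$classification)[,
  c("species", "group", "coverage_evidence", "timing", "rule")], 3)
#>  species group coverage_evidence timing rule
#>    sp001     A           decline  early    A
#>    sp002     A           decline  early    A
#>    sp003     A           decline  early    A
```

Individual pieces are exported too, e.g. `mdg(2, 3, 4, 1)` returns `21`
(= (0 + 15 + 120 + 75)/10), `permanova()`, `nmds()`, `gap_statistic()`,
`assign_reads()`, `g4_species()`, and `report(result)` renders a markdown
table of the classification.  `write_study()` / `read_study()` round-trip a
study through the CSV/FASTA formats the pipeline ingests.

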
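# driftwood

Source assignment and founder-effect analysis for dominant-marker island
colonization data.

Every plant on an oceanic island is descended from long-distance dispersers,
and the founding bottleneck leaves a measurable genetic signature.
`driftwood` is for population geneticists and biogeographers working with
dominant markers (AFLP-style band presence/absence scores) on recipient
islands and their candidate mainland sources. It provides:

- **Source assignment.** Multilocus allocation of island individuals to
  candidate source regions under the dominant-marker Bernoulli model: the
  log10 likelihood of a phenotype in group *g* is
  `sum_{x_l=1} log10(f_gl) + sum_{x_l=0} log10(1 - f_gl)` over non-missing
  loci, with zero-replacement smoothing of band frequencies
  (`0 -> 1/(n+1)`, `1 -> n/(n+1)`). An individual is allocated only when the
  best source beats the runner-up by the minimum log-likelihood difference
  (default `mld = 1`, a tenfold likelihood ratio); otherwise it stays
  unassigned.
- **Six founder-effect measures** per species × island, relative to the
  inferred main source region: the minimum number of colonizing propagules
  (an exact/greedy set cover of the island's markers by source genotypes),
  population and regional diversity ratios from mean pairwise band
  differences, the marker proportion, and the minimum and assignment-based
  source-region counts — plus private markers and a glacial-survival screen
  (high relative diversity *and* private markers required).
- **Floristics.** Island–source floristic similarity bracketed over
  pessimistic/optimistic resolutions of uncertain occurrences, strict
  endemic counts, and colonization intervals `T/(S·q)` (years per species
  establishment) and `T/(S·q·P)` (years per propagule arrival).
- **A forward simulator** of regionally structured band data
  (Balding–Nichols regional allele frequencies, dominance
  `p = 1-(1-q)^2`, founder sampling, optional Wright–Fisher drift) with
  recorded ground truth, used throughout the tests.

## Worked example

Simulate a three-region scenario with a known source, assign the island
sample, and build the founder-effect report:

```r
library(driftwood)

sim <- simulate_colonization(scenario_config(seed = 11))
asg <- assign_sources(sim$dataset, island = "island")
summary(asg)
#> Assignment summary, island 'island' (mld = 1)
#>   assigned 20/20; main source: R1; source regions receiving colonists: 1
#> R1
#>  1

founder_report(sim$dataset, "island", species = "simulated",
               assignment = asg, distance_km = 500)
#> Founder-effect report (set-cover solver: exact)
#>    species island main_source distance_km private_markers propagules
#>  simulated island          R1         500               0          5
#>  population_diversity regional_diversity marker_proportion sources_markers
#>                  0.94               0.93              0.94               1
#>  sources_allocation survival status
#>                   1    FALSE     ok
```

All 20 island individuals allocate to the true source `R1`. Five source
genotypes suffice to cover every island marker (the simulation used 10
founders — the set cover is a lower bound), the island retains ~93 % of the
source's regional diversity and ~94 % of its markers, and with no private
markers and sub-unity diversity the occurrence is read as postglacial
colonization, not glacial survival.

Colonization rates from checklist inputs (here Svalbard: first palaeorecord
9000 yr BP, 180–181 species, 92 % assumed postglacial, mean 8.9 propagules
per species):

```r
sv <- island_metadata()[island_metadata()$island == "Svalbard", ]
colonization_intervals(sv$palaeorecord_age_yr,
                       c(sv$species_min, sv$species_max),
                       mean_propagules = 8.9)
#>   per_species per_propagule
#>          54.2           6.1
```

i.e. one successful species establishment every ~54 years and one effective
propagule arrival every ~6 years.

The package also bundles a transcription of the published 46-row
species × island founder-effect table for 25 North Atlantic species
(`load_founder_table()`), which `summarize_founder()` aggregates into
per-island and overall mean ± SD summaries.

## Command line

A thin wrapper over the same functions lives in `inst/scripts/driftwood.R`
(subcommands `simulate`, `assign`, `report`, `intervals`); all analysis
logic is in the package.

See the methods vignette (`vignettes/island-founder-methods.Rmd`) for the
model, conventions (missing data, smoothing, rounding, tie-breaks) and
limitations.
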
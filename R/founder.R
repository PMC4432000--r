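#' Minimum number of colonizing propagules (set cover over genotypes)
#'
#' The smallest number of individual genotypes from the main source region
#' whose combined band sets account for every marker observed in the
#' recipient island. Island markers present in no source genotype cannot be
#' covered by any propagule set; they are removed from the universe first
#' (with a message) — the island-private ones among them are reported
#' separately by [private_markers()].
#'
#' The exact method is a depth-first branch-and-bound over genotypes seeded
#' with the greedy solution as incumbent, practical up to a few dozen
#' genotypes; the greedy method repeatedly takes the genotype covering the
#' most still-uncovered markers, breaking ties by the lexicographically
#' smallest genotype id, and is an upper bound on the optimum.
#'
#' @param island_markers character vector of marker (locus) ids observed in
#'   the island.
#' @param source_genotypes named list of character vectors: per source
#'   individual, the set of loci at which it carries the band. Unnamed lists
#'   are named \code{g1..gk}.
#' @param method \code{"auto"} (exact up to \code{exact_limit} genotypes,
#'   greedy beyond), \code{"exact"} or \code{"greedy"}.
#' @param exact_limit genotype count above which \code{"auto"} falls back to
#'   greedy (default 25).
#' @return integer count with attributes \code{method} (which algorithm ran),
#'   \code{uncovered} (island markers removed as uncoverable) and
#'   \code{genotypes} (ids of one optimal/greedy covering set). An empty
#'   coverable set yields 0.
#' @examples
#' min_propagules(c("m1", "m2", "m3"),
#'                list(a = c("m1", "m2"), b = c("m2", "m3"), c = c("m1", "m3")))
#' @export
min_propagules <- function(island_markers, source_genotypes,
                           method = c("auto", "exact", "greedy"),
                           exact_limit = 25) {
  method <- match.arg(method)
  if (is.null(names(source_genotypes)) && length(source_genotypes))
    names(source_genotypes) <- paste0("g", seq_along(source_genotypes))
  island_markers <- unique(as.character(island_markers))
  if (!length(source_genotypes) && length(island_markers))
    fail("no source genotypes supplied but island markers are demanded")
  covered_anywhere <- unique(unlist(source_genotypes))
  uncoverable <- setdiff(island_markers, covered_anywhere)
  universe <- setdiff(island_markers, uncoverable)
  if (length(uncoverable))
    message(length(uncoverable),
            " island marker(s) found in no source genotype; removed from the cover universe")
  if (!length(universe))
    return(structure(0L, method = "none", uncovered = uncoverable,
                     genotypes = character(0)))
  if (!length(source_genotypes))
    fail("no source genotypes supplied but the coverable island set is non-empty")
  # bit representation: genotype x universe incidence
  inc <- vapply(source_genotypes, function(g) universe %in% g,
                logical(length(universe)))
  inc <- matrix(inc, nrow = length(universe),
                dimnames = list(universe, names(source_genotypes)))
  greedy <- greedy_cover(inc)
  run_exact <- method == "exact" ||
    (method == "auto" && ncol(inc) <= exact_limit)
  if (!run_exact)
    return(structure(length(greedy), method = "greedy",
                     uncovered = uncoverable, genotypes = greedy))
  best <- exact_cover(inc, incumbent = greedy)
  structure(length(best), method = "exact", uncovered = uncoverable,
            genotypes = best)
}

# greedy largest-uncovered-first cover; ties -> lexicographically smallest id
greedy_cover <- function(inc) {
  uncovered <- rep(TRUE, nrow(inc))
  ids <- colnames(inc)
  chosen <- character(0)
  while (any(uncovered)) {
    gain <- colSums(inc & uncovered)
    cand <- ids[gain == max(gain)]
    pick <- sort(cand)[1]
    chosen <- c(chosen, pick)
    uncovered <- uncovered & !inc[, pick]
  }
  chosen
}

# depth-first branch and bound on the uncovered-element branching rule:
# pick an uncovered marker, branch on the genotypes that contain it.
exact_cover <- function(inc, incumbent) {
  best <- incumbent
  n_marker <- nrow(inc)
  recurse <- function(uncovered, chosen) {
    if (!any(uncovered)) {
      if (length(chosen) < length(best)) best <<- chosen
      return(invisible())
    }
    # lower bound: remaining / largest single-genotype gain
    gains <- colSums(inc & uncovered)
    maxgain <- max(gains)
    if (maxgain == 0) return(invisible())  # infeasible branch
    lb <- length(chosen) + ceiling(sum(uncovered) / maxgain)
    if (lb >= length(best)) return(invisible())
    # branch on the hardest uncovered marker (fewest covering genotypes)
    m <- which.min(ifelse(uncovered, rowSums(inc), Inf))
    for (g in colnames(inc)[inc[m, ]]) {
      recurse(uncovered & !inc[, g], c(chosen, g))
    }
    invisible()
  }
  recurse(rep(TRUE, n_marker), character(0))
  best
}

#' Minimum number of source regions accounting for the island's markers
#'
#' Smallest number of candidate source regions whose combined marker sets
#' cover every island marker found in at least one region; markers absent
#' from all regions (island-private) are excluded first. Solved exactly by
#' enumerating region subsets in order of size — region counts in this kind
#' of study are small (here at most about ten).
#'
#' @param island_markers character vector of island marker ids.
#' @param region_marker_sets named list: region id -> character vector of
#'   markers present in that region.
#' @return integer count with attributes \code{regions} (one optimal subset)
#'   and \code{uncovered} (island-private markers excluded); 0 for an empty
#'   coverable set.
#' @export
min_source_regions <- function(island_markers, region_marker_sets) {
  island_markers <- unique(as.character(island_markers))
  covered_anywhere <- unique(unlist(region_marker_sets))
  uncoverable <- setdiff(island_markers, covered_anywhere)
  universe <- setdiff(island_markers, uncoverable)
  if (length(uncoverable))
    message(length(uncoverable),
            " island marker(s) found in no source region; excluded (island-private)")
  if (!length(universe))
    return(structure(0L, regions = character(0), uncovered = uncoverable))
  ids <- names(region_marker_sets)
  for (k in seq_along(ids)) {
    subsets <- utils::combn(ids, k, simplify = FALSE)
    for (s in subsets) {
      if (all(universe %in% unlist(region_marker_sets[s])))
        return(structure(k, regions = s, uncovered = uncoverable))
    }
  }
  fail("internal error: no region subset covers the coverable universe")
}

#' Mean number of pairwise band differences
#'
#' Average, over all unordered pairs of individuals, of the number of loci at
#' which the two band phenotypes differ. Comparisons are pairwise-complete:
#' loci missing in either member of a pair are skipped for that pair, and the
#' raw difference count is not rescaled to a common locus number.
#'
#' @param bands matrix of 0/1/NA, individuals in rows.
#' @return mean pairwise difference count; \code{NA} (with a warning) for
#'   fewer than two individuals.
#' @export
mean_pairwise_differences <- function(bands) {
  bands <- as.matrix(bands)
  n <- nrow(bands)
  if (n < 2) {
    warning("mean pairwise differences undefined for fewer than 2 genotypes",
            call. = FALSE)
    return(NA_real_)
  }
  one <- (!is.na(bands) & bands == 1L) * 1
  zero <- (!is.na(bands) & bands == 0L) * 1
  d <- one %*% t(zero)      # loci where i has band and j has not
  diffs <- d + t(d)
  sum(diffs[upper.tri(diffs)]) / (n * (n - 1) / 2)
}

#' Island-to-source genetic diversity ratios
#'
#' The two diversity measures of the founder effect. Population diversity:
#' within each local population the mean pairwise band differences among its
#' individuals is computed, and these population values are averaged over the
#' island's populations and over the main source region's populations; the
#' ratio island/source is returned. Regional diversity: the mean pairwise
#' differences across all island individuals divided by the value across all
#' source-region individuals. Populations with fewer than two individuals are
#' skipped (with a message). Ratios are not capped at 1 — a recipient island
#' can be more diverse than its main source.
#'
#' @param ds a [marker_dataset()].
#' @param island recipient island region id.
#' @param main_source main source region id.
#' @return list with \code{population_ratio}, \code{regional_ratio}, and the
#'   underlying island/source diversities. Ratios are \code{NA} (flagged by a
#'   warning) when the source diversity is zero while the island's is not;
#'   0/0 is reported as 0 (no diversity anywhere).
#' @export
diversity_ratios <- function(ds, island, main_source) {
  reg <- individual_region(ds)
  pop_mean <- function(region) {
    rows <- which(reg == region)
    pops <- split(rows, ds$population_of[rows])
    vals <- vapply(pops, function(idx) {
      if (length(idx) < 2) {
        message("population '", ds$population_of[idx[1]],
                "' has <2 individuals; skipped in population diversity")
        return(NA_real_)
      }
      mean_pairwise_differences(ds$bands[idx, , drop = FALSE])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  reg_mean <- function(region)
    mean_pairwise_differences(ds$bands[reg == region, , drop = FALSE])
  ratio <- function(isl, src) {
    if (is.na(isl) || is.na(src)) return(NA_real_)
    if (src == 0) {
      if (isl == 0) return(0)
      warning("source diversity is zero with non-zero island diversity; ratio undefined",
              call. = FALSE)
      return(NA_real_)
    }
    isl / src
  }
  isl_pop <- pop_mean(island); src_pop <- pop_mean(main_source)
  isl_reg <- reg_mean(island); src_reg <- reg_mean(main_source)
  list(population_ratio = ratio(isl_pop, src_pop),
       regional_ratio = ratio(isl_reg, src_reg),
       island_population = isl_pop, source_population = src_pop,
       island_regional = isl_reg, source_regional = src_reg)
}

#' Proportion of island markers relative to the main source
#'
#' Size of the island's marker set divided by the size of the main source
#' region's marker set; may exceed 1 when the island harbours more markers
#' than its main source.
#'
#' @inheritParams diversity_ratios
#' @return numeric ratio.
#' @export
marker_proportion <- function(ds, island, main_source) {
  src <- region_marker_set(ds, main_source)
  if (!length(src)) fail("main source region '", main_source, "' has an empty marker set")
  length(region_marker_set(ds, island)) / length(src)
}

#' Glacial-survival screen
#'
#' A species' island occurrence is flagged as consistent with in situ glacial
#' survival (rather than postglacial colonization) when the island retains at
#' least as much regional genetic diversity as the threshold fraction of its
#' main source and carries at least the threshold number of private markers.
#' Either signal alone is not enough: private markers without high diversity
#' are read as insufficient evidence of long in situ persistence.
#'
#' @param regional_ratio island/source regional diversity ratio.
#' @param private_markers private-marker count of the island.
#' @param diversity_threshold minimum ratio (default 1.0).
#' @param private_threshold minimum private-marker count (default 2).
#' @return logical flag with attribute \code{rule} recording the thresholds.
#' @export
survival_flag <- function(regional_ratio, private_markers,
                          diversity_threshold = 1.0, private_threshold = 2) {
  flag <- !is.na(regional_ratio) &&
    regional_ratio >= diversity_threshold &&
    private_markers >= private_threshold
  structure(flag, rule = c(diversity_threshold = diversity_threshold,
                           private_threshold = private_threshold))
}

# internal: band set of one individual row
genotype_marker_sets <- function(ds, rows) {
  sets <- lapply(rows, function(i) ds$loci[which(ds$bands[i, ] == 1L)])
  names(sets) <- ds$individuals[rows]
  sets
}

#' Assemble a founder-effect report row for one species x island
#'
#' Runs the full measure set against one recipient island: the main source
#' region comes from the assignment summary, and the six founder-effect
#' measures plus the private-marker count and survival screen are computed
#' relative to it. With an undetermined assignment (no individual passed the
#' threshold, or a monomorphic species where no test is possible) the
#' source-relative measures are left \code{NA} and the row is marked
#' undetermined, mirroring how island x species combinations without a
#' determinable direction are excluded from downstream summaries.
#'
#' @param ds a [marker_dataset()] containing island and sources.
#' @param island recipient island region id.
#' @param species species label for the row.
#' @param assignment a \code{source_assignment} from [assign_sources()], or
#'   \code{NULL} to run it here with defaults.
#' @param distance_km dispersal distance input for the row (coast-to-coast
#'   distance to the main source; measured upstream).
#' @param propagule_method passed to [min_propagules()].
#' @param survival_rule list with \code{diversity_threshold},
#'   \code{private_threshold} for [survival_flag()].
#' @return An object of class \code{founder_report}: a one-row data frame
#'   with columns species, island, main_source, distance_km, private_markers,
#'   propagules, population_diversity, regional_diversity, marker_proportion,
#'   sources_markers, sources_allocation, survival, status, plus attribute
#'   \code{solver} naming the set-cover method used.
#' @export
founder_report <- function(ds, island, species, assignment = NULL,
                           distance_km = NA_real_,
                           propagule_method = c("auto", "exact", "greedy"),
                           survival_rule = list(diversity_threshold = 1.0,
                                                private_threshold = 2)) {
  propagule_method <- match.arg(propagule_method)
  if (is.null(assignment)) assignment <- assign_sources(ds, island)
  smry <- summary(assignment)
  priv <- private_markers(ds, island)
  isl_set <- region_marker_set(ds, island)
  row <- data.frame(species = species, island = island,
                    main_source = NA_character_, distance_km = distance_km,
                    private_markers = priv, propagules = NA_integer_,
                    population_diversity = NA_real_, regional_diversity = NA_real_,
                    marker_proportion = NA_real_,
                    sources_markers = NA_integer_, sources_allocation = NA_integer_,
                    survival = NA, status = smry$status,
                    stringsAsFactors = FALSE)
  solver <- "none"
  if (smry$status == "ok") {
    src <- smry$main_source
    reg <- individual_region(ds)
    src_rows <- which(reg == src)
    prop <- min_propagules(isl_set, genotype_marker_sets(ds, src_rows),
                           method = propagule_method)
    solver <- attr(prop, "method")
    region_sets <- lapply(stats::setNames(nm = assignment$candidates),
                          region_marker_set, ds = ds)
    dv <- diversity_ratios(ds, island, src)
    row$main_source <- src
    row$propagules <- as.integer(prop)
    row$population_diversity <- dv$population_ratio
    row$regional_diversity <- dv$regional_ratio
    row$marker_proportion <- marker_proportion(ds, island, src)
    row$sources_markers <- as.integer(min_source_regions(isl_set, region_sets))
    row$sources_allocation <- smry$sources_allocation
    row$survival <- as.logical(survival_flag(row$regional_diversity, priv,
                                             survival_rule$diversity_threshold,
                                             survival_rule$private_threshold))
  }
  structure(row, class = c("founder_report", "data.frame"), solver = solver)
}

#' @export
print.founder_report <- function(x, ...) {
  cat("Founder-effect report (set-cover solver: ",
      attr(x, "solver"), ")\n", sep = "")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round_half_up(v, 2))
  print(y, row.names = FALSE)
  invisible(x)
}
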
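#' Load the bundled founder-effect reference table
#'
#' A transcription of the published per-species founder-effect table for 25
#' North Atlantic vascular plants across five recipient islands: 46 species x
#' island rows with dispersal distance, private-marker count and the six
#' founder-effect measures, plus the main source region inferred by the
#' assignment test. Shipped as transcribed data — the underlying raw AFLP
#' matrices are not publicly deposited, so these rows cannot be recomputed
#' from genotypes.
#'
#' @return data frame with 46 rows and columns species, target_island,
#'   main_source, distance_km, private_markers, propagules,
#'   population_diversity, regional_diversity, marker_proportion,
#'   sources_markers, sources_allocation.
#' @export
load_founder_table <- function() {
  path <- system.file("extdata", "table1_founder.csv", package = "driftwood",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  islands <- c("East Greenland", "Iceland", "Svalbard", "Faroe Islands",
               "Jan Mayen")
  stopifnot(nrow(d) == 46, all(d$target_island %in% islands),
            all(d$private_markers >= 0), all(d$propagules >= 0),
            all(d$population_diversity >= 0), all(d$regional_diversity >= 0))
  d
}

#' Bundled recipient-island metadata
#'
#' Scalar inputs for the five recipient islands: area, age of the first
#' postglacial palaeorecord (for Jan Mayen, which lacks palaeobotanical
#' records, an assumed age comparable to the neighbouring islands), and the
#' checklist range of vascular-plant species counts.
#'
#' @return data frame with columns island, area_km2, palaeorecord_age_yr,
#'   species_min, species_max.
#' @export
island_metadata <- function() {
  data.frame(
    island = c("East Greenland", "Iceland", "Svalbard", "Faroe Islands",
               "Jan Mayen"),
    area_km2 = c(182440, 103000, 24453, 1396, 377),
    palaeorecord_age_yr = c(12700, 13000, 9000, 13100, 12800),
    species_min = c(369, 428, 180, 282, 65),
    species_max = c(388, 430, 181, 293, 65),
    stringsAsFactors = FALSE)
}

#' Per-island and overall mean +/- SD summary of founder-effect rows
#'
#' Aggregates founder-report rows (or the bundled reference table) into the
#' conventional island-by-island summary: mean and sample standard deviation
#' (n-1 denominator) of distance, private markers and the six founder
#' measures, plus an overall row pooling every island row. Values are
#' rounded half-up at the precision at which such tables are printed:
#' integers for distance, one decimal for private markers, propagules and
#' the two source counts, two decimals for the three ratios.
#'
#' @param rows data frame with the columns of [load_founder_table()] (a
#'   \code{founder_report} works via its island/measure columns, with
#'   \code{target_island} taken from \code{island}).
#' @return object of class \code{founder_summary}: data frame with one row
#'   per island plus \code{"Overall"}, columns \code{n} and, for each
#'   measure, \code{<measure>_mean} and \code{<measure>_sd} (rounded), with
#'   the unrounded matrices kept in attribute \code{unrounded}.
#' @export
summarize_founder <- function(rows) {
  rows <- as.data.frame(rows)
  if (!nrow(rows)) fail("no rows to summarize")
  if (!"target_island" %in% names(rows) && "island" %in% names(rows))
    rows$target_island <- rows$island
  measures <- c(distance_km = 0, private_markers = 1, propagules = 1,
                population_diversity = 2, regional_diversity = 2,
                marker_proportion = 2, sources_markers = 1,
                sources_allocation = 1)
  use <- intersect(names(measures), names(rows))
  islands <- sort(unique(rows$target_island))  # deterministic row order
  groups <- c(stats::setNames(islands, islands), Overall = NA)
  out <- data.frame(island = names(groups), n = NA_integer_,
                    stringsAsFactors = FALSE)
  raw <- list()
  for (m in use) {
    means <- sds <- numeric(length(groups))
    for (i in seq_along(groups)) {
      v <- if (names(groups)[i] == "Overall") rows[[m]]
           else rows[[m]][rows$target_island == names(groups)[i]]
      v <- v[!is.na(v)]
      means[i] <- mean(v)
      sds[i] <- if (length(v) > 1) stats::sd(v) else 0
    }
    raw[[m]] <- cbind(mean = means, sd = sds)
    out[[paste0(m, "_mean")]] <- round_half_up(means, measures[m])
    out[[paste0(m, "_sd")]] <- round_half_up(sds, measures[m])
  }
  for (i in seq_along(groups))
    out$n[i] <- if (names(groups)[i] == "Overall") nrow(rows)
                else sum(rows$target_island == names(groups)[i])
  structure(out, class = c("founder_summary", "data.frame"), unrounded = raw)
}

#' @export
print.founder_summary <- function(x, ...) {
  cat("Founder-effect summary (mean +/- SD, half-up at printed precision)\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Percentage of species assumed to have colonized postglacially
#'
#' The complement of the glacial-survival screen across species: 100 times
#' the fraction of species not flagged as consistent with in situ glacial
#' survival, rounded half-up to an integer percentage.
#'
#' @param species_flags named logical vector: species -> survival flag.
#' @return integer percentage.
#' @examples
#' postglacial_share(c(a = FALSE, b = TRUE))  # 50
#' @export
postglacial_share <- function(species_flags) {
  if (!length(species_flags)) fail("at least one species required")
  as.integer(round_half_up(100 * sum(!species_flags) / length(species_flags)))
}

# empty report with the full column set, for pipelines with nothing to do
founder_report_skeleton <- function() {
  data.frame(species = character(0), island = character(0),
             main_source = character(0), distance_km = numeric(0),
             private_markers = integer(0), propagules = integer(0),
             population_diversity = numeric(0), regional_diversity = numeric(0),
             marker_proportion = numeric(0), sources_markers = integer(0),
             sources_allocation = integer(0), survival = logical(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Run the assignment-to-founder-report pipeline
#'
#' Orchestrates the full analysis over a marker dataset (read from file or
#' simulated): for each configured recipient island and species the island
#' individuals are allocated to candidate source regions, the founder-effect
#' measures are computed against the inferred main source, and the rows are
#' aggregated into the island summary. Stage parameters are logged to
#' standard error via \code{message()}; any stage failure aborts with the
#' stage named.
#'
#' @param config list with elements: either \code{markers} (path to a marker
#'   CSV) or \code{scenario} (a [scenario_config()]); \code{islands}
#'   (character vector of recipient region ids); optional \code{species}
#'   (label, default \code{"sim"}), \code{mld} (default 1),
#'   \code{distances} (named numeric, island -> km), \code{survival_rule},
#'   \code{propagule_method}, \code{out} (directory to write TSVs into).
#' @return list with \code{reports} (stacked founder-report data frame),
#'   \code{summary} (a [summarize_founder()] table) and \code{assignments}
#'   (per island, the \code{source_assignment}).
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      fail("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  ds <- stage("input", {
    if (!is.null(config$scenario)) {
      message("[input] simulating scenario, seed = ", config$scenario$seed)
      simulate_colonization(config$scenario)$dataset
    } else if (!is.null(config$markers)) {
      message("[input] reading markers from ", config$markers)
      read_marker_table(config$markers)
    } else fail("config needs 'markers' or 'scenario'")
  })
  islands <- config$islands
  if (is.null(islands)) islands <- character(0)
  species <- if (is.null(config$species)) "sim" else config$species
  mld <- if (is.null(config$mld)) 1 else config$mld
  rule <- if (is.null(config$survival_rule))
    list(diversity_threshold = 1.0, private_threshold = 2) else config$survival_rule
  pmethod <- if (is.null(config$propagule_method)) "auto" else config$propagule_method
  reports <- list(); assignments <- list()
  for (isl in islands) {
    message("[assign] island ", isl, ", mld = ", mld)
    asg <- stage("assign", assign_sources(ds, isl, mld = mld))
    assignments[[isl]] <- asg
    dist <- if (!is.null(config$distances)) unname(config$distances[isl]) else NA_real_
    message("[founder] island ", isl)
    reports[[isl]] <- stage("founder",
      founder_report(ds, isl, species = species, assignment = asg,
                     distance_km = dist, propagule_method = pmethod,
                     survival_rule = rule))
  }
  if (!length(reports)) {
    all_rows <- founder_report_skeleton()
    smry <- NULL
  } else {
    all_rows <- do.call(rbind, lapply(reports, as.data.frame))
    smry <- stage("summary", summarize_founder(all_rows))
  }
  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(all_rows, file.path(config$out, "founder_reports.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(smry), file.path(config$out, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message("[output] wrote TSVs to ", config$out)
  }
  list(reports = all_rows, summary = smry, assignments = assignments)
}
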
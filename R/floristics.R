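#' Construct a flora occurrence table
#'
#' Taxon x region occurrence with a three-valued status: \code{"present"},
#' \code{"absent"} or \code{"uncertain"} (checklists disagree or the record
#' is doubtful). Taxa closely associated with human activity are assumed
#' anthropogenically introduced and are dropped from all similarity and
#' endemism computations.
#'
#' @param status character matrix (taxa x regions) with values
#'   present/absent/uncertain, or the compact codes \code{"1"}, \code{"0"},
#'   \code{"?"}.
#' @param anthropogenic character vector of taxon ids to exclude.
#' @return object of class \code{flora_table}: list with \code{status}
#'   (normalized matrix), \code{taxa}, \code{regions_list},
#'   \code{anthropogenic}.
#' @export
flora_table <- function(status, anthropogenic = character(0)) {
  status <- as.matrix(status)
  map <- c("1" = "present", "0" = "absent", "?" = "uncertain",
           present = "present", absent = "absent", uncertain = "uncertain")
  norm <- matrix(map[as.character(status)], nrow(status), ncol(status),
                 dimnames = dimnames(status))
  if (anyNA(norm))
    fail("flora status values must be present/absent/uncertain (or 1/0/?)")
  if (is.null(rownames(norm))) rownames(norm) <- paste0("t", seq_len(nrow(norm)))
  if (is.null(colnames(norm))) colnames(norm) <- paste0("r", seq_len(ncol(norm)))
  keep <- setdiff(rownames(norm), anthropogenic)
  structure(list(status = norm[keep, , drop = FALSE], taxa = keep,
                 regions_list = colnames(norm),
                 anthropogenic = intersect(rownames(norm), anthropogenic)),
            class = "flora_table")
}

#' Read a flora table from long-format delimited text
#'
#' Columns \code{taxon,region,status} with status in \code{1/0/?} (or the
#' words present/absent/uncertain). Missing taxon x region combinations are
#' treated as absent.
#'
#' @param path path to the CSV.
#' @param anthropogenic optional path to a one-column file of taxa to
#'   exclude, or a character vector.
#' @return a [flora_table()].
#' @export
read_flora_table <- function(path, anthropogenic = character(0)) {
  d <- utils::read.csv(path, colClasses = "character")
  if (!all(c("taxon", "region", "status") %in% names(d)))
    fail("flora file needs columns taxon, region, status")
  if (length(anthropogenic) == 1 && file.exists(anthropogenic))
    anthropogenic <- readLines(anthropogenic, warn = FALSE)
  taxa <- unique(d$taxon); regs <- unique(d$region)
  m <- matrix("0", length(taxa), length(regs), dimnames = list(taxa, regs))
  m[cbind(d$taxon, d$region)] <- d$status
  flora_table(m, anthropogenic = anthropogenic)
}

#' @export
print.flora_table <- function(x, ...) {
  cat("Flora table:", length(x$taxa), "taxa x", length(x$regions_list), "regions\n")
  cat("  uncertain records:", sum(x$status == "uncertain"),
      " anthropogenic taxa excluded:", length(x$anthropogenic), "\n")
  invisible(x)
}

#' Floristic similarity between an island and a candidate source
#'
#' Proportion of the recipient island's taxa that also occur in the source
#' region, bracketed over the two extreme resolutions of uncertain records:
#' the pessimistic bound (\code{min}) drops uncertain island taxa from the
#' island list and treats uncertain source occurrences as absent; the
#' optimistic bound (\code{max}) keeps uncertain island taxa and treats
#' uncertain source occurrences as present. The working value (\code{mean})
#' is the midpoint of the two bounds. For very small or heavily uncertain
#' floras the two resolutions can invert (an uncertain island taxon absent
#' from the source enlarges the optimistic denominator without enlarging its
#' numerator); the bracket returned is always the sorted pair, so
#' \code{min <= mean <= max} holds by construction.
#'
#' @param flora a [flora_table()].
#' @param island,source region ids (columns of the table).
#' @return named numeric vector \code{c(min, max, mean)}, all in [0, 1].
#' @export
similarity <- function(flora, island, source) {
  s <- flora$status
  if (!all(c(island, source) %in% colnames(s)))
    fail("unknown region in flora table")
  isl_certain <- rownames(s)[s[, island] == "present"]
  isl_optimistic <- rownames(s)[s[, island] %in% c("present", "uncertain")]
  if (!length(isl_optimistic)) fail("island '", island, "' has no taxa")
  src_certain <- rownames(s)[s[, source] == "present"]
  src_optimistic <- rownames(s)[s[, source] %in% c("present", "uncertain")]
  hi <- length(intersect(isl_optimistic, src_optimistic)) / length(isl_optimistic)
  lo <- if (length(isl_certain))
    length(intersect(isl_certain, src_certain)) / length(isl_certain)
  else hi  # island list entirely uncertain: the bracket collapses
  c(min = min(lo, hi), max = max(lo, hi), mean = (lo + hi) / 2)
}

#' Endemic taxa of an island
#'
#' Taxa present on the island and recorded absent — not merely uncertain —
#' in every other region of the table (strict rule: an uncertain record
#' elsewhere disqualifies endemism).
#'
#' @param flora a [flora_table()].
#' @param island region id.
#' @return integer count, with attribute \code{taxa} listing them.
#' @export
endemics <- function(flora, island) {
  s <- flora$status
  if (!island %in% colnames(s)) fail("unknown region: ", island)
  if (ncol(s) < 2) fail("endemism needs a multi-region table")
  others <- setdiff(colnames(s), island)
  hit <- s[, island] == "present" &
    apply(s[, others, drop = FALSE] == "absent", 1, all)
  structure(sum(hit), taxa = rownames(s)[hit])
}

#' Colonization-interval estimates for an island
#'
#' Rough rates of postglacial immigration: the expected number of years
#' between successful species establishments is the time since the island's
#' first postglacial palaeorecord divided by the number of postglacially
#' colonizing species, \eqn{T / (S q)}; dividing further by the mean number
#' of propagules per species gives the years between successful individual
#' propagule arrivals, \eqn{T / (S q P)}. The species count \eqn{S} enters
#' as the midpoint of the checklist range. Values are reported rounded half
#' up to one decimal.
#'
#' @param palaeorecord_age \eqn{T}, years since the first postglacial
#'   palaeorecord.
#' @param species_range numeric length-2 (min, max) checklist species count,
#'   or a single count.
#' @param postglacial_q proportion of species assumed to have colonized
#'   postglacially (default 0.92).
#' @param mean_propagules \eqn{P}, average propagule number per species
#'   (optional; per-propagule interval is \code{NA} without it).
#' @return named numeric vector \code{c(per_species, per_propagule)} in
#'   years, rounded half-up to one decimal.
#' @examples
#' colonization_intervals(9000, c(180, 181))          # Svalbard-like inputs
#' colonization_intervals(13000, c(428, 430), mean_propagules = 9.4)
#' @export
colonization_intervals <- function(palaeorecord_age, species_range,
                                   postglacial_q = 0.92,
                                   mean_propagules = NULL) {
  if (palaeorecord_age <= 0) fail("palaeorecord age must be positive")
  if (length(species_range) == 1) species_range <- rep(species_range, 2)
  if (species_range[1] > species_range[2]) fail("species range must be (min, max)")
  if (postglacial_q <= 0 || postglacial_q > 1) fail("postglacial proportion must be in (0, 1]")
  s <- mean(species_range)
  per_species <- palaeorecord_age / (s * postglacial_q)
  per_propagule <- if (is.null(mean_propagules)) NA_real_ else {
    if (mean_propagules <= 0) fail("mean propagules must be positive")
    per_species / mean_propagules
  }
  c(per_species = round_half_up(per_species, 1),
    per_propagule = round_half_up(per_propagule, 1))
}
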
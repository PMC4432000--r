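#' Construct a dominant-marker dataset
#'
#' A \code{marker_dataset} holds a binary band matrix (individuals x loci,
#' values 1 = band present, 0 = band absent, \code{NA} = not scored) together
#' with the two-level sampling hierarchy used throughout the package: each
#' individual belongs to exactly one local population and each population to
#' exactly one geographical region. AFLP and other dominant markers are scored
#' this way: a band either amplifies or it does not, and heterozygotes are
#' indistinguishable from dominant homozygotes.
#'
#' @param bands integer/numeric matrix of 0/1/NA with rownames = individual
#'   ids and colnames = locus ids (assigned \code{ind1..n}/\code{L1..L} when
#'   absent).
#' @param population character vector, one population id per individual (row).
#' @param region character vector, one region id per individual; must be
#'   constant within each population.
#' @return An object of class \code{marker_dataset}: a list with elements
#'   \code{bands} (matrix), \code{individuals}, \code{loci},
#'   \code{population_of} (named character, individual -> population) and
#'   \code{region_of} (named character, population -> region).
#' @examples
#' b <- rbind(a1 = c(1, 0, 1), a2 = c(0, 0, 1), b1 = c(1, 1, NA))
#' colnames(b) <- c("L1", "L2", "L3")
#' ds <- marker_dataset(b, population = c("p1", "p1", "p2"),
#'                      region = c("A", "A", "B"))
#' ds
#' @seealso [read_marker_table()], [region_marker_set()], [private_markers()]
#' @export
marker_dataset <- function(bands, population, region) {
  bands <- as.matrix(bands)
  if (is.null(rownames(bands))) rownames(bands) <- paste0("ind", seq_len(nrow(bands)))
  if (is.null(colnames(bands))) colnames(bands) <- paste0("L", seq_len(ncol(bands)))
  storage.mode(bands) <- "integer"
  population <- as.character(population)
  region <- as.character(region)
  if (length(population) != nrow(bands) || length(region) != nrow(bands))
    fail("'population' and 'region' must have one entry per individual")
  if (anyDuplicated(rownames(bands)))
    fail("duplicate individual id: ",
         paste(unique(rownames(bands)[duplicated(rownames(bands))]), collapse = ", "))
  bad <- which(!(bands %in% c(0L, 1L, NA_integer_)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(bands))
    fail("band matrix must contain only 0, 1 or NA; offending cell: individual '",
         rownames(bands)[rc[1]], "', locus '", colnames(bands)[rc[2]], "'")
  }
  if (ncol(bands) > 0 && any(colSums(!is.na(bands)) == 0))
    fail("locus with no scored individuals: ",
         paste(colnames(bands)[colSums(!is.na(bands)) == 0], collapse = ", "))
  # each population must map to a single region
  pr <- unique(data.frame(population = population, region = region,
                          stringsAsFactors = FALSE))
  if (anyDuplicated(pr$population))
    fail("population mapped to two regions: ",
         paste(unique(pr$population[duplicated(pr$population)]), collapse = ", "))
  population_of <- stats::setNames(population, rownames(bands))
  region_of <- stats::setNames(pr$region, pr$population)
  structure(list(bands = bands,
                 individuals = rownames(bands),
                 loci = colnames(bands),
                 population_of = population_of,
                 region_of = region_of),
            class = "marker_dataset")
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat("Dominant-marker dataset\n")
  cat("  individuals:", length(x$individuals),
      " populations:", length(x$region_of),
      " regions:", length(unique(x$region_of)),
      " loci:", length(x$loci), "\n")
  cat("  missing cells:", sum(is.na(x$bands)), "\n")
  invisible(x)
}

# internal: region id of each individual
individual_region <- function(ds) {
  unname(ds$region_of[ds$population_of[ds$individuals]])
}

#' Subset a marker dataset by individuals
#'
#' @param x a [marker_dataset()].
#' @param i individual index (integer, logical or id).
#' @param ... unused.
#' @return a [marker_dataset()] restricted to the selected individuals.
#' @export
`[.marker_dataset` <- function(x, i, ...) {
  keep <- x$individuals[i]
  marker_dataset(x$bands[keep, , drop = FALSE],
                 population = x$population_of[keep],
                 region = x$region_of[x$population_of[keep]])
}

#' Regions, populations and individuals of a dataset
#'
#' @param ds a [marker_dataset()].
#' @return character vector of region ids, in first-appearance order.
#' @export
regions <- function(ds) unique(unname(ds$region_of))

#' Read a dominant-marker table from delimited text
#'
#' Canonical dialect: comma-separated UTF-8 with header
#' \code{individual,population,region,<locus1>,...}; cells 0, 1 or \code{NA}.
#' Row order is preserved and the matrix is validated on construction.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default comma).
#' @param na.strings strings read as missing (default \code{"NA"}).
#' @return a [marker_dataset()].
#' @export
read_marker_table <- function(path, sep = ",", na.strings = "NA") {
  if (!file.exists(path)) fail("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na.strings,
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("individual", "population", "region")
  if (!all(need %in% names(d)[1:3]))
    fail("header must start with 'individual,population,region'")
  loci <- setdiff(names(d), need)
  if (!length(loci)) fail("no locus columns found")
  m <- as.matrix(d[, loci, drop = FALSE])
  num <- suppressWarnings(matrix(as.integer(m), nrow(m), ncol(m),
                                 dimnames = list(d$individual, loci)))
  bad <- which(!is.na(m) & (is.na(num) | !(num %in% c(0L, 1L))), arr.ind = TRUE)
  if (nrow(bad))
    fail("non-{0,1,NA} cell value '", m[bad[1, 1], bad[1, 2]],
         "' at individual '", d$individual[bad[1, 1]],
         "', locus '", loci[bad[1, 2]], "'")
  marker_dataset(num, population = d$population, region = d$region)
}

#' Write a dominant-marker table
#'
#' Inverse of [read_marker_table()]: the canonical comma/UTF-8/\code{NA}
#' dialect round-trips the band matrix exactly.
#'
#' @param ds a [marker_dataset()].
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_marker_table <- function(ds, path, sep = ",") {
  d <- data.frame(individual = ds$individuals,
                  population = unname(ds$population_of[ds$individuals]),
                  region = individual_region(ds),
                  ds$bands, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Marker set of a region
#'
#' Loci at which at least one individual sampled in the region carries the
#' band. Missing scores carry no evidence of presence.
#'
#' @param ds a [marker_dataset()].
#' @param region a region id present in \code{ds}.
#' @return character vector of locus ids (possibly empty).
#' @export
region_marker_set <- function(ds, region) {
  if (!region %in% regions(ds)) fail("unknown region: ", region)
  rows <- individual_region(ds) == region
  sub <- ds$bands[rows, , drop = FALSE]
  ds$loci[colSums(sub == 1L, na.rm = TRUE) > 0]
}

#' Private markers of a region
#'
#' Number of loci whose band occurs in the given region and in no other
#' region of the dataset. An excess of private markers in a recipient island
#' suggests local mutation accumulation, i.e. long in situ persistence rather
#' than recent colonization.
#'
#' @param ds a [marker_dataset()] with at least two regions.
#' @param region a region id.
#' @return integer count.
#' @export
private_markers <- function(ds, region) {
  regs <- regions(ds)
  if (length(regs) < 2) fail("private markers are undefined for a single-region dataset")
  own <- region_marker_set(ds, region)
  others <- unique(unlist(lapply(setdiff(regs, region), region_marker_set, ds = ds)))
  length(setdiff(own, others))
}
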
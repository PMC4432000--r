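#' Estimate band frequencies per candidate group
#'
#' Fits the parameters of the multilocus assignment model: for each group
#' (region or population) and each locus, the band frequency is the count of
#' band-present scores divided by the count of non-missing scores, then
#' smoothed away from the boundaries so that no phenotype has likelihood
#' zero. The default smoothing is the zero-replacement rule used by
#' dominant-marker allocation software: a raw frequency of 0 becomes
#' \eqn{1/(n+1)} and a raw frequency of 1 becomes \eqn{n/(n+1)}, with
#' \eqn{n} the non-missing sample size at that group x locus.
#'
#' If a group has no scored individual at some locus the frequency cannot be
#' estimated; it is recorded as \eqn{1/(n_g+1)} with \eqn{n_g} the group's
#' individual count, and a warning names the group and locus.
#'
#' @param ds a [marker_dataset()].
#' @param level \code{"region"} (default) or \code{"population"}: grouping at
#'   which frequencies are estimated.
#' @param smoothing \code{"zero_replacement"} (default, above) or
#'   \code{"none"} (raw frequencies; likelihoods will refuse boundary values).
#' @return An object of class \code{band_freq}: list with \code{freq}
#'   (loci x groups matrix of smoothed frequencies), \code{raw} (unsmoothed),
#'   \code{n} (loci x groups non-missing counts), \code{level},
#'   \code{smoothing}.
#' @examples
#' b <- rbind(a1 = c(1, 1), a2 = c(1, 0), b1 = c(0, 0), b2 = c(0, 0))
#' ds <- marker_dataset(b, population = c("p1", "p1", "p2", "p2"),
#'                      region = c("A", "A", "B", "B"))
#' band_frequencies(ds)
#' @export
band_frequencies <- function(ds, level = c("region", "population"),
                             smoothing = c("zero_replacement", "none")) {
  level <- match.arg(level)
  smoothing <- match.arg(smoothing)
  grp <- switch(level,
                region = individual_region(ds),
                population = unname(ds$population_of[ds$individuals]))
  groups <- unique(grp)
  L <- length(ds$loci)
  ones <- n <- matrix(0L, L, length(groups),
                      dimnames = list(ds$loci, groups))
  for (g in groups) {
    sub <- ds$bands[grp == g, , drop = FALSE]
    ones[, g] <- colSums(sub == 1L, na.rm = TRUE)
    n[, g] <- colSums(!is.na(sub))
  }
  raw <- ifelse(n > 0, ones / n, NA_real_)
  freq <- raw
  if (smoothing == "zero_replacement") {
    at0 <- which(raw == 0)
    at1 <- which(raw == 1)
    freq[at0] <- 1 / (n[at0] + 1)
    freq[at1] <- n[at1] / (n[at1] + 1)
  }
  if (anyNA(raw)) {
    idx <- which(is.na(raw), arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      g <- groups[idx[k, 2]]
      ng <- sum(grp == g)
      freq[idx[k, 1], idx[k, 2]] <- 1 / (ng + 1)
      warning("group '", g, "' has no scored individual at locus '",
              ds$loci[idx[k, 1]], "'; frequency set to 1/(", ng, "+1)",
              call. = FALSE)
    }
  }
  structure(list(freq = freq, raw = raw, n = n,
                 level = level, smoothing = smoothing),
            class = "band_freq")
}

#' @export
print.band_freq <- function(x, ...) {
  cat("Band-frequency model (", x$level, " level, smoothing: ",
      x$smoothing, ")\n", sep = "")
  cat("  loci:", nrow(x$freq), " groups:", paste(colnames(x$freq), collapse = ", "), "\n")
  cat("  frequency range:", sprintf("%.4f-%.4f", min(x$freq), max(x$freq)), "\n")
  invisible(x)
}

#' Multilocus log10 likelihood of band phenotypes
#'
#' Under the dominant-marker model each locus is an independent Bernoulli
#' trial: within a candidate group with smoothed band frequency \eqn{f}, a
#' band-present score contributes \eqn{\log_{10} f} and a band-absent score
#' \eqn{\log_{10}(1-f)}; missing scores are skipped. Likelihoods are of the
#' observed phenotype, so they are always \eqn{\le 0}.
#'
#' @param bands matrix (individuals x loci) or a single phenotype vector of
#'   0/1/NA; loci must match \code{freqs} row order.
#' @param freqs a [band_frequencies()] fit, or a loci x groups matrix of
#'   smoothed frequencies.
#' @return individuals x groups matrix of log10 likelihoods.
#' @export
log10_likelihood <- function(bands, freqs) {
  f <- if (inherits(freqs, "band_freq")) freqs$freq else as.matrix(freqs)
  if (is.null(dim(bands))) bands <- matrix(bands, nrow = 1)
  if (ncol(bands) != nrow(f))
    fail("phenotype length (", ncol(bands), ") does not match locus count (",
         nrow(f), ")")
  if (any(f <= 0 | f >= 1))
    fail("unsmoothed frequency of 0 or 1 encountered; smooth before computing likelihoods")
  present <- !is.na(bands) & bands == 1L
  absent <- !is.na(bands) & bands == 0L
  mode(present) <- "numeric"; mode(absent) <- "numeric"
  present %*% log10(f) + absent %*% log10(1 - f)
}

#' Allocate island individuals to candidate source regions
#'
#' The assignment test for dominant markers: each island individual is scored
#' against every candidate source group under [log10_likelihood()] and
#' allocated to the most likely group only when the log10-likelihood gap to
#' the runner-up is at least \code{mld} (minimum log-likelihood difference).
#' The conventional threshold \code{mld = 1} demands the best source be at
#' least ten times as likely as any other; individuals failing the threshold
#' are left \code{"unassigned"}. An exact tie is never allocated, so
#' \code{mld = 0} reduces to plain maximum-likelihood assignment up to ties.
#' Candidate groups exclude the recipient island itself, since island plants
#' are to be traced to external sources.
#'
#' @param ds a [marker_dataset()] containing the island and all candidate
#'   source regions.
#' @param island region id of the recipient island.
#' @param mld minimum log10-likelihood difference for allocation
#'   (default 1, i.e. a tenfold likelihood ratio).
#' @param smoothing passed to [band_frequencies()].
#' @return An object of class \code{source_assignment}: list with
#'   \code{loglik} (island individuals x candidate regions), \code{allocation}
#'   (named character, \code{"unassigned"} where below threshold),
#'   \code{mld}, \code{island}, \code{candidates}, and the \code{band_freq}
#'   fit used.
#' @examples
#' set.seed(1)
#' sim <- simulate_colonization(scenario_config(seed = 1))
#' asg <- assign_sources(sim$dataset, island = "island")
#' summary(asg)
#' @export
assign_sources <- function(ds, island, mld = 1,
                           smoothing = c("zero_replacement", "none")) {
  regs <- regions(ds)
  if (!island %in% regs) fail("unknown island region: ", island)
  candidates <- setdiff(regs, island)
  if (length(candidates) < 2)
    fail("allocation needs at least two candidate source regions")
  src <- ds[individual_region(ds) != island]
  fit <- band_frequencies(src, level = "region", smoothing = match.arg(smoothing))
  isl_rows <- individual_region(ds) == island
  ll <- log10_likelihood(ds$bands[isl_rows, , drop = FALSE], fit)
  allocation <- apply(ll, 1, function(l) {
    o <- order(l, decreasing = TRUE)
    gap <- l[o[1]] - l[o[2]]
    if (gap >= mld && gap > 0) colnames(ll)[o[1]] else "unassigned"
  })
  structure(list(loglik = ll, allocation = allocation, mld = mld,
                 island = island, candidates = candidates, freq = fit),
            class = "source_assignment")
}

#' Allocate phenotypes against an existing frequency fit
#'
#' \code{predict()} on a [band_frequencies()] fit applies the same threshold
#' rule as [assign_sources()] to arbitrary phenotypes.
#'
#' @param object a \code{band_freq} fit.
#' @param bands phenotype matrix or vector (0/1/NA).
#' @param mld minimum log10-likelihood difference.
#' @param ... unused.
#' @return named character vector of allocations (\code{"unassigned"} where
#'   below threshold).
#' @export
predict.band_freq <- function(object, bands, mld = 1, ...) {
  if (ncol(object$freq) < 2)
    fail("allocation needs at least two candidate groups")
  ll <- log10_likelihood(bands, object)
  out <- apply(ll, 1, function(l) {
    o <- order(l, decreasing = TRUE)
    gap <- l[o[1]] - l[o[2]]
    if (gap >= mld && gap > 0) colnames(ll)[o[1]] else "unassigned"
  })
  stats::setNames(out, rownames(ll))
}

#' @export
print.source_assignment <- function(x, ...) {
  cat("Source assignment for island '", x$island, "' (mld = ", x$mld, ")\n", sep = "")
  n <- length(x$allocation)
  cat("  individuals:", n, " assigned:", sum(x$allocation != "unassigned"), "\n")
  print(table(allocation = x$allocation))
  invisible(x)
}

#' Summarise an assignment: per-source proportions and main source
#'
#' Proportions are over assigned individuals only (unassigned excluded). The
#' source region with the highest proportion is the main source region, ties
#' broken alphabetically (with a message). \code{sources_allocation} counts
#' candidate regions receiving more than \code{min_share} of the assigned
#' individuals (default: any assigned individual). With no assigned
#' individual the summary is flagged undetermined.
#'
#' @param object a \code{source_assignment}.
#' @param min_share minimum allocation share for a region to count towards
#'   \code{sources_allocation} (default 0, exclusive).
#' @param ... unused.
#' @return An object of class \code{assignment_summary}: list with
#'   \code{status} ("ok" or "undetermined"), \code{proportions} (named, sums
#'   to 1 over sources with assigned individuals), \code{main_source},
#'   \code{sources_allocation}, \code{n_assigned}, \code{n_total},
#'   \code{island}, \code{mld}.
#' @export
summary.source_assignment <- function(object, min_share = 0, ...) {
  assigned <- object$allocation[object$allocation != "unassigned"]
  out <- list(island = object$island, mld = object$mld,
              n_total = length(object$allocation), n_assigned = length(assigned))
  if (!length(assigned)) {
    out$status <- "undetermined"
    out$proportions <- NULL
    out$main_source <- NA_character_
    out$sources_allocation <- NA_integer_
  } else {
    tab <- table(factor(assigned, levels = sort(unique(assigned))))
    prop <- as.numeric(tab) / length(assigned)
    names(prop) <- names(tab)
    top <- names(prop)[prop == max(prop)]
    if (length(top) > 1)
      message("main-source tie between ", paste(top, collapse = ", "),
              "; alphabetically first retained")
    out$status <- "ok"
    out$proportions <- prop
    out$main_source <- sort(top)[1]
    out$sources_allocation <- sum(prop > min_share)
  }
  structure(out, class = "assignment_summary")
}

#' @export
print.assignment_summary <- function(x, ...) {
  cat("Assignment summary, island '", x$island, "' (mld = ", x$mld, ")\n", sep = "")
  if (x$status == "undetermined") {
    cat("  undetermined: no individual passed the allocation threshold (",
        x$n_total, " individuals)\n", sep = "")
  } else {
    cat("  assigned ", x$n_assigned, "/", x$n_total,
        "; main source: ", x$main_source,
        "; source regions receiving colonists: ", x$sources_allocation, "\n", sep = "")
    print(round(x$proportions, 3))
  }
  invisible(x)
}
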
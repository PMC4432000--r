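#' Configure an island-colonization simulation scenario
#'
#' The generator emulates the structure assumed by the analyses in this
#' package: several geographical source regions, each holding a few local
#' populations of diploid plants scored at many dominant (band
#' presence/absence) loci, and one island founded by \code{n_founders}
#' individuals drawn from a single true source region, optionally followed by
#' Wright-Fisher drift. Regional structure follows the Balding-Nichols model:
#' each locus has a shared ancestral allele frequency and each region draws
#' its own frequency around it with divergence controlled by a single
#' Fst-like parameter, so one scalar knob maps monotonically to assignment
#' difficulty.
#'
#' @param n_regions number of source regions (default 3).
#' @param pops_per_region local populations per region (default 2).
#' @param inds_per_pop diploid individuals per population (default 10).
#' @param n_loci dominant loci (default 120).
#' @param fst differentiation among regions, in (0, 1); larger = more
#'   differentiated (default 0.25, strong structure).
#' @param ancestral_range range of the shared per-locus ancestral allele
#'   frequency (default c(0.05, 0.95)).
#' @param true_source region id (by index) that founds the island (default 1).
#' @param n_founders founder individuals sampled from the true source
#'   (default 10).
#' @param drift_generations generations of post-founding Wright-Fisher drift
#'   (default 0).
#' @param ne effective island population size during drift (default 50).
#' @param island_pops,island_inds_per_pop sampling design of the island
#'   (defaults 2 populations x 10 individuals).
#' @param seed integer seed; recorded in the output. Every stochastic
#'   operation in the generator takes its state from this seed — there is no
#'   dependence on the global RNG state.
#' @return a \code{scenario_config} list.
#' @export
scenario_config <- function(n_regions = 3, pops_per_region = 2,
                            inds_per_pop = 10, n_loci = 120, fst = 0.25,
                            ancestral_range = c(0.05, 0.95),
                            true_source = 1, n_founders = 10,
                            drift_generations = 0, ne = 50,
                            island_pops = 2, island_inds_per_pop = 10,
                            seed = 1) {
  cfg <- list(n_regions = n_regions, pops_per_region = pops_per_region,
              inds_per_pop = inds_per_pop, n_loci = n_loci, fst = fst,
              ancestral_range = ancestral_range, true_source = true_source,
              n_founders = n_founders, drift_generations = drift_generations,
              ne = ne, island_pops = island_pops,
              island_inds_per_pop = island_inds_per_pop, seed = as.integer(seed))
  counts <- unlist(cfg[c("n_regions", "pops_per_region", "inds_per_pop",
                         "n_loci", "n_founders", "ne", "island_pops",
                         "island_inds_per_pop")])
  if (any(counts < 1)) fail("all scenario counts must be >= 1")
  if (fst <= 0 || fst >= 1) fail("fst must lie strictly in (0, 1)")
  if (n_founders > pops_per_region * inds_per_pop)
    fail("n_founders exceeds the true source sample size")
  class(cfg) <- "scenario_config"
  cfg
}

# band frequency implied by allele frequency q under random mating:
# a band shows unless the individual is homozygous for the null allele
band_from_allele <- function(q) 1 - (1 - q)^2

#' Draw per-region allele and band frequencies
#'
#' Balding-Nichols hierarchical draw: per locus an ancestral allele frequency
#' \eqn{\mu} is drawn uniformly on \code{ancestral_range}; each region then
#' draws \eqn{q \sim Beta(\mu(1-F)/F, (1-\mu)(1-F)/F)} with \eqn{F} the
#' \code{fst} knob. Band frequencies follow as \eqn{p = 1-(1-q)^2}.
#'
#' @param cfg a [scenario_config()].
#' @return list with \code{allele} and \code{band}, both
#'   \code{n_loci x n_regions} matrices (columns \code{R1..Rk}), and
#'   \code{ancestral} (per-locus mean).
#' @export
simulate_regional_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  mu <- stats::runif(cfg$n_loci, cfg$ancestral_range[1], cfg$ancestral_range[2])
  f <- cfg$fst
  a <- mu * (1 - f) / f
  b <- (1 - mu) * (1 - f) / f
  q <- matrix(stats::rbeta(cfg$n_loci * cfg$n_regions, a, b),
              nrow = cfg$n_loci,
              dimnames = list(paste0("L", seq_len(cfg$n_loci)),
                              paste0("R", seq_len(cfg$n_regions))))
  list(allele = q, band = band_from_allele(q), ancestral = mu)
}

#' Sample band phenotypes from band frequencies
#'
#' Each of \code{n} individuals carries the band at locus \eqn{\ell} with
#' probability \eqn{p_\ell}, independently across loci and individuals.
#'
#' @param band_freq numeric vector of per-locus band frequencies.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return n x loci 0/1 integer matrix.
#' @export
simulate_population <- function(band_freq, n, seed = 1) {
  set.seed(seed)
  L <- length(band_freq)
  m <- matrix(stats::rbinom(n * L, 1L, rep(band_freq, each = n)), nrow = n)
  colnames(m) <- if (!is.null(names(band_freq))) names(band_freq)
                 else paste0("L", seq_len(L))
  m
}

# diploid genotypes (allele dose 0/1/2 per locus) for n individuals
sample_dose <- function(q, n) {
  matrix(stats::rbinom(n * length(q), 2L, rep(q, each = n)), nrow = n)
}

#' Simulate an island colonization with known ground truth
#'
#' Source regions are populated by diploid sampling from the regional allele
#' frequencies of [simulate_regional_frequencies()]. The island is founded by
#' \code{n_founders} individuals sampled without replacement from the true
#' source region's sample; the island allele frequencies are those implied by
#' the founders' allele doses, then drift for \code{drift_generations}
#' generations of Wright-Fisher binomial resampling at diploid size
#' \code{ne}. Drift acts on the latent allele frequencies — under dominance,
#' band-level drift is not Markovian in the band frequency alone — and band
#' phenotypes are re-expressed when the island sample is emitted.
#'
#' @param cfg a [scenario_config()].
#' @return list with \code{dataset} (a [marker_dataset()] containing regions
#'   \code{R1..Rk} plus region \code{"island"}) and \code{truth} (list:
#'   \code{true_source}, \code{founder_ids}, \code{founder_bands},
#'   \code{island_allele_freq} per generation, \code{seed}).
#' @export
simulate_colonization <- function(cfg) {
  freqs <- simulate_regional_frequencies(cfg)  # seeds the RNG with cfg$seed
  L <- cfg$n_loci
  per_region_n <- cfg$pops_per_region * cfg$inds_per_pop
  doses <- list(); bands <- list(); pop <- c(); regv <- c()
  for (r in seq_len(cfg$n_regions)) {
    rid <- paste0("R", r)
    d <- sample_dose(freqs$allele[, r], per_region_n)
    doses[[rid]] <- d
    b <- (d > 0) * 1L
    rownames(b) <- paste0(rid, "_i", seq_len(per_region_n))
    bands[[rid]] <- b
    pop <- c(pop, rep(paste0(rid, "_p", seq_len(cfg$pops_per_region)),
                      each = cfg$inds_per_pop))
    regv <- c(regv, rep(rid, per_region_n))
  }
  src_id <- paste0("R", cfg$true_source)
  founder_idx <- sample.int(per_region_n, cfg$n_founders)
  founder_dose <- doses[[src_id]][founder_idx, , drop = FALSE]
  q <- colSums(founder_dose) / (2 * cfg$n_founders)
  freq_path <- list(q)
  if (cfg$drift_generations > 0) {
    for (g in seq_len(cfg$drift_generations)) {
      q <- stats::rbinom(L, 2L * cfg$ne, q) / (2 * cfg$ne)
      freq_path[[g + 1]] <- q
    }
  }
  isl_n <- cfg$island_pops * cfg$island_inds_per_pop
  isl_dose <- sample_dose(q, isl_n)
  isl_bands <- (isl_dose > 0) * 1L
  rownames(isl_bands) <- paste0("island_i", seq_len(isl_n))
  all_bands <- do.call(rbind, c(bands, list(isl_bands)))
  colnames(all_bands) <- paste0("L", seq_len(L))
  pop <- c(pop, rep(paste0("island_p", seq_len(cfg$island_pops)),
                    each = cfg$island_inds_per_pop))
  regv <- c(regv, rep("island", isl_n))
  ds <- marker_dataset(all_bands, population = pop, region = regv)
  truth <- list(true_source = src_id,
                founder_ids = rownames(bands[[src_id]])[founder_idx],
                founder_bands = (founder_dose > 0) * 1L,
                island_allele_freq = freq_path,
                seed = cfg$seed)
  list(dataset = ds, truth = truth)
}
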
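# Small in-code fixtures shared across test files.

# a tiny fixed three-region dataset with known marker geography
toy_dataset <- function() {
  b <- rbind(
    A1 = c(1, 0, 1, 0, NA),
    A2 = c(1, 0, 0, 0, 0),
    B1 = c(0, 1, 1, 0, 0),
    B2 = c(0, 1, 0, 0, 1),
    C1 = c(0, 0, 1, 0, 0),
    C2 = c(0, 0, 1, 0, 0))
  colnames(b) <- paste0("L", 1:5)
  marker_dataset(b,
                 population = c("pA", "pA", "pB", "pB", "pC", "pC"),
                 region = c("A", "A", "B", "B", "C", "C"))
}

# random multi-region dataset; missingness optional
random_dataset <- function(seed, n_regions = 3, pops_per_region = 2,
                           inds_per_pop = 3, n_loci = 8, p_missing = 0) {
  set.seed(seed)
  n <- n_regions * pops_per_region * inds_per_pop
  b <- matrix(rbinom(n * n_loci, 1, runif(n_loci, 0.1, 0.9)[rep(1:n_loci, each = n)]),
              nrow = n)
  if (p_missing > 0) b[runif(length(b)) < p_missing] <- NA
  # keep every locus scored at least once
  for (j in which(colSums(!is.na(b)) == 0)) b[1, j] <- 1
  colnames(b) <- paste0("L", seq_len(n_loci))
  rownames(b) <- paste0("i", seq_len(n))
  region <- rep(paste0("R", seq_len(n_regions)), each = pops_per_region * inds_per_pop)
  pop <- rep(paste0(rep(paste0("R", seq_len(n_regions)), each = pops_per_region),
                    "_p", seq_len(pops_per_region)), each = inds_per_pop)
  marker_dataset(b, population = pop, region = region)
}

# region label per individual (mirrors the package-internal mapping)
individual_region_test <- function(ds)
  unname(ds$region_of[ds$population_of[ds$individuals]])

# exhaustive set-cover minimum by subset enumeration (oracle)
brute_force_cover <- function(universe, sets) {
  if (!length(universe)) return(0L)
  k <- length(sets)
  best <- Inf
  for (mask in 1:(2^k - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(members) >= best) next
    if (all(universe %in% unlist(sets[members]))) best <- length(members)
  }
  as.integer(best)
}

# brute-force mean pairwise difference count (oracle)
brute_force_mpd <- function(bands) {
  n <- nrow(bands)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(bands[i, ]) & !is.na(bands[j, ])
    tot <- tot + sum(bands[i, ok] != bands[j, ok])
  }
  tot / (n * (n - 1) / 2)
}

# random flora table over 3-valued status codes
random_flora <- function(seed, n_taxa = 12, n_regions = 4) {
  set.seed(seed)
  m <- matrix(sample(c("1", "0", "?"), n_taxa * n_regions, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)),
              n_taxa, n_regions,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("r", seq_len(n_regions))))
  # every island used in tests must have at least one (possibly uncertain) taxon
  m[1, ] <- "1"
  flora_table(m)
}
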
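test_that("minimum propagules: worked examples", {
  # one genotype covers everything
  expect_equal(as.integer(min_propagules(
    c("m1", "m2", "m3"),
    list(a = c("m1", "m2"), b = "m3", c = c("m1", "m2", "m3")))), 1L)
  # no single genotype covers, two do
  p <- min_propagules(c("m1", "m2", "m3"),
                      list(a = c("m1", "m2"), b = c("m2", "m3"), c = c("m1", "m3")))
  expect_equal(as.integer(p), 2L)
  expect_equal(attr(p, "method"), "exact")
  # uncoverable island markers are dropped with a message
  expect_message(
    q <- min_propagules(c("m1", "mX"), list(a = "m1")),
    "no source genotype")
  expect_equal(as.integer(q), 1L)
  expect_equal(attr(q, "uncovered"), "mX")
  # empty coverable set
  expect_equal(as.integer(suppressMessages(min_propagules("mX", list(a = "m1")))), 0L)
  # empty genotype list with coverable demand is an error
  expect_error(min_propagules("m1", list()), "no source genotypes")
  expect_equal(as.integer(min_propagules(character(0), list())), 0L)
})

test_that("exact solver equals exhaustive enumeration; greedy never beats it", {
  set.seed(303)
  for (rep in 1:50) {
    n_g <- sample(3:12, 1)
    n_m <- sample(4:15, 1)
    loci <- paste0("m", seq_len(n_m))
    sets <- lapply(seq_len(n_g), function(i)
      loci[runif(n_m) < runif(1, 0.15, 0.7)])
    names(sets) <- paste0("g", seq_len(n_g))
    island <- loci[runif(n_m) < 0.8]
    coverable <- intersect(island, unique(unlist(sets)))
    oracle <- brute_force_cover(coverable, sets)
    exact <- suppressMessages(min_propagules(island, sets, method = "exact"))
    greedy <- suppressMessages(min_propagules(island, sets, method = "greedy"))
    expect_equal(as.integer(exact), oracle)
    expect_gte(as.integer(greedy), as.integer(exact))
    # both returned sets actually cover the coverable universe
    expect_true(all(coverable %in% unlist(sets[attr(exact, "genotypes")])))
    expect_true(all(coverable %in% unlist(sets[attr(greedy, "genotypes")])))
  }
})

test_that("greedy tie-break is deterministic (lexicographically smallest id)", {
  sets <- list(b = c("m1", "m2"), a = c("m1", "m2"), c = "m3")
  g <- suppressMessages(min_propagules(c("m1", "m2", "m3"), sets, method = "greedy"))
  expect_equal(attr(g, "genotypes"), c("a", "c"))
})

test_that("minimum source regions: examples and exhaustive check", {
  # island set inside one region
  expect_equal(as.integer(min_source_regions(c("m1", "m2"),
                                             list(A = c("m1", "m2", "m3"), B = "m1"))), 1L)
  # A union B needed
  r <- min_source_regions(c("m1", "m2"), list(A = "m1", B = "m2", C = "m1"))
  expect_equal(as.integer(r), 2L)
  # supports five or more regions
  sets5 <- setNames(lapply(1:5, function(i) paste0("m", i)), paste0("R", 1:5))
  expect_equal(as.integer(min_source_regions(paste0("m", 1:5), sets5)), 5L)
  # random instances vs subset oracle
  set.seed(77)
  for (rep in 1:20) {
    regions <- setNames(lapply(1:5, function(i) paste0("m", sample(10, sample(2:6, 1)))),
                        paste0("R", 1:5))
    island <- paste0("m", sample(10, 6))
    coverable <- intersect(island, unique(unlist(regions)))
    expect_equal(as.integer(suppressMessages(min_source_regions(island, regions))),
                 brute_force_cover(coverable, regions))
  }
})

test_that("mean pairwise differences: direct counts, missing loci skipped pairwise", {
  expect_equal(mean_pairwise_differences(rbind(c(1, 0, 1), c(1, 0, 1))), 0)
  expect_equal(mean_pairwise_differences(rbind(c(1, 0, 1), c(1, 1, 0))), 2)
  # three genotypes 101, 100, 001 -> (1 + 1 + 2)/3
  m <- rbind(c(1, 0, 1), c(1, 0, 0), c(0, 0, 1))
  expect_equal(mean_pairwise_differences(m), 4 / 3)
  # pairwise-complete: NA loci dropped per pair, no rescaling
  m2 <- rbind(c(1, NA, 1), c(0, 1, 1))
  expect_equal(mean_pairwise_differences(m2), 1)
  expect_warning(v <- mean_pairwise_differences(m[1, , drop = FALSE]), "fewer than 2")
  expect_true(is.na(v))
  # invariant under locus and individual reordering; oracle on random matrices
  set.seed(8)
  for (rep in 1:5) {
    mm <- matrix(sample(c(0L, 1L, NA), 40, replace = TRUE, prob = c(.45, .45, .1)),
                 nrow = 5)
    expect_equal(mean_pairwise_differences(mm), brute_force_mpd(mm))
    expect_equal(mean_pairwise_differences(mm[sample(5), sample(8)]),
                 mean_pairwise_differences(mm))
  }
})

test_that("diversity ratios behave at the limits and are not capped at 1", {
  # island identical in composition to source -> ratios 1
  b <- rbind(i1 = c(1, 0, 1, 0), i2 = c(0, 1, 0, 1),
             s1 = c(1, 0, 1, 0), s2 = c(0, 1, 0, 1))
  colnames(b) <- paste0("L", 1:4)
  ds <- marker_dataset(b, c("ip", "ip", "sp", "sp"),
                       c("isl", "isl", "src", "src"))
  dv <- diversity_ratios(ds, "isl", "src")
  expect_equal(dv$population_ratio, 1)
  expect_equal(dv$regional_ratio, 1)

  # clonal island, variable source -> (0, 0)
  b2 <- rbind(i1 = c(1, 0), i2 = c(1, 0), s1 = c(1, 1), s2 = c(0, 0))
  colnames(b2) <- c("L1", "L2")
  ds2 <- marker_dataset(b2, c("ip", "ip", "sp", "sp"),
                        c("isl", "isl", "src", "src"))
  dv2 <- diversity_ratios(ds2, "isl", "src")
  expect_equal(dv2$population_ratio, 0)
  expect_equal(dv2$regional_ratio, 0)

  # island more diverse than source -> ratio above 1, no capping
  b3 <- rbind(i1 = c(1, 1, 0, 0), i2 = c(0, 0, 1, 1),
              s1 = c(1, 0, 0, 0), s2 = c(1, 1, 0, 0))
  colnames(b3) <- paste0("L", 1:4)
  ds3 <- marker_dataset(b3, c("ip", "ip", "sp", "sp"),
                        c("isl", "isl", "src", "src"))
  expect_gt(diversity_ratios(ds3, "isl", "src")$regional_ratio, 1)

  # zero source diversity with non-zero island diversity is flagged NA
  b4 <- rbind(i1 = c(1, 0), i2 = c(0, 1), s1 = c(1, 0), s2 = c(1, 0))
  colnames(b4) <- c("L1", "L2")
  ds4 <- marker_dataset(b4, c("ip", "ip", "sp", "sp"),
                        c("isl", "isl", "src", "src"))
  w <- capture_warnings(dv4 <- diversity_ratios(ds4, "isl", "src"))
  expect_match(w, "undefined", all = TRUE)
  expect_true(is.na(dv4$regional_ratio))
  expect_true(is.na(dv4$population_ratio))
})

test_that("marker proportion is a plain set-size ratio, possibly above 1", {
  ds <- toy_dataset()
  # island A: {L1, L3}; source C: {L3}
  expect_equal(marker_proportion(ds, "A", "C"), 2)
  expect_equal(marker_proportion(ds, "C", "A"), 0.5)
  expect_equal(marker_proportion(ds, "A", "A"), 1)
  b <- rbind(x = c(0, 0), y = c(1, 0))
  colnames(b) <- c("L1", "L2")
  ds0 <- marker_dataset(b, c("p1", "p2"), c("A", "B"))
  expect_error(marker_proportion(ds0, "B", "A"), "empty marker set")
})

test_that("glacial-survival screen needs both high diversity and private markers", {
  expect_false(survival_flag(0.5, 0))
  expect_true(survival_flag(1.2, 4))
  # high private-marker count alone is not survival evidence
  expect_false(survival_flag(0.81, 5))
  expect_false(survival_flag(1.2, 1))
  expect_equal(unname(attr(survival_flag(1, 2), "rule")), c(1, 2))
})

test_that("founder report rows populate fully, or go undetermined when no test is possible", {
  sim <- simulate_colonization(scenario_config(seed = 5))
  rep <- founder_report(sim$dataset, "island", "spX", distance_km = 321)
  expect_s3_class(rep, "founder_report")
  expect_equal(rep$status, "ok")
  expect_equal(rep$main_source, sim$truth$true_source)
  expect_equal(rep$distance_km, 321)
  expect_true(rep$propagules >= 1)
  expect_true(all(c("population_diversity", "regional_diversity",
                    "marker_proportion") %in% names(rep)))

  # monomorphic species: no variation, no assignment possible -> undetermined
  b <- matrix(1L, 9, 3, dimnames = list(paste0("i", 1:9), paste0("L", 1:3)))
  pops <- rep(c("pi", "pa", "pb"), each = 3)
  mono <- marker_dataset(b, pops, rep(c("isl", "A", "B"), each = 3))
  rep0 <- founder_report(mono, "isl", "mono")
  expect_equal(rep0$status, "undetermined")
  expect_true(is.na(rep0$propagules))
  expect_true(is.na(rep0$main_source))
})
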
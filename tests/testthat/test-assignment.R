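test_that("band frequencies equal direct column tallies and smooth off the boundary", {
  ds <- toy_dataset()
  fit <- band_frequencies(ds)
  # region A, L1: 2/2 present -> smoothed 2/3; L2: 0/2 -> 1/3; L5: one NA -> 0/1 -> 1/2
  expect_equal(fit$raw["L1", "A"], 1)
  expect_equal(fit$freq["L1", "A"], 2 / 3)
  expect_equal(fit$freq["L2", "A"], 1 / 3)
  expect_equal(fit$n["L5", "A"], 1)
  expect_equal(fit$freq["L5", "A"], 1 / 2)
  expect_true(all(fit$freq > 0 & fit$freq < 1))

  # stated rule: 9 individuals all 0 at a locus -> 1/(9+1)
  b <- matrix(0L, 9, 2, dimnames = list(paste0("i", 1:9), c("L1", "L2")))
  b[, 2] <- 1L
  one <- marker_dataset(b, rep("p", 9), rep("A", 9))
  f1 <- band_frequencies(one)
  expect_equal(f1$freq["L1", "A"], 0.1)
  expect_equal(f1$freq["L2", "A"], 0.9)

  # random datasets: raw frequencies match per-column counting oracle
  for (seed in 41:43) {
    d <- random_dataset(seed, p_missing = 0.2)
    ft <- band_frequencies(d, level = "population")
    for (p in colnames(ft$raw)) {
      rows <- unname(d$population_of) == p
      expect_equal(unname(ft$raw[, p]),
                   unname(colMeans(d$bands[rows, , drop = FALSE] == 1L, na.rm = TRUE)))
    }
  }
})

test_that("an all-missing group x locus cell warns and gets a pseudo-frequency", {
  b <- rbind(a = c(1L, NA), b = c(0L, NA), c = c(1L, 1L))
  colnames(b) <- c("L1", "L2")
  ds <- marker_dataset(b, c("p1", "p1", "p2"), c("A", "A", "B"))
  expect_warning(fit <- band_frequencies(ds), "no scored individual")
  expect_equal(fit$freq["L2", "A"], 1 / 3)  # group of 2 -> 1/(2+1)
})

test_that("log10 likelihoods match a brute-force product oracle", {
  # single locus, band present, f = 0.5
  expect_equal(drop(log10_likelihood(1L, matrix(0.5))), log10(0.5))
  # two loci, bands (1,0), f = (0.1, 0.9)
  expect_equal(drop(log10_likelihood(c(1L, 0L), matrix(c(0.1, 0.9), ncol = 1))), -2)
  # missing loci are skipped
  expect_equal(drop(log10_likelihood(c(1L, NA), matrix(c(0.5, 0.9), ncol = 1))),
               log10(0.5))
  # 20-locus random cases against the direct product
  set.seed(99)
  for (rep in 1:10) {
    f <- matrix(runif(20 * 3, 0.02, 0.98), 20, 3,
                dimnames = list(paste0("L", 1:20), c("A", "B", "C")))
    x <- rbinom(20, 1, 0.5)
    ll <- log10_likelihood(x, f)
    oracle <- apply(f, 2, function(fc) log10(prod(ifelse(x == 1, fc, 1 - fc))))
    expect_equal(drop(ll), oracle, tolerance = 1e-12)
    expect_true(all(ll <= 0))
  }
  expect_error(log10_likelihood(1L, matrix(1)), "unsmoothed")
})

test_that("threshold semantics: inclusive boundary, ties never allocated", {
  # one locus, band present, f_A = 0.5, f_B = 0.05: gap exactly 1.0 -> assigned
  f <- matrix(c(0.5, 0.05), 1, 2, dimnames = list("L1", c("A", "B")))
  fit <- structure(list(freq = f, raw = f, n = f * 0 + 10,
                        level = "region", smoothing = "zero_replacement"),
                   class = "band_freq")
  expect_equal(unname(predict(fit, matrix(1L, 1, 1), mld = 1)), "A")
  # just under the threshold -> unassigned
  f2 <- matrix(c(0.5, 0.051), 1, 2, dimnames = list("L1", c("A", "B")))
  fit2 <- structure(list(freq = f2, raw = f2, n = f2 * 0 + 10,
                         level = "region", smoothing = "zero_replacement"),
                    class = "band_freq")
  expect_equal(unname(predict(fit2, matrix(1L, 1, 1), mld = 1)), "unassigned")
  # identical frequencies in all groups: every individual unassigned, any mld
  f3 <- matrix(0.4, 5, 3, dimnames = list(paste0("L", 1:5), c("A", "B", "C")))
  fit3 <- structure(list(freq = f3, raw = f3, n = f3 * 0 + 10,
                         level = "region", smoothing = "zero_replacement"),
                    class = "band_freq")
  x <- matrix(rbinom(25, 1, 0.5), 5, 5)
  expect_true(all(predict(fit3, x, mld = 0) == "unassigned"))
})

test_that("raising the threshold never increases the number of assigned individuals", {
  for (seed in 51:70) {
    sim <- simulate_colonization(scenario_config(seed = seed, n_loci = 40,
                                                 fst = 0.15))
    counts <- vapply(c(0, 0.5, 1, 2, 4), function(m) {
      a <- assign_sources(sim$dataset, "island", mld = m)
      sum(a$allocation != "unassigned")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("self-assignment: source individuals assign to their own region on average", {
  hits <- total <- 0
  for (seed in 71:75) {
    sim <- simulate_colonization(scenario_config(seed = seed, n_loci = 60))
    ds <- sim$dataset
    fit <- band_frequencies(ds[individual_region_test(ds) != "island"])
    for (r in c("R1", "R2", "R3")) {
      rows <- individual_region_test(ds) == r
      alloc <- predict(fit, ds$bands[rows, , drop = FALSE], mld = 0)
      assigned <- alloc[alloc != "unassigned"]
      hits <- hits + sum(assigned == r)
      total <- total + length(assigned)
    }
  }
  expect_gt(hits / total, 0.5)
})

test_that("allocation summary: proportions, main source, undetermined flag", {
  mk_asg <- function(alloc) {
    structure(list(loglik = NULL, allocation = alloc, mld = 1,
                   island = "isl", candidates = c("NOR", "RUS", "ICE")),
              class = "source_assignment")
  }
  s <- summary(mk_asg(c(rep("RUS", 7), rep("NOR", 3), rep("unassigned", 2))))
  expect_equal(s$status, "ok")
  expect_equal(unname(s$proportions[c("RUS", "NOR")]), c(0.7, 0.3))
  expect_equal(sum(s$proportions), 1)
  expect_equal(s$main_source, "RUS")
  expect_equal(s$sources_allocation, 2)

  expect_equal(summary(mk_asg(rep("unassigned", 4)))$status, "undetermined")

  # three or more receiving regions must be representable
  s3 <- summary(mk_asg(c("A", "A", "B", "C", "D")))
  expect_equal(s3$sources_allocation, 4)
  # tie: alphabetically first wins, with a message
  expect_message(st <- summary(mk_asg(c("B", "A"))), "tie")
  expect_equal(st$main_source, "A")
})

test_that("assignment refuses degenerate candidate sets", {
  b <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  colnames(b) <- c("L1", "L2")
  ds <- marker_dataset(b, c("p1", "p2", "p2"), c("isl", "src", "src"))
  expect_error(assign_sources(ds, "isl"), "at least two candidate")
  expect_error(assign_sources(ds, "elsewhere"), "unknown island")
})
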
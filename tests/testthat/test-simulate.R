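test_that("allele-frequency draws are valid simplex vectors with the Dirichlet mean", {
  expect_equal(sample_allele_frequencies(1), 1)
  p <- sample_allele_frequencies(8, seed = 3)
  expect_length(p, 8)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sample_allele_frequencies(8, seed = 3), p)  # reproducible
  expect_error(sample_allele_frequencies(0), "k must be")

  # Monte-Carlo check of the symmetric Dirichlet mean 1/k
  set.seed(11)
  draws <- replicate(10000, sample_allele_frequencies(4)[1])
  expect_equal(mean(draws), 1 / 4, tolerance = 0.01)
})

test_that("iso-length variant splits conserve frequency and collapse back exactly", {
  p <- c("9" = 0.4, "10" = 0.35, "11.3" = 0.25)
  out1 <- split_into_sequence_variants(p, period = 4, n_variants = 1)
  expect_equal(as.numeric(out1), as.numeric(p))

  out <- split_into_sequence_variants(p, period = 4, n_variants = c(2, 3, 2),
                                      seed = 9)
  ce <- attr(out, "ce")
  expect_equal(as.numeric(tapply(as.numeric(out), ce, sum)[names(p)]),
               as.numeric(p), tolerance = 1e-12)
  expect_equal(unname(vapply(names(out), collapse_to_length, character(1),
                             period = 4)), unname(ce))
  expect_error(split_into_sequence_variants(p, 4, n_variants = 0), ">= 1")

  # a 13-allele marker split ~4 ways lands in the ~300% growth class
  p13 <- stats::setNames(rep(1 / 13, 13), as.character(8:20))
  big <- split_into_sequence_variants(p13, period = 4, n_variants = 4,
                                      seed = 2)
  growth <- 100 * (length(big) - 13) / 13
  expect_gte(growth, 250)
  expect_lte(growth, 333.34)
})

test_that("diploid simulation reproduces Hardy-Weinberg and inbreeding heterozygosity", {
  p <- c(A = 0.5, B = 0.5)
  g0 <- simulate_autosomal_genotypes(p, 20000, f = 0, seed = 4)
  expect_equal(mean(g0[, 1] != g0[, 2]), 0.5, tolerance = 0.015)
  g2 <- simulate_autosomal_genotypes(p, 20000, f = 0.2, seed = 4)
  expect_equal(mean(g2[, 1] != g2[, 2]), 0.4, tolerance = 0.015)
  expect_error(simulate_autosomal_genotypes(p, 10, f = 1), "f must be")
})

test_that("Y haplotype simulation respects copy number, dependence and bounds", {
  freqs <- list(YS1 = c("12" = 1), YMC = c("14" = 0.5, "17" = 0.5))
  classes <- c(YS1 = "y_single", YMC = "y_multicopy", AM1 = "autosomal")
  periods <- c(YS1 = 4L, YMC = 4L)
  yh <- simulate_y_haplotypes(freqs, 10, classes, periods, founders = NULL,
                              mu = 0, seed = 1)
  expect_equal(unique(yh$YS1), "12")
  expect_true(all(vapply(strsplit(yh$YMC, ","), length, integer(1)) == 2))
  # multi-copy cells are sorted, so (17,14) never appears
  expect_true(all(yh$YMC %in% c("14,14", "14,17", "17,17")))
  expect_error(simulate_y_haplotypes(list(AM1 = c("9" = 1)), 5, classes,
                                     periods), "non-Y")

  # founder model: haplotype count bounded by lineages and near the
  # occupancy expectation for uniform founder assignment
  k <- 6  # enough loci/alleles that founder haplotypes are all distinct
  fr <- lapply(stats::setNames(paste0("L", 1:k), paste0("L", 1:k)),
               function(m) stats::setNames(rep(0.05, 20),
                                           as.character(10:29)))
  cl <- stats::setNames(rep("y_single", k), paste0("L", 1:k))
  pe <- stats::setNames(rep(4L, k), paste0("L", 1:k))
  n <- 547; founders <- 400
  yh2 <- simulate_y_haplotypes(fr, n, cl, pe, founders = founders, mu = 0,
                               seed = 21)
  hap <- do.call(paste, yh2)
  # occupancy: expected distinct founders drawn in n uniform draws
  expected <- founders * (1 - (1 - 1 / founders)^n)
  expect_lte(length(unique(hap)), founders)
  expect_equal(length(unique(hap)), expected, tolerance = 0.05)
})

test_that("population simulation is seed-reproducible and HWE-consistent", {
  a <- simulate_str_population(n_samples = 30, n_males = 20, seed = 77)
  b <- simulate_str_population(n_samples = 30, n_males = 20, seed = 77)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_str_population(n_samples = 30, n_males = 20, seed = 78)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  expect_true(all(is.na(c$DYS19[c$sex == "F"])))
  # truth sidecar frequencies collapse consistently
  tr <- attr(a, "truth")
  m <- names(tr$freq_sequence)[1]
  per <- attr(a, "panel")$period[1]
  ce <- vapply(names(tr$freq_sequence[[m]]), collapse_to_length,
               character(1), period = per)
  expect_equal(sort(as.numeric(tapply(as.numeric(tr$freq_sequence[[m]]),
                                      ce, sum))),
               sort(as.numeric(tr$freq_length[[m]])), tolerance = 1e-12)
})

test_that("direct-counting frequencies converge to the generating truth", {
  sim <- simulate_str_population(n_samples = 800, n_males = 2,
                                 panel = small_panel()[1:2, ], seed = 31)
  tr <- attr(sim, "truth")
  ft <- allele_frequencies(sim, level = "sequence")
  for (m in c("AM1", "AM2")) {
    est <- ft[ft$marker == m, ]
    truth <- tr$freq_sequence[[m]]
    dev <- abs(est$frequency - truth[est$allele])
    expect_lt(max(dev), 0.05)
  }
})

test_that("Balding-Nichols divergence vanishes as f_div approaches zero", {
  div <- simulate_diverged_populations(n_pops = 2, f_div = 1e-4,
                                       n_per_pop = 200,
                                       panel = small_panel()[1:4, ],
                                       seed = 13)
  th <- pairwise_fst(div$tables)
  expect_lt(th["pop1", "pop2"], 0.02)
  expect_error(simulate_diverged_populations(f_div = 0), "f_div")
})
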
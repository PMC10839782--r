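make_pop <- function(freqs, n, seed, panel) {
  strpopgen:::with_seed(seed,
    strpopgen:::build_population_table(panel, freqs, n, n,
                                       founders = NULL, mu = 0))
}

test_that("Fst of a population against itself is ~0 and under permutation ~0", {
  panel <- small_panel()[1:4, ]
  fr <- lapply(stats::setNames(panel$marker, panel$marker), function(m)
    stats::setNames(sample_allele_frequencies(6, seed = match(m, panel$marker)),
                    as.character(7:12)))
  a <- make_pop(fr, 150, 1, panel)
  b <- make_pop(fr, 150, 2, panel)  # same frequencies, independent draw
  th <- pairwise_fst(list(A = a, B = b))
  expect_equal(th["A", "A"], 0)
  expect_lt(abs(attr(th, "raw")["A", "B"]), 0.01)
  # clamped matrix is non-negative and symmetric
  expect_true(all(th >= 0))
  expect_equal(unclass(th)[1:2, 1:2], t(unclass(th)[1:2, 1:2]))
})

test_that("Weir-Cockerham theta recovers the Balding-Nichols truth", {
  div <- simulate_diverged_populations(n_pops = 2, f_div = 0.05,
                                       n_per_pop = 500,
                                       panel = default_panel()[1:15, ],
                                       seed = 101)
  th <- pairwise_fst(div$tables)
  expect_equal(th["pop1", "pop2"], 0.05, tolerance = 0.6)  # single replicate
  expect_gt(th["pop1", "pop2"], 0.01)
})

test_that("Fst is invariant under allele relabeling", {
  panel <- small_panel()[1:2, ]
  fr <- lapply(stats::setNames(panel$marker, panel$marker), function(m)
    stats::setNames(c(0.5, 0.3, 0.2), c("8", "9", "10")))
  a <- make_pop(fr, 80, 3, panel)
  b <- make_pop(lapply(fr, function(p) stats::setNames(rev(p), names(p))),
                80, 4, panel)
  th1 <- pairwise_fst(list(A = a, B = b))["A", "B"]
  # relabel alleles consistently in both tables: 8->x, 9->y, 10->z
  relab <- function(t) {
    df <- as.data.frame(t)
    for (cl in c("AM1_1", "AM1_2", "AM2_1", "AM2_2"))
      df[[cl]] <- c("8" = "x", "9" = "y", "10" = "z")[df[[cl]]]
    genotype_table(df, panel, level = "length")
  }
  th2 <- pairwise_fst(list(A = relab(a), B = relab(b)))["A", "B"]
  expect_equal(th1, th2, tolerance = 1e-12)
})

test_that("Rst is 1 for fixed differences and invariant under affine count transforms", {
  x <- list(P = matrix(10, 30, 1, dimnames = list(NULL, "YS1")),
            Q = matrix(20, 30, 1, dimnames = list(NULL, "YS1")))
  r <- pairwise_rst(x)
  expect_equal(r["P", "Q"], 1)
  expect_equal(r["P", "P"], 0)

  set.seed(61)
  y <- list(P = matrix(sample(8:14, 60, TRUE), 30, 2,
                       dimnames = list(NULL, c("L1", "L2"))),
            Q = matrix(sample(10:16, 60, TRUE), 30, 2,
                       dimnames = list(NULL, c("L1", "L2"))))
  r1 <- pairwise_rst(y)["P", "Q"]
  y2 <- lapply(y, function(m) 3 * m + 7)
  r2 <- pairwise_rst(y2)["P", "Q"]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("identical populations give Rst 0; microvariants map to integer part or exclude the locus", {
  m <- matrix(c(10, 11, 10, 11), 4, 1, dimnames = list(NULL, "YS1"))
  r <- pairwise_rst(list(A = m, B = m))
  expect_equal(r["A", "B"], 0)

  df <- data.frame(sample_id = sprintf("m%d", 1:6), sex = "M",
                   YS1 = c("9.3", "9.3", "10", "9", "9.3", "10"),
                   YS2 = c("20", "21", "20", "21", "20", "21"),
                   stringsAsFactors = FALSE)
  t1 <- genotype_table(df, small_panel()[5:6, ], level = "length")
  rc_int <- repeat_counts(t1)
  expect_equal(unname(rc_int[1, "YS1"]), 9)
  rc_excl <- repeat_counts(t1, microvariant = "exclude")
  expect_equal(colnames(rc_excl), "YS2")
  expect_error(repeat_counts(t1, loci = "YMC"), "unknown")
  expect_error(repeat_counts(tiny_table(), loci = "YMC"), "single-copy")
})

test_that("Rst grows stochastically with the generative divergence", {
  panel <- default_panel()
  panel <- panel[panel$class == "y_single", ][1:10, ]
  rst_at <- function(fd, seed) {
    div <- simulate_diverged_populations(n_pops = 2, f_div = fd,
                                         n_per_pop = 150, panel = panel,
                                         seed = seed)
    pairwise_rst(div$tables)["pop1", "pop2"]
  }
  lo <- vapply(1:5, function(s) rst_at(0.01, 200 + s), numeric(1))
  hi <- vapply(1:5, function(s) rst_at(0.15, 300 + s), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("nearest populations rank ascending with lexical tie-breaks", {
  m <- matrix(c(0, .1, .3, .1, 0, .2, .3, .2, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nn <- nearest_populations(m, "C")
  expect_equal(nn$population, c("B", "A"))
  # star topology: equidistant neighbours tie-broken lexically
  s <- matrix(0.2, 4, 4, dimnames = list(c("Z", "Y", "X", "F"),
                                         c("Z", "Y", "X", "F")))
  diag(s) <- 0
  expect_equal(nearest_populations(s, "F")$population, c("X", "Y", "Z"))
  expect_equal(nrow(nearest_populations(s, "F", k = 2)), 2)
  expect_error(nearest_populations(s, "Q"), "not in matrix")
})

test_that("frequency-only Fst fallback behaves like a distance and vanishes for identical spectra", {
  fr <- list(L1 = c("8" = 0.6, "9" = 0.4), L2 = c("10" = 0.5, "11" = 0.5))
  fr2 <- list(L1 = c("8" = 0.2, "9" = 0.8), L2 = c("10" = 0.9, "11" = 0.1))
  d <- pairwise_fst_freq(list(A = fr, B = fr, C = fr2),
                         n_list = c(A = 100, B = 100, C = 100))
  expect_lt(d["A", "B"], d["A", "C"])
  expect_equal(attr(d, "estimator"), "Nei coancestry (frequency-only)")
})
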
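test_that("direct counting gives integer-count frequencies over typed gene copies", {
  tab <- tiny_table()
  ft <- allele_frequencies(tab, "AM3", level = "length")
  p <- ft[ft$marker == "AM3", ]
  expect_equal(sort(p$allele), c("7", "8"))
  expect_equal(sum(p$frequency), 1, tolerance = 1e-12)
  expect_equal(p$frequency[p$allele == "7"], 4 / 8)
  expect_equal(unname(attr(ft, "gene_count")["AM3"]), 8L)

  # two samples AA and AB
  df <- data.frame(sample_id = c("a", "b"), sex = c("F", "F"),
                   AM1_1 = c("9", "9"), AM1_2 = c("9", "10"),
                   stringsAsFactors = FALSE)
  t2 <- genotype_table(df, small_panel()[1, ], level = "length")
  p2 <- allele_frequencies(t2, "AM1")
  expect_equal(stats::setNames(p2$frequency, p2$allele),
               c("10" = 0.25, "9" = 0.75))

  # monomorphic marker
  pm <- allele_frequencies(tab, "AM4")
  expect_equal(pm$frequency[pm$marker == "AM4"], 1)
})

test_that("observed heterozygosity is the typed heterozygote fraction", {
  tab <- tiny_table()
  expect_equal(observed_heterozygosity(tab, "AM1"), 0.5)
  expect_equal(observed_heterozygosity(tab, "AM4"), 0)
  expect_error(observed_heterozygosity(tab, "YS1"), "haploid")
})

test_that("expected heterozygosity matches the closed form and the pair-sum oracle", {
  expect_equal(expected_heterozygosity(1, gene_count = 10), 0)
  expect_equal(expected_heterozygosity(c(0.5, 0.5), 100), 100 / 99 * 0.5)
  expect_error(expected_heterozygosity(c(1), 1), "gene_count")
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:12, 1)
    p <- sample_allele_frequencies(k)
    g <- sample(10:500, 1)
    expect_equal(expected_heterozygosity(p, g), brute_gene_diversity(p, g),
                 tolerance = 1e-12)
  }
})

test_that("PIC matches Botstein's closed form and the double-loop oracle", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  set.seed(9)
  for (i in 1:20) {
    p <- sample_allele_frequencies(sample(2:10, 1))
    expect_equal(pic(p), brute_pic(p), tolerance = 1e-12)
  }
})

test_that("match probability sums squared genotype frequencies; PD is its exact complement", {
  tab <- tiny_table()
  # AM2 genotypes: 12/13, 13/13, 12/12, 14/14 all distinct -> PM = 1/n
  expect_equal(match_probability(tab, "AM2"), 4 * (1 / 4)^2)
  expect_equal(match_probability(tab, "AM4"), 1)  # one shared genotype
  expect_equal(power_of_discrimination(tab, "AM4"), 0)
  sim <- simulate_str_population(60, 2, panel = small_panel()[1:4, ],
                                 seed = 14)
  for (m in c("AM1", "AM2")) {
    expect_identical(power_of_discrimination(sim, m),
                     1 - match_probability(sim, m))
  }
})

test_that("PE and TPI follow their heterozygosity formulas and are monotone", {
  expect_equal(power_of_exclusion(0), 0)
  expect_equal(typical_paternity_index(0.5), 1)
  expect_error(typical_paternity_index(1), "undefined")
  h <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(power_of_exclusion(h)) > 0))
  expect_true(all(diff(typical_paternity_index(h)) > 0))
})

test_that("combined powers equal the brute-force product within double precision", {
  one <- data.frame(PE = 0.3, PD = 0.8)
  cp1 <- combined_powers(one)
  expect_equal(cp1$CPD, 0.8)
  expect_equal(combined_powers(data.frame(PE = 0, PD = c(0.9, 0.9)))$CPD,
               0.99)
  set.seed(10)
  pe <- runif(52, 0.3, 0.95); pd <- runif(52, 0.7, 0.999)
  cp <- combined_powers(data.frame(PE = pe, PD = pd))
  expect_equal(cp$residual_CPE, prod(1 - pe), tolerance = 1e-12)
  expect_equal(cp$residual_CPD, prod(1 - pd), tolerance = 1e-12)
  expect_equal(cp$CPE, 1 - prod(1 - pe), tolerance = 1e-12)
  expect_true(cp$residual_CPD > 0 && cp$residual_CPD <= 1)
})

test_that("residual formatting follows the published scientific-notation style", {
  expect_equal(strpopgen:::format_residual(5.077962e-21), "5.0779620E-21")
  expect_equal(strpopgen:::format_residual(3.257436e-24, digits = 6),
               "3.257436E-24")
})

test_that("sequence resolution never reduces discrimination", {
  sim <- simulate_str_population(n_samples = 120, n_males = 2,
                                 panel = small_panel()[1:4, ], seed = 19)
  for (m in paste0("AM", 1:4)) {
    expect_gte(power_of_discrimination(sim, m, level = "sequence"),
               power_of_discrimination(sim, m, level = "length") - 1e-12)
  }
})
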
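# Genotype-array log-probability under the exact conditional distribution
# given allele counts: proportional to 2^h / prod(genotype counts!), with h
# the number of heterozygous individuals. Constant terms are dropped since
# only comparisons within one allele-count margin matter.
geno_log_score <- function(het, counts) {
  het * log(2) - sum(lgamma(counts + 1))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Tests a diploid marker's genotype array against Hardy-Weinberg
#' proportions conditionally on the observed allele counts. The p-value is
#' the probability, under the exact conditional distribution of genotype
#' arrays given allele counts, of arrays whose conditional probability does
#' not exceed that of the observed array. For biallelic markers the
#' distribution is fully enumerated; for more alleles a Monte-Carlo version
#' shuffles the gene array (`n_permutations` replicates, seeded).
#' Monomorphic markers return `p = 1` by convention.
#'
#' @param genotypes Either an `n x 2` character matrix of allele labels, or
#'   a named integer vector of genotype counts with `"A/B"`-style names.
#' @param n_permutations Monte-Carlo replicates when enumeration is not
#'   used.
#' @param seed Optional seed for the Monte-Carlo path.
#' @return List of class `hwe_result`: `p_value`, `method` (`"enumeration"`,
#'   `"monte_carlo"` or `"monomorphic"`), `n_permutations`, `seed`.
#' @examples
#' hwe_exact_test(c("A/A" = 1, "A/B" = 2, "B/B" = 1))
#' @export
hwe_exact_test <- function(genotypes, n_permutations = 17000, seed = NULL) {
  if (is.matrix(genotypes)) {
    g <- genotypes[stats::complete.cases(genotypes), , drop = FALSE]
    if (nrow(g) < 2) stop("need >= 2 typed samples")
    pairs <- cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
  } else {
    stopifnot(!is.null(names(genotypes)), all(genotypes >= 0))
    ab <- strsplit(names(genotypes), "/", fixed = TRUE)
    if (any(lengths(ab) != 2)) stop("genotype names must be 'A/B'")
    ab <- do.call(rbind, ab)
    pairs <- cbind(pmin(ab[, 1], ab[, 2]), pmax(ab[, 1], ab[, 2]))
    pairs <- pairs[rep(seq_len(nrow(pairs)), genotypes), , drop = FALSE]
    if (nrow(pairs) < 2) stop("need >= 2 typed samples")
  }
  alleles <- sort(unique(as.vector(pairs)))
  k <- length(alleles)
  res <- if (k == 1L) {
    list(p_value = 1, method = "monomorphic", n_permutations = NA_integer_)
  } else if (k == 2L) {
    list(p_value = hwe_enumerate_biallelic(pairs, alleles),
         method = "enumeration", n_permutations = NA_integer_)
  } else {
    list(p_value = hwe_monte_carlo(pairs, alleles, n_permutations, seed),
         method = "monte_carlo", n_permutations = as.integer(n_permutations))
  }
  res$seed <- seed
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE exact test: p = %.6g (%s%s)\n", x$p_value, x$method,
              if (x$method == "monte_carlo")
                sprintf(", %d permutations", x$n_permutations) else ""))
  invisible(x)
}

# Full enumeration over heterozygote counts for two alleles (Levene's
# conditional distribution).
hwe_enumerate_biallelic <- function(pairs, alleles) {
  copies <- as.vector(pairs)
  nA <- sum(copies == alleles[1])
  nB <- sum(copies == alleles[2])
  h_obs <- sum(pairs[, 1] != pairs[, 2])
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(hs, function(h)
    geno_log_score(h, c((nA - h) / 2, h, (nB - h) / 2)), numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(h_obs, hs)] * (1 + 1e-12)])
}

# Monte-Carlo exact test: shuffle the 2n gene copies, re-pair, and compare
# conditional probabilities of the resulting genotype arrays.
hwe_monte_carlo <- function(pairs, alleles, n_permutations, seed) {
  n <- nrow(pairs)
  k <- length(alleles)
  code <- matrix(match(pairs, alleles), ncol = 2)
  key_obs <- (pmin(code[, 1], code[, 2]) - 1L) * k +
    pmax(code[, 1], code[, 2])
  obs <- geno_log_score(sum(code[, 1] != code[, 2]),
                        tabulate(key_obs, nbins = k * k))
  genes <- as.vector(code)
  with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample(genes)
      a1 <- perm[seq_len(n)]; a2 <- perm[n + seq_len(n)]
      key <- (pmin(a1, a2) - 1L) * k + pmax(a1, a2)
      sc <- geno_log_score(sum(a1 != a2), tabulate(key, nbins = k * k))
      if (sc <= obs + 1e-9) hits <- hits + 1L
    }
    (1 + hits) / (n_permutations + 1)
  })
}

#' Hardy-Weinberg tests across a genotype table with Bonferroni correction
#'
#' Runs [hwe_exact_test()] on every autosomal marker at the requested
#' resolution and applies the Bonferroni threshold `alpha / m` over the
#' `m` tested markers.
#'
#' @param tab A `genotype_table`.
#' @param level Analysis level.
#' @param markers Autosomal markers (default: all).
#' @param alpha Family-wise significance level.
#' @param n_permutations,seed Passed to [hwe_exact_test()]; marker `i` uses
#'   seed `seed + i` so results are reproducible yet independent.
#' @return data.frame with columns `marker`, `p_value`, `method`,
#'   `n_permutations`, `threshold`, `flagged` (p below threshold).
#' @export
hwe_test <- function(tab, level = c("sequence", "length"), markers = NULL,
                     alpha = 0.05, n_permutations = 17000, seed = NULL) {
  level <- match.arg(level)
  tabl <- at_level(tab, level)
  panel <- attr(tabl, "panel")
  if (is.null(markers)) markers <- panel$marker[panel$class == "autosomal"]
  res <- lapply(seq_along(markers), function(i) {
    r <- hwe_exact_test(marker_genotypes(tabl, markers[i]),
                        n_permutations = n_permutations,
                        seed = if (is.null(seed)) NULL else seed + i)
    data.frame(marker = markers[i], p_value = r$p_value, method = r$method,
               n_permutations = r$n_permutations, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  bf <- bonferroni(out$p_value, alpha = alpha)
  out$threshold <- bf$threshold
  out$flagged <- bf$flagged
  out
}

#' Bonferroni correction
#'
#' Flags p-values below `alpha / m`, the family-wise threshold for `m`
#' simultaneous tests.
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Family-wise significance level.
#' @return List with `threshold` (`alpha/m`), `flagged` (logical vector),
#'   `m`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  stopifnot(m >= 1)
  list(threshold = alpha / m, flagged = p_values < alpha / m, m = m)
}
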
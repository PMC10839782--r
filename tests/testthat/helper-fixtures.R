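# Small in-code fixtures shared across test files.

# A compact panel: 4 autosomal, 3 single-copy Y, 1 multi-copy Y.
small_panel <- function() {
  data.frame(
    marker = c("AM1", "AM2", "AM3", "AM4", "YS1", "YS2", "YS3", "YMC"),
    class = c(rep("autosomal", 4), rep("y_single", 3), "y_multicopy"),
    period = c(4L, 4L, 3L, 5L, 4L, 4L, 3L, 4L),
    stringsAsFactors = FALSE)
}

# Hand-written 4-sample table at length level over small_panel().
tiny_table <- function() {
  df <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    sex = c("M", "M", "M", "F"),
    AM1_1 = c("9", "9", "10", "9"), AM1_2 = c("9", "10", "10", "9.3"),
    AM2_1 = c("12", "13", "12", "14"), AM2_2 = c("13", "13", "12", "14"),
    AM3_1 = c("7", "7", "8", "7"), AM3_2 = c("7", "8", "8", "8"),
    AM4_1 = c("11", "11", "11", "11"), AM4_2 = c("11", "11", "11", "11"),
    YS1 = c("14", "15", "14", NA), YS2 = c("20", "20", "21", NA),
    YS3 = c("9", "9", "9", NA), YMC = c("14,17", "17,14", "15,17", NA),
    stringsAsFactors = FALSE)
  genotype_table(df, small_panel(), level = "length")
}

# Brute-force oracles, independent of the package's formulas.
brute_pic <- function(p) {
  k <- length(p)
  acc <- 1 - sum(p^2)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i) acc <- acc - 2 * p[i]^2 * p[j]^2
  }
  acc
}

brute_gene_diversity <- function(p, g) {
  # sum over ordered pairs of distinct alleles, with the g/(g-1) correction
  acc <- 0
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i != j) acc <- acc + p[i] * p[j]
  }
  g / (g - 1) * acc
}

# Exhaustive conditional HWE p-value for a genotype count matrix given
# allele counts: enumerate all genotype arrays with the observed allele
# margins by depth-first search over the k x k lower triangle.
brute_hwe_p <- function(counts_mat) {
  # counts_mat: genotype counts in the lower triangle (upper must be 0)
  k <- nrow(counts_mat)
  stopifnot(all(counts_mat[upper.tri(counts_mat)] == 0))
  allele_counts <- sapply(seq_len(k), function(a)
    2 * counts_mat[a, a] + sum(counts_mat[a, -a]) + sum(counts_mat[-a, a]))
  cells <- which(lower.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  logprob <- function(cnt) {
    h <- sum(cnt[cells[, 1] != cells[, 2]])
    h * log(2) - sum(lgamma(cnt + 1))
  }
  obs <- logprob(counts_mat[cells])
  probs <- c(); scores <- c()
  rec <- function(idx, cnt, rem) {
    if (idx > nrow(cells)) {
      if (all(rem == 0)) {
        scores <<- c(scores, logprob(cnt))
      }
      return(invisible())
    }
    a <- cells[idx, 1]; b <- cells[idx, 2]
    mx <- if (a == b) rem[a] %/% 2 else min(rem[a], rem[b])
    for (v in 0:mx) {
      cnt2 <- cnt; cnt2[idx] <- v
      rem2 <- rem
      if (a == b) rem2[a] <- rem2[a] - 2 * v
      else { rem2[a] <- rem2[a] - v; rem2[b] <- rem2[b] - v }
      rec(idx + 1, cnt2, rem2)
    }
  }
  rec(1, numeric(nrow(cells)), allele_counts)
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  sum(w[scores <= obs + 1e-9])
}
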
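# Evaluate code under a temporary RNG state so seeded generators do not
# disturb (or depend on) the caller's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) { # shapes so tiny every draw underflowed
    g <- as.numeric(alpha == max(alpha))
  }
  g / sum(g)
}

#' Draw a random allele-frequency vector
#'
#' Symmetric Dirichlet draw over `k` alleles; the workhorse for building
#' synthetic marker panels. Smaller `concentration` gives more skewed
#' spectra (a few common alleles plus rare ones), as real STR loci show.
#'
#' @param k Number of alleles (>= 1).
#' @param concentration Dirichlet concentration per allele (default 1).
#' @param seed Optional integer seed; the draw is then reproducible and the
#'   caller's RNG state is untouched.
#' @return Numeric vector of length `k`, strictly positive, summing to 1.
#' @export
sample_allele_frequencies <- function(k, concentration = 1, seed = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (k == 1) return(1)
  with_seed(seed, {
    p <- rdirichlet1(rep(concentration, k))
    # keep every allele representable: nudge exact zeros up to a floor
    p <- pmax(p, 1e-12)
    p / sum(p)
  })
}

# Motif pools used to compose iso-length sequence variants.
motif_pool <- function(period) {
  switch(as.character(period),
         "2" = c("CA", "GT", "AC", "TG"),
         "3" = c("TCT", "ATT", "AAG", "TCC", "ATA"),
         "4" = c("TCTA", "TCTG", "AGAT", "AGAC", "GATA", "TAGA"),
         "5" = c("AAAGA", "AAAGG", "TCTTT", "AGAAA", "GAAAA"),
         "6" = c("AGTACA", "AGTACG", "ACTGCA", "ACTGCG"),
         stop("period must be 2..6"))
}

# Distinct bracket-notation strings whose CE designation equals `ce`.
# Variants differ in how the total repeat count is split across two motifs
# (and, beyond that, in which motif pair is used). Returns at most the
# number of distinct structures available.
make_iso_variants <- function(ce, period, n) {
  parts <- strsplit(as.character(ce), ".", fixed = TRUE)[[1]]
  m <- as.integer(parts[1])
  flen <- if (length(parts) > 1) as.integer(parts[2]) else 0L
  pool <- motif_pool(period)
  partial <- if (flen > 0) substr(pool[1], 1, flen) else ""
  out <- character(0)
  for (alt in pool[-1]) {          # vary the second motif, then the split
    for (b in 0:(m - 1)) {
      a <- m - b
      s <- if (b == 0) sprintf("[%s]%d", pool[1], a)
           else sprintf("[%s]%d[%s]%d", pool[1], a, alt, b)
      if (nzchar(partial)) s <- paste(s, partial)
      out <- c(out, s)
      if (length(unique(out)) >= n) return(unique(out)[seq_len(n)])
    }
  }
  unique(out)
}

#' Split length-allele frequencies into iso-length sequence variants
#'
#' Partitions each CE allele's frequency across one or more sequence
#' variants sharing that CE designation, emulating the nesting of
#' sequence-level alleles inside length-level alleles that MPS typing
#' reveals. Collapsing the output back to length level recovers the input
#' exactly.
#'
#' @param freqs Named numeric frequency vector; names are CE labels.
#' @param period Marker repeat-unit length (for composing variant motifs).
#' @param n_variants Integer vector (recycled) of variants per length
#'   allele, all >= 1; or `NULL` to draw `1 + rpois(lambda)` per allele.
#' @param lambda Poisson mean for the default variant-count draw.
#' @param concentration Dirichlet concentration for the within-allele split.
#' @param seed Optional seed.
#' @return Named numeric vector over bracket-notation labels summing to 1,
#'   with attribute `"ce"` giving each variant's parent CE label.
#' @export
split_into_sequence_variants <- function(freqs, period, n_variants = NULL,
                                         lambda = 0.8, concentration = 5,
                                         seed = NULL) {
  stopifnot(is.numeric(freqs), !is.null(names(freqs)))
  if (!is.null(n_variants) && any(n_variants < 1))
    stop("n_variants must all be >= 1")
  with_seed(seed, {
    k <- length(freqs)
    nv <- if (is.null(n_variants)) 1L + stats::rpois(k, lambda)
          else rep_len(as.integer(n_variants), k)
    labels <- character(0); values <- numeric(0); parent <- character(0)
    for (i in seq_len(k)) {
      vars <- make_iso_variants(names(freqs)[i], period, nv[i])
      w <- if (length(vars) == 1) 1 else rdirichlet1(rep(concentration, length(vars)))
      labels <- c(labels, vars)
      values <- c(values, freqs[i] * w)
      parent <- c(parent, rep(names(freqs)[i], length(vars)))
    }
    out <- stats::setNames(values, labels)
    attr(out, "ce") <- stats::setNames(parent, labels)
    out
  })
}

#' Simulate diploid genotypes at one marker
#'
#' Draws `n` genotypes from allele frequencies `freqs`. With inbreeding
#' coefficient `f = 0` the two gene copies are independent (Hardy-Weinberg);
#' with `f > 0` the second copy duplicates the first with probability `f`,
#' giving the homozygote excess P(aa) = p^2 + f p (1 - p).
#'
#' @param freqs Named numeric frequency vector.
#' @param n Number of individuals.
#' @param f Inbreeding coefficient in `[0, 1)`.
#' @param seed Optional seed.
#' @return Character matrix `n x 2` of allele labels.
#' @export
simulate_autosomal_genotypes <- function(freqs, n, f = 0, seed = NULL) {
  stopifnot(n >= 1)
  if (f < 0 || f >= 1) stop("f must be in [0, 1)")
  labels <- names(freqs)
  with_seed(seed, {
    a1 <- sample(labels, n, replace = TRUE, prob = freqs)
    a2 <- sample(labels, n, replace = TRUE, prob = freqs)
    dup <- stats::runif(n) < f
    a2[dup] <- a1[dup]
    cbind(a1, a2, deparse.level = 0)
  })
}

# Single stepwise-mutation move on an allele label: +/-1 repeat on the
# integer part (CE labels) or on the last motif block (bracket labels).
step_mutation <- function(label, period) {
  if (is_ce_label(label)) {
    parts <- strsplit(label, ".", fixed = TRUE)[[1]]
    i <- as.integer(parts[1])
    i <- max(2L, i + sample(c(-1L, 1L), 1))
    if (length(parts) > 1) paste0(i, ".", parts[2]) else as.character(i)
  } else {
    s <- parse_bracket_notation(label, period)
    j <- nrow(s$blocks)
    s$blocks$count[j] <- max(1L, s$blocks$count[j] + sample(c(-1L, 1L), 1))
    emit_bracket_notation(s)
  }
}

#' Simulate Y-STR haplotypes for a male cohort
#'
#' Either draws loci independently from per-locus frequencies, or (default)
#' uses a founder-lineage model: `founders` founder haplotypes are drawn
#' locus-wise from the frequencies, each male copies a random founder, and
#' each gene copy then mutates by a single repeat step with probability
#' `mu`. Founder sharing creates the between-locus dependence real Y data
#' show; independent loci would overstate haplotype diversity.
#'
#' @param freqs_list Named list: Y marker -> named frequency vector.
#' @param n_males Number of males.
#' @param classes Named character vector: marker -> `"y_single"` or
#'   `"y_multicopy"` (multi-copy units get an unordered allele pair).
#' @param periods Named integer vector: marker -> repeat period.
#' @param founders Number of founder lineages, or `NULL` for independent
#'   loci.
#' @param mu Per-copy single-step mutation probability.
#' @param seed Optional seed.
#' @return data.frame of `n_males` rows, one column per marker; multi-copy
#'   cells are comma-joined sorted pairs.
#' @export
simulate_y_haplotypes <- function(freqs_list, n_males, classes, periods,
                                  founders = 400, mu = 0.002, seed = NULL) {
  stopifnot(n_males >= 1)
  markers <- names(freqs_list)
  if (any(!classes[markers] %in% c("y_single", "y_multicopy")))
    stop("freqs_list contains non-Y markers")
  with_seed(seed, {
    draw_col <- function(m, n) {
      p <- freqs_list[[m]]
      ncopy <- if (classes[[m]] == "y_multicopy") 2L else 1L
      cells <- replicate(n, {
        a <- sample(names(p), ncopy, replace = TRUE, prob = p)
        paste(a, collapse = ",")
      })
      cells
    }
    base <- if (is.null(founders)) {
      as.data.frame(lapply(stats::setNames(markers, markers),
                           function(m) draw_col(m, n_males)),
                    check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      fd <- as.data.frame(lapply(stats::setNames(markers, markers),
                                 function(m) draw_col(m, founders)),
                          check.names = FALSE, stringsAsFactors = FALSE)
      fd[sample.int(founders, n_males, replace = TRUE), , drop = FALSE]
    }
    rownames(base) <- NULL
    if (mu > 0) {
      for (m in markers) {
        per <- periods[[m]]
        base[[m]] <- vapply(base[[m]], function(cell) {
          parts <- strsplit(cell, ",", fixed = TRUE)[[1]]
          hit <- stats::runif(length(parts)) < mu
          parts[hit] <- vapply(parts[hit], step_mutation, character(1),
                               period = per)
          paste(parts, collapse = ",")
        }, character(1), USE.NAMES = FALSE)
      }
    }
    for (m in markers[classes[markers] == "y_multicopy"])
      base[[m]] <- vapply(base[[m]], normalize_multicopy, character(1),
                          USE.NAMES = FALSE)
    base
  })
}

# Draw the allele-count and frequency scaffold for one marker class.
draw_marker_freqs <- function(panel, concentration, lambda_a, lambda_y,
                              microvariant_prob) {
  freq_len <- list(); freq_seq <- list()
  for (i in seq_len(nrow(panel))) {
    cls <- panel$class[i]; per <- panel$period[i]
    if (cls == "autosomal") {
      k <- 6L + stats::rbinom(1, 19, 0.25)          # 6..25, mean ~10.7
      lambda <- lambda_a
    } else {
      k <- if (stats::runif(1) < 0.03) 1L else 2L + stats::rpois(1, 3.8)
      lambda <- lambda_y
    }
    start <- sample(6:14, 1)
    labels <- as.character(seq(start, start + k - 1L))
    mv <- stats::runif(k) < microvariant_prob
    labels[mv] <- paste0(labels[mv], ".", sample(seq_len(per - 1L),
                                                 sum(mv), replace = TRUE))
    p <- stats::setNames(sample_allele_frequencies(k, concentration), labels)
    freq_len[[panel$marker[i]]] <- p
    freq_seq[[panel$marker[i]]] <-
      split_into_sequence_variants(p, per, lambda = lambda)
  }
  list(length = freq_len, sequence = freq_seq)
}

#' Simulate a full forensic STR population sample
#'
#' Generates a sequence-level [genotype_table()] with the structure of a
#' typical MPS forensic population study: Dirichlet allele spectra per
#' marker, iso-length sequence variants nested in CE alleles, diploid
#' autosomal genotypes for all samples (Hardy-Weinberg unless `f > 0`), and
#' founder-lineage Y haplotypes for male samples. Defaults emulate a cohort
#' of 628 samples (547 male, 81 female) typed at 52 autosomal and 81 Y
#' markers.
#'
#' @param n_samples,n_males Cohort size and number of males.
#' @param panel Marker panel (see [default_panel()]).
#' @param concentration Dirichlet concentration for allele spectra.
#' @param f Autosomal inbreeding coefficient (0 = Hardy-Weinberg).
#' @param founders,mu Founder-lineage count and per-copy stepwise mutation
#'   rate for the Y model.
#' @param lambda_a,lambda_y Poisson means for extra iso-length variants per
#'   CE allele (autosomal / Y); defaults give sequence:length allele-count
#'   ratios of about 1.8 and 1.4.
#' @param microvariant_prob Per-allele probability of a `.k` microvariant
#'   label.
#' @param seed Optional seed; fixed seeds reproduce the table bit-for-bit.
#' @return A sequence-level `genotype_table` with a `truth` attribute
#'   (list: generating frequencies at both levels, `f`, `founders`, `mu`,
#'   `seed`).
#' @export
simulate_str_population <- function(n_samples = 628, n_males = 547,
                                    panel = default_panel(),
                                    concentration = 1, f = 0,
                                    founders = 400, mu = 0.002,
                                    lambda_a = 0.79, lambda_y = 0.40,
                                    microvariant_prob = 0.05, seed = NULL) {
  stopifnot(n_males <= n_samples)
  panel <- validate_panel(panel)
  with_seed(seed, {
    fr <- draw_marker_freqs(panel, concentration, lambda_a, lambda_y,
                            microvariant_prob)
    tab <- build_population_table(panel, fr$sequence, n_samples, n_males,
                                  f, founders, mu)
    attr(tab, "truth") <- list(freq_length = fr$length,
                               freq_sequence = fr$sequence,
                               f = f, founders = founders, mu = mu,
                               seed = seed)
    tab
  })
}

# Assemble a genotype_table from per-marker sequence-level frequencies.
build_population_table <- function(panel, freq_seq, n_samples, n_males,
                                   f = 0, founders = 400, mu = 0.002) {
  sex <- c(rep("M", n_males), rep("F", n_samples - n_males))
  df <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                   sex = sex, stringsAsFactors = FALSE)
  for (i in which(panel$class == "autosomal")) {
    m <- panel$marker[i]
    g <- simulate_autosomal_genotypes(freq_seq[[m]], n_samples, f = f)
    df[[paste0(m, "_1")]] <- g[, 1]
    df[[paste0(m, "_2")]] <- g[, 2]
  }
  ym <- panel$marker[panel$class != "autosomal"]
  if (length(ym) && n_males > 0) {
    classes <- stats::setNames(panel$class, panel$marker)
    periods <- stats::setNames(panel$period, panel$marker)
    yh <- simulate_y_haplotypes(freq_seq[ym], n_males, classes, periods,
                                founders = founders, mu = mu)
    for (m in ym) df[[m]] <- c(yh[[m]], rep(NA_character_,
                                            n_samples - n_males))
  } else {
    for (m in ym) df[[m]] <- rep(NA_character_, n_samples)
  }
  genotype_table(df, panel, level = "sequence")
}

#' Simulate populations diverged from a common ancestor
#'
#' Balding-Nichols divergence: for each marker, each daughter population's
#' frequency vector is a Dirichlet draw with parameters
#' `p * (1 - f_div) / f_div` around the ancestral vector `p`, so each
#' allele's marginal is the Beta distribution of the Balding-Nichols model
#' and `f_div` is the expected Fst between the populations. Genotype tables
#' are then drawn as in [simulate_str_population()] (independent Y loci, no
#' founder structure, so divergence is the only cross-population signal).
#'
#' @param n_pops Number of daughter populations.
#' @param f_div Divergence parameter in (0, 1).
#' @param n_per_pop Samples per population (scalar or vector); all male so
#'   every marker is typed in every sample.
#' @param panel Marker panel.
#' @param ancestral Optional list marker -> named frequency vector; drawn
#'   via [sample_allele_frequencies()] when `NULL`.
#' @param concentration Dirichlet concentration for ancestral spectra.
#' @param seed Optional seed.
#' @return List with `tables` (list of `genotype_table`), `ancestral`
#'   frequencies, and `f_div`.
#' @export
simulate_diverged_populations <- function(n_pops = 2, f_div = 0.05,
                                          n_per_pop = 500,
                                          panel = default_panel(),
                                          ancestral = NULL,
                                          concentration = 1, seed = NULL) {
  if (f_div <= 0 || f_div >= 1) stop("f_div must be in (0, 1)")
  panel <- validate_panel(panel)
  n_per_pop <- rep_len(n_per_pop, n_pops)
  with_seed(seed, {
    if (is.null(ancestral)) {
      fr <- draw_marker_freqs(panel, concentration, 0.79, 0.40, 0.05)
      ancestral <- fr$sequence
    }
    tables <- vector("list", n_pops)
    for (j in seq_len(n_pops)) {
      fj <- lapply(ancestral, function(p) {
        if (length(p) == 1) return(p)
        q <- rdirichlet1(p * (1 - f_div) / f_div)
        stats::setNames(pmax(q, 0) / sum(pmax(q, 0)), names(p))
      })
      tables[[j]] <- build_population_table(panel, fj, n_per_pop[j],
                                            n_per_pop[j], f = 0,
                                            founders = NULL, mu = 0)
    }
    names(tables) <- sprintf("pop%d", seq_len(n_pops))
    list(tables = tables, ancestral = ancestral, f_div = f_div)
  })
}
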
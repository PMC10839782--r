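#' Allele frequencies by direct counting
#'
#' Per-marker relative allele frequencies over the observed gene copies:
#' 2N for a diploid marker over the N samples typed at that marker
#' (complete-case per locus), one copy per typed male for a single-copy Y
#' marker and two for a multi-copy unit. Every frequency is an integer
#' count divided by the marker's gene count.
#'
#' @param tab A `genotype_table`.
#' @param markers Markers to tabulate (default: whole panel).
#' @param level `"sequence"` or `"length"`.
#' @return A `freq_table`: data.frame with columns `marker`, `allele`,
#'   `count`, `frequency`, and a `gene_count` attribute (named vector).
#' @export
allele_frequencies <- function(tab, markers = NULL,
                               level = c("sequence", "length")) {
  level <- match.arg(level)
  tab <- at_level(tab, level)
  panel <- attr(tab, "panel")
  if (is.null(markers)) markers <- panel$marker
  rows <- list(); gc <- integer(0)
  for (m in markers) {
    p <- panel_row(tab, m)
    if (p$class == "autosomal") {
      g <- marker_genotypes(tab, m)
      copies <- as.vector(g[stats::complete.cases(g), , drop = FALSE])
    } else {
      copies <- unlist(strsplit(y_calls(tab, m)[!is.na(y_calls(tab, m))],
                                ",", fixed = TRUE))
    }
    if (length(copies) == 0L) stop(sprintf("no typed sample at '%s'", m))
    cnt <- table(copies)
    rows[[m]] <- data.frame(marker = m, allele = names(cnt),
                            count = as.integer(cnt),
                            frequency = as.integer(cnt) / length(copies),
                            stringsAsFactors = FALSE)
    gc[m] <- length(copies)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "gene_count") <- gc
  attr(out, "level") <- level
  class(out) <- c("freq_table", "data.frame")
  out
}

#' @export
print.freq_table <- function(x, ...) {
  gc <- attr(x, "gene_count")
  cat(sprintf("freq_table: %d markers, %d alleles (%s level)\n",
              length(gc), nrow(x), attr(x, "level")))
  NextMethod()
}

# Frequency vector of one marker from a freq_table.
freqs_of <- function(ft, marker) {
  sub <- ft[ft$marker == marker, ]
  if (nrow(sub) == 0L) stop(sprintf("marker '%s' absent from freq_table", marker))
  stats::setNames(sub$frequency, sub$allele)
}

#' Observed heterozygosity
#'
#' Fraction of typed samples carrying two distinct alleles at a diploid
#' marker.
#'
#' @param tab A `genotype_table`.
#' @param marker Autosomal marker name.
#' @param level Analysis level.
#' @return Scalar in `[0, 1]`.
#' @export
observed_heterozygosity <- function(tab, marker,
                                    level = c("sequence", "length")) {
  tab <- at_level(tab, match.arg(level))
  g <- marker_genotypes(tab, marker)
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (nrow(g) == 0L) stop(sprintf("no typed sample at '%s'", marker))
  mean(g[, 1] != g[, 2])
}

#' Expected heterozygosity / gene diversity (unbiased Nei estimator)
#'
#' `H_exp = g/(g-1) * (1 - sum(p^2))` with `g` the number of gene copies
#' counted. GD and H_exp are the same quantity and share this code path.
#'
#' @param freqs Numeric frequency vector (sums to 1).
#' @param gene_count Number of gene copies behind the frequencies (>= 2).
#' @return Scalar in `[0, 1]`.
#' @export
expected_heterozygosity <- function(freqs, gene_count) {
  if (gene_count < 2) stop("gene_count must be >= 2")
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  gene_count / (gene_count - 1) * (1 - sum(freqs^2))
}

#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param freqs Numeric frequency vector.
#' @return Scalar in `[0, 1]`.
#' @export
pic <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-9) stop("frequencies must sum to 1")
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  1 - s2 - (s2^2 - s4)
}

#' Match probability and power of discrimination
#'
#' `PM` is the sum of squared observed genotype frequencies (the
#' probability that two individuals drawn from the sample share a
#' genotype); `PD = 1 - PM` exactly. Computed from observed genotype
#' proportions, not Hardy-Weinberg expectations.
#'
#' @param tab A `genotype_table`.
#' @param marker Autosomal marker name.
#' @param level Analysis level.
#' @return Scalar `PM` (for [match_probability()]) or `PD`.
#' @export
match_probability <- function(tab, marker, level = c("sequence", "length")) {
  tab <- at_level(tab, match.arg(level))
  g <- marker_genotypes(tab, marker)
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (nrow(g) == 0L) stop(sprintf("no typed sample at '%s'", marker))
  key <- paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]), sep = "/")
  sum((table(key) / length(key))^2)
}

#' @rdname match_probability
#' @export
power_of_discrimination <- function(tab, marker,
                                    level = c("sequence", "length")) {
  1 - match_probability(tab, marker, level)
}

#' Power of exclusion
#'
#' Trio-paternity exclusion probability from observed heterozygosity:
#' `PE = h^2 * (1 - 2 h H^2)` with `h = H_obs` and `H = 1 - h`.
#'
#' @param h_obs Observed heterozygosity (vectorised).
#' @return `PE` in `[0, 1]`.
#' @examples
#' power_of_exclusion(0.61306) # ~0.3068
#' @export
power_of_exclusion <- function(h_obs) {
  stopifnot(all(h_obs >= 0 & h_obs <= 1))
  H <- 1 - h_obs
  h_obs^2 * (1 - 2 * h_obs * H^2)
}

#' Typical paternity index
#'
#' `TPI = 1 / (2 (1 - H_obs))`; undefined when every sample is
#' heterozygous.
#'
#' @param h_obs Observed heterozygosity (vectorised), `< 1`.
#' @return `TPI >= 0.5`.
#' @export
typical_paternity_index <- function(h_obs) {
  stopifnot(all(h_obs >= 0 & h_obs <= 1))
  if (any(h_obs == 1))
    stop("TPI undefined at H_obs = 1 (no homozygote observed)")
  1 / (2 * (1 - h_obs))
}

#' Per-locus forensic parameter table
#'
#' Computes the full autosomal suite for every diploid marker of a genotype
#' table at the requested resolution: `H_obs`, `H_exp` (= `GD`), `PIC`,
#' `PM`, `PD`, `PE`, `TPI` and the per-locus typed-sample count.
#'
#' @param tab A `genotype_table`.
#' @param level `"sequence"` or `"length"`.
#' @param markers Autosomal markers (default: all in panel).
#' @return A `forensic_params` data.frame, one row per marker.
#' @export
forensic_params <- function(tab, level = c("sequence", "length"),
                            markers = NULL) {
  level <- match.arg(level)
  tabl <- at_level(tab, level)
  panel <- attr(tabl, "panel")
  if (is.null(markers)) markers <- panel$marker[panel$class == "autosomal"]
  ft <- allele_frequencies(tabl, markers, level = level)
  gc <- attr(ft, "gene_count")
  rows <- lapply(markers, function(m) {
    h <- observed_heterozygosity(tabl, m, level = level)
    p <- freqs_of(ft, m)
    pm <- match_probability(tabl, m, level = level)
    data.frame(marker = m, level = level,
               n = as.integer(gc[[m]] / 2),
               H_obs = h,
               H_exp = expected_heterozygosity(p, gc[[m]]),
               GD = expected_heterozygosity(p, gc[[m]]),
               PIC = pic(p),
               PM = pm, PD = 1 - pm,
               PE = power_of_exclusion(h),
               TPI = typical_paternity_index(h),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("forensic_params", "data.frame")
  out
}

#' Combined multi-locus powers of exclusion and discrimination
#'
#' `CPE = 1 - prod(1 - PE_l)` and `CPD = 1 - prod(1 - PD_l)` over loci.
#' The residual products are accumulated in log space and kept in full
#' precision, since the combined powers are typically
#' 1 minus a quantity of order 1e-20 or smaller; printing follows the
#' `1-5.0779620E-21` convention.
#'
#' @param params A `forensic_params` table (or data.frame with `PE`, `PD`).
#' @return An object of class `combined_power`: list with `CPE`, `CPD`,
#'   `residual_CPE`, `residual_CPD`, `n_loci`.
#' @export
combined_powers <- function(params) {
  stopifnot(all(c("PE", "PD") %in% names(params)), nrow(params) >= 1)
  log_res_pe <- sum(log1p(-params$PE))
  log_res_pd <- sum(log1p(-params$PD))
  structure(list(CPE = -expm1(log_res_pe),
                 CPD = -expm1(log_res_pd),
                 residual_CPE = exp(log_res_pe),
                 residual_CPD = exp(log_res_pd),
                 n_loci = nrow(params)),
            class = "combined_power")
}

# "5.0779620E-21"-style scientific formatting of a residual.
format_residual <- function(x, digits = 7) {
  toupper(formatC(x, format = "e", digits = digits))
}

#' @export
print.combined_power <- function(x, ...) {
  cat(sprintf("Combined powers over %d loci\n", x$n_loci))
  cat("  CPE = 1-", format_residual(x$residual_CPE), "\n", sep = "")
  cat("  CPD = 1-", format_residual(x$residual_CPD), "\n", sep = "")
  invisible(x)
}
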
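#' Build Y-STR haplotypes for the male cohort
#'
#' One haplotype per male: the ordered tuple of allele labels over the
#' requested Y loci, with multi-copy loci contributing their normalized
#' (numerically, then lexically sorted) allele multiset. Males missing a
#' call at any requested locus are excluded (haplotypes must be complete to
#' compare) and their number is reported.
#'
#' @param tab A `genotype_table`.
#' @param loci Y markers to use (default: every Y marker of the panel).
#' @param level Analysis level.
#' @return Character vector of haplotype keys (one per retained male) with
#'   attributes `n_excluded` and `loci`.
#' @export
build_haplotypes <- function(tab, loci = NULL,
                             level = c("sequence", "length")) {
  level <- match.arg(level)
  tabl <- at_level(tab, level)
  panel <- attr(tabl, "panel")
  if (is.null(loci)) loci <- panel$marker[panel$class != "autosomal"]
  cls <- panel$class[match(loci, panel$marker)]
  if (anyNA(cls)) stop("unknown loci: ",
                       paste(loci[is.na(cls)], collapse = ", "))
  if (any(cls == "autosomal"))
    stop("autosomal loci in haplotype request: ",
         paste(loci[cls == "autosomal"], collapse = ", "))
  cols <- lapply(loci, function(m) y_calls(tabl, m))
  mat <- do.call(cbind, cols)
  ok <- stats::complete.cases(mat)
  haps <- apply(mat[ok, , drop = FALSE], 1, paste, collapse = "|")
  attr(haps, "n_excluded") <- sum(!ok)
  attr(haps, "loci") <- loci
  haps
}

#' Haplotype diversity from a match probability
#'
#' The small-sample identity `HD = n (1 - HMP) / (n - 1)`, where `HMP` is
#' the sum of squared haplotype frequencies over `n` sampled males.
#'
#' @param hmp Haplotype match probability (sum of squared frequencies).
#' @param n Number of males.
#' @return Haplotype diversity in `[0, 1]`.
#' @examples
#' haplotype_diversity(0.00418102, 547)
#' @export
haplotype_diversity <- function(hmp, n) {
  stopifnot(n >= 2, hmp >= 0, hmp <= 1)
  n * (1 - hmp) / (n - 1)
}

#' Direct-counting Y-haplotype statistics
#'
#' From the haplotype list of a male cohort: haplotype match probability
#' `HMP = sum(p_i^2)`, haplotype diversity `HD = n (1 - HMP) / (n - 1)`,
#' discrimination capacity `DC = distinct / n`, and the fraction of
#' distinct haplotypes seen exactly once.
#'
#' @param haplotypes Character vector from [build_haplotypes()] (any
#'   vector of haplotype keys works).
#' @return Object of class `haplotype_stats`: list with `n_males`,
#'   `n_haplotypes`, `HMP`, `HD`, `DC`, `fraction_unique`.
#' @export
haplotype_stats <- function(haplotypes) {
  n <- length(haplotypes)
  if (n < 2) stop("haplotype diversity undefined for n < 2")
  cnt <- table(haplotypes)
  p <- as.numeric(cnt) / n
  hmp <- sum(p^2)
  structure(list(n_males = n,
                 n_haplotypes = length(cnt),
                 HMP = hmp,
                 HD = haplotype_diversity(hmp, n),
                 DC = length(cnt) / n,
                 fraction_unique = sum(cnt == 1) / length(cnt)),
            class = "haplotype_stats")
}

#' @export
print.haplotype_stats <- function(x, ...) {
  cat(sprintf("%d haplotypes in %d males\n", x$n_haplotypes, x$n_males))
  cat(sprintf("  HD  = %.8f\n  HMP = %.8f\n  DC  = %.8f\n", x$HD, x$HMP, x$DC))
  cat(sprintf("  unique haplotypes: %.2f%% of distinct\n",
              100 * x$fraction_unique))
  invisible(x)
}

#' Haploid gene diversity at one Y locus
#'
#' `GD = n (1 - sum(p^2)) / (n - 1)` over haploid allele frequencies, with
#' `n` the number of typed males at that locus. A multi-copy unit is
#' treated as one compound allele: its normalized allele multiset.
#'
#' @param tab A `genotype_table`.
#' @param locus Y marker name.
#' @param level Analysis level.
#' @return Scalar GD in `[0, 1]`; 0 for a monomorphic locus.
#' @export
haploid_locus_gd <- function(tab, locus, level = c("sequence", "length")) {
  tabl <- at_level(tab, match.arg(level))
  x <- y_calls(tabl, locus)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop(sprintf("need >= 2 typed males at '%s'", locus))
  p <- as.numeric(table(x)) / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Compare Y-STR kits on one male cohort
#'
#' Computes [haplotype_stats()] for each kit's locus list on the same
#' genotype table, for head-to-head comparison of haplotype resolution.
#' Discrimination capacity can only grow as loci are added, so nested kits
#' sort by panel size.
#'
#' @param tab A `genotype_table`.
#' @param kits Named list of marker-name vectors (see [default_kits()];
#'   a `NULL` entry means "all Y markers of the panel").
#' @param level Analysis level.
#' @return data.frame with one row per kit: `kit`, `n_loci`, `n_males`,
#'   `n_haplotypes`, `HD`, `HMP`, `DC`, `fraction_unique`, sorted by `DC`.
#' @export
kit_comparison <- function(tab, kits = default_kits(),
                           level = c("sequence", "length")) {
  level <- match.arg(level)
  panel <- attr(tab, "panel")
  ally <- panel$marker[panel$class != "autosomal"]
  rows <- lapply(names(kits), function(kn) {
    loci <- kits[[kn]]
    if (is.null(loci)) loci <- ally
    if (length(loci) == 0) stop(sprintf("kit '%s' is empty", kn))
    loci <- intersect(loci, ally)
    if (length(loci) == 0)
      stop(sprintf("kit '%s' shares no locus with the panel", kn))
    st <- haplotype_stats(build_haplotypes(tab, loci, level = level))
    data.frame(kit = kn, n_loci = length(loci), n_males = st$n_males,
               n_haplotypes = st$n_haplotypes, HD = st$HD, HMP = st$HMP,
               DC = st$DC, fraction_unique = st$fraction_unique,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$DC, out$kit), , drop = FALSE]
}
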
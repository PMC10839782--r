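dist_matrix <- function(mat, statistic, raw = NULL, loci = NULL,
                        estimator = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat),
            !is.null(rownames(mat)), !anyDuplicated(rownames(mat)))
  colnames(mat) <- rownames(mat)
  structure(mat, statistic = statistic, raw = raw, loci = loci,
            estimator = estimator, class = c("dist_matrix", "matrix"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix, %d populations (%s)\n",
              attr(x, "statistic"), nrow(x),
              attr(x, "estimator") %||% "direct"))
  print(unclass(structure(x, statistic = NULL, raw = NULL, loci = NULL,
                          estimator = NULL)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weir-Cockerham (1984) variance components summed over alleles of one
# locus; genos = list of n x 2 allele-label matrices, one per population.
wc_locus_components <- function(genos) {
  genos <- lapply(genos, function(g)
    g[stats::complete.cases(g), , drop = FALSE])
  n <- vapply(genos, nrow, integer(1))
  keep <- n > 0
  genos <- genos[keep]; n <- n[keep]
  r <- length(genos)
  if (r < 2 || sum(n) < 2) return(c(a = 0, abc = 0))
  alleles <- sort(unique(unlist(genos)))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  a_tot <- 0; abc_tot <- 0
  for (al in alleles) {
    p <- vapply(genos, function(g) mean(g == al), numeric(1))
    h <- vapply(genos, function(g)
      mean((g[, 1] == al) != (g[, 2] == al)), numeric(1))
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_tot <- a_tot + a
    abc_tot <- abc_tot + a + b + cc
  }
  c(a = a_tot, abc = abc_tot)
}

#' Pairwise Fst between populations (Weir-Cockerham theta)
#'
#' Multi-locus theta for every population pair: variance components are
#' computed per allele and locus from diploid genotypes and summed before
#' taking the ratio, the standard multi-locus Weir-Cockerham estimator.
#' Negative estimates are floored at 0 in the matrix (MDS and
#' neighbour-joining need non-negative distances); raw values are kept in
#' the `"raw"` attribute.
#'
#' @param pops Named list of `genotype_table` objects, one per population.
#' @param loci Autosomal loci to use (default: shared autosomal panel).
#' @param level Analysis level at which alleles are compared.
#' @return A `dist_matrix` with statistic `"Fst"`.
#' @export
pairwise_fst <- function(pops, loci = NULL,
                         level = c("length", "sequence")) {
  level <- match.arg(level)
  stopifnot(is.list(pops), length(pops) >= 2, !is.null(names(pops)))
  pops <- lapply(pops, at_level, level = level)
  if (is.null(loci)) {
    loci <- Reduce(intersect, lapply(pops, function(t) {
      p <- attr(t, "panel"); p$marker[p$class == "autosomal"]
    }))
  }
  if (length(loci) == 0) stop("no shared autosomal loci")
  labs <- names(pops)
  raw <- mat <- matrix(0, length(labs), length(labs),
                       dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    comp <- rowSums(vapply(loci, function(m)
      wc_locus_components(list(marker_genotypes(pops[[i]], m),
                               marker_genotypes(pops[[j]], m))),
      numeric(2)))
    th <- if (comp["abc"] == 0) 0 else comp["a"] / comp["abc"]
    raw[i, j] <- raw[j, i] <- th
    mat[i, j] <- mat[j, i] <- max(0, th)
  }
  dist_matrix(mat, "Fst", raw = raw, loci = loci,
              estimator = "Weir-Cockerham theta")
}

#' Pairwise Fst from allele-frequency tables only
#'
#' Fallback when genotypes are unavailable: Nei's coancestry-based Fst,
#' `(HT - HS) / HT`, with the Nei-Chesser small-sample correction of HS
#' using the harmonic mean sample size, accumulated over loci as a ratio
#' of sums.
#'
#' @param freq_list Named list (one per population) of lists mapping locus
#'   to a named frequency vector.
#' @param n_list Named list/vector of per-population sample sizes
#'   (individuals).
#' @return A `dist_matrix` with statistic `"Fst"`.
#' @export
pairwise_fst_freq <- function(freq_list, n_list) {
  labs <- names(freq_list)
  stopifnot(length(labs) >= 2, all(labs %in% names(n_list)))
  raw <- mat <- matrix(0, length(labs), length(labs),
                       dimnames = list(labs, labs))
  loci <- Reduce(intersect, lapply(freq_list, names))
  if (length(loci) == 0) stop("no shared loci")
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    nh <- 2 / (1 / n_list[[labs[i]]] + 1 / n_list[[labs[j]]])
    num <- 0; den <- 0
    for (m in loci) {
      p1 <- freq_list[[labs[i]]][[m]]; p2 <- freq_list[[labs[j]]][[m]]
      alleles <- union(names(p1), names(p2))
      q1 <- ifelse(alleles %in% names(p1), p1[alleles], 0)
      q2 <- ifelse(alleles %in% names(p2), p2[alleles], 0)
      hs <- mean(c(1 - sum(q1^2), 1 - sum(q2^2)))
      hs <- 2 * nh / (2 * nh - 1) * hs
      ht <- 1 - sum(((q1 + q2) / 2)^2) + hs / (4 * nh)
      num <- num + (ht - hs); den <- den + ht
    }
    fst <- if (den == 0) 0 else num / den
    raw[i, j] <- raw[j, i] <- fst
    mat[i, j] <- mat[j, i] <- max(0, fst)
  }
  dist_matrix(mat, "Fst", raw = raw, loci = loci,
              estimator = "Nei coancestry (frequency-only)")
}

#' Integer repeat counts of single-copy Y loci
#'
#' Length-level CE designations of single-copy Y markers converted to
#' numeric repeat counts for Rst analysis. Microvariant labels (`"9.3"`)
#' map to their integer part by default, or the whole locus can be
#' excluded. Multi-copy units carry no single repeat count per sample and
#' are never included.
#'
#' @param tab A `genotype_table`.
#' @param loci Single-copy Y loci (default: all in panel).
#' @param microvariant `"integer"` (truncate) or `"exclude"` (drop loci
#'   with any fractional label).
#' @return Numeric matrix, males x loci, `NA` for missing calls.
#' @export
repeat_counts <- function(tab, loci = NULL,
                          microvariant = c("integer", "exclude")) {
  microvariant <- match.arg(microvariant)
  tabl <- at_level(tab, "length")
  panel <- attr(tabl, "panel")
  if (is.null(loci)) loci <- panel$marker[panel$class == "y_single"]
  cls <- panel$class[match(loci, panel$marker)]
  if (anyNA(cls))
    stop("unknown loci: ", paste(loci[is.na(cls)], collapse = ", "))
  if (any(cls != "y_single"))
    stop("repeat counts need single-copy Y loci; offending: ",
         paste(loci[cls != "y_single"], collapse = ", "))
  cols <- lapply(loci, function(m) {
    x <- suppressWarnings(as.numeric(y_calls(tabl, m)))
    x
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- loci
  frac <- apply(mat, 2, function(x) any(x %% 1 != 0, na.rm = TRUE))
  if (microvariant == "integer") {
    mat <- floor(mat)
  } else if (any(frac)) {
    mat <- mat[, !frac, drop = FALSE]
  }
  mat
}

# One-way ANOVA variance components of repeat counts at one locus;
# x = list of numeric vectors per population.
rst_locus_components <- function(x) {
  x <- lapply(x, function(v) v[!is.na(v)])
  n <- lengths(x)
  x <- x[n > 0]; n <- n[n > 0]
  r <- length(x)
  if (r < 2 || sum(n) <= r) return(c(a = 0, w = 0))
  gm <- mean(unlist(x))
  means <- vapply(x, mean, numeric(1))
  ssw <- sum(vapply(x, function(v) sum((v - mean(v))^2), numeric(1)))
  ssa <- sum(n * (means - gm)^2)
  msw <- ssw / (sum(n) - r)
  msa <- ssa / (r - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  c(a = (msa - msw) / nc, w = msw)
}

#' Pairwise Rst between populations
#'
#' Slatkin's Rst from variance components of Y-STR repeat counts: for each
#' locus a one-way ANOVA of repeat counts on population yields
#' among-population and within-population components; components are summed
#' over loci and `Rst = sigma_a / (sigma_a + sigma_w)`. Being a ratio of
#' variance components, Rst is invariant under any affine transform of the
#' repeat counts. Negative estimates are floored at 0 in the matrix with
#' raw values retained. Loci whose labels cannot be read as repeat counts
#' are skipped with a warning.
#'
#' @param pops Named list of `genotype_table` objects, or named list of
#'   numeric males-x-loci matrices (as from [repeat_counts()]).
#' @param loci Single-copy Y loci to use (default: shared set).
#' @param microvariant Passed to [repeat_counts()].
#' @return A `dist_matrix` with statistic `"Rst"`.
#' @export
pairwise_rst <- function(pops, loci = NULL,
                         microvariant = c("integer", "exclude")) {
  microvariant <- match.arg(microvariant)
  stopifnot(is.list(pops), length(pops) >= 2, !is.null(names(pops)))
  mats <- lapply(pops, function(p) {
    if (inherits(p, "genotype_table"))
      repeat_counts(p, loci = loci, microvariant = microvariant)
    else as.matrix(p)
  })
  shared <- Reduce(intersect, lapply(mats, colnames))
  if (length(shared) == 0) stop("no shared Y loci with repeat counts")
  bad <- shared[vapply(shared, function(m)
    all(vapply(mats, function(x) all(is.na(x[, m])), logical(1))),
    logical(1))]
  if (length(bad)) {
    warning("skipping loci without numeric repeat counts: ",
            paste(bad, collapse = ", "))
    shared <- setdiff(shared, bad)
  }
  labs <- names(pops)
  raw <- mat <- matrix(0, length(labs), length(labs),
                       dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    comp <- rowSums(vapply(shared, function(m)
      rst_locus_components(list(mats[[i]][, m], mats[[j]][, m])),
      numeric(2)))
    rst <- if (comp["a"] + comp["w"] == 0) 0 else
      comp["a"] / (comp["a"] + comp["w"])
    raw[i, j] <- raw[j, i] <- rst
    mat[i, j] <- mat[j, i] <- max(0, rst)
  }
  dist_matrix(mat, "Rst", raw = raw, loci = shared,
              estimator = "Slatkin variance components")
}

#' Rank the populations nearest to a focal population
#'
#' @param mat A `dist_matrix` (or plain labelled symmetric matrix).
#' @param focal Label of the focal population.
#' @param k How many neighbours to return (default: all others).
#' @return data.frame with columns `population`, `distance`, ascending by
#'   distance with ties broken lexically.
#' @export
nearest_populations <- function(mat, focal, k = NULL) {
  labs <- rownames(mat)
  if (!focal %in% labs) stop(sprintf("focal population '%s' not in matrix",
                                     focal))
  d <- mat[focal, setdiff(labs, focal)]
  ord <- order(d, names(d))
  out <- data.frame(population = names(d)[ord], distance = as.numeric(d[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(k)) out <- utils::head(out, k)
  rownames(out) <- NULL
  out
}

#' Write a distance matrix as square CSV or PHYLIP
#'
#' @param mat A `dist_matrix`.
#' @param path Output file.
#' @param format `"csv"` (square, labelled) or `"phylip"`.
#' @param order Optional row/column ordering: `"given"` or `"hclust"`
#'   (average-linkage leaf order, the layout used for heatmap export).
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(mat, path, format = c("csv", "phylip"),
                              order = c("given", "hclust")) {
  format <- match.arg(format); order <- match.arg(order)
  m <- unclass(mat)[seq_len(nrow(mat)), seq_len(ncol(mat))]
  if (order == "hclust" && nrow(m) > 2) {
    o <- stats::hclust(stats::as.dist(m), method = "average")$order
    m <- m[o, o]
  }
  if (format == "csv") {
    df <- data.frame(population = rownames(m),
                     formatC(m, format = "f", digits = 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m)))
      writeLines(paste(formatC(rownames(m)[i], width = -10),
                       paste(formatC(m[i, ], format = "f", digits = 6),
                             collapse = " ")), con)
  }
  invisible(path)
}
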
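#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of a distance matrix: double-centre `-1/2 J D^2 J`,
#' eigendecompose, and use the top eigenvectors scaled by the square roots
#' of their (positive) eigenvalues as coordinates. Negative eigenvalues are
#' reported but never used for coordinates; if fewer positive eigenvalues
#' than `dims` exist, the embedding is truncated with a warning.
#'
#' @param mat A `dist_matrix` or labelled symmetric matrix.
#' @param dims Target dimensionality (>= 1).
#' @return Object of class `mds_result`: `labels`, `points` (n x dims,
#'   column-centred), `eig` (all eigenvalues, descending), `prop`
#'   (fraction of positive-eigenvalue mass captured by the coordinates).
#' @export
classical_mds <- function(mat, dims = 2) {
  stopifnot(dims >= 1)
  m <- as.matrix(mat)
  n <- nrow(m)
  if (dims > n - 1) stop("dims must be <= n - 1")
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = dims,
                                          eig = TRUE))
  pts <- fit$points
  eig <- sort(fit$eig, decreasing = TRUE)
  npos <- sum(eig > 1e-9 * max(abs(eig), 1e-300))
  if (ncol(pts) > npos) {
    warning(sprintf("only %d positive eigenvalue(s); embedding truncated",
                    npos))
    pts <- pts[, seq_len(npos), drop = FALSE]
  }
  pos <- sum(eig[eig > 0])
  used <- sum(pmax(eig[seq_len(ncol(pts))], 0))
  structure(list(labels = rownames(m), points = pts, eig = eig,
                 prop = if (pos > 0) used / pos else NA_real_),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("classical MDS: %d populations in %d dimension(s), %.1f%% of positive eigenvalue mass\n",
              length(x$labels), ncol(x$points), 100 * x$prop))
  print(round(x$points, 4))
  invisible(x)
}

#' @export
plot.mds_result <- function(x, dims = c(1, 2), ...) {
  stopifnot(max(dims) <= ncol(x$points))
  plot(x$points[, dims[1]], x$points[, dims[2]],
       xlab = sprintf("Dimension %d", dims[1]),
       ylab = sprintf("Dimension %d", dims[2]), type = "n", ...)
  graphics::text(x$points[, dims[1]], x$points[, dims[2]],
                 labels = x$labels)
  invisible(x)
}

#' Write MDS coordinates to CSV
#'
#' @param mds An `mds_result`.
#' @param path Output file; columns `label, dim1, dim2, ...`.
#' @return `path`, invisibly.
#' @export
write_mds_coords <- function(mds, path) {
  df <- data.frame(label = mds$labels, mds$points,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", paste0("dim", seq_len(ncol(mds$points))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

quote_newick_label <- function(x) {
  bad <- grepl("[][();:,'\"[:space:]]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with Q-matrix pair selection. Ties in the
#' Q-criterion are broken deterministically by the lexicographically lowest
#' pair of subtree labels (each subtree represented by its smallest leaf
#' label), so the result is invariant to input row order. Negative branch
#' lengths arising from the two-point formulas are floored at 0 with the
#' deficit moved to the sibling branch of the join; the raw lengths are
#' kept in the `"raw_lengths"` attribute.
#'
#' @param mat A `dist_matrix` or labelled symmetric matrix, `n >= 3`.
#' @return An unrooted `phylo` tree (ape) with a basal trifurcation.
#' @export
neighbor_joining <- function(mat) {
  D <- as.matrix(mat)
  n <- nrow(D)
  if (n < 3) stop("neighbour-joining needs >= 3 populations")
  labs <- rownames(D)
  frag <- quote_newick_label(labs)
  key <- labs
  raw <- list()
  fmt <- function(v) sprintf("%.12g", v)

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1, function(ij)
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r"))
    pick <- cand[order(pk)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    raw[[length(raw) + 1]] <- c(vi, vj)
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    newkey <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nm <- c(rownames(D)[keep], newkey)
    dimnames(D2) <- list(nm, nm)
    D <- D2
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
  }

  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  raw[[length(raw) + 1]] <- c(v1, v2, v3)
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(v[1]), frag[2], fmt(v[2]), frag[3], fmt(v[3]))
  tree <- ape::read.tree(text = nwk)
  # the parser keeps quote characters on protected labels; restore raw labels
  q <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[q] <- gsub("''", "'",
                            sub("^'(.*)'$", "\\1", tree$tip.label[q]))
  attr(tree, "raw_lengths") <- raw
  tree
}

#' Serialize a tree to Newick text
#'
#' Branch lengths are written at 6 decimals; labels containing
#' Newick-reserved characters are quoted.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file to write to.
#' @param digits Decimal places for branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
to_newick <- function(tree, path = NULL, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- quote_newick_label(tree$tip.label)
  len <- tree$edge.length
  node_str <- function(node, edge_idx) {
    s <- if (node <= ntip) {
      lab[node]
    } else {
      ch <- kids[[as.character(node)]]
      paste0("(", paste(vapply(ch, function(e)
        node_str(tree$edge[e, 2], e), character(1)), collapse = ","), ")")
    }
    if (!is.na(edge_idx) && !is.null(len))
      s <- sprintf("%s:%s", s, sprintf("%.10g", round(len[edge_idx], digits)))
    s
  }
  s <- paste0(node_str(ntip + 1L, NA_integer_), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
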
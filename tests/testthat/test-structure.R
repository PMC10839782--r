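test_that("classical MDS embeds Euclidean inputs exactly", {
  # 3 collinear points, distances 1, 1, 2 -> perfect 1-D embedding
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- classical_mds(d, dims = 1)
  emb <- as.matrix(stats::dist(m$points))
  expect_equal(unname(emb), unname(d), tolerance = 1e-9)
  expect_equal(colMeans(m$points), 0, tolerance = 1e-9,
               ignore_attr = TRUE)

  # random planted point clouds: pairwise distances reproduced to 1e-8
  set.seed(70)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    rownames(X) <- paste0("p", 1:n)
    D <- as.matrix(stats::dist(X))
    m2 <- classical_mds(D, dims = 2)
    expect_equal(as.matrix(stats::dist(m2$points)), D,
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(m2$eig) <= 1e-9))
  }
})

test_that("MDS handles duplicates, dimension limits and negative eigenvalues", {
  X <- matrix(rnorm(10), 5, 2)
  X[2, ] <- X[1, ]
  D <- as.matrix(stats::dist(X))
  rownames(D) <- colnames(D) <- paste0("p", 1:5)
  m <- classical_mds(D, dims = 2)
  expect_equal(m$points[1, ], m$points[2, ], tolerance = 1e-9)
  expect_error(classical_mds(D, dims = 5), "dims")

  # non-Euclidean matrix: negative eigenvalues reported, coordinates capped
  d2 <- matrix(c(0, 1, 1, 1, 1, 0, 1, 1, 1, 1, 0, 2.9,
                 1, 1, 2.9, 0), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(classical_mds(d2, dims = 3), "truncated")
})

test_that("neighbour-joining recovers 3-taxon closed form and additive matrices exactly", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[rownames(d), colnames(d)], d, tolerance = 1e-9,
               ignore_attr = TRUE)

  # random additive matrices from known trees: topology and path lengths
  set.seed(71)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    t0 <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(t0)
    tr2 <- neighbor_joining(D)
    expect_equal(ape::cophenetic.phylo(tr2)[rownames(D), colnames(D)],
                 D, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(ape::dist.topo(ape::unroot(t0), tr2)[1], 0)
  }
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("neighbour-joining agrees with the reference implementation and ignores label order", {
  set.seed(72)
  n <- 8
  X <- matrix(rnorm(n * 3), n, 3)
  rownames(X) <- paste0("pop", 1:n)
  D <- as.matrix(stats::dist(X))
  tr <- neighbor_joining(D)
  ref <- ape::nj(stats::as.dist(D))
  expect_equal(ape::dist.topo(tr, ref)[1], 0)
  expect_equal(sort(tr$edge.length), sort(ref$edge.length),
               tolerance = 1e-9)

  perm <- sample(n)
  tr2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(tr, tr2)[1], 0)
  expect_equal(ape::cophenetic.phylo(tr2)[rownames(D), rownames(D)],
               ape::cophenetic.phylo(tr)[rownames(D), rownames(D)],
               tolerance = 1e-9)
})

test_that("Newick serialization round-trips and quotes reserved labels", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  s <- to_newick(tr)
  expect_match(s, "^\\(.*\\);$")
  re <- ape::read.tree(text = s)
  expect_setequal(re$tip.label, c("A", "B", "C"))
  expect_equal(sort(re$edge.length), sort(round(tr$edge.length, 6)))

  rownames(d) <- colnames(d) <- c("Pop (north)", "B", "C")
  s2 <- to_newick(neighbor_joining(d))
  expect_match(s2, "'Pop \\(north\\)'", fixed = FALSE)
  re2 <- ape::read.tree(text = s2)
  # ape keeps the protective quotes on the label; the name survives intact
  expect_true(any(grepl("Pop (north)", re2$tip.label, fixed = TRUE)))

  tmp <- tempfile(fileext = ".nwk")
  to_newick(tr, tmp)
  expect_equal(readLines(tmp), s)
})

test_that("distance-matrix export supports square CSV, PHYLIP and clustered heatmap order", {
  set.seed(73)
  X <- matrix(rnorm(12), 6, 2)
  rownames(X) <- paste0("P", 1:6)
  D <- strpopgen:::dist_matrix(as.matrix(stats::dist(X)), "Rst")
  csv <- tempfile(fileext = ".csv")
  write_dist_matrix(D, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(back$population, rownames(D))
  expect_equal(as.matrix(back[, -1]), unclass(D)[1:6, 1:6],
               tolerance = 1e-6, ignore_attr = TRUE)

  phy <- tempfile()
  write_dist_matrix(D, phy, format = "phylip")
  expect_equal(as.integer(trimws(readLines(phy)[1])), 6)

  hm <- tempfile(fileext = ".csv")
  write_dist_matrix(D, hm, order = "hclust")
  ord <- utils::read.csv(hm, check.names = FALSE)$population
  expected <- rownames(D)[stats::hclust(stats::as.dist(unclass(D)[1:6, 1:6]),
                                        method = "average")$order]
  expect_equal(ord, expected)
})
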
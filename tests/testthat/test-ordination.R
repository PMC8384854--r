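test_that("PCA of residuals has exact spectral properties", {
  set.seed(51)
  # rank-1 input: all variance on the first component
  v <- rnorm(6L)
  r1 <- outer(rnorm(10L), v)
  p1 <- shape_pca(r1)
  expect_equal(p1$variance_fraction[1L], 1, tolerance = 1e-12)
  expect_lt(sum(p1$variance_fraction[-1L]), 1e-12)

  # toy matrix vs an independent eigen(cov) oracle
  X <- matrix(rnorm(20L), 5L, 4L)
  p <- shape_pca(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(p$eigenvalues[1:4], ev[1:4], tolerance = 1e-10)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-10)
  # loadings orthonormal, reconstruction exact
  expect_equal(unname(crossprod(p$loadings)), diag(ncol(p$loadings)),
               tolerance = 1e-8)
  rec <- sweep(p$scores %*% t(p$loadings), 2L, p$center, "+")
  expect_equal(rec, X, tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: the largest-magnitude element of each loading is positive
  for (j in seq_len(ncol(p$loadings))) {
    l <- p$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
  expect_error(shape_pca(X[1L, , drop = FALSE]), "at least 2")
})

test_that("distances over all PCs equal distances between residual vectors", {
  set.seed(52)
  X <- matrix(rnorm(60L), 10L, 6L)
  rownames(X) <- sprintf("r%d", 1:10)
  p <- shape_pca(X)
  D <- pc_distance_matrix(p)
  Xc <- sweep(X, 2L, colMeans(X))
  expect_equal(unname(D), unname(as.matrix(dist(Xc))), tolerance = 1e-10)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))

  # identical rows -> distance 0; subsets and unknown labels
  X2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 6))
  p2 <- shape_pca(X2)
  D2 <- pc_distance_matrix(p2, c("a", "b"))
  expect_equal(D2["a", "b"], 0, tolerance = 1e-12)
  D3 <- pc_distance_matrix(p2)
  expect_equal(D3["a", "c"], 5, tolerance = 1e-10)  # centered 3-4-5 triangle
  expect_error(pc_distance_matrix(p2, c("a", "zz")), "unknown")
})

test_that("neighbor joining reproduces the 4-taxon worked example exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4L, 4L,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  expect_true(is_exclusive_clade(tr, c("A", "B")))
  expect_true(is_exclusive_clade(tr, c("C", "D")))
  cph <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cph, D, tolerance = 1e-10)
  ext <- setNames(tr$edge.length[tr$edge[, 2L] <= 4L],
                  tr$tip.label[tr$edge[tr$edge[, 2L] <= 4L, 2L]])
  expect_equal(ext[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2L] > 4L]
  expect_equal(unname(internal), 1)
})

test_that("two taxa give a single edge of the input distance", {
  D <- matrix(c(0, 3, 3, 0), 2L, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- neighbor_joining(D)
  expect_equal(sum(tr$edge.length), 3)
  expect_identical(write_newick(tr, digits = 1L), "(A:1.5,B:1.5);")
})

test_that("neighbor joining is exact on random additive matrices", {
  set.seed(53)
  for (rep in 1:30) {
    sim <- rand_additive(sample(4:8, 1L))
    tr <- neighbor_joining(sim$D)
    lab <- rownames(sim$D)
    expect_equal(ape::cophenetic.phylo(tr)[lab, lab], sim$D, tolerance = 1e-8)
    expect_same_tree(tr, sim$tree)
    expect_same_tree(tr, ape::nj(as.dist(sim$D)))  # independent implementation
  }
})

test_that("neighbor joining validates input and is tip-permutation invariant", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3L,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  bad <- D; bad[1L, 2L] <- 5
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- D; neg[1L, 2L] <- neg[2L, 1L] <- -1
  expect_error(neighbor_joining(neg), "negative")
  set.seed(54)
  sim <- rand_additive(7L)
  perm <- sample(7L)
  tr1 <- neighbor_joining(sim$D)
  tr2 <- neighbor_joining(sim$D[perm, perm])
  expect_same_tree(tr1, tr2)
})

test_that("Newick output round-trips bit-identically with quoted labels", {
  set.seed(55)
  sim <- rand_additive(6L)
  rownames(sim$D) <- colnames(sim$D) <-
    c("plain", "with space", "semi;colon", "paren(label)", "quote'mark", "t6")
  tr <- neighbor_joining(sim$D)
  f1 <- tempfile(fileext = ".nwk"); f2 <- tempfile(fileext = ".nwk")
  write_newick(tr, f1)
  back <- read_newick(f1)
  expect_setequal(back$tip.label, rownames(sim$D))
  write_newick(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  lab <- rownames(sim$D)
  expect_equal(ape::cophenetic.phylo(back)[lab, lab],
               ape::cophenetic.phylo(tr)[lab, lab], tolerance = 1e-6)
})

test_that("deepest bipartition and clade queries agree on a known tree", {
  tr <- read_newick(text = "((a:1,b:1):10,(c:1,d:1):0.5,e:1);")
  bp <- deepest_bipartition(tr)
  expect_setequal(bp$side_a, c("a", "b"))
  expect_true(is_exclusive_clade(tr, c("a", "b")))
  expect_true(is_exclusive_clade(tr, c("c", "d")))
  expect_false(is_exclusive_clade(tr, c("b", "c")))
  expect_true(is_exclusive_clade(tr, c("c", "d", "e")))  # complement side
})
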
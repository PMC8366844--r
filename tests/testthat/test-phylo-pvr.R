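test_that("patristic distances are path sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- patristic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_equal(unname(diag(D)), rep(0, 3))

  ## random 10-leaf tree against the edge-walking oracle
  tr10 <- simulate_phylogeny(10, seed = 77)
  D10 <- patristic_distances(tr10)
  O <- oracle_patristic(tr10)
  expect_equal(D10, O[rownames(D10), colnames(D10)], tolerance = 1e-12)

  bad <- tr; bad$edge.length <- NULL
  expect_error(patristic_distances(bad), "branch length")
})

test_that("pcoa recovers analytic embeddings", {
  ## two points at distance d: one positive eigenvalue d^2/2, coords +-d/2
  d <- 3.2
  D2 <- matrix(c(0, d, d, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  es2 <- pcoa_axes(D2)
  expect_equal(length(es2$relative_eigenvalues), 1L)
  expect_equal(max(es2$eigenvalues), d^2 / 2, tolerance = 1e-12)
  expect_equal(unname(sort(es2$vectors[, 1])), c(-d / 2, d / 2),
               tolerance = 1e-12)

  ## equilateral triangle at unit distance: two equal eigenvalues 0.5
  D3 <- matrix(1, 3, 3) - diag(3)
  dimnames(D3) <- list(letters[1:3], letters[1:3])
  es3 <- pcoa_axes(D3)
  expect_equal(sort(es3$eigenvalues, decreasing = TRUE)[1:2], c(0.5, 0.5),
               tolerance = 1e-10)
  ## numeric eigensolver oracle on the centered matrix
  A <- -0.5 * D3^2
  C <- diag(3) - matrix(1 / 3, 3, 3)
  expect_equal(sort(eigen(C %*% A %*% C)$values, decreasing = TRUE)[1:2],
               es3$eigenvalues[1:2], tolerance = 1e-10)
})

test_that("tree distances are fully euclidean: all-axis reconstruction", {
  tr <- simulate_phylogeny(12, seed = 5)
  D <- patristic_distances(tr)
  es <- pcoa_axes(D)
  X <- es$vectors
  Dhat <- as.matrix(dist(X))
  expect_lt(max(abs(Dhat[rownames(D), colnames(D)] - D)), 1e-8)
  ## positive eigenvalues sum to the trace of the centered matrix
  A <- -0.5 * D^2
  n <- nrow(D)
  C <- diag(n) - matrix(1 / n, n, n)
  expect_equal(sum(es$eigenvalues[es$eigenvalues > 0]),
               sum(diag(C %*% A %*% C)), tolerance = 1e-8)
})

test_that("pcoa agrees with an independent implementation", {
  tr <- simulate_phylogeny(15, seed = 8)
  D <- patristic_distances(tr)
  mine <- pcoa_axes(D)
  ref <- ape::pcoa(as.dist(D))
  npos <- length(mine$relative_eigenvalues)
  expect_equal(mine$eigenvalues[seq_len(npos)],
               ref$values$Eigenvalues[seq_len(npos)], tolerance = 1e-8)
  ## scores agree up to column sign
  for (k in 1:3) {
    a <- mine$vectors[rownames(ref$vectors), k]
    b <- ref$vectors[, k]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-6,
                                 check.attributes = FALSE)) ||
                isTRUE(all.equal(a, -b, tolerance = 1e-6,
                                 check.attributes = FALSE)))
  }
})

test_that("axis scores are invariant to species relabeling (up to sign)", {
  tr <- simulate_phylogeny(10, seed = 13)
  D <- patristic_distances(tr)
  set.seed(13)
  perm <- sample(nrow(D))
  Dp <- D[perm, perm]
  e1 <- pcoa_axes(D); e2 <- pcoa_axes(Dp)
  for (k in 1:4) {
    a <- e1$vectors[rownames(Dp), k]
    b <- e2$vectors[, k]
    expect_true(max(abs(a - b)) < 1e-8 || max(abs(a + b)) < 1e-8)
  }
})

test_that("broken-stick retention follows the expected-share rule", {
  ## direct evaluation of b_k for S = 3: {0.6111, 0.2778, 0.1111}
  expect_equal(broken_stick(c(0.7, 0.2, 0.1)), 1L)
  expect_identical(broken_stick(rep(1, 3) / 3), integer(0))
  expect_error(broken_stick(numeric(0)), "empty")
  ## leading-run rule: a later exceedance after a failure is not retained
  ## b = {0.5208, 0.2708, 0.1458, 0.0625} for S = 4
  expect_equal(broken_stick(c(0.6, 0.2, 0.13, 0.07)), 1L)
  ## expectations sum to 1
  for (S in c(1, 3, 10, 50)) {
    b <- rev(cumsum(1 / rev(seq_len(S)))) / S
    expect_equal(sum(b), 1, tolerance = 1e-12)
  }
})

test_that("pv_design aligns by label and yields centered orthogonal axes", {
  tr <- simulate_phylogeny(24, seed = 2)
  es <- pcoa_axes(patristic_distances(tr))
  X <- pv_design(es, n_axes = 5)
  expect_equal(dim(X), c(24L, 5L))
  expect_lt(max(abs(colSums(X))), 1e-8)                 # centered
  ip <- crossprod(X)
  expect_lt(max(abs(ip - diag(diag(ip)))), 1e-6)        # orthogonal

  ## alignment by label under permutation
  set.seed(2)
  perm <- sample(es$labels)
  Xp <- pv_design(es, species = perm, n_axes = 5)
  expect_equal(Xp, X[perm, ], tolerance = 0)

  ## zero axes: empty design
  X0 <- pv_design(es, n_axes = 0)
  expect_equal(ncol(X0), 0L)
  expect_error(pv_design(es, species = c("nosuch", es$labels)),
               "absent")
  expect_error(pv_design(es, n_axes = 100), "exceeds")
})
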
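test_that("PCA matches the covariance eigendecomposition", {
  x <- metabofuse:::with_seed(10, scale(matrix(rnorm(20), 5, 4)))
  attributes(x)[c("scaled:center", "scaled:scale")] <- NULL
  m <- pca_fit(x, max_components = 4)
  eig <- eigen(cov(x))
  k <- 4
  expect_equal(abs(m$loadings), abs(eig$vectors[, 1:k]),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(m$sdev[1:k]^2, eig$values[1:k], tolerance = 1e-8)
  expect_equal(abs(m$scores), abs(x %*% eig$vectors[, 1:k]),
               ignore_attr = TRUE, tolerance = 1e-8)
  # full reconstruction
  expect_equal(m$scores %*% t(m$loadings), x, ignore_attr = TRUE,
               tolerance = 1e-8)
  # loadings orthonormal, scores orthogonal, explained fractions sane
  expect_equal(crossprod(m$loadings), diag(k), ignore_attr = TRUE)
  tt <- crossprod(m$scores)
  expect_true(all(abs(tt[upper.tri(tt)]) < 1e-8))
  expect_true(all(diff(m$explained) < 1e-12))
  expect_lte(sum(m$explained), 1 + 1e-12)
})

test_that("rank-1 data loads entirely on the first component", {
  x <- outer(c(-2, -1, 0, 1, 2), c(1, 2, 3))
  m <- pca_fit(x, max_components = 2)
  expect_equal(m$explained[1], 1)
  expect_lt(sum(m$explained[-1]), 1e-12)
})

test_that("duplicated columns get identical loading weights", {
  x <- metabofuse:::with_seed(3, scale(matrix(rnorm(40), 10, 4)))
  x <- cbind(x, x[, 1])
  m <- pca_fit(x, max_components = 3)
  expect_equal(m$loadings[1, ], m$loadings[5, ], tolerance = 1e-8)
})

test_that("PCA sign convention is deterministic", {
  x <- metabofuse:::with_seed(4, scale(matrix(rnorm(60), 10, 6)))
  m <- pca_fit(x, 4)
  for (k in 1:4) {
    v <- m$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_fit(x, 20), "max_components")
})

test_that("cross-validated rank: none on noise, two on planted structure", {
  n_sig_noise <- vapply(1:10, function(s) {
    x <- metabofuse:::with_seed(s, matrix(rnorm(20 * 30), 20, 30))
    select_significant_pcs(autoscale(x), max_components = 5, seed = s)
  }, numeric(1))
  expect_gte(mean(n_sig_noise == 0), 0.9)

  n_sig_2 <- vapply(1:5, function(s) metabofuse:::with_seed(s, {
    scores <- matrix(rnorm(20 * 2, sd = 8), 20, 2)
    x <- scores %*% matrix(rnorm(2 * 30), 2, 30) +
      matrix(rnorm(20 * 30), 20, 30)
    select_significant_pcs(autoscale(x), max_components = 6, seed = s)
  }), numeric(1))
  expect_true(all(n_sig_2 == 2))

  x <- metabofuse:::with_seed(1, matrix(rnorm(40), 10, 4))
  expect_true(select_significant_pcs(autoscale(x), max_components = 1,
                                     seed = 1) %in% 0:1)
})

test_that("Ward clustering reproduces the hand Lance-Williams solution", {
  # 4 points: two tight pairs 10 apart. Singleton merges at euclidean
  # distance 1; Ward distance between the pairs:
  #   d^2(AB, CD) via Lance-Williams on squared distances
  #   = sqrt(2 * (n1 n2 / (n1 + n2)) * ||c1 - c2||^2) = sqrt(2 * 100) on
  #   the distance scale with centroids (0, 0.5), (10, 0.5)
  x <- matrix(c(0, 0, 0, 1, 10, 0, 10, 1), 4, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  hc <- hierarchical_cluster(x)
  expect_equal(hc$height, c(1, 1, sqrt(200)))
  expect_true(all(diff(hc$height) >= 0))
  expect_equal(nrow(hc$merge), 3)
  # first merges pair the near neighbours
  expect_setequal_chr(cut_first_split(hc)[[1]], c("A", "B"))

  # duplicate points merge at height 0
  dup <- matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE,
                dimnames = list(c("u", "v"), NULL))
  hcd <- hierarchical_cluster(dup)
  expect_equal(hcd$height, 0)
  expect_error(hierarchical_cluster(dup[1, , drop = FALSE]), "2 samples")
})

test_that("row order only relabels the dendrogram", {
  x <- two_blob_matrix(n_per = 4, seed = 2)
  perm <- metabofuse:::with_seed(9, sample(nrow(x)))
  h1 <- hierarchical_cluster(x)
  h2 <- hierarchical_cluster(x[perm, ])
  expect_equal(sort(h1$height), sort(h2$height))
  expect_identical(lapply(cut_first_split(h1), sort),
                   lapply(cut_first_split(h2), sort))
})

test_that("the first cluster break recovers well-separated groups", {
  x <- two_blob_matrix(n_per = 5, gap = 10, seed = 1)
  split <- cut_first_split(hierarchical_cluster(x))
  expect_setequal_chr(split[[1]], rownames(x)[1:5])
  expect_setequal_chr(split[[2]], rownames(x)[6:10])
  expect_equal(sum(lengths(split)), nrow(x))

  # k well-separated blobs are recovered exactly by cutting into k groups
  y <- rbind(two_blob_matrix(4, gap = 20, seed = 3),
             matrix(rnorm(8, 100, 0.1), 4, 2))
  rownames(y) <- sprintf("P%02d", 1:12)
  grp <- cutree(hierarchical_cluster(y), k = 3)
  expect_equal(unname(grp), rep(1:3, each = 4))
})

test_that("Newick export follows the ultrametric convention", {
  two <- matrix(c(0, 3), 2, 1, dimnames = list(c("A", "B"), NULL))
  hc <- hierarchical_cluster(two)
  expect_identical(dendrogram_to_newick(hc), "(A:1.5,B:1.5);")

  skip_if_not_installed("ape")
  x <- two_blob_matrix(n_per = 4, seed = 5)
  hc <- hierarchical_cluster(x)
  tree <- ape::read.tree(text = dendrogram_to_newick(hc))
  expect_setequal_chr(tree$tip.label, rownames(x))
  expect_equal(tree$Nnode, nrow(x) - 1)
  # ultrametric: every leaf sits at depth root_height / 2
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  expect_equal(depths, rep(max(hc$height) / 2, length(depths)),
               tolerance = 1e-9)
})
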
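test_that("z-scoring yields unit-variance centered columns, idempotently", {
  tab <- generate_site(default_site_spec(seed = 3))
  z <- zscore_metals(tab)
  expect_equal(unname(colMeans(z)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 8), tolerance = 1e-12)
  expect_equal(unname(zscore_metals(z)), unname(z), tolerance = 1e-12)
  # two-sample column: forced +/- 1/sqrt(2)
  z2 <- zscore_metals(matrix(c(1, 3), 2, 1))
  expect_equal(as.vector(z2), c(-1, 1) / sqrt(2))
  const <- as.data.frame(tab); const$Cd <- 2
  expect_error(zscore_metals(sample_table(const)), "Cd")
})

test_that("identical metal profiles merge first at height zero", {
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4)
  x[, 2] <- x[, 1]
  colnames(x) <- c("A", "B", "C", "D")
  dend <- ward_cluster(x)
  expect_equal(dend$height[1], 0, tolerance = 1e-12)
  expect_true(all(sort(dend$merge[1, ]) == c(-2, -1)))
})

test_that("well-separated correlated pairs are recovered at k = 2", {
  set.seed(2)
  base1 <- rnorm(30)
  base2 <- rnorm(30) + 50
  x <- cbind(A = base1 + rnorm(30, 0, 0.05),
             B = base1 + rnorm(30, 0, 0.05),
             C = base2 + rnorm(30, 0, 0.05),
             D = base2 + rnorm(30, 0, 0.05))
  dend <- ward_cluster(zscore_metals(x))
  k <- cut_metals(dend, k = 2)
  expect_equal(k[["A"]], k[["B"]])
  expect_equal(k[["C"]], k[["D"]])
  expect_false(k[["A"]] == k[["C"]])
  # automatic cut by largest fusion-coefficient increase finds the same
  expect_equal(unname(cut_metals(dend)), unname(k))
})

test_that("merge heights equal the brute-force Ward oracle", {
  for (trial in 1:25) {
    set.seed(trial)
    n_leaves <- sample(4:6, 1)
    x <- matrix(rnorm(n_leaves * 7), nrow = n_leaves)
    dend <- ward_cluster(t(x))  # leaves are columns of t(x)
    expect_equal(dend$height, oracle_ward_heights(x), tolerance = 1e-9,
                 info = paste("trial", trial))
  }
})

test_that("dendrogram serializes to parseable Newick", {
  tab <- generate_site(default_site_spec(seed = 6))
  nwk <- dendrogram_newick(ward_cluster(zscore_metals(tab)))
  expect_match(nwk, "^\\(.*\\);$")
  for (m in soil_metals()) expect_match(nwk, m, fixed = TRUE)
})

test_that("PCA retains by Kaiser and rotation preserves communalities", {
  set.seed(4)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(A = f1 + rnorm(n, 0, 0.1), B = f1 + rnorm(n, 0, 0.1),
             C = f2 + rnorm(n, 0, 0.1), D = f2 + rnorm(n, 0, 0.1))
  pca <- pca_varimax(zscore_metals(x))
  expect_equal(pca$n_retained, 2)
  expect_equal(sum(pca$eigenvalues), 4, tolerance = 1e-10)  # trace
  expect_equal(rowSums(pca$loadings^2), pca$communality,
               tolerance = 1e-10)
  # the correlated pairs load together after rotation
  dominant <- apply(abs(pca$loadings), 1, which.max)
  expect_equal(dominant[["A"]], dominant[["B"]])
  expect_equal(dominant[["C"]], dominant[["D"]])
  expect_false(dominant[["A"]] == dominant[["C"]])
  # sign convention: column maxima positive
  for (j in seq_len(ncol(pca$loadings))) {
    expect_gt(max(pca$loadings[, j]), 0)
  }
})

test_that("full-rank loadings reconstruct the correlation matrix", {
  tab <- generate_site(default_site_spec(seed = 8))
  z <- zscore_metals(tab)
  r <- cor(z)
  eig <- eigen(r, symmetric = TRUE)
  l_full <- eig$vectors %*% diag(sqrt(eig$values))
  expect_equal(l_full %*% t(l_full), r, tolerance = 1e-10,
               ignore_attr = TRUE)
  # unrotated retained loadings are orthogonal columns
  pca <- pca_varimax(z)
  ltl <- crossprod(pca$unrotated)
  expect_equal(ltl, diag(diag(ltl)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("loading interpretation applies the 0.5 / 0.3 thresholds", {
  pca <- list(loadings = matrix(c(0.8, 0.4, 0.1, -0.6), 2, 2,
                                dimnames = list(c("A", "B"),
                                                c("PC1", "PC2"))))
  class(pca) <- "pca_result"
  li <- loading_interpretation(pca)
  expect_equal(li$strength, c("strong", "moderate", "weak", "strong"))
})
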
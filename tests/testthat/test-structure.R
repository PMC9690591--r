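test_that("dosage matrix transposes genotypes with missing preserved", {
  rows <- rbind(vrow("v1", "chr1", 100, 599, "DEL"),
                vrow("v2", "chr1", 1000, 1499, "DEL"))
  geno <- rbind(c(0L, 1L, 2L), c(NA, NA, NA))
  colnames(geno) <- c("s1", "s2", "s3")
  cs <- cnv_callset(rows, geno, colnames(geno))
  m <- build_dosage(cs)
  expect_equal(dim(m), c(3, 2))
  expect_equal(unname(m[, "v1"]), c(0L, 1L, 2L))
  expect_true(all(is.na(m[, "v2"])))
})

test_that("PCA matches a direct eigendecomposition and normalizes variance", {
  set.seed(12)
  m <- matrix(sample(0:2, 20 * 30, TRUE), 20, 30,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("v%02d", 1:30)))
  res <- pca_dosage(m, scale = FALSE)
  # oracle: eigen of the covariance of the centered matrix
  x <- sweep(m, 2, colMeans(m))
  x <- x[, colSums(x != 0) > 0, drop = FALSE]
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  frac <- ev[ev > 1e-12] / sum(ev[ev > 1e-12])
  k <- length(frac)
  expect_equal(res$explained_fraction[seq_len(k)], frac, tolerance = 1e-8)
  expect_equal(sum(res$explained_fraction), 1)
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
  # sample distances in PC space equal centered-data distances (rotation)
  d_pc <- dist(res$coordinates)
  d_x <- dist(x)
  expect_equal(as.numeric(d_pc), as.numeric(d_x), tolerance = 1e-8)
})

test_that("identical samples collapse to the same PC coordinates", {
  m <- rbind(a = c(0L, 1L, 2L, 0L, 1L), b = c(0L, 1L, 2L, 0L, 1L),
             c = c(2L, 1L, 0L, 2L, 0L), d = c(2L, 1L, 0L, 2L, 0L))
  res <- pca_dosage(m)
  expect_equal(res$coordinates["a", ], res$coordinates["b", ], tolerance = 1e-10)
  expect_gt(abs(res$coordinates["a", 1] - res$coordinates["c", 1]), 0.1)
})

test_that("two planted clusters separate on PC1 with dominant variance", {
  set.seed(99)
  n_var <- 60
  base_a <- rbinom(n_var, 2, 0.15); base_b <- rbinom(n_var, 2, 0.85)
  flip <- function(base) vapply(base, function(d)
    max(0L, min(2L, d + sample(c(-1L, 0L, 1L), 1, prob = c(0.1, 0.8, 0.1)))),
    integer(1))
  m <- rbind(t(replicate(6, flip(base_a))), t(replicate(6, flip(base_b))))
  rownames(m) <- sprintf("s%02d", 1:12)
  res <- pca_dosage(m)
  expect_gt(res$explained_fraction[1], res$explained_fraction[2])
  pc1 <- res$coordinates[, 1]
  expect_equal(length(unique(sign(pc1[1:6]))), 1)
  expect_equal(length(unique(sign(pc1[7:12]))), 1)
  expect_true(sign(pc1[1]) != sign(pc1[7]))
})

test_that("PCA errors on constant matrices and missing data are mean-imputed", {
  expect_error(pca_dosage(matrix(1L, 4, 5)), "no variance")
  m <- rbind(c(0L, NA), c(2L, 1L), c(1L, NA), c(NA, 0L))
  expect_silent(res <- pca_dosage(m, scale = FALSE))
  expect_equal(nrow(res$coordinates), 4)
})

test_that("allele-sharing distances follow the hand formula", {
  m <- rbind(s1 = c(0L, 0L, 0L, 0L), s2 = c(2L, 2L, 2L, 2L),
             s3 = c(0L, 1L, 2L, NA))
  d <- allele_sharing_distance(m)
  expect_equal(d["s1", "s2"], 1)                       # opposite homozygotes
  expect_equal(d["s1", "s3"], mean(c(0, 1, 2)) / 2)    # jointly typed: 3 sites
  expect_equal(d["s2", "s3"], mean(c(2, 1, 0)) / 2)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(d, t(d))
  m2 <- rbind(a = c(0L, NA), b = c(NA, 1L))
  expect_error(allele_sharing_distance(m2), "a and b")
})

test_that("NJ resolves the 2- and 3-taxon cases by the closed formulas", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(nj_tree(d2), "(A:0.2,B:0.2);")
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- ape::read.tree(text = nj_tree(d3))
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ recovers additive distances exactly (patristic == input)", {
  set.seed(7)
  for (n in 4:8) {
    for (rep in 1:5) {
      tr0 <- ape::rtree(n, rooted = FALSE)
      d <- ape::cophenetic.phylo(tr0)
      nwk <- nj_tree(d)
      tr <- ape::read.tree(text = nwk)
      dd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
      expect_equal(dd, d, tolerance = 1e-7)
    }
  }
})

test_that("NJ agrees with the reference implementation on random matrices", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 7
    p <- matrix(runif(n * 20), n)
    d <- as.matrix(dist(p)) / 4
    dimnames(d) <- list(sprintf("t%d", 1:n), sprintf("t%d", 1:n))
    mine <- ape::read.tree(text = nj_tree(d, clamp = FALSE))
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref))[1], 0)
    dd_m <- ape::cophenetic.phylo(mine)[rownames(d), ]
    dd_r <- ape::cophenetic.phylo(ref)[rownames(d), colnames(dd_m)]
    expect_equal(dd_m, dd_r, tolerance = 1e-6)
  }
})

test_that("NJ output is invariant under taxon relabeling", {
  set.seed(10)
  tr0 <- ape::rtree(6, rooted = FALSE)
  d <- ape::cophenetic.phylo(tr0)
  perm <- sample(nrow(d))
  d2 <- d[perm, perm]
  t1 <- ape::read.tree(text = nj_tree(d))
  t2 <- ape::read.tree(text = nj_tree(d2))
  expect_equal(ape::dist.topo(t1, t2)[1], 0)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(d), colnames(d)],
               ape::cophenetic.phylo(t1)[rownames(d), colnames(d)],
               tolerance = 1e-8)
})

test_that("degenerate distance inputs are rejected", {
  d <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "symmetric")
  d2 <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d2), "non-negative")
})
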
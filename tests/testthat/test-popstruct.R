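test_that("allele_frequencies counts reference alleles over non-missing data", {
  a <- rbind(c(0, 0), c(0, 0), c(1, 0), c(NA, 0))
  p <- toy_panel(a, samples = c("x", "y"))
  pm <- data.frame(sample_id = c("x", "y"), group = "G")
  expect_equal(allele_frequencies(p, pm, "G"), c(2 / 3, 1))
  expect_error(allele_frequencies(p, pm, "H"), "group")
  # counting oracle on a random toy
  set.seed(1)
  a2 <- matrix(sample(c(0L, 1L, NA), 80, replace = TRUE,
                      prob = c(.45, .45, .1)), nrow = 8)
  p2 <- toy_panel(a2)
  pm2 <- data.frame(sample_id = p2$sample_ids, group = "G")
  oracle <- apply(a2, 2, function(v) sum(v == 0, na.rm = TRUE) /
                    sum(!is.na(v)))
  expect_equal(allele_frequencies(p2, pm2, "G"), oracle)
})

test_that("p_distance matches hand counts and handles missingness", {
  a <- rbind(c(0, 0, 1, 0),   # h1
             c(0, 0, 1, 0),   # h2 identical to h1
             c(1, 1, 0, 1),   # h3 complementary to h1
             c(0, 1, 1, NA))  # h4: differs from h1 at site 2 of 3 usable
  p <- toy_panel(a, samples = c("sA", "sB"))
  d <- p_distance_matrix(p, unit = "haplotype")$d
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
  expect_equal(d[1, 4], 1 / 3)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # sample mode: dosage mismatch / 2; sA = h1+h2, sB = h3+h4
  ds <- p_distance_matrix(p, unit = "sample")$d
  # dosages: sA = (0,0,2,0); sB = (1,2,1,NA) -> mean(|diff|/2) over 3 sites
  expect_equal(ds[1, 2], mean(c(1, 2, 1) / 2))
  # pair with no joint non-missing sites is NA
  a3 <- rbind(c(0L, NA), c(NA, 1L))
  d3 <- suppressWarnings(p_distance_matrix(toy_panel(a3,
                                                     samples = "s"),
                                           unit = "haplotype")$d)
  expect_true(is.na(d3[1, 2]))
})

test_that("nj_tree recovers additive topologies and closed forms", {
  # additive matrix for ((A,B),(C,D)) with internal branch 2
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3        # 1 + 2
  d["C", "D"] <- d["D", "C"] <- 7        # 3 + 4
  d["A", "C"] <- d["C", "A"] <- 1 + 2 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 2 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 2 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 2 + 4
  tr <- nj_tree(d)
  ref <- ape::read.tree(text = "((A:1,B:2):2,C:3,D:4);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  len <- setNames(t3$edge.length[match(seq_len(3), t3$edge[, 2])],
                  t3$tip.label)
  expect_equal(unname(len["A"]), (2 + 3 - 4) / 2)
  expect_equal(unname(len["B"]), (2 + 4 - 3) / 2)
  expect_equal(unname(len["C"]), (3 + 4 - 2) / 2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 labels")
})

test_that("nj_tree inverts tree-derived distances (property)", {
  set.seed(9)
  for (n in c(5, 6, 8)) {
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    out <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(out)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("pca_panel separates clusters and matches the spectral identity", {
  # two internally-identical clusters
  block <- function(g, n) matrix(rep(g, each = 2 * n), nrow = 2 * n)
  a <- rbind(block(c(0, 0, 1, 1, 0, 1, 0, 1), 3),
             block(c(1, 1, 0, 0, 1, 0, 1, 0), 3))
  p <- toy_panel(a)
  pc <- pca_panel(p, n_components = 3L)
  expect_lt(max(abs(tapply(pc$scores[, 1],
                           rep(1:2, each = 3), sd))), 1e-10)
  expect_gt(abs(diff(tapply(pc$scores[, 1], rep(1:2, each = 3), mean))), 1)
  # eigen-oracle on a 5 x 8 toy
  set.seed(4)
  a2 <- matrix(rbinom(80, 1, 0.4), nrow = 10)
  p2 <- toy_panel(a2)
  pc2 <- pca_panel(p2, n_components = 4L)
  # reconstruct the scaled matrix exactly as documented
  g <- a2[seq(1, 10, 2), ] + a2[seq(2, 10, 2), ]
  mu <- colMeans(g); x <- sweep(g, 2, mu)
  sdv <- sqrt(2 * (mu / 2) * (1 - mu / 2)); use <- sdv > 0
  x <- sweep(x[, use, drop = FALSE], 2, sdv[use], "/")
  ev <- eigen(tcrossprod(x), symmetric = TRUE)
  k <- ncol(pc2$scores)
  for (j in seq_len(k)) {
    sc <- pc2$scores[, j]
    ref <- ev$vectors[, j] * sqrt(ev$values[j])
    expect_lt(min(sum((sc - ref)^2), sum((sc + ref)^2)), 1e-10)
  }
  # explained variance sums to total variance of the scaled matrix
  expect_equal(sum(pc2$explained), sum(apply(x, 2, var) * (nrow(x) - 1)) /
                 (nrow(x) - 1))
  # sign-invariance under sample permutation
  perm <- c(3, 1, 5, 2, 4)
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  p3 <- toy_panel(a2[rows, ], samples = p2$sample_ids[perm])
  pc3 <- pca_panel(p3, n_components = 2L)
  for (j in 1:2) {
    x1 <- pc2$scores[perm, j]; x2 <- pc3$scores[, j]
    expect_lt(min(sum((x1 - x2)^2), sum((x1 + x2)^2)), 1e-8)
  }
})
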
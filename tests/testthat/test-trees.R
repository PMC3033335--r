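# UPGMA trees, nodal matrices, and tree discordance.

test_that("two taxa form a cherry at half the distance", {
  D <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- upgma(D)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(tr$edge.length, c(2, 2))
  expect_error(upgma(D[1, 1, drop = FALSE]), "2 taxa")
})

test_that("an ultrametric matrix is recovered exactly", {
  # generating tree: ((a:1,b:1):2,(c:2,d:2):1); with ultrametric distances
  lab <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 4,
                6, 6, 4, 0), 4, dimnames = list(lab, lab))
  tr <- upgma(D)
  expect_true(ape::is.ultrametric(tr))
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_true(ape::is.monophyletic(tr, c("c", "d")))
  # heights: cherry (a,b) at 1, (c,d) at 2, root at 3
  depth <- ape::node.depth.edgelength(tr)
  expect_equal(max(depth), 3)
  cd <- ape::getMRCA(tr, c("c", "d"))
  expect_equal(max(depth) - depth[cd], 2)
  ab <- ape::getMRCA(tr, c("a", "b"))
  expect_equal(max(depth) - depth[ab], 1)
})

test_that("ties merge the lexicographically smallest label pair", {
  lab <- c("c", "a", "b")
  D <- matrix(1, 3, 3, dimnames = list(lab, lab)); diag(D) <- 0
  tr <- upgma(D)
  # the first cherry is {a, b} by label order despite input order
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
})

test_that("UPGMA agrees with the reference implementation on random matrices", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  for (i in 1:12) {
    n <- sample(4:10, 1)
    M <- matrix(stats::runif(n * n, 1, 10), n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    rownames(M) <- colnames(M) <- paste0("t", seq_len(n))
    t1 <- upgma(M)
    t2 <- phangorn::upgma(stats::as.dist(M))
    expect_equal(phangorn::RF.dist(t1, t2), 0)
    expect_true(ape::is.ultrametric(t1))
    # same root height
    expect_equal(max(ape::node.depth.edgelength(t1)),
                 max(ape::node.depth.edgelength(t2)), tolerance = 1e-9)
  }
})

test_that("negative distances are clipped with a warning", {
  D <- matrix(c(0, -0.1, 2, -0.1, 0, 2, 2, 2, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- upgma(D), "clipped")
  expect_equal(min(tr$edge.length), 0)
})

test_that("nodal matrices count intervening internal nodes", {
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(nodal_matrix(cherry)["a", "b"], 1L)
  bal <- ape::read.tree(text = "((a,b),(c,d));")
  cat4 <- ape::read.tree(text = "(((a,b),c),d);")
  expect_equal(nodal_matrix(bal), oracle_nodal(bal))
  expect_equal(nodal_matrix(cat4), oracle_nodal(cat4))
  expect_equal(nodal_matrix(bal)["a", "c"], 3L)
  expect_equal(nodal_matrix(cat4)["a", "d"], 3L)
  expect_equal(nodal_matrix(cat4)["c", "d"], 2L)
  # multifurcation counts once
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_true(all(nodal_matrix(star)[upper.tri(diag(4))] == 1L))
})

test_that("nodal matrices are equivariant under consistent relabeling", {
  set.seed(14)
  tr <- ape::rtree(9)
  M <- nodal_matrix(tr)
  perm <- sample(tr$tip.label)
  tr2 <- tr
  tr2$tip.label <- perm[match(tr$tip.label, sort(tr$tip.label))]
  # mapping old label -> new label preserves pairwise counts
  map <- stats::setNames(tr2$tip.label, tr$tip.label)
  M2 <- nodal_matrix(tr2)
  for (a in rownames(M)) for (b in colnames(M)) {
    expect_equal(M2[map[[a]], map[[b]]], M[a, b], ignore_attr = TRUE)
  }
})

test_that("discordance of a tree with itself is zero and significant", {
  set.seed(20)
  tr <- ape::rtree(10)
  rep1 <- tree_discordance(tr, tr, n_perm = 100, seed = 1)
  expect_equal(rep1$rmsd, 0)
  expect_lt(rep1$p_value, 0.05)
  expect_lt(rep1$p_exact, 0.05)
  expect_gt(rep1$null_mean, 0)
  expect_equal(rep1$n_permutations, 100L)
})

test_that("the permutation null is seed-reproducible", {
  set.seed(21)
  tf <- ape::rtree(9); tref <- ape::rtree(9)
  r1 <- tree_discordance(tf, tref, seed = 7)
  r2 <- tree_discordance(tf, tref, seed = 7)
  expect_identical(r1$null_mean, r2$null_mean)
  expect_identical(r1$null_sd, r2$null_sd)
  r3 <- tree_discordance(tf, tref, seed = 8)
  expect_false(identical(r1$null_mean, r3$null_mean))
})

test_that("the null distribution is insensitive to the feature tree labeling", {
  set.seed(22)
  tf <- ape::rtree(12)
  tref <- ape::rtree(12)
  tf2 <- tf
  tf2$tip.label <- sample(tf$tip.label)
  r1 <- tree_discordance(tf, tref, n_perm = 200, seed = 5)
  r2 <- tree_discordance(tf2, tref, n_perm = 200, seed = 5)
  # same topology, permuted labels: null means agree within joint noise
  se <- sqrt(r1$null_sd^2 / 200 + r2$null_sd^2 / 200)
  expect_lt(abs(r1$null_mean - r2$null_mean), 5 * se)
})

test_that("leaf-set mismatches are intersected with a warning", {
  set.seed(23)
  tf <- ape::rtree(8)
  tref <- ape::keep.tip(tf, tf$tip.label[1:5])
  expect_warning(r <- tree_discordance(tf, tref, seed = 2), "shared")
  expect_equal(r$rmsd, 0)
  expect_error(suppressWarnings(
    tree_discordance(tf, ape::keep.tip(tf, tf$tip.label[1:2]))),
    "shared leaves")
})
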
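# Sum-difference distances, agglomerative trees, Newick serialization.

test_that("sum-difference matches hand arithmetic and the L1 definition", {
  expect_equal(sum_difference(c(60.1, 88.6), c(88.6, 88.6)), 28.5)
  expect_equal(sum_difference(c(60.1, 0), c(60.1, 140.0)), 140.0)
  x <- rand_numstring(50, seed = 1)
  expect_equal(sum_difference(x, x), 0)
  expect_error(sum_difference(1:3, 1:4), "mismatch")
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    expect_equal(sum_difference(a, b), oracle_sumdiff(a, b))
  }
})

test_that("sum-difference satisfies the metric axioms on random triples", {
  set.seed(11)
  for (i in 1:200) {
    a <- rnorm(20); b <- rnorm(20); c <- rnorm(20)
    dab <- sum_difference(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, sum_difference(b, a))
    expect_lte(dab, sum_difference(a, c) + sum_difference(c, b) + 1e-12)
  }
})

test_that("the merge loop follows the smallest-pair/profile-average trace", {
  # 2 taxa: single merge at their distance
  t2 <- build_sumdiff_tree(list(A = c(0, 2), B = c(1, 6)))
  expect_equal(t2$height, 5)
  # 3 one-position taxa 0, 1, 10: merge (0,1) at 1, profile 0.5,
  # then merge at |0.5 - 10| = 9.5
  t3 <- build_sumdiff_tree(list(A = 0, B = 1, C = 10))
  expect_equal(t3$height, c(1, 9.5))
  expect_equal(sort(t3$merge[1, ]), c(-2, -1))  # A and B merge first
})

test_that("the first merge pair is the brute-force argmin of all pairs", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    vecs <- lapply(seq_len(n), function(i) rnorm(25))
    names(vecs) <- paste0("t", seq_len(n))
    t <- build_sumdiff_tree(vecs)
    d <- outer(seq_len(n), seq_len(n),
               Vectorize(function(i, j) oracle_sumdiff(vecs[[i]], vecs[[j]])))
    diag(d) <- Inf
    expect_equal(t$height[1], min(d))
    best <- which(d == min(d), arr.ind = TRUE)[1, ]
    expect_setequal(-t$merge[1, ], as.integer(best))
  }
})

test_that("distance-matrix trees follow WPGMA and match the reference", {
  m <- matrix(c(0, 1, 4, 1, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- build_tree_from_distances(m)
  expect_equal(t$height, c(1, 5))   # (4 + 6) / 2

  t1 <- build_tree_from_distances(matrix(c(0, 0.3, 0.3, 0), 2,
                                         dimnames = list(c("a", "b"),
                                                         c("a", "b"))))
  expect_equal(t1$height, 0.3)

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(build_tree_from_distances(z)$height, c(0, 0, 0))

  expect_error(build_tree_from_distances(matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
  expect_error(build_tree_from_distances(matrix(c(0, -1, -1, 0), 2)),
               "non-negative")

  # independent reference: stats::hclust McQuitty linkage, cophenetic equality
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    p <- matrix(rnorm(n * 10), n)
    rownames(p) <- paste0("t", seq_len(n))
    d <- dist(p)
    mine <- cophenetic(build_tree_from_distances(as.matrix(d)))
    ref <- cophenetic(hclust(d, method = "mcquitty"))
    expect_equal(as.matrix(mine)[labels(ref), labels(ref)], as.matrix(ref),
                 tolerance = 1e-10)
  }
})

test_that("equal minimal distances resolve to the lowest pair in order", {
  m <- matrix(1, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(m) <- 0
  t <- build_tree_from_distances(m)
  expect_equal(t$merge[1, ], c(-1L, -2L))   # (x, y), not (x, z) or (y, z)
})

test_that("similarity converts to distance as 1 - r", {
  expect_equal(similarity_to_distance(1), 0)
  expect_equal(similarity_to_distance(0), 1)
  expect_equal(similarity_to_distance(-1), 2)
  expect_error(similarity_to_distance(1.5), "\\[-1, 1\\]")
})

test_that("Newick output round-trips through an independent parser", {
  t2 <- build_sumdiff_tree(list(A = c(0, 0), B = c(2, 2)))  # distance 4
  phy <- ape::read.tree(text = to_newick(t2))
  expect_setequal(phy$tip.label, c("A", "B"))
  expect_equal(unname(phy$edge.length), c(2, 2))  # halved heights

  leaf <- structure(list(labels = "A", merge = matrix(0, 0, 2),
                         height = numeric(0)), class = "merge_tree")
  expect_equal(to_newick(leaf), "A;")

  skip_if_not_installed("phangorn")
  set.seed(9)
  for (rep in 1:10) {
    fam <- planted_quartet(seed = rep, root_length = 120)
    enc <- encode_alignment(fam$alignment, "volume")
    vecs <- lapply(fam$alignment$taxa, function(tx) enc[[tx]][["volume"]])
    t <- build_sumdiff_tree(vecs, labels = fam$alignment$taxa)
    phy <- ape::read.tree(text = to_newick(t))
    expect_s3_class(phy, "phylo")
    expect_true(all(phy$edge.length >= 0))
    # isomorphic to itself after a reparse (stable serialization)
    phy2 <- ape::read.tree(text = ape::write.tree(phy))
    expect_equal(phangorn::RF.dist(ape::unroot(phy), ape::unroot(phy2)), 0)
  }
})
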
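test_that("row scaling gives zero-mean unit-SD rows, zeros for constants", {
  expect_equal(row_scale(rbind(a = c(1, 2, 3)))[1, ],
               c(-1, 0, 1), ignore_attr = TRUE)
  expect_warning(sc <- row_scale(rbind(k = c(5, 5, 5))), "constant")
  expect_equal(sc[1, ], c(0, 0, 0), ignore_attr = TRUE)
  set.seed(1)
  m <- matrix(rnorm(50), 5, dimnames = list(paste0("r", 1:5), NULL))
  sc <- row_scale(m)
  expect_true(all(abs(rowMeans(sc)) < 1e-12))
  expect_true(all(abs(apply(sc, 1, sd) - 1) < 1e-12))
  # idempotence on non-constant rows
  expect_equal(row_scale(sc), sc, tolerance = 1e-12)
  expect_error(row_scale(rbind(a = c(1, NA, NA))), "fewer than 2")
})

test_that("hierarchical clustering is faithful to pairwise distances", {
  m <- rbind(r1 = c(0, 0), r2 = c(0, 1), r3 = c(10, 10))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$hclust$height[1], 1)  # first merge: {r1, r2} at height 1
  first <- sort(-hc$hclust$merge[1, ])
  expect_equal(sort(hc$hclust$labels[first]), c("r1", "r2"))
  # identical rows merge at height 0 and sit adjacent in the leaf order
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 0), d = c(0, 8, 2))
  hc2 <- hierarchical_cluster(m2)
  expect_equal(min(hc2$hclust$height), 0)
  pos <- match(c("a", "b"), hc2$order)
  expect_equal(abs(diff(pos)), 1)
  # row permutation preserves topology (same merge heights)
  perm <- c(3, 1, 4, 2)
  hc3 <- hierarchical_cluster(m2[perm, ])
  expect_equal(sort(hc3$hclust$height), sort(hc2$hclust$height))
})

test_that("Newick export re-parses to the same merge heights", {
  set.seed(5)
  m <- matrix(rnorm(8 * 6), 8, dimnames = list(paste0("g", 1:8), NULL))
  hc <- hierarchical_cluster(m)
  tree <- ape::read.tree(text = hc$newick)
  expect_setequal(tree$tip.label, rownames(m))
  # depths from the parsed tree: node height = leaf depth - node depth
  depth <- ape::node.depth.edgelength(tree)
  leaf_depth <- max(depth[seq_len(length(tree$tip.label))])
  node_heights <- leaf_depth - depth[-seq_len(length(tree$tip.label))]
  expect_equal(sort(node_heights), sort(hc$hclust$height), tolerance = 1e-8)
})

test_that("k-means recovers planted up/down split and flags upward cluster", {
  set.seed(2)
  up <- t(replicate(10, scale(1:4 + rnorm(4, 0, 0.1))[, 1]))
  down <- t(replicate(10, scale(4:1 + rnorm(4, 0, 0.1))[, 1]))
  m <- rbind(up, down)
  rownames(m) <- paste0("g", 1:20)
  km <- kmeans_trends(m, 2, seed = 4)
  expect_equal(length(unique(km$labels[1:10])), 1)
  expect_equal(length(unique(km$labels[11:20])), 1)
  expect_false(km$labels[1] == km$labels[20])
  expect_length(km$upward, 1)
  expect_setequal(km$upward_members, paste0("g", 1:10))
  # determinism under a fixed seed
  km2 <- kmeans_trends(m, 2, seed = 4)
  expect_identical(km$labels, km2$labels)
  # k = n: every row its own cluster; upward set = individually rising rows
  small <- m[c(1, 2, 11, 12), ]
  kn <- kmeans_trends(small, 4, seed = 1)
  expect_equal(sort(unname(kn$labels)), 1:4)
  expect_setequal(kn$upward_members, c("g1", "g2"))
  expect_error(kmeans_trends(m, 1), "k must be")
  expect_error(kmeans_trends(m, 21), "k must be")
})

test_that("k-means equals brute-force Lloyd from the same initial centers", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    m <- matrix(rnorm(n * 4), n)
    k <- sample(2:3, 1)
    seeds <- 100 + rep
    km <- kmeans_trends(`rownames<-`(m, paste0("r", 1:n)), k, seed = seeds)
    # recover the package's initial centers by re-running its seeding
    init <- grapeterp:::with_seed(seeds, grapeterp:::kmeanspp_init(m, k))
    bf <- oracle_lloyd(m, init)
    # same partition up to label permutation
    expect_equal(length(unique(paste(km$labels, bf$labels))),
                 length(unique(km$labels)))
    # objective never increases: final within-SS <= initial assignment SS
    init_ss <- sum(vapply(seq_len(n), function(i)
      min(colSums((t(init) - m[i, ])^2)), 0))
    expect_lte(sum(km$withinss), init_ss + 1e-9)
  }
})

test_that("trend classification follows the correlation and peak rules", {
  expect_equal(classify_trend(c(1, 2, 3, 4))$class, "increased")
  expect_equal(classify_trend(c(4, 3, 2, 1))$class, "decreased")
  nc <- classify_trend(c(5, 9, NA, NA))
  expect_equal(nc$class, "NC")
  expect_equal(classify_trend(c(1, 5, 4, 1)),
               list(class = "stable", peaked = TRUE))
  expect_equal(classify_trend(c(1, 2, 3, 4), annotated = FALSE)$class, "ND")
  # invariance to positive affine transforms
  p <- c(2, 7, 5, 9)
  expect_equal(classify_trend(p)$class, classify_trend(3 * p + 11)$class)
})

test_that("cell means average replicate libraries per condition", {
  m <- matrix(c(1, 3, 10, 20, 2, 4), 1)
  colnames(m) <- paste0("l", 1:6)
  rownames(m) <- "g"
  libs <- data.frame(library = colnames(m),
                     cell = c("c1", "c1", "c2", "c2", "c3", "c3"))
  cm <- cell_means(m, libs)
  expect_equal(cm["g", ], c(c1 = 2, c2 = 15, c3 = 3))
})
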
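make_profiles <- function(n, prefix, ncell = 16) {
  m <- matrix(rnorm(n * ncell), n,
              dimnames = list(paste0(prefix, seq_len(n)),
                              paste0("cell", seq_len(ncell))))
  m
}

test_that("correlation edges respect threshold, boundary and symmetry", {
  set.seed(6)
  a <- make_profiles(3, "a")
  b <- rbind(make_profiles(2, "b"), b3 = a["a1", ])  # b3 duplicates a1
  e <- correlation_edges(a, b, threshold = 0)
  expect_false(any(e$source == e$target))
  dup <- e[e$source == "a1" & e$target == "b3", ]
  expect_equal(dup$r, 1, tolerance = 1e-12)
  # a self pair (same id in both sets) is skipped even at r = 1
  b_self <- rbind(b, a1 = a["a1", ])
  e_self <- correlation_edges(a, b_self, threshold = 0.99)
  expect_false(any(e_self$source == "a1" & e_self$target == "a1"))
  # inclusive boundary: r exactly at threshold retained
  x <- rbind(p = c(1, 2, 3, 4))
  y <- rbind(q = c(1, 2, 3, 4))
  e2 <- correlation_edges(x, y, threshold = 1, inclusive = TRUE)
  expect_equal(nrow(e2), 1)
  e3 <- correlation_edges(x, y, threshold = 1, inclusive = FALSE)
  expect_equal(nrow(e3), 0)
  # symmetry of canonical edge sets
  eab <- correlation_edges(a, b, threshold = 0.2)
  eba <- correlation_edges(b, a, threshold = 0.2)
  expect_equal(eab[, c("source", "target")], eba[, c("source", "target")])
  expect_equal(eab$r, eba$r, tolerance = 1e-12)
})

test_that("edges match the brute-force all-pairs oracle", {
  set.seed(16)
  for (rep in 1:5) {
    a <- make_profiles(sample(3:6, 1), "a")
    b <- make_profiles(sample(3:6, 1), "b")
    for (thr in c(0, 0.3, 0.6)) {
      got <- correlation_edges(a, b, threshold = thr)
      want <- oracle_all_pairs(a, b, thr)
      expect_equal(got$source, want$source)
      expect_equal(got$target, want$target)
      expect_equal(got$r, want$r, tolerance = 1e-10)
    }
  }
})

test_that("raising the threshold never adds edges", {
  set.seed(26)
  a <- make_profiles(8, "a")
  b <- make_profiles(8, "b")
  thrs <- c(0, 0.2, 0.4, 0.6, 0.8, 0.95)
  ns <- vapply(thrs, function(t) nrow(correlation_edges(a, b, t)), 0L)
  expect_true(all(diff(ns) <= 0))
  key <- function(e) paste(e$source, e$target)
  for (i in seq_along(thrs)[-1]) {
    expect_true(all(key(correlation_edges(a, b, thrs[i])) %in%
                    key(correlation_edges(a, b, thrs[i - 1]))))
  }
})

test_that("anchored network admits TFs against every anchor", {
  set.seed(36)
  z1 <- as.numeric(scale(rnorm(16)))
  z2 <- as.numeric(scale(rnorm(16)))
  mk <- function(z, r, flip = 1)
    flip * (r * z + sqrt(1 - r^2) * rnorm(16)) * 1.3 + 5
  anchors <- rbind(anch1 = 5 + 1.5 * z1, anch2 = 5 + 1.5 * z2)
  # both-anchor TFs need correlation with z1 AND z2: use their average
  zb <- as.numeric(scale(z1 + z2))
  # r(TF, anchor_i) when TF tracks zb: dilute; instead plant via both
  tf_both <- function(sgn) sgn * (0.97 * z1 + 0.97 * z2) / sd(z1 + z2) + 5
  tfs <- rbind(tfneg1 = tf_both(-1) + rnorm(16, 0, 0.05),
               tfneg2 = tf_both(-1) + rnorm(16, 0, 0.05),
               tfpos1 = tf_both(1) + rnorm(16, 0, 0.05),
               tfonly1 = mk(z1, 0.97),
               tfonly2 = mk(z2, 0.97))
  colnames(anchors) <- colnames(tfs) <- paste0("cell", 1:16)
  ripening <- rbind(rip1 = -tfs["tfpos1", ] + rnorm(16, 0, 0.05),
                    rip2 = rnorm(16))
  colnames(ripening) <- colnames(anchors)
  # admission depends on realized correlations; require |r| >= 0.8 with both
  r1 <- cor(t(tfs), anchors["anch1", ])
  r2 <- cor(t(tfs), anchors["anch2", ])
  expected_tfs <- rownames(tfs)[abs(r1) >= 0.8 & abs(r2) >= 0.8]
  net <- build_anchored_network(anchors, tfs, ripening, threshold = 0.8)
  expect_setequal(net$tfs$id, expected_tfs)
  # single-anchor TFs excluded whenever they miss the other anchor
  expect_false("tfonly1" %in% net$tfs$id && abs(r2["tfonly1", 1]) < 0.8)
  # no anchor-ripening edges; every TF touches every anchor
  expect_true(all(net$edges$layer %in% c("anchor-TF", "TF-ripening")))
  at <- net$edges[net$edges$layer == "anchor-TF", ]
  expect_equal(nrow(at), 2 * nrow(net$tfs))
  # ripening members connect to >= 1 admitted TF
  tr <- net$edges[net$edges$layer == "TF-ripening", ]
  expect_true(all(tr$source %in% net$tfs$id))
  expect_setequal(net$ripening, unique(tr$target))
})

test_that("anchored network edge cases behave by contract", {
  set.seed(46)
  anchors <- rbind(g = rnorm(8))
  tf <- rbind(tf1 = 0.5 * anchors["g", ] + rnorm(8))
  colnames(anchors) <- colnames(tf) <- paste0("c", 1:8)
  r <- cor(tf["tf1", ], anchors["g", ])
  # below-threshold TF excluded
  net <- build_anchored_network(anchors, tf, tf[0, , drop = FALSE],
                                threshold = min(abs(r) + 0.01, 1))
  expect_equal(nrow(net$tfs), 0)
  expect_equal(nrow(net$edges), 0)
  # threshold above max |r|: empty network, never an error
  net2 <- build_anchored_network(anchors, tf, tf[0, , drop = FALSE],
                                 threshold = 1)
  expect_s3_class(net2, "anchored_network")
  expect_equal(length(net2$ripening), 0)
})

test_that("network export round-trips through SIF and GraphML", {
  set.seed(56)
  a <- make_profiles(3, "a")
  b <- make_profiles(3, "b")
  e <- correlation_edges(a, b, threshold = 0)
  dir <- tempfile()
  paths <- export_network(e, dir, "net")
  sif <- readLines(paths[1])
  expect_equal(length(sif), nrow(e))
  expect_true(all(grepl(" (pos|neg) ", sif)))
  g <- igraph::read_graph(paths[2], format = "graphml")
  expect_equal(igraph::gsize(g), nrow(e))
  got <- igraph::as_data_frame(g, "edges")
  key <- function(s, t) paste(pmin(s, t), pmax(s, t))
  m <- match(key(e$source, e$target), key(got$from, got$to))
  expect_false(anyNA(m))
  expect_equal(got$weight[m], e$r, tolerance = 1e-9)
  # empty network: valid files plus warning
  expect_warning(p0 <- export_network(e[0, ], tempfile(), "empty"),
                 "empty")
  expect_equal(readLines(p0[1]), character(0))
})
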
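test_that("read filtering trims 2 nt per end and applies the QC rule", {
  r <- filter_reads(data.frame(length = c(64, 63, 100, 70),
                               ambiguous = c(0, 0, 3, 2)))
  expect_equal(r$trimmed_length, c(60, 59, 96, 66))
  expect_equal(r$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(filter_reads(data.frame(length = -1, ambiguous = 0)),
               "negative")
})

test_that("multi-read rescue splits proportionally with uniform fallback", {
  expect_equal(
    assign_multireads(c(A = 30, B = 10),
                      list(list(candidates = c("A", "B"), multiplicity = 100))),
    c(A = 105, B = 35))
  expect_equal(
    assign_multireads(c(A = 0, B = 0),
                      list(list(candidates = c("A", "B"), multiplicity = 10))),
    c(A = 5, B = 5))
  expect_error(assign_multireads(c(A = 1),
                                 list(list(candidates = character(),
                                           multiplicity = 1))),
               "empty candidate")
})

test_that("rescue matches the per-read brute-force oracle and conserves reads", {
  set.seed(42)
  for (rep in 1:20) {
    n_t <- sample(3:8, 1)
    ids <- paste0("t", seq_len(n_t))
    U <- setNames(sample(0:50, n_t, replace = TRUE), ids)
    groups <- lapply(seq_len(sample(1:4, 1)), function(i) {
      list(candidates = sample(ids, sample(2:min(4, n_t), 1)),
           multiplicity = sample(0:200, 1))
    })
    stopifnot(sum(vapply(groups, `[[`, 0, "multiplicity")) <= 1000)
    got <- assign_multireads(U, groups)
    want <- oracle_assign_multireads(U, groups)
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(sum(got),
                 sum(U) + sum(vapply(groups, `[[`, 0, "multiplicity")),
                 tolerance = 1e-6)
  }
})

test_that("RPKM follows the definition and is scale-equivariant", {
  expect_equal(rpkm(1000, 2000, 1e6), 500)
  expect_equal(rpkm(0, 2000, 1e6), 0)
  expect_equal(rpkm(1e6, 1000, 1e6), 1e6)
  expect_error(rpkm(10, 0, 1e6), "length")
  expect_error(rpkm(10, 1000, 0), "total")
  m <- matrix(c(10, 20, 30, 40), 2,
              dimnames = list(c("a", "b"), c("l1", "l2")))
  r1 <- rpkm(m, c(1000, 2000), c(1e6, 2e6))
  r2 <- rpkm(2 * m, c(1000, 2000), 2 * c(1e6, 2e6))
  expect_equal(r1, r2)
  expect_equal(r1["a", "l1"], 1e9 * 10 / (1e6 * 1000))
})

test_that("exact conditional binomial test matches tail-sum oracle", {
  expect_equal(unname(deg_test(50, 1e6, 50, 1e6)),
               c(0, 1))
  expect_equal(unname(deg_test(0, 1e6, 64, 1e6)["log2_ratio"]), -6)
  # direct binomial tail summation oracle at p0 = 1/2
  oracle_p <- 2 * sum(choose(65, 0:1) / 2^65)
  expect_equal(unname(deg_test(1, 1e6, 64, 1e6)["p"]), oracle_p,
               tolerance = 1e-12)
  # antisymmetry
  a <- deg_test(17, 2e6, 90, 1e6)
  b <- deg_test(90, 1e6, 17, 2e6)
  expect_equal(unname(a["log2_ratio"]), -unname(b["log2_ratio"]))
  expect_equal(unname(a["p"]), unname(b["p"]))
  # unequal library sizes against an explicit conditional binomial
  x <- 30; y <- 12; n1 <- 3e6; n2 <- 1e6
  k <- x + y; p0 <- n1 / (n1 + n2)
  want <- min(1, 2 * min(sum(dbinom(0:x, k, p0)), sum(dbinom(x:k, k, p0))))
  expect_equal(unname(deg_test(x, n1, y, n2)["p"]), want, tolerance = 1e-12)
})

test_that("log2 ratio is monotone in x for fixed y", {
  ps <- vapply(c(1, 5, 20, 80, 320), function(x)
    unname(deg_test(x, 1e6, 40, 1e6)["log2_ratio"]), 0)
  expect_true(all(diff(ps) > 0))
})

test_that("DEG calling applies pooling, Bonferroni and the joint threshold", {
  counts <- rbind(g1 = c(10, 1280), g2 = c(100, 100), g3 = c(100, 100),
                  g4 = c(100, 100))
  colnames(counts) <- c("lib1", "lib2")
  libs <- data.frame(library = c("lib1", "lib2"),
                     cell = c("condA", "condB"),
                     total_reads = c(1e6, 1e6))
  res <- call_degs(counts, libs, list(c("condA", "condB")))
  expect_equal(sum(res$significant), 1)
  expect_equal(res$id[res$significant], "g1")
  expect_equal(res$adjusted_p, pmin(1, 4 * res$p))
  expect_true(all(res$adjusted_p >= res$p & res$adjusted_p <= 1))
  # identical counts: nothing significant
  same <- call_degs(rbind(a = c(5, 5), b = c(9, 9)), libs,
                    list(c("condA", "condB")))
  expect_false(any(same$significant))
  # Bonferroni arithmetic: m * p, not significant at alpha
  expect_equal(min(1, 100 * 0.001), 0.1)
  expect_error(call_degs(counts, libs, list(c("condA", "nope"))),
               "unknown condition")
  # replicate pooling: two replicate libraries sum before testing
  counts3 <- cbind(counts, lib3 = c(1280, 100, 100, 100))
  libs3 <- rbind(libs, data.frame(library = "lib3", cell = "condB",
                                  total_reads = 1e6))
  pooled <- call_degs(counts3, libs3, list(c("condA", "condB")))
  direct <- deg_test(10, 1e6, 1280 + 1280, 2e6)
  expect_equal(pooled$p[pooled$id == "g1"], unname(direct["p"]))
})

test_that("null simulation keeps the exact test at or below nominal size", {
  set.seed(7)
  n_pairs <- 500
  lam <- 100
  ps <- vapply(seq_len(n_pairs), function(i) {
    unname(deg_test(rpois(1, lam), 1e6, rpois(1, lam), 1e6)["p"])
  }, 0)
  expect_lte(mean(ps <= 0.05), 0.06)
})
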
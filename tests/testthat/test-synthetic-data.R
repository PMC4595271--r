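test_that("default design yields the study's library and sample counts", {
  d <- design_config()
  expect_equal(d$n_libraries, 24)
  expect_equal(d$n_metab_samples, 32)
  b <- simulate_berry_dataset(design_config(seed = 11))
  expect_equal(ncol(b$unique_counts), 24)
  expect_equal(nrow(b$libraries), 24)
  expect_equal(nrow(unique(b$metabolites[, c("region", "year", "stage",
                                             "replicate")])), 32)
  # design arithmetic under a non-default design
  d2 <- design_config(regions = c("A", "B", "C"), years = 2020,
                      libs_per_cell = c("E-L31" = 2L, "E-L35" = 2L,
                                        "E-L36" = 2L, "E-L38" = 1L),
                      metab_reps_per_cell = 3L)
  expect_equal(d2$n_libraries, 3 * 7)
  expect_equal(d2$n_metab_samples, 3 * 4 * 3)
  b2 <- simulate_berry_dataset(d2)
  expect_equal(ncol(b2$unique_counts), d2$n_libraries)
})

test_that("identical seed regenerates a bit-identical bundle and files", {
  b1 <- simulate_berry_dataset(design_config(seed = 5))
  b2 <- simulate_berry_dataset(design_config(seed = 5))
  expect_identical(b1, b2)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset_bundle(b1, d1)
  write_dataset_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  b3 <- simulate_berry_dataset(design_config(seed = 6))
  expect_false(identical(b1$unique_counts, b3$unique_counts))
})

test_that("simulation does not disturb the session RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_berry_dataset(design_config(seed = 2)))
  expect_identical(.Random.seed, before)
})

test_that("counts and concentrations are non-negative; totals conserved", {
  b <- simulate_berry_dataset(design_config(seed = 8))
  expect_true(all(b$unique_counts >= 0))
  expect_true(all(b$unique_counts == floor(b$unique_counts)))
  expect_true(all(b$metabolites$concentration_ug_L >= 0))
  for (l in b$libraries$library) {
    mult <- sum(b$multiread_groups$multiplicity[b$multiread_groups$library == l])
    expect_equal(b$libraries$total_reads[b$libraries$library == l],
                 sum(b$unique_counts[, l]) + mult)
  }
})

test_that("stable archetype stays flat across stages", {
  b <- simulate_berry_dataset(design_config(seed = 13))
  stable <- names(which(apply(b$latent_expression, 1, function(x) {
    # recovered archetype proxy: stable rows have tiny latent stage spread
    max(x) - min(x) < 1
  })))
  expect_gt(length(stable), 0)
  # per-stage CV of latent-mean linear expression stays small for flat rows
  cv <- apply(2^b$latent_expression[stable, , drop = FALSE], 1,
              function(x) sd(x) / mean(x))
  expect_true(all(cv < 0.5))
})

test_that("planted partner correlations are realized near target", {
  # realized r between the planted gene and compound latent cell profiles
  rs <- vapply(1:60, function(s) {
    eff <- planted_effect("UGT_01", "increasing",
                          partners = data.frame(id = "boundCpd01", r = 0.95),
                          noise_sd = 0.05)
    b <- simulate_berry_dataset(design_config(seed = 1000 + s), list(eff))
    cor(b$latent_expression["UGT_01", ], b$latent_metabolites["boundCpd01", ])
  }, 0)
  expect_true(all(abs(rs - 0.95) <= 0.12))
  expect_lt(abs(mean(rs) - 0.95), 0.05)
})

test_that("impossible correlation and unknown archetype are rejected", {
  expect_error(planted_effect("g", partners = data.frame(id = "m", r = 1.2)),
               "impossible correlation")
  expect_error(planted_effect("g", archetype = "wiggly"))
  expect_error(simulate_berry_dataset(design_config(),
                                      list(planted_effect("nope_99"))),
               "not among generated ids")
})

test_that("worked fixture has its documented hand-checkable structure", {
  f <- make_worked_fixture()
  expect_lte(nrow(f$transcripts), 10)
  expect_lte(length(unique(f$metabolites$compound)), 4)
  hdr <- f$unique_counts["HDRlike", ]
  expect_true(all(diff(hdr) > 0))
  expect_equal(classify_trend(hdr)$class, "increased")
  # proportional rescue of the {GENEA, GENEB} group: 30/10 uniques -> 75/25
  lib1 <- colnames(f$unique_counts)[1]
  C <- assign_multireads(
    f$unique_counts[, lib1],
    f$multiread_groups[f$multiread_groups$library == lib1, ])
  expect_equal(unname(C["GENEA"] - f$unique_counts["GENEA", lib1]), 75)
  expect_equal(unname(C["GENEB"] - f$unique_counts["GENEB", lib1]), 25)
  # totals conserve uniques + multireads
  expect_equal(unname(f$libraries$total_reads),
               unname(colSums(f$unique_counts) + 100))
})
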
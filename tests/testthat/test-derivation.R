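test_that("AAindex1 records map file order onto the canonical alphabet", {
  rec <- aaindex_record("TST0001", 1:20)
  pm <- parse_aaindex1(rec)
  v <- pm$values["TST0001", ]
  expect_identical(unname(v[c("A", "L", "R", "K", "I", "V")]),
                   c(1, 11, 2, 12, 10, 20))
  expect_identical(colnames(pm$values), aa_alphabet())

  two <- parse_aaindex1(c(aaindex_record("TSTB", 21:40),
                          aaindex_record("TSTA", 41:60)))
  expect_identical(rownames(two$values), c("TSTB", "TSTA"))  # file order kept
})

test_that("NA tokens populate the missing mask", {
  vals <- as.character(1:20)
  vals[5] <- "NA"  # file position 5 is C/P first row -> amino acid C
  rec <- aaindex_record("TSTNA", vals)
  rec[4] <- sub("NA", "NA    ", rec[4])
  pm <- parse_aaindex1(rec)
  expect_true(pm$missing_mask["TSTNA", "C"])
  expect_false(any(pm$missing_mask["TSTNA", setdiff(aa_alphabet(), "C")]))
})

test_that("malformed records raise a parse error naming the accession", {
  rec <- aaindex_record("TSTBAD", 1:20)
  rec[4] <- "     1  2  3"  # 3 slots instead of 10
  err <- expect_error(parse_aaindex1(rec), class = "ps_error_parse")
  expect_match(conditionMessage(err), "TSTBAD")
})

test_that("unit-interval scaling is exact, idempotent, and drops constants", {
  m <- new_property_matrix(
    rbind(a = seq(1, 39, by = 2), b = rep(7, 20), c = rnorm(20)) |>
      `colnames<-`(aa_alphabet()),
    index_ids = c("a", "b", "c"))
  expect_warning(s <- scale_unit_interval(m),
                 class = "ps_warning_constant_index")
  expect_identical(attr(s, "dropped_constant"), "b")
  expect_equal(unname(s$values["a", ]), seq(0, 1, length.out = 20))
  expect_equal(min(s$values["c", ]), 0)
  expect_equal(max(s$values["c", ]), 1)
  s2 <- scale_unit_interval(s)
  expect_equal(s2$values, s$values)
})

test_that("co-varying elimination removes one of a correlated pair", {
  set.seed(11)
  base <- rnorm(20)
  indep <- rnorm(20)
  vals <- rbind(i1 = base, i2 = 2 * base + 1, i3 = indep)
  colnames(vals) <- aa_alphabet()
  m <- new_property_matrix(vals)
  out <- eliminate_covarying(m, target_n = 2)
  kept <- rownames(out$values)
  # brute force: of the three possible removals, only dropping i1 or i2
  # leaves a residual pair that is not perfectly correlated
  expect_true("i3" %in% kept)
  expect_length(intersect(kept, c("i1", "i2")), 1)
  expect_identical(attr(out, "removal_order"),
                   setdiff(c("i1", "i2"), kept))
})

test_that("elimination honours target size, identity and missing-value rules", {
  set.seed(12)
  vals <- matrix(rnorm(8 * 20), nrow = 8,
                 dimnames = list(paste0("x", 1:8), aa_alphabet()))
  vals["x3", "P"] <- NA
  m <- new_property_matrix(vals)
  out <- eliminate_covarying(m, target_n = 4)
  expect_identical(nrow(out$values), 4L)
  expect_identical(attr(out, "dropped_missing"), "x3")
  same <- eliminate_covarying(m, target_n = 7)  # 7 = all without-missing rows
  expect_length(attr(same, "removal_order"), 0)
  expect_error(eliminate_covarying(m, target_n = 8),
               class = "ps_error_eliminate")
})

test_that("PCA recovers analytic variance ratios 4:2:1 from exact factors", {
  latent <- exact_latent_factors(c(4, 2, 1), seed = 21)     # 20 x 3
  mix <- random_orthogonal(3, seed = 22)
  x <- latent %*% mix                                       # variables 20 x 3
  m <- new_property_matrix(t(x) |> `colnames<-`(aa_alphabet()),
                           index_ids = paste0("v", 1:3))
  fit <- pca_scores(m, n_components = 3, center = TRUE, scale = FALSE)
  expect_equal(fit$pca$variance_fractions[1:3], c(4, 2, 1) / 7,
               tolerance = 1e-9)
})

test_that("PCA variance fractions match eigen-decomposition oracles", {
  for (seed in c(31, 32, 33)) {
    set.seed(seed)
    p <- sample(4:10, 1)
    vals <- matrix(rnorm(p * 20), nrow = p,
                   dimnames = list(paste0("v", seq_len(p)), aa_alphabet()))
    m <- new_property_matrix(vals)
    for (sc in c(FALSE, TRUE)) {
      fit <- pca_scores(m, n_components = 2, center = TRUE, scale = sc)
      vf <- fit$pca$variance_fractions
      oracle <- oracle_variance_fractions(t(vals), scale = sc)
      expect_equal(vf[seq_len(p)], oracle[seq_len(p)], tolerance = 1e-9)
      expect_equal(sum(vf), 1, tolerance = 1e-9)
    }
  }
})

test_that("PCA contracts hold: centering, rotation invariance, determinism", {
  set.seed(41)
  vals <- matrix(rnorm(6 * 20), nrow = 6,
                 dimnames = list(paste0("v", 1:6), aa_alphabet()))
  m <- new_property_matrix(vals)
  fit <- pca_scores(m, n_components = 4, center = TRUE, scale = FALSE)
  expect_true(all(abs(colMeans(fit$pca$scores)) < 1e-9))
  # orthogonal remap of the variables leaves eigen-spectrum untouched
  rot <- random_orthogonal(6, seed = 42)
  m2 <- new_property_matrix(t(t(vals) %*% rot) |> `colnames<-`(aa_alphabet()),
                            index_ids = paste0("w", 1:6))
  fit2 <- pca_scores(m2, n_components = 4, center = TRUE, scale = FALSE)
  expect_equal(fit$pca$variance_fractions, fit2$pca$variance_fractions,
               tolerance = 1e-9)
  # bit-identical rerun incl. the sign convention
  again <- pca_scores(m, n_components = 4, center = TRUE, scale = FALSE)
  expect_identical(fit$pca$scores, again$pca$scores)
  expect_identical(desc_matrix(fit$table), desc_matrix(again$table))
})

test_that("scaling refuses zero-variance variables by name", {
  vals <- rbind(ok = rnorm(20), flat = rep(3, 20))
  colnames(vals) <- aa_alphabet()
  m <- new_property_matrix(vals)
  err <- expect_error(pca_scores(m, 1, scale = TRUE), class = "ps_error_pca")
  expect_match(conditionMessage(err), "flat")
})

test_that("the fixture generator is seeded and bookkeeps planted variance", {
  a <- generate_fixture_property_matrix(30, 3, noise_sd = 0.1, seed = 5)
  b <- generate_fixture_property_matrix(30, 3, noise_sd = 0.1, seed = 5)
  expect_identical(a$values, b$values)
  noiseless <- generate_fixture_property_matrix(30, 3, noise_sd = 0, seed = 6)
  fit <- pca_scores(noiseless, 3, center = TRUE, scale = TRUE)
  expect_equal(sum(fit$pca$variance_fractions[1:3]), 1, tolerance = 1e-9)
  expect_equal(attr(noiseless, "planted")$planted_fraction, 1,
               tolerance = 1e-12)
})

test_that("the derivation pipeline recovers planted factor structure", {
  pm <- generate_fixture_property_matrix(100, 3, noise_sd = 0.05, seed = 7)
  fit <- derive_protfp(pm, target_n = 90, n_components = 3)
  expect_gte(cumsum(fit$pca$variance_fractions)[3], 0.75)
  expect_identical(nrow(fit$table), 20L)
  expect_error(derive_protfp(pm, target_n = 101), class = "ps_error_eliminate")
  # deterministic rerun
  fit2 <- derive_protfp(pm, target_n = 90, n_components = 3)
  expect_identical(desc_matrix(fit$table), desc_matrix(fit2$table))
})

test_that("parameter recovery: explained variance tracks the planted fraction", {
  pm <- generate_fixture_property_matrix(60, 3, noise_sd = 0.1, seed = 8)
  planted <- attr(pm, "planted")$planted_fraction
  fit <- derive_protfp(pm, target_n = 60, n_components = 3)
  cum3 <- cumsum(fit$pca$variance_fractions)[3]
  expect_lt(abs(cum3 - planted), 0.02)
})
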
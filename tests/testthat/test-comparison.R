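test_that("amino-acid distance matrices have metric structure", {
  for (nm in c("ProtFP_PCA3", "Zscales_5", "Zscales_Binned")) {
    d <- aa_distance_matrix(get_table(nm))
    expect_identical(dim(unclass(d)), c(20L, 20L))
    expect_true(all(diag(unclass(d)) == 0))
    expect_lt(max(abs(unclass(d) - t(unclass(d)))), 1e-12)
    expect_true(all(unclass(d) >= 0 & unclass(d) <= 1))
    expect_equal(max(unclass(d)), 1)
  }
})

test_that("the L-I distance under ProtFP matches hand arithmetic", {
  d <- aa_distance_matrix(get_table("ProtFP_PCA3"), scale = FALSE)
  # Table rows: L = (5.76, -1.33, -1.71), I = (6.58, -1.73, -2.49)
  expect_equal(d["L", "I"], sqrt(0.82^2 + 0.40^2 + 0.78^2),
               tolerance = 1e-12)
})

test_that("distances match a brute-force double-loop oracle", {
  for (seed in c(51, 52)) {
    tab <- random_descriptor_table(k = sample(2:5, 1), seed = seed)
    mine <- aa_distance_matrix(tab, scale = FALSE)
    expect_equal(unclass(mine), oracle_distance_matrix(desc_matrix(tab)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("feature tables are rejected from the distance calculation", {
  expect_error(aa_distance_matrix(get_table("ProtFP_Feature")),
               class = "ps_error_unsupported")
})

test_that("pair statistics count 400 cells and match the loop oracle", {
  a <- aa_distance_matrix(random_descriptor_table(3, seed = 61))
  b <- aa_distance_matrix(random_descriptor_table(5, seed = 62))
  st <- pair_difference_stats(a, b)
  expect_identical(st$n_pairs, 400L)
  oracle <- oracle_pair_stats(unclass(a), unclass(b))
  expect_equal(st$mean_abs_difference, oracle$mean, tolerance = 1e-12)
  expect_equal(st$sd_difference, oracle$sd, tolerance = 1e-12)
  # identity
  self <- pair_difference_stats(a, a)
  expect_identical(self$mean_abs_difference, 0)
  expect_identical(self$sd_difference, 0)
})

test_that("unscaled matrices are refused by the pair statistics", {
  a <- aa_distance_matrix(get_table("MSWHIM"), scale = FALSE)
  b <- aa_distance_matrix(get_table("VHSE"))
  expect_error(pair_difference_stats(a, b), class = "ps_error_unscaled")
})

test_that("inter-descriptor distance is blind to rotation, scale and order", {
  tab <- random_descriptor_table(4, seed = 71, name = "base")
  vals <- desc_matrix(tab)
  variants <- list(
    rotated = vals %*% random_orthogonal(4, seed = 72),
    reflected = vals %*% diag(c(-1, 1, -1, 1)),
    scaled = 3.7 * vals,
    permuted = vals[, c(3, 1, 4, 2)]
  )
  for (nm in names(variants)) {
    v <- variants[[nm]]
    colnames(v) <- paste0("C", 1:4)
    other <- new_descriptor_table(v, name = nm, kind = "physicochemical-PCA")
    st <- pair_difference_stats(aa_distance_matrix(tab),
                                aa_distance_matrix(other))
    expect_lt(st$mean_abs_difference, 1e-12)
  }
})

test_that("the inter-descriptor matrix is symmetric with zero diagonal", {
  tabs <- list(A = random_descriptor_table(3, 81, "A"),
               B = random_descriptor_table(4, 82, "B"),
               C = random_descriptor_table(5, 83, "C"))
  im <- inter_descriptor_matrix(tabs)
  m <- unclass(im)[seq_along(tabs), seq_along(tabs)]
  expect_identical(diag(m), setNames(c(0, 0, 0), names(tabs)))
  expect_identical(m, t(m))
  expect_true(all(m >= 0))
  expect_identical(nrow(attr(im, "pair_stats")), 3L)
  expect_error(inter_descriptor_matrix(tabs[1]), class = "ps_error_compare")
})

test_that("descriptor-space PCA obeys variance contracts and guards", {
  im <- run_full_analysis()$inter_matrix
  pca <- pca_of_descriptor_space(im)
  vf <- pca$variance_fractions
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-9)
  expect_error(pca_of_descriptor_space(im, n_components = 13),
               class = "ps_error_compare")
  expect_error(pca_of_descriptor_space(unclass(im)[1:2, 1:2]),
               class = "ps_error_compare")
  # eigen oracle on the centered 12 x 12 matrix
  oracle <- oracle_variance_fractions(unclass(im), scale = FALSE)
  expect_equal(vf[1:11], oracle[1:11], tolerance = 1e-9)
})

test_that("the default comparison uses 12 numeric sets, feature excluded", {
  cmp <- run_full_analysis()
  expect_length(cmp$tables, 12)
  expect_identical(cmp$excluded, "ProtFP_Feature")
  expect_identical(dim(unclass(cmp$inter_matrix)), c(12L, 12L))
  expect_true(all(cmp$pair_stats$n_pairs == 400L))
  expect_identical(nrow(cmp$pair_stats), 66L)  # 12 choose 2
})

test_that("the limited analysis collapses duplicate truncations", {
  lim <- run_full_analysis(truncate_to = 2)
  expect_length(lim$tables, 8)
  expect_true(all(c("ProtFP_PCA", "Zscales") %in% names(lim$tables)))
  expect_setequal(lim$collapsed$ProtFP_PCA,
                  c("ProtFP_PCA3", "ProtFP_PCA5", "ProtFP_PCA8"))
  expect_setequal(lim$collapsed$Zscales, c("Zscales_3", "Zscales_5"))
  expect_true("Zscales_Binned" %in% lim$excluded)
  expect_true(all(vapply(lim$tables, function(t)
    length(desc_components(t)), numeric(1)) == 2))
})

test_that("comparison artifacts are written as the five TSV families", {
  dir <- withr::local_tempdir()
  cmp <- run_full_analysis(c("MSWHIM", "Tscales", "STscales"))
  write_comparison_outputs(cmp, dir, header_lines = "seed: none")
  files <- list.files(dir)
  expect_true(all(c("aa_distance_MSWHIM.tsv", "pair_stats.tsv",
                    "inter_descriptor_matrix.tsv", "pca_scores.tsv",
                    "pca_variance.tsv") %in% files))
  dm <- utils::read.delim(file.path(dir, "aa_distance_MSWHIM.tsv"),
                          comment.char = "#", check.names = FALSE)
  expect_identical(dim(dm), c(20L, 21L))  # AA column + 20 distance columns
  expect_equal(as.matrix(dm[, -1]),
               unclass(cmp$distance_matrices$MSWHIM), ignore_attr = TRUE)
})

test_that("tidy and glance summarise comparison objects", {
  cmp <- run_full_analysis(c("MSWHIM", "Tscales", "STscales", "VHSE"))
  td <- tidy(cmp)
  expect_identical(nrow(td), 6L)
  gl <- glance(cmp)
  expect_identical(gl$n_sets, 4L)
  expect_true(gl$cum_var_pc2 > 0 && gl$cum_var_pc2 <= 1)
  ev <- tidy(cmp$pca, matrix = "eigenvalues")
  expect_equal(max(ev$cumulative), 1, tolerance = 1e-9)
})
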
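# Descriptor-set similarity methodology: per-set scaled 20x20 Euclidean
# amino-acid distance matrices, |difference| statistics over all 400 cells
# per pair of sets, the symmetric inter-descriptor matrix of mean
# differences, and its PCA.

#' Amino-acid distance matrix of a descriptor set
#'
#' Pairwise Euclidean distances between the 20 standard amino acids in the
#' component space of one descriptor set, as a full 20 x 20 matrix (diagonal
#' zero, both symmetric copies present). With `scale = TRUE` (the default,
#' and a required step of the comparison methodology) the matrix is scaled
#' linearly to `[0, 1]` by dividing by its largest entry, so 0 means "most
#' similar" and 1 "most dissimilar". Binned tables are allowed (bits act as
#' 0/1 coordinates); feature tables carry arbitrary hash integers whose
#' distances are meaningless, and are rejected.
#'
#' @param table A `descriptor_table` (numeric or binned).
#' @param scale Scale entries to `[0, 1]` by the maximum.
#' @return An `aa_distance_matrix`: a 20 x 20 matrix with attributes
#'   `descriptor` and `scaled`.
#' @export
#' @examples
#' d <- aa_distance_matrix(get_table("ProtFP_PCA3"))
#' d["L", "I"]
aa_distance_matrix <- function(table, scale = TRUE) {
  if (is_feature_table(table)) {
    abort(paste0("descriptor set '", desc_name(table),
                 "' is feature/hash based; distances between hash values ",
                 "are not meaningful"),
          class = "ps_error_unsupported")
  }
  d <- as.matrix(stats::dist(desc_matrix(table), method = "euclidean"))
  if (scale) {
    mx <- max(d)
    if (mx > 0) d <- d / mx
  }
  structure(d, descriptor = desc_name(table), scaled = scale,
            class = c("aa_distance_matrix", "matrix", "array"))
}

#' @method tidy aa_distance_matrix
#' @export
tidy.aa_distance_matrix <- function(x, ...) {
  df <- as_tibble(as.data.frame(unclass(x)), rownames = "aa_1")
  out <- tidyr::pivot_longer(df, -"aa_1", names_to = "aa_2",
                             values_to = "distance")
  dplyr::mutate(out, descriptor = attr(x, "descriptor"), .before = 1)
}

#' Heat map of an amino-acid distance matrix
#'
#' @param object An `aa_distance_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aa_distance_matrix
#' @export
autoplot.aa_distance_matrix <- function(object, ...) {
  df <- tidy.aa_distance_matrix(object)
  df$aa_1 <- factor(df$aa_1, levels = .AA_CODES)
  df$aa_2 <- factor(df$aa_2, levels = rev(.AA_CODES))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa_1, y = .data$aa_2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = attr(object, "descriptor"), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Distance-difference statistics for a pair of descriptor sets
#'
#' Over all 400 cells of two scaled amino-acid distance matrices (diagonal
#' and both symmetric copies included, exactly as the methodology counts
#' them), takes the absolute difference per cell and returns its mean and
#' standard deviation. The mean is the inter-descriptor distance; a large
#' value means the two sets perceive amino-acid similarity very differently.
#' Unscaled input is rejected: scaling is part of the published procedure.
#'
#' @param a,b `aa_distance_matrix` objects, scaled, same amino-acid order.
#' @param sd_method `"population"` (divide by n = 400; default) or
#'   `"sample"` (n - 1).
#' @return A one-row tibble: `set_a`, `set_b`, `n_pairs`,
#'   `mean_abs_difference`, `sd_difference`.
#' @export
pair_difference_stats <- function(a, b, sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  if (!isTRUE(attr(a, "scaled")) || !isTRUE(attr(b, "scaled"))) {
    abort("pair_difference_stats needs scaled distance matrices",
          class = "ps_error_unscaled")
  }
  if (!identical(rownames(a), rownames(b))) {
    abort("amino-acid ordering differs between the two matrices",
          class = "ps_error_shape")
  }
  d <- abs(unclass(a) - unclass(b))
  n <- length(d)
  mu <- mean(d)
  sdv <- if (sd_method == "population") {
    sqrt(mean((d - mu)^2))
  } else {
    stats::sd(d)
  }
  tibble(set_a = attr(a, "descriptor"), set_b = attr(b, "descriptor"),
         n_pairs = n, mean_abs_difference = mu, sd_difference = sdv)
}

#' Inter-descriptor distance matrix
#'
#' Builds the symmetric matrix whose entry (i, j) is the mean absolute
#' difference between the scaled amino-acid distance matrices of descriptor
#' sets i and j (zero diagonal). This is the matrix submitted to PCA to map
#' the space of descriptor sets.
#'
#' @param tables A named list of `descriptor_table` objects (>= 2; feature
#'   tables are rejected by [aa_distance_matrix()]).
#' @param sd_method Passed to [pair_difference_stats()].
#' @return An `inter_descriptor_matrix` with attributes `pair_stats` (tibble
#'   of all unordered pairs) and `distance_matrices`.
#' @export
inter_descriptor_matrix <- function(tables, sd_method = "population") {
  if (length(tables) < 2) {
    abort("need at least 2 descriptor tables", class = "ps_error_compare")
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- purrr::map_chr(tables, desc_name)
  }
  dms <- purrr::map(tables, aa_distance_matrix, scale = TRUE)
  n <- length(dms)
  m <- matrix(0, n, n, dimnames = list(names(tables), names(tables)))
  stats_list <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st <- pair_difference_stats(dms[[i]], dms[[j]], sd_method = sd_method)
      st$set_a <- names(tables)[i]
      st$set_b <- names(tables)[j]
      m[i, j] <- m[j, i] <- st$mean_abs_difference
      stats_list[[length(stats_list) + 1]] <- st
    }
  }
  structure(m, pair_stats = dplyr::bind_rows(stats_list),
            distance_matrices = dms,
            class = c("inter_descriptor_matrix", "matrix", "array"))
}

#' @method tidy inter_descriptor_matrix
#' @export
tidy.inter_descriptor_matrix <- function(x, ...) {
  df <- as_tibble(as.data.frame(unclass(x)), rownames = "set_a")
  tidyr::pivot_longer(df, -"set_a", names_to = "set_b",
                      values_to = "mean_abs_difference")
}

#' @method autoplot inter_descriptor_matrix
#' @export
autoplot.inter_descriptor_matrix <- function(object, ...) {
  df <- tidy.inter_descriptor_matrix(object)
  lev <- rownames(object)
  df$set_a <- factor(df$set_a, levels = lev)
  df$set_b <- factor(df$set_b, levels = rev(lev))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_a, y = .data$set_b,
                                   fill = .data$mean_abs_difference)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean |d|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' PCA of the inter-descriptor matrix
#'
#' Maps descriptor sets into a low-dimensional space: rows of the
#' inter-descriptor matrix are observations, columns are variables. The
#' matrix is mean-centered but not variable-standardized by default (all
#' entries already share one scale); classical multidimensional scaling is
#' available as an alternative embedding.
#'
#' @param m An `inter_descriptor_matrix` (n >= 3).
#' @param n_components Components to keep (default: all computable).
#' @param scale Standardize variables before the PCA.
#' @param method `"pca"` (default) or `"cmdscale"` for classical MDS.
#' @return A `descriptor_pca` (for `"cmdscale"`, loadings are absent).
#' @export
pca_of_descriptor_space <- function(m, n_components = NULL, scale = FALSE,
                                    method = c("pca", "cmdscale")) {
  method <- match.arg(method)
  n <- nrow(m)
  if (n < 3) {
    abort("need at least 3 descriptor sets for a meaningful PCA",
          class = "ps_error_compare")
  }
  if (!is.null(n_components) && n_components > n) {
    abort(paste0("n_components (", n_components, ") exceeds the number of ",
                 "descriptor sets (", n, ")"),
          class = "ps_error_compare")
  }
  if (method == "cmdscale") {
    k <- n_components %||% (n - 1)
    fit <- stats::cmdscale(unclass(m), k = k, eig = TRUE)
    pos_eig <- pmax(fit$eig, 0)
    return(new_descriptor_pca(
      scores = fit$points, loadings = matrix(numeric(0), 0, 0),
      variance_fractions = (pos_eig / sum(pos_eig))[seq_len(k)],
      n_informative = sum(fit$eig > 1e-12)))
  }
  pr <- stats::prcomp(unclass(m), center = TRUE, scale. = scale)
  fixed <- .fix_signs(pr$rotation, pr$x)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  k <- n_components %||% ncol(pr$x)
  new_descriptor_pca(
    scores = fixed$scores[, seq_len(k), drop = FALSE],
    loadings = fixed$rotation[, seq_len(k), drop = FALSE],
    variance_fractions = vf,
    center = pr$center, scale = pr$scale,
    n_informative = sum(pr$sdev > 1e-12))
}

# longest common prefix of a character vector, trimmed of trailing '_'
.common_label <- function(names) {
  if (length(names) == 1) return(names)
  chars <- strsplit(names, "")
  upto <- min(lengths(chars))
  k <- 0
  for (i in seq_len(upto)) {
    if (length(unique(purrr::map_chr(chars, i))) == 1) k <- i else break
  }
  lab <- sub("_+$", "", substr(names[1], 1, k))
  if (nzchar(lab)) lab else names[1]
}

#' Run the full descriptor-set comparison
#'
#' One call reproducing the complete comparison methodology: resolve the
#' descriptor sets (by default every bundled numeric set — the feature-based
#' ProtFP variant is excluded automatically since all of its hash distances
#' would be maximal), build each scaled amino-acid distance matrix, compute
#' all pairwise distance-difference statistics, assemble the
#' inter-descriptor matrix and run its PCA.
#'
#' With `truncate_to`, every numeric set is first cut to its leading
#' components (the "limited" analysis focusing on the dominant structure).
#' Sets that become value-identical after truncation (the ProtFP PCA
#' variants; the two Z-scales versions) are collapsed into one entry, and
#' binned sets — which have no ordered components to truncate — are dropped.
#'
#' @param set_names Identifiers to compare (default: all bundled sets).
#' @param truncate_to Optional number of leading components for the limited
#'   analysis.
#' @param sd_method Passed to [pair_difference_stats()].
#' @param pca_scale Standardize variables in the descriptor-space PCA.
#' @return A `descriptor_comparison`: list with `tables`,
#'   `distance_matrices`, `pair_stats`, `inter_matrix`, `pca`, and the
#'   bookkeeping fields `excluded` and `collapsed`.
#' @export
#' @examples
#' cmp <- run_full_analysis()
#' glance(cmp)
run_full_analysis <- function(set_names = NULL, truncate_to = NULL,
                              sd_method = "population", pca_scale = FALSE) {
  set_names <- set_names %||% list_descriptor_sets()
  tables <- purrr::map(set_names, get_table)
  names(tables) <- purrr::map_chr(tables, desc_name)
  excluded <- character()

  feat <- purrr::map_lgl(tables, is_feature_table)
  if (any(feat)) {
    excluded <- c(excluded, names(tables)[feat])
    tables <- tables[!feat]
  }
  collapsed <- list()
  if (!is.null(truncate_to)) {
    binned <- purrr::map_lgl(tables, is_binned_table)
    if (any(binned)) {
      excluded <- c(excluded, names(tables)[binned])
      tables <- tables[!binned]
    }
    tables <- purrr::map(tables, truncate_table, k = truncate_to)
    names(tables) <- purrr::map_chr(tables, desc_name)
    # collapse value-identical truncations (deterministic, first-seen order)
    sig <- purrr::map_chr(tables, function(t)
      paste(signif(desc_matrix(t), 12), collapse = ","))
    groups <- split(names(tables), factor(sig, levels = unique(sig)))
    keep <- character()
    new_names <- character()
    for (g in groups) {
      lab <- .common_label(g)
      keep <- c(keep, g[1])
      new_names <- c(new_names, lab)
      if (length(g) > 1) collapsed[[lab]] <- g
    }
    tables <- tables[keep]
    names(tables) <- new_names
  }
  if (length(tables) < 2) {
    abort("fewer than 2 usable descriptor sets", class = "ps_error_compare")
  }
  im <- inter_descriptor_matrix(tables, sd_method = sd_method)
  pca <- pca_of_descriptor_space(im, scale = pca_scale)
  structure(
    list(tables = tables,
         distance_matrices = attr(im, "distance_matrices"),
         pair_stats = attr(im, "pair_stats"),
         inter_matrix = im,
         pca = pca,
         excluded = excluded,
         collapsed = collapsed,
         truncate_to = truncate_to),
    class = "descriptor_comparison"
  )
}

#' @export
print.descriptor_comparison <- function(x, ...) {
  cat("<descriptor_comparison> ", length(x$tables), " descriptor sets",
      if (!is.null(x$truncate_to)) paste0(" (truncated to ", x$truncate_to,
                                          " components)"), "\n", sep = "")
  if (length(x$excluded) > 0) {
    cat("excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  vf <- x$pca$variance_fractions
  cat("descriptor-space PCA: PC1+PC2 explain ",
      round(100 * sum(vf[1:2]), 1), "% of the variance\n", sep = "")
  invisible(x)
}

#' @method tidy descriptor_comparison
#' @export
tidy.descriptor_comparison <- function(x, ...) x$pair_stats

#' @method glance descriptor_comparison
#' @export
glance.descriptor_comparison <- function(x, ...) {
  vf <- x$pca$variance_fractions
  tibble(n_sets = length(x$tables),
         n_pairs_per_set = 400L,
         cum_var_pc2 = sum(vf[1:2]),
         truncate_to = x$truncate_to %||% NA_integer_)
}

#' @method autoplot descriptor_comparison
#' @export
autoplot.descriptor_comparison <- function(object, ...) {
  autoplot.descriptor_pca(object$pca)
}

#' Write the comparison artifacts as TSV files
#'
#' Writes `aa_distance_<set>.tsv` for every set, `pair_stats.tsv`,
#' `inter_descriptor_matrix.tsv`, `pca_scores.tsv` and `pca_variance.tsv`
#' into `dir`.
#'
#' @param x A `descriptor_comparison`.
#' @param dir Output directory (created if needed).
#' @param header_lines Optional provenance `#` lines for every file.
#' @return Invisibly, the paths written.
#' @export
write_comparison_outputs <- function(x, dir, header_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(x$distance_matrices)) {
    p <- file.path(dir, paste0("aa_distance_", nm, ".tsv"))
    df <- as.data.frame(unclass(x$distance_matrices[[nm]]))
    df <- cbind(AA = rownames(df), df)
    .write_tsv(df, p, header_lines)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "pair_stats.tsv")
  .write_tsv(x$pair_stats, p, header_lines); paths <- c(paths, p)
  p <- file.path(dir, "inter_descriptor_matrix.tsv")
  df <- as.data.frame(unclass(x$inter_matrix))
  df <- cbind(set = rownames(df), df)
  .write_tsv(df, p, header_lines); paths <- c(paths, p)
  p <- file.path(dir, "pca_scores.tsv")
  sc <- as.data.frame(x$pca$scores)
  sc <- cbind(set = rownames(sc), sc)
  .write_tsv(sc, p, header_lines); paths <- c(paths, p)
  p <- file.path(dir, "pca_variance.tsv")
  .write_tsv(as.data.frame(tidy(x$pca, matrix = "eigenvalues")), p,
             header_lines)
  paths <- c(paths, p)
  invisible(paths)
}
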
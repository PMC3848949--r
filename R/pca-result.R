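#' PCA results
#'
#' Container for a principal component analysis as used throughout the
#' package: `scores` (observations x components), `loadings` (variables x
#' components), per-component explained-variance fractions (over all
#' computable components, summing to 1), and the centering/scaling vectors
#' applied to the variables.
#'
#' @param scores,loadings Numeric matrices with dimnames.
#' @param variance_fractions Per-component explained-variance fractions.
#' @param center,scale Centering / scaling vectors (or `FALSE`).
#' @param n_informative Number of components with non-negligible variance.
#' @return A `descriptor_pca` object.
#' @export
new_descriptor_pca <- function(scores, loadings, variance_fractions,
                               center = FALSE, scale = FALSE,
                               n_informative = ncol(scores)) {
  structure(
    list(scores = scores, loadings = loadings,
         variance_fractions = as.numeric(variance_fractions),
         center = center, scale = scale,
         n_informative = n_informative),
    class = "descriptor_pca"
  )
}

#' @export
print.descriptor_pca <- function(x, ...) {
  cat("<descriptor_pca> ", nrow(x$scores), " observations, ",
      ncol(x$scores), " components\n", sep = "")
  vf <- x$variance_fractions
  cat("variance fractions:", paste(round(utils::head(vf, 8), 3),
                                   collapse = " "),
      if (length(vf) > 8) "...", "\n")
  invisible(x)
}

#' Tidy a PCA result
#'
#' @param x A `descriptor_pca`.
#' @param matrix Which matrix to tidy: `"scores"` (default), `"loadings"`,
#'   or `"eigenvalues"` (per-component variance fractions).
#' @param ... Unused.
#' @return A tibble in long format.
#' @method tidy descriptor_pca
#' @export
tidy.descriptor_pca <- function(x, matrix = c("scores", "loadings",
                                              "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble(component = seq_along(x$variance_fractions),
                  variance_fraction = x$variance_fractions,
                  cumulative = cumsum(x$variance_fractions)))
  }
  m <- x[[matrix]]
  who <- if (matrix == "scores") "observation" else "variable"
  df <- as_tibble(as.data.frame(m), rownames = who)
  tidyr::pivot_longer(df, -dplyr::all_of(who), names_to = "component",
                      values_to = "value")
}

#' @method glance descriptor_pca
#' @export
glance.descriptor_pca <- function(x, ...) {
  vf <- x$variance_fractions
  tibble(n_obs = nrow(x$scores),
         n_components = ncol(x$scores),
         var_pc1 = vf[1],
         var_pc2 = if (length(vf) >= 2) vf[2] else NA_real_,
         cum_var_pc2 = if (length(vf) >= 2) vf[1] + vf[2] else vf[1])
}

#' Plot the first two components of a PCA result
#'
#' Scatter plot of observation scores on PC1/PC2 with text labels and the
#' explained variance in the axis titles.
#'
#' @param object A `descriptor_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot descriptor_pca
#' @export
autoplot.descriptor_pca <- function(object, ...) {
  df <- as_tibble(as.data.frame(object$scores[, 1:2, drop = FALSE]),
                  rownames = "label")
  names(df)[2:3] <- c("PC1", "PC2")
  vf <- round(100 * object$variance_fractions[1:2], 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.6, size = 3) +
    ggplot2::labs(x = paste0("PC1 (", vf[1], "%)"),
                  y = paste0("PC2 (", vf[2], "%)")) +
    ggplot2::theme_minimal()
}
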
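# ProtFP-style derivation: raw amino-acid property matrices -> unit-interval
# scaling -> recursive elimination of co-varying indices -> PCA scores.

#' Property matrices
#'
#' A `property_matrix` holds raw per-amino-acid property indices (AAindex
#' style): an n_indices x 20 numeric matrix with columns in canonical
#' alphabet order, a parallel logical `missing_mask`, and the index
#' identifiers as rownames.
#'
#' @param values n x 20 numeric matrix (columns keyed by amino acid; any
#'   column order is accepted and reordered canonically).
#' @param index_ids Identifiers, one per row; must be unique.
#' @param missing_mask Optional logical matrix flagging absent values; by
#'   default wherever `values` is `NA`.
#' @return A `property_matrix`.
#' @export
new_property_matrix <- function(values, index_ids = rownames(values),
                                missing_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(index_ids)) {
    abort("property matrix needs index identifiers", class = "ps_error_pm")
  }
  if (anyDuplicated(index_ids) > 0) {
    abort(paste0("duplicated index id(s): ",
                 paste(unique(index_ids[duplicated(index_ids)]),
                       collapse = ", ")),
          class = "ps_error_pm")
  }
  if (is.null(colnames(values)) || !setequal(colnames(values), .AA_CODES)) {
    abort("property matrix columns must be the 20 standard amino acids",
          class = "ps_error_pm")
  }
  values <- values[, .AA_CODES, drop = FALSE]
  storage.mode(values) <- "double"
  rownames(values) <- index_ids
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    missing_mask <- as.matrix(missing_mask)[, .AA_CODES, drop = FALSE]
    dimnames(missing_mask) <- dimnames(values)
  }
  structure(list(values = values, missing_mask = missing_mask),
            class = "property_matrix")
}

#' @export
print.property_matrix <- function(x, ...) {
  cat("<property_matrix> ", nrow(x$values), " index/indices x 20 amino acids",
      if (any(x$missing_mask)) paste0(" (", sum(x$missing_mask),
                                      " missing values)"), "\n", sep = "")
  print(utils::head(x$values, 4))
  invisible(x)
}

#' @method tidy property_matrix
#' @export
tidy.property_matrix <- function(x, ...) {
  df <- as_tibble(as.data.frame(x$values), rownames = "index_id")
  tidyr::pivot_longer(df, -"index_id", names_to = "AA", values_to = "value")
}

# AAindex1 data block column order: two rows of ten under the 'I' header
.AAINDEX_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
.AAINDEX_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse AAindex1-format property records
#'
#' Reads one or more AAindex1 flat-file records (`H` accession line, `D`
#' description, an `I` header followed by two data lines of ten values in
#' the conventional A/L, R/K, N/M, D/F, C/P, Q/S, E/T, G/W, H/Y, I/V column
#' order, records terminated by `//`). `NA` tokens flag missing values.
#'
#' @param input A file path or a character vector of lines.
#' @return A [new_property_matrix()] with one row per record, in file order.
#' @export
parse_aaindex1 <- function(input) {
  lines <- if (length(input) == 1 && file.exists(input)) {
    readLines(input, encoding = "UTF-8")
  } else {
    as.character(input)
  }
  lines <- .normalize_minus(lines)
  rec_start <- 1L
  acc <- character()
  vals <- list()
  i <- 1L
  current_acc <- NA_character_
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^H ", ln)) {
      current_acc <- trimws(sub("^H ", "", ln))
    } else if (grepl("^I( |$)", ln)) {
      if (i + 2 > n) {
        abort(paste0("record '", current_acc, "': data lines missing after 'I' ",
                     "header at line ", i),
              class = "ps_error_parse")
      }
      tok1 <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
      tok2 <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
      if (length(tok1) != 10 || length(tok2) != 10) {
        abort(paste0("record '", current_acc, "': expected 2 x 10 value slots ",
                     "at lines ", i + 1, "-", i + 2, ", found ",
                     length(tok1), " + ", length(tok2)),
              class = "ps_error_parse")
      }
      row <- setNames(numeric(20), c(.AAINDEX_ROW1, .AAINDEX_ROW2))
      tok <- c(tok1, tok2)
      is_na <- toupper(tok) == "NA"
      suppressWarnings(num <- as.numeric(tok))
      if (any(is.na(num) & !is_na)) {
        bad <- which(is.na(num) & !is_na)[1]
        abort(paste0("record '", current_acc, "': unparseable value '",
                     tok[bad], "' near line ", i + 1),
              class = "ps_error_parse")
      }
      row[] <- num
      if (is.na(current_acc)) {
        current_acc <- paste0("RECORD", length(acc) + 1)
      }
      acc <- c(acc, current_acc)
      vals[[length(vals) + 1]] <- row
      i <- i + 2L
    } else if (grepl("^//", ln)) {
      current_acc <- NA_character_
    }
    i <- i + 1L
  }
  if (length(vals) == 0) {
    abort("no AAindex1 records found", class = "ps_error_parse")
  }
  m <- do.call(rbind, vals)
  new_property_matrix(m, index_ids = acc)
}

#' Read a property matrix from plain TSV
#'
#' Rows are index ids (first column `index_id`), columns the 20 standard
#' amino acids. Empty cells and `NA` flag missing values.
#'
#' @param path File path.
#' @return A [new_property_matrix()].
#' @export
read_property_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  new_property_matrix(m, index_ids = ids)
}

#' Linearly scale each property index to the unit interval
#'
#' Each index (row) is mapped by `(x - min) / (max - min)` over its
#' non-missing values, so the minimum becomes 0 and the maximum 1 — the
#' pre-scaling applied before descriptor derivation, in place of raw index
#' values. Missing entries stay missing. Constant indices cannot be scaled
#' and are dropped with a warning.
#'
#' @param m A `property_matrix`.
#' @return A `property_matrix` with values in `[0, 1]`.
#' @export
scale_unit_interval <- function(m) {
  stopifnot(inherits(m, "property_matrix"))
  vals <- m$values
  vals[m$missing_mask] <- NA
  rng <- t(apply(vals, 1, range, na.rm = TRUE))
  const <- rng[, 2] - rng[, 1] <= 0
  if (any(const)) {
    warn(paste0("dropping constant index/indices (cannot scale to [0,1]): ",
                paste(rownames(vals)[const], collapse = ", ")),
         class = "ps_warning_constant_index")
  }
  keep <- which(!const)
  scaled <- (vals[keep, , drop = FALSE] - rng[keep, 1]) /
    (rng[keep, 2] - rng[keep, 1])
  out <- new_property_matrix(scaled, index_ids = rownames(vals)[keep])
  attr(out, "dropped_constant") <- rownames(vals)[const]
  out
}

# max absolute Pearson correlation of each index against the others
.max_abs_cor <- function(vals) {
  cm <- abs(stats::cor(t(vals)))
  diag(cm) <- NA
  apply(cm, 1, max, na.rm = TRUE)
}

#' Recursively eliminate the most co-varying property indices
#'
#' Repeatedly removes the index whose maximum absolute Pearson correlation
#' against the remaining indices is largest, until `target_n` indices are
#' left. Ties break lexicographically on the index id, making the procedure
#' deterministic. Indices with any missing value among the 20 amino acids
#' are excluded up front (and reported), since correlations over partial
#' profiles are not comparable.
#'
#' @param m A `property_matrix`.
#' @param target_n Number of indices to retain.
#' @return A `property_matrix` with `target_n` rows; attributes
#'   `removal_order` (ids in removal order) and `dropped_missing` record the
#'   audit trail.
#' @export
eliminate_covarying <- function(m, target_n) {
  stopifnot(inherits(m, "property_matrix"))
  has_missing <- apply(m$missing_mask | is.na(m$values), 1, any)
  dropped_missing <- rownames(m$values)[has_missing]
  vals <- m$values[!has_missing, , drop = FALSE]
  if (!is.numeric(target_n) || length(target_n) != 1 ||
      target_n < 1 || target_n != round(target_n) || target_n > nrow(vals)) {
    abort(paste0("target_n must be an integer in [1, ", nrow(vals),
                 "] (indices without missing values)"),
          class = "ps_error_eliminate")
  }
  removal_order <- character()
  while (nrow(vals) > target_n) {
    score <- .max_abs_cor(vals)
    worst <- which(score >= max(score) - 1e-12)
    victim <- sort(rownames(vals)[worst])[1]
    removal_order <- c(removal_order, victim)
    vals <- vals[rownames(vals) != victim, , drop = FALSE]
  }
  out <- new_property_matrix(vals, index_ids = rownames(vals))
  attr(out, "removal_order") <- removal_order
  attr(out, "dropped_missing") <- dropped_missing
  out
}

# deterministic sign convention: per component, the largest-|loading|
# variable gets a positive loading
.fix_signs <- function(rotation, scores) {
  for (j in seq_len(ncol(rotation))) {
    pivot <- which.max(abs(rotation[, j]))
    if (rotation[pivot, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' PCA of a property matrix with amino acids as observations
#'
#' Runs principal component analysis treating the 20 amino acids as
#' observations and the property indices as variables (the orientation that
#' yields one score vector per amino acid), with optional mean centering and
#' unit-variance scaling of the indices. Component signs follow a fixed
#' convention — the largest-magnitude loading of each component is positive —
#' so repeated runs are bit-identical.
#'
#' @param m A `property_matrix` without missing values.
#' @param n_components Number of leading components to keep in the returned
#'   descriptor table.
#' @param center,scale Centering / scaling flags passed to the PCA.
#' @param name Name given to the derived descriptor table.
#' @return List with `table` (a [new_descriptor_table()] of scores) and
#'   `pca` (a `descriptor_pca`: scores, loadings, variance fractions and the
#'   centering/scaling vectors used).
#' @export
pca_scores <- function(m, n_components, center = TRUE, scale = TRUE,
                       name = "derived") {
  stopifnot(inherits(m, "property_matrix"))
  if (any(m$missing_mask | is.na(m$values))) {
    abort("property matrix contains missing values; filter them first",
          class = "ps_error_pca")
  }
  x <- t(m$values)  # 20 observations x n indices
  if (scale) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      abort(paste0("zero-variance variable(s) cannot be scaled: ",
                   paste(colnames(x)[v == 0], collapse = ", ")),
            class = "ps_error_pca")
    }
  }
  pr <- stats::prcomp(x, center = center, scale. = scale)
  n_avail <- sum(pr$sdev > 1e-12)
  if (!is.numeric(n_components) || length(n_components) != 1 ||
      n_components < 1 || n_components != round(n_components) ||
      n_components > ncol(pr$x)) {
    abort(paste0("n_components must be an integer in [1, ", ncol(pr$x), "]"),
          class = "ps_error_pca")
  }
  fixed <- .fix_signs(pr$rotation, pr$x)
  variance_fractions <- pr$sdev^2 / sum(pr$sdev^2)
  pca <- new_descriptor_pca(scores = fixed$scores, loadings = fixed$rotation,
                            variance_fractions = variance_fractions,
                            center = pr$center, scale = pr$scale,
                            n_informative = n_avail)
  k <- n_components
  tab <- new_descriptor_table(
    fixed$scores[, seq_len(k), drop = FALSE],
    name = name, kind = "physicochemical-PCA",
    source = paste0("derived from ", nrow(m$values), " property indices"),
    variance_fractions = variance_fractions[seq_len(k)],
    cumulative_fractions = cumsum(variance_fractions)[seq_len(k)]
  )
  list(table = tab, pca = pca)
}

#' Derive a ProtFP-style descriptor set from raw property indices
#'
#' The full derivation pipeline: unit-interval scaling of every index,
#' recursive elimination of the most co-varying indices down to `target_n`,
#' then PCA (mean-centered and variance-scaled) of the retained indices with
#' amino acids as observations. The returned audit log records dropped
#' indices and the elimination order.
#'
#' @param raw A `property_matrix` of raw index values.
#' @param target_n Number of indices to retain before the PCA.
#' @param n_components Number of principal components kept in the table.
#' @param name Name for the derived table.
#' @return List with `table`, `pca` and `audit` (a tibble of pipeline steps).
#' @export
#' @examples
#' pm <- generate_fixture_property_matrix(30, 3, noise_sd = 0.05, seed = 7)
#' fit <- derive_protfp(pm, target_n = 20, n_components = 3)
#' cumulative_fractions(fit$table)
derive_protfp <- function(raw, target_n = 58, n_components = 8,
                          name = "ProtFP_derived") {
  stopifnot(inherits(raw, "property_matrix"))
  audit <- tibble(step = "input",
                  detail = paste0(nrow(raw$values), " raw indices"))
  scaled <- withCallingHandlers(
    scale_unit_interval(raw),
    ps_warning_constant_index = function(w) invokeRestart("muffleWarning")
  )
  dropped_const <- attr(scaled, "dropped_constant")
  if (length(dropped_const) > 0) {
    audit <- bind_rows(audit, tibble(
      step = "scale_unit_interval",
      detail = paste0("dropped constant: ", paste(dropped_const, collapse = ", "))))
  }
  reduced <- eliminate_covarying(scaled, target_n = target_n)
  if (length(attr(reduced, "dropped_missing")) > 0) {
    audit <- bind_rows(audit, tibble(
      step = "eliminate_covarying",
      detail = paste0("excluded (missing values): ",
                      paste(attr(reduced, "dropped_missing"), collapse = ", "))))
  }
  audit <- bind_rows(audit, tibble(
    step = "eliminate_covarying",
    detail = paste0("removal order: ",
                    paste(attr(reduced, "removal_order"), collapse = ", "))))
  fit <- pca_scores(reduced, n_components = n_components,
                    center = TRUE, scale = TRUE, name = name)
  audit <- bind_rows(audit, tibble(
    step = "pca_scores",
    detail = paste0(target_n, " indices -> ", n_components,
                    " components; cumulative variance ",
                    round(cumsum(fit$pca$variance_fractions)[n_components], 4))))
  list(table = fit$table, pca = fit$pca, audit = audit)
}
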
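#' Descriptor tables
#'
#' A descriptor table maps each of the 20 standard amino acids to a short
#' numeric vector (its "scale" values). It is stored as a tibble whose first
#' column is `AA` (canonical order) followed by one numeric column per
#' component, with metadata held in attributes: `ps_name`, `kind`, `source`,
#' `variance_fractions`, `cumulative_fractions` and free-text `notes`.
#' Binned tables ([binned_descriptor_table]) additionally carry a `bins`
#' attribute and hold 0/1 bit columns.
#'
#' @param values A 20-row data frame or matrix of component values, rows
#'   keyed by amino acid (rownames or an `AA` column).
#' @param name Identifier of the set.
#' @param kind One of `"physicochemical-PCA"`, `"topological-PCA"`,
#'   `"factor-analysis"`, `"electrostatic-PCA"`, `"substitution-derived"`,
#'   `"binned"`, `"feature"`.
#' @param source Citation string.
#' @param variance_fractions Optional per-component explained-variance
#'   fractions, stored as published.
#' @param cumulative_fractions Optional cumulative explained variance.
#' @param notes Optional free-text metadata.
#' @return A `descriptor_table` (a tibble subclass).
#' @export
new_descriptor_table <- function(values, name, kind, source = NA_character_,
                                 variance_fractions = NULL,
                                 cumulative_fractions = NULL,
                                 notes = NULL) {
  kinds <- c("physicochemical-PCA", "topological-PCA", "factor-analysis",
             "electrostatic-PCA", "substitution-derived", "binned", "feature")
  if (!kind %in% kinds) {
    abort(paste0("unknown descriptor kind '", kind, "'"), class = "ps_error_kind")
  }
  if (is.matrix(values)) {
    values <- as.data.frame(values)
    values <- cbind(AA = rownames(values), values)
  }
  values <- as_tibble(values)
  if (!"AA" %in% names(values)) {
    abort("descriptor values need an 'AA' column or rownames",
          class = "ps_error_table")
  }
  values <- values[match(.AA_CODES, values$AA), , drop = FALSE]
  tbl <- tibble::new_tibble(values, nrow = nrow(values),
                            class = "descriptor_table")
  attr(tbl, "ps_name") <- name
  attr(tbl, "kind") <- kind
  attr(tbl, "source") <- source
  attr(tbl, "variance_fractions") <- variance_fractions
  attr(tbl, "cumulative_fractions") <- cumulative_fractions
  attr(tbl, "notes") <- notes
  violations <- validate_table(tbl)
  if (length(violations) > 0) {
    abort(paste0("invalid descriptor table '", name, "': ",
                 paste(violations, collapse = "; ")),
          class = "ps_error_table")
  }
  tbl
}

#' @rdname new_descriptor_table
#' @param bins Tibble of bin definitions with columns `scale`, `zscale`,
#'   `label`, `lower`, `upper`; a residue scores 1 in the bin whose
#'   `[lower, upper)` interval contains its underlying scale value.
#' @export
new_binned_descriptor_table <- function(values, name, bins,
                                        source = NA_character_, notes = NULL) {
  tbl <- new_descriptor_table(values, name = name, kind = "binned",
                              source = source, notes = notes)
  class(tbl) <- c("binned_descriptor_table", class(tbl))
  attr(tbl, "bins") <- as_tibble(bins)
  violations <- validate_table(tbl)
  if (length(violations) > 0) {
    abort(paste0("invalid binned descriptor table '", name, "': ",
                 paste(violations, collapse = "; ")),
          class = "ps_error_table")
  }
  tbl
}

#' Accessors for descriptor-table metadata
#'
#' @param x A `descriptor_table`.
#' @return `desc_name()`, `desc_kind()` and `desc_source()` return a string;
#'   `desc_components()` the component labels; `desc_matrix()` the 20 x k
#'   numeric matrix with amino-acid rownames; `variance_fractions()` and
#'   `cumulative_fractions()` the stored fractions (or `NULL`).
#' @export
desc_name <- function(x) attr(x, "ps_name")

#' @rdname desc_name
#' @export
desc_kind <- function(x) attr(x, "kind")

#' @rdname desc_name
#' @export
desc_source <- function(x) attr(x, "source")

#' @rdname desc_name
#' @export
desc_components <- function(x) setdiff(names(x), "AA")

#' @rdname desc_name
#' @export
desc_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, desc_components(x), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$AA
  m
}

#' @rdname desc_name
#' @export
variance_fractions <- function(x) attr(x, "variance_fractions")

#' @rdname desc_name
#' @export
cumulative_fractions <- function(x) attr(x, "cumulative_fractions")

is_binned_table <- function(x) inherits(x, "binned_descriptor_table")
is_feature_table <- function(x) identical(desc_kind(x), "feature")

#' Validate a descriptor table
#'
#' Checks the structural invariants of a descriptor table and reports every
#' violation found: exactly one row per standard amino acid in canonical
#' order, no missing or non-finite values, cumulative explained-variance
#' fractions non-decreasing and at most 1, and — for binned tables — 0/1
#' bits with pairwise-distinct amino-acid bit vectors and exactly one active
#' bin per scale.
#'
#' @param table A `descriptor_table` or anything table-shaped.
#' @return Character vector of violation messages; empty when valid.
#' @export
#' @examples
#' validate_table(get_table("ProtFP_PCA8"))  # character(0)
validate_table <- function(table) {
  out <- character()
  if (!"AA" %in% names(table)) {
    return("missing 'AA' column")
  }
  missing_aa <- setdiff(.AA_CODES, table$AA)
  if (length(missing_aa) > 0) {
    out <- c(out, paste0("missing amino acid(s): ",
                         paste(missing_aa, collapse = ", ")))
  }
  if (anyDuplicated(table$AA) > 0) {
    out <- c(out, paste0("duplicated amino acid(s): ",
                         paste(unique(table$AA[duplicated(table$AA)]),
                               collapse = ", ")))
  }
  if (nrow(table) != 20) {
    out <- c(out, paste0("expected 20 rows, found ", nrow(table)))
  }
  comp <- setdiff(names(table), "AA")
  if (length(comp) < 1) {
    out <- c(out, "no component columns")
  } else {
    vals <- as.matrix(as.data.frame(table)[, comp, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    if (any(!is.finite(vals))) {
      out <- c(out, "non-finite or missing values")
    }
  }
  cf <- attr(table, "cumulative_fractions")
  if (!is.null(cf)) {
    if (any(diff(cf) < 0)) out <- c(out, "cumulative_fractions decrease")
    if (any(cf > 1 + 1e-12)) out <- c(out, "cumulative_fractions exceed 1")
  }
  vf <- attr(table, "variance_fractions")
  if (!is.null(vf) && (any(vf <= 0) || any(vf > 1))) {
    out <- c(out, "variance_fractions outside (0, 1]")
  }
  if (inherits(table, "binned_descriptor_table") && length(comp) >= 1 &&
      length(out) == 0) {
    bits <- desc_matrix(table)
    if (!all(bits %in% c(0, 1))) {
      out <- c(out, "binned table contains non-binary values")
    }
    keys <- apply(bits, 1, paste, collapse = "")
    if (anyDuplicated(keys) > 0) {
      dup <- rownames(bits)[duplicated(keys) | duplicated(keys, fromLast = TRUE)]
      out <- c(out, paste0("bit vectors not pairwise distinct (",
                           paste(sort(dup), collapse = ", "), ")"))
    }
    bins <- attr(table, "bins")
    if (!is.null(bins)) {
      per_scale <- split(seq_len(nrow(bins)), bins$scale)
      for (sc in names(per_scale)) {
        cols <- paste0(bins$scale[per_scale[[sc]]], "_",
                       bins$label[per_scale[[sc]]])
        cols <- intersect(cols, colnames(bits))
        if (length(cols) > 0 &&
            !all(rowSums(bits[, cols, drop = FALSE]) == 1)) {
          out <- c(out, paste0("scale '", sc,
                               "' does not have exactly one active bin per amino acid"))
        }
      }
    }
  }
  out
}

#' Keep the first k components of a descriptor table
#'
#' Returns a copy of a numeric descriptor table restricted to its first `k`
#' components, with variance metadata truncated to match. Binned and
#' feature tables have no ordered components and are rejected.
#'
#' @param table A numeric `descriptor_table`.
#' @param k Number of leading components to keep (`1 <= k <= ncomp`).
#' @return A `descriptor_table` with `k` components; the input is untouched.
#' @export
#' @examples
#' truncate_table(get_table("ProtFP_PCA8"), 2)
truncate_table <- function(table, k) {
  if (is_binned_table(table) || is_feature_table(table)) {
    abort(paste0("cannot truncate ", desc_kind(table), " table '",
                 desc_name(table), "': components are not ordered"),
          class = "ps_error_truncate")
  }
  comp <- desc_components(table)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > length(comp) ||
      k != round(k)) {
    abort(paste0("k must be an integer in [1, ", length(comp), "]"),
          class = "ps_error_truncate")
  }
  vf <- variance_fractions(table)
  cf <- cumulative_fractions(table)
  out <- new_descriptor_table(
    as.data.frame(table)[, c("AA", comp[seq_len(k)]), drop = FALSE],
    name = desc_name(table),
    kind = desc_kind(table),
    source = desc_source(table),
    variance_fractions = if (!is.null(vf)) vf[seq_len(min(k, length(vf)))],
    cumulative_fractions = if (!is.null(cf)) cf[seq_len(min(k, length(cf)))],
    notes = attr(table, "notes")
  )
  attr(out, "truncated_to") <- as.integer(k)
  out
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", desc_name(x), " (", desc_kind(x), "), ",
      length(desc_components(x)), " component(s)\n", sep = "")
  cf <- cumulative_fractions(x)
  if (!is.null(cf)) {
    cat("cumulative variance:", paste(format(cf), collapse = " "), "\n")
  }
  NextMethod()
}

#' @method tidy descriptor_table
#' @export
tidy.descriptor_table <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(as.data.frame(x)), -"AA",
                      names_to = "component", values_to = "value")
}
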
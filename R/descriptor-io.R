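# Descriptor table file format: optional '# key: value' metadata header lines,
# then a TSV body with header 'AA<TAB>c1..ck' and one row per amino acid.
# The reader normalizes the Unicode minus sign (U+2212) so tables copied out
# of typeset documents load cleanly.

.normalize_minus <- function(x) gsub("−", "-", x)

.parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (!grepl(":", body, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", body))
    val <- trimws(sub("^[^:]*:\\s*", "", body))
    meta[[key]] <- val
  }
  meta
}

.meta_numeric <- function(meta, key) {
  if (is.null(meta[[key]])) return(NULL)
  as.numeric(trimws(strsplit(meta[[key]], ",")[[1]]))
}

#' Read and write descriptor tables as TSV
#'
#' The on-disk format is plain TSV with a `AA` first column, one row per
#' amino acid, preceded by optional `# key: value` metadata lines (`name`,
#' `kind`, `source`, `variance_fractions`, `cumulative_fractions`, `notes`).
#' Unicode minus signs are normalized on read.
#'
#' @param path File path.
#' @param name,kind Override metadata from the file header.
#' @return `read_descriptor_table()` returns a `descriptor_table`.
#' @export
read_descriptor_table <- function(path, name = NULL, kind = NULL) {
  lines <- .normalize_minus(readLines(path, encoding = "UTF-8"))
  is_meta <- grepl("^#", lines)
  meta <- .parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2) {
    abort(paste0("descriptor file '", path, "' has no data rows"),
          class = "ps_error_io")
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  rows <- fields[-1]
  bad <- which(lengths(rows) != length(header))
  if (length(bad) > 0) {
    abort(paste0("descriptor file '", path, "': row ", bad[1], " has ",
                 lengths(rows)[bad[1]], " fields, expected ", length(header)),
          class = "ps_error_io")
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  for (cc in setdiff(header, "AA")) df[[cc]] <- as.numeric(df[[cc]])
  new_descriptor_table(
    df,
    name = name %||% meta$name %||% tools::file_path_sans_ext(basename(path)),
    kind = kind %||% meta$kind %||% "physicochemical-PCA",
    source = meta$source %||% NA_character_,
    variance_fractions = .meta_numeric(meta, "variance_fractions"),
    cumulative_fractions = .meta_numeric(meta, "cumulative_fractions"),
    notes = meta$notes
  )
}

#' @rdname read_descriptor_table
#' @param x A `descriptor_table`.
#' @param extra_meta Named character vector of additional `# key: value`
#'   header lines (e.g. provenance from a CLI run).
#' @return `write_descriptor_table()` invisibly returns `path`.
#' @export
write_descriptor_table <- function(x, path, extra_meta = NULL) {
  meta <- c(
    name = desc_name(x), kind = desc_kind(x),
    source = if (!is.na(desc_source(x) %||% NA)) desc_source(x),
    variance_fractions = if (!is.null(variance_fractions(x)))
      paste(variance_fractions(x), collapse = ","),
    cumulative_fractions = if (!is.null(cumulative_fractions(x)))
      paste(cumulative_fractions(x), collapse = ","),
    extra_meta
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  df <- as.data.frame(x)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(df, format, trim = TRUE, scientific = FALSE),
                              sep = "\t")), con)
  invisible(path)
}

# generic TSV writer used by the analysis/CLI outputs
.write_tsv <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines) > 0) writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
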
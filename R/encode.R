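# Sequence encoding: position-major concatenation of descriptor rows.

# core worker: `actions` gives one of "encode", "zero", "skip" per residue
.encode_core <- function(res, table, actions, id) {
  keep <- actions != "skip"
  res_k <- res[keep]
  act_k <- actions[keep]
  mat <- desc_matrix(table)
  comp <- desc_components(table)
  k <- length(comp)
  L <- length(res_k)
  values <- numeric(L * k)
  for (i in seq_len(L)) {
    if (act_k[i] == "encode") {
      values[(i - 1) * k + seq_len(k)] <- mat[res_k[i], ]
    }
  }
  names(values) <- paste0("p", rep(seq_len(L), each = k), "_",
                          rep(comp, times = L))
  flagged <- which(actions != "encode")
  manifest <- tibble(position = flagged, symbol = res[flagged],
                     action = actions[flagged])
  structure(
    list(id = id, length = L, values = values, manifest = manifest,
         descriptor = desc_name(table)),
    class = "encoded_sequence"
  )
}

.clean_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(gsub("\\s", "", seq))
  if (!nzchar(seq)) {
    abort("sequence is empty after whitespace stripping",
          class = "ps_error_encode")
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(res == .STOP_CODE)) {
    abort(paste0("stop symbol '*' at position ",
                 which(res == .STOP_CODE)[1], " cannot be encoded"),
          class = "ps_error_encode")
  }
  res
}

#' Encode a sequence with a descriptor table
#'
#' Converts a single-letter amino-acid sequence into the position-major
#' concatenation of the descriptor rows of its residues, the standard input
#' representation for proteochemometric (PCM) and peptide QSAR models.
#' A sequence of length L encoded with a k-component table yields L*k values
#' labelled `p<position>_<component>` (1-based positions).
#'
#' Residues without a descriptor row (B, J, O, U, X, Z and the gap symbol
#' `-`) follow `unknown_policy`: `"error"` (default) aborts naming the
#' offending position and symbol, `"skip"` drops the residue (the encoded
#' length shrinks and positions renumber), and `"zero"` emits a block of
#' zeros for it. The stop symbol `*` is always an error. Lowercase input is
#' uppercased and whitespace stripped first.
#'
#' @param seq A single sequence string.
#' @param table A `descriptor_table` (numeric, binned or feature).
#' @param unknown_policy `"error"`, `"skip"` or `"zero"`.
#' @param id Optional sequence identifier carried into the result.
#' @return An `encoded_sequence`: list with `id`, `length` (residues encoded),
#'   `values` (named numeric vector) and a `manifest` tibble of residues that
#'   were skipped or zero-filled.
#' @export
#' @examples
#' encode_sequence("GA", get_table("ProtFP_PCA3"))
encode_sequence <- function(seq, table,
                            unknown_policy = c("error", "skip", "zero"),
                            id = NA_character_) {
  unknown_policy <- match.arg(unknown_policy)
  res <- .clean_sequence(seq)
  known <- res %in% .AA_CODES
  if (any(!known) && unknown_policy == "error") {
    pos <- which(!known)[1]
    abort(paste0("non-standard residue '", res[pos], "' at position ", pos,
                 " (policy = 'error')"),
          class = "ps_error_encode")
  }
  actions <- ifelse(known, "encode", unknown_policy)
  .encode_core(res, table, actions, id)
}

#' @export
print.encoded_sequence <- function(x, ...) {
  cat("<encoded_sequence> id=", x$id, " length=", x$length,
      " descriptor=", x$descriptor, " (", length(x$values), " values)\n",
      sep = "")
  print(utils::head(x$values, 12))
  invisible(x)
}

#' @method as_tibble encoded_sequence
#' @export
as_tibble.encoded_sequence <- function(x, ...) {
  tibble(id = x$id, !!!as.list(x$values))
}

#' Encode a sequence with the binned Z-scales
#'
#' Shortcut for [encode_sequence()] with the `Zscales_Binned` table: each
#' residue contributes the 0/1 bit vector of its Z-scale class assignments
#' (one active class per scale; all 20 amino acids have distinct patterns).
#'
#' @inheritParams encode_sequence
#' @return An `encoded_sequence` of bits.
#' @export
#' @examples
#' encode_zscales_binned("W")
encode_zscales_binned <- function(seq,
                                  unknown_policy = c("error", "skip", "zero"),
                                  id = NA_character_) {
  encode_sequence(seq, get_table("Zscales_Binned"),
                  unknown_policy = match.arg(unknown_policy), id = id)
}

#' Encode a collection of (aligned) sequences into a feature matrix
#'
#' Encodes every record and binds the results into one wide tibble (first
#' column `id`, then position-major feature columns), the layout consumed by
#' downstream model fitting. All effective sequence lengths must agree —
#' encode aligned binding-site residues, not raw full-length sequences of
#' different lengths. Alignment gaps (`-`) are controlled separately from
#' unknown residues: `gap_policy = "zero"` keeps the alignment column and
#' writes zeros for gapped positions.
#'
#' @param records A data frame / tibble with `id` and `seq` columns, or a
#'   named character vector of sequences.
#' @param table A `descriptor_table`.
#' @param unknown_policy Passed to [encode_sequence()].
#' @param gap_policy `"error"` or `"zero"`.
#' @return List with `matrix` (tibble, rows ordered as the input) and
#'   `manifest` (tibble of skipped / zero-filled residues per sequence).
#' @export
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), seq = c("GAV", "WYH"))
#' encode_collection(recs, get_table("ProtFP_PCA3"))$matrix
encode_collection <- function(records, table,
                              unknown_policy = c("error", "skip", "zero"),
                              gap_policy = c("error", "zero")) {
  unknown_policy <- match.arg(unknown_policy)
  gap_policy <- match.arg(gap_policy)
  if (is.character(records)) {
    records <- tibble(id = names(records) %||%
                        paste0("seq", seq_along(records)),
                      seq = unname(records))
  }
  if (!all(c("id", "seq") %in% names(records))) {
    abort("records need 'id' and 'seq' columns", class = "ps_error_encode")
  }
  encode_one <- function(id, seq) {
    res <- .clean_sequence(seq)
    is_gap <- res == .GAP_CODE
    known <- res %in% .AA_CODES
    if (any(is_gap) && gap_policy == "error") {
      abort(paste0("sequence '", id, "' contains alignment gaps at position(s) ",
                   paste(which(is_gap), collapse = ", "),
                   " (gap_policy = 'error')"),
            class = "ps_error_encode")
    }
    if (any(!known & !is_gap) && unknown_policy == "error") {
      pos <- which(!known & !is_gap)[1]
      abort(paste0("non-standard residue '", res[pos], "' at position ", pos,
                   " in sequence '", id, "' (policy = 'error')"),
            class = "ps_error_encode")
    }
    actions <- ifelse(known, "encode",
                      ifelse(is_gap, "zero", unknown_policy))
    .encode_core(res, table, actions, id)
  }
  encs <- purrr::map2(records$id, records$seq, encode_one)
  lens <- purrr::map_int(encs, function(e) e$length)
  if (length(unique(lens)) > 1) {
    tab <- base::table(lens)
    modal <- as.integer(names(tab)[which.max(tab)])
    off <- records$id[lens != modal]
    abort(paste0("effective sequence lengths differ (",
                 paste(sort(unique(lens)), collapse = ", "),
                 "); offending id(s): ", paste(off, collapse = ", ")),
          class = "ps_error_shape")
  }
  mat <- dplyr::bind_rows(purrr::map(encs, as_tibble))
  manifest <- dplyr::bind_rows(purrr::map(encs, function(e) {
    if (nrow(e$manifest) > 0) dplyr::mutate(e$manifest, id = e$id,
                                            .before = 1) else NULL
  }))
  if (nrow(manifest) == 0) {
    manifest <- tibble(id = character(), position = integer(),
                       symbol = character(), action = character())
  }
  list(matrix = mat, manifest = manifest)
}

#' Read sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped lines; the record id is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with `id` and `seq` columns.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package",
          class = "ps_error_io")
  }
  set <- Biostrings::readAAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(set)),
         seq = as.character(set, use.names = FALSE))
}

#' Write an encoded collection to TSV
#'
#' @param enc Result of [encode_collection()].
#' @param path Output file.
#' @param long Write in long format (`id`, `feature`, `value`) instead of wide.
#' @param header_lines Optional provenance lines written as `#` comments.
#' @return Invisibly, `path`.
#' @export
write_encoded_tsv <- function(enc, path, long = FALSE, header_lines = NULL) {
  df <- enc$matrix
  if (long) {
    df <- tidyr::pivot_longer(df, -"id", names_to = "feature",
                              values_to = "value")
  }
  .write_tsv(df, path, header_lines)
}
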
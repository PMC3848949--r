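# Registry of the 13 bundled descriptor sets. Tables live as versioned TSV
# files under inst/extdata/descriptors and are loaded (and validated) once per
# session. The Z-scales (3) / ProtFP (PCA3/PCA5) entries are stored-once
# truncations of their parent files, registered with their own metadata.

.registry <- new.env(parent = emptyenv())

.REGISTRY_ORDER <- c("BLOSUM", "FASGAI", "MSWHIM",
                     "ProtFP_PCA3", "ProtFP_PCA5", "ProtFP_PCA8",
                     "ProtFP_Feature", "STscales", "Tscales", "VHSE",
                     "Zscales_3", "Zscales_5", "Zscales_Binned")

.descriptor_file <- function(fname) {
  path <- system.file("extdata", "descriptors", fname, package = "protscales")
  if (!nzchar(path)) {
    abort(paste0("bundled descriptor file '", fname, "' not found"),
          class = "ps_error_io")
  }
  path
}

.read_bin_definitions <- function(path) {
  lines <- .normalize_minus(readLines(path, encoding = "UTF-8"))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  df <- as.data.frame(do.call(rbind, fields[-1]), stringsAsFactors = FALSE)
  names(df) <- trimws(fields[[1]])
  df$lower <- as.numeric(df$lower)
  df$upper <- as.numeric(df$upper)
  as_tibble(df)
}

# one bit column per (scale, label); residue scores 1 where its underlying
# z value falls in [lower, upper)
.bin_bits <- function(zscales, bins) {
  zmat <- desc_matrix(zscales)
  bits <- matrix(0L, nrow = 20, ncol = nrow(bins),
                 dimnames = list(rownames(zmat),
                                 paste0(bins$scale, "_", bins$label)))
  for (i in seq_len(nrow(bins))) {
    z <- zmat[, bins$zscale[i]]
    bits[, i] <- as.integer(z >= bins$lower[i] & z < bins$upper[i])
  }
  bits
}

.build_registry <- function() {
  zs5 <- read_descriptor_table(.descriptor_file("zscales_5.tsv"))
  zs3 <- truncate_table(zs5, 3)
  attr(zs3, "ps_name") <- "Zscales_3"
  attr(zs3, "notes") <- "first three Sandberg Z-scales (Hellberg lineage)"

  bins <- .read_bin_definitions(.descriptor_file("zscales_bins.tsv"))
  zsb <- new_binned_descriptor_table(
    .bin_bits(zs5, bins), name = "Zscales_Binned", bins = bins,
    source = desc_source(zs5),
    notes = "binned classification over the five Z-scales; one active class per scale")

  pfp8 <- read_descriptor_table(.descriptor_file("protfp_pca.tsv"))
  pfp5 <- truncate_table(pfp8, 5)
  attr(pfp5, "ps_name") <- "ProtFP_PCA5"
  pfp3 <- truncate_table(pfp8, 3)
  attr(pfp3, "ps_name") <- "ProtFP_PCA3"

  tabs <- list(
    BLOSUM = read_descriptor_table(.descriptor_file("blosum.tsv")),
    FASGAI = read_descriptor_table(.descriptor_file("fasgai.tsv")),
    MSWHIM = read_descriptor_table(.descriptor_file("mswhim.tsv")),
    ProtFP_PCA3 = pfp3, ProtFP_PCA5 = pfp5, ProtFP_PCA8 = pfp8,
    ProtFP_Feature = read_descriptor_table(.descriptor_file("protfp_feature.tsv")),
    STscales = read_descriptor_table(.descriptor_file("stscales.tsv")),
    Tscales = read_descriptor_table(.descriptor_file("tscales.tsv")),
    VHSE = read_descriptor_table(.descriptor_file("vhse.tsv")),
    Zscales_3 = zs3, Zscales_5 = zs5, Zscales_Binned = zsb
  )
  attr(tabs$ProtFP_PCA8, "ps_name") <- "ProtFP_PCA8"
  tabs[.REGISTRY_ORDER]
}

.registry_tables <- function() {
  if (is.null(.registry$tables)) .registry$tables <- .build_registry()
  .registry$tables
}

#' List the bundled descriptor sets
#'
#' @return Character vector of the 13 bundled descriptor-set identifiers, in
#'   canonical (alphabetical) order.
#' @export
#' @examples
#' list_descriptor_sets()
list_descriptor_sets <- function() {
  names(.registry_tables())
}

#' Fetch a bundled descriptor table
#'
#' Lookup is case-insensitive; the returned table carries its canonical name.
#'
#' @param name A descriptor-set identifier (see [list_descriptor_sets()]).
#' @return A validated [new_descriptor_table()] object (or binned variant).
#' @export
#' @examples
#' get_table("ProtFP_PCA3")
#' get_table("vhse")
get_table <- function(name) {
  tabs <- .registry_tables()
  hit <- match(tolower(name), tolower(names(tabs)))
  if (is.na(hit)) {
    abort(paste0("unknown descriptor set '", name, "'; valid identifiers: ",
                 paste(names(tabs), collapse = ", ")),
          class = "ps_error_lookup")
  }
  tabs[[hit]]
}
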
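# Canonical amino-acid alphabet. Every matrix in the package is indexed in
# this fixed order; readers reorder on ingest so downstream code can rely on it.

.AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residues that occur in real-world sequence data but have no descriptor row
.NONSTANDARD_CODES <- c("B", "J", "O", "U", "X", "Z")
.GAP_CODE <- "-"
.STOP_CODE <- "*"

#' The 20 standard amino acids in canonical order
#'
#' Single-letter codes in the fixed order used to index every descriptor
#' table and distance matrix in the package (A, R, N, D, C, Q, E, G, H, I,
#' L, K, M, F, P, S, T, W, Y, V).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() .AA_CODES
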
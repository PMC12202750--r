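#' Amino-acid vocabulary
#'
#' The 20 standard amino acids in alphabetical order at indices 0--19, plus the
#' pseudo-residue `X` (unknown / out-of-sequence padding) at index 20. This is
#' the fixed 21-symbol vocabulary used by the embedding layer; tokenization
#' maps any non-standard residue (`B`, `J`, `O`, `U`, `Z`, `*`, ...) to `X`.
#'
#' @return A named integer vector of length 21 mapping residue characters to
#'   0-based token indices.
#' @examples
#' aa_vocab()[c("A", "K", "X")]
#' @export
aa_vocab <- function() {
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  setNames(0:20, c(letters20, "X"))
}

#' Tokenize fragments into integer index vectors
#'
#' Splits each fragment into unigrams (single residues) and maps them through
#' [aa_vocab()]. Residues outside the 20-letter alphabet collapse to the `X`
#' token, so the function is total on any character input.
#'
#' @param fragments Character vector of equal-length fragments, or a fragment
#'   tibble with a `fragment` column (as returned by [extract_fragments()]).
#' @return An integer matrix with one row per fragment and one column per
#'   window position; values are 0-based token indices in `[0, 20]`.
#' @examples
#' tokenize("XAKCD")
#' @export
tokenize <- function(fragments) {
  if (is.data.frame(fragments)) fragments <- fragments$fragment
  stopifnot(is.character(fragments), length(fragments) > 0)
  lens <- unique(nchar(fragments))
  if (length(lens) != 1) {
    abort("all fragments must have the same length for tokenization")
  }
  vocab <- aa_vocab()
  chars <- matrix(unlist(strsplit(fragments, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(fragments), byrow = TRUE)
  idx <- vocab[chars]
  idx[is.na(idx)] <- vocab[["X"]]
  matrix(as.integer(idx), nrow = length(fragments))
}

#' Reconstruct fragment strings from token indices
#'
#' Inverse of [tokenize()] up to the collapse of non-standard residues onto
#' `X`: `detokenize(tokenize(f)) == f` whenever `f` contains only the 20
#' standard residues and `X`.
#'
#' @param indices Integer matrix of 0-based token indices (rows = fragments).
#' @return Character vector of fragments.
#' @export
detokenize <- function(indices) {
  if (is.vector(indices)) indices <- matrix(indices, nrow = 1)
  stopifnot(all(indices >= 0L & indices <= 20L))
  alpha <- names(aa_vocab())
  apply(indices, 1L, function(r) paste(alpha[r + 1L], collapse = ""))
}
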
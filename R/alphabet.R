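#' Amino-acid alphabet with terminal gap state
#'
#' The model alphabet is the 20 standard amino acids followed by the
#' alignment gap \code{"-"}, for a total of \code{q = 21} states. Codes are
#' 0-based: \code{"A"} is 0 and the gap is 20. The order is fixed so that
#' serialized models and test fixtures are deterministic.
#'
#' @param symbols Character string with the alphabet, one character per
#'   state, gap last. Defaults to the standard 21-state protein alphabet.
#' @return An object of class \code{"aa_alphabet"}: a list with
#'   \code{symbols} (character vector), \code{string}, \code{q} and
#'   \code{gap_code} (0-based code of the gap state).
#' @examples
#' ab <- aa_alphabet()
#' ab$q          # 21
#' ab$gap_code   # 20
#' @export
aa_alphabet <- function(symbols = "ACDEFGHIKLMNPQRSTVWY-") {
  syms <- strsplit(symbols, "")[[1]]
  if (anyDuplicated(syms)) stop("alphabet symbols must be distinct")
  structure(
    list(
      symbols = syms,
      string = symbols,
      q = length(syms),
      gap_code = length(syms) - 1L
    ),
    class = "aa_alphabet"
  )
}

#' @export
print.aa_alphabet <- function(x, ...) {
  cat("Alphabet (q =", x$q, "):", x$string, "\n")
  invisible(x)
}

#' Encode character sequences as integer codes
#'
#' Lowercase letters are uppercased first. Any character not in the
#' alphabet (including \code{"."}, \code{"X"}, \code{"B"}, \code{"Z"})
#' maps to the gap code, since the 21-state model has no other state for
#' them.
#'
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param alphabet An [aa_alphabet()].
#' @return Integer matrix, one row per sequence, entries in
#'   \code{0..q-1}.
#' @export
encode_sequences <- function(seqs, alphabet = aa_alphabet()) {
  stopifnot(length(seqs) >= 1)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths: ", paste(unique(lens), collapse = ", "))
  chars <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = length(seqs), byrow = TRUE)
  idx <- match(chars, alphabet$symbols)
  idx[is.na(idx)] <- alphabet$gap_code + 1L
  matrix(as.integer(idx - 1L), nrow = length(seqs))
}

#' Decode an integer code matrix back to character sequences
#'
#' @param codes Integer matrix with entries in \code{0..q-1}.
#' @param alphabet An [aa_alphabet()].
#' @return Character vector of sequences.
#' @export
decode_sequences <- function(codes, alphabet = aa_alphabet()) {
  codes <- as.matrix(codes)
  stopifnot(all(codes >= 0), all(codes < alphabet$q))
  chars <- matrix(alphabet$symbols[codes + 1L], nrow = nrow(codes))
  apply(chars, 1, paste0, collapse = "")
}
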
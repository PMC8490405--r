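#' Read an aligned FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that preserves
#' headers verbatim and enforces the contracts the rest of the package
#' relies on: the file must contain at least one record, and a sequence
#' line before the first header is a parse error (reported with the
#' offending line by the underlying reader).
#'
#' @param path Path to a FASTA file.
#' @return A list with \code{ids} (headers, verbatim, in file order) and
#'   \code{seqs} (character vector of sequences).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("no sequences in ", path)
  list(ids = names(set), seqs = as.character(unname(set)))
}

#' Write aligned sequences as FASTA
#'
#' Lines are wrapped at 80 columns.
#'
#' @param ids Character vector of record headers.
#' @param seqs Character vector of sequences (same length as \code{ids}).
#' @param path Output path.
#' @export
write_fasta <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta", width = 80L)
  invisible(path)
}

#' Encode a set of FASTA records as an integer MSA
#'
#' @param records A list as returned by [read_fasta()], or a named/unnamed
#'   character vector of aligned sequences.
#' @param alphabet An [aa_alphabet()].
#' @return An object of class \code{"encoded_msa"}: list with \code{codes}
#'   (M x L integer matrix, 0-based codes), \code{ids}, \code{M}, \code{L},
#'   \code{q} and \code{alphabet}.
#' @export
encode_msa <- function(records, alphabet = aa_alphabet()) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("seq", seq_along(records))
    seqs <- unname(records)
  } else {
    ids <- records$ids
    seqs <- records$seqs
  }
  if (length(seqs) == 0L) stop("no sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]]
    stop("alignment length mismatch for record(s): ", paste(bad, collapse = ", "))
  }
  codes <- encode_sequences(seqs, alphabet)
  new_encoded_msa(codes, ids, alphabet)
}

new_encoded_msa <- function(codes, ids = NULL, alphabet = aa_alphabet()) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(codes)))
  stopifnot(nrow(codes) >= 1, ncol(codes) >= 1,
            all(codes >= 0L), all(codes < alphabet$q))
  structure(
    list(codes = codes, ids = ids, M = nrow(codes), L = ncol(codes),
         q = alphabet$q, alphabet = alphabet),
    class = "encoded_msa"
  )
}

#' @export
print.encoded_msa <- function(x, ...) {
  cat("Encoded MSA:", x$M, "sequences x", x$L, "sites (q =", x$q, ")\n")
  invisible(x)
}

#' Write an encoded MSA back to FASTA
#'
#' @param msa An \code{"encoded_msa"}.
#' @param path Output path.
#' @export
write_msa <- function(msa, path) {
  write_fasta(msa$ids, decode_sequences(msa$codes, msa$alphabet), path)
}
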
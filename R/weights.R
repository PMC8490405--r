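#' Phylogenetic sequence reweighting
#'
#' Each sequence m receives weight \eqn{w_m = 1 / |\{m' :
#' \mathrm{identity}(m, m') \ge \theta\}|}, the neighbourhood including m
#' itself. Identity is the fraction of identical codes over all L columns,
#' with the gap treated as an ordinary 21st symbol. The effective number of
#' sequences is \eqn{M_\mathrm{eff} = \sum_m w_m}. This down-weights
#' clusters of closely related sequences so that the likelihood is not
#' dominated by oversampled clades.
#'
#' @param msa An \code{"encoded_msa"}.
#' @param theta Identity threshold as a fraction in (0, 1]; default 0.8
#'   (sequences at \eqn{\ge} 80\% identity count as neighbours).
#' @return An object of class \code{"seq_weights"}: list with \code{w}
#'   (length-M weights in (0, 1]), \code{theta} and \code{Meff}.
#' @examples
#' msa <- encode_msa(c(a = "ACDE", b = "ACDE", c = "WYWY"))
#' compute_weights(msa)$Meff  # 2: the two identical sequences share weight
#' @export
compute_weights <- function(msa, theta = 0.8) {
  stopifnot(inherits(msa, "encoded_msa"))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
    stop("theta must be in (0, 1]")
  counts <- neighbor_counts(msa$codes, theta)
  w <- 1 / as.numeric(counts)
  structure(list(w = w, theta = theta, Meff = sum(w)), class = "seq_weights")
}

#' @export
print.seq_weights <- function(x, ...) {
  cat("Sequence weights: M =", length(x$w),
      " Meff =", format(x$Meff, digits = 6),
      " theta =", x$theta, "\n")
  invisible(x)
}

#' Uniform weights (every sequence counts once)
#'
#' Convenience constructor used when the input is known to be an i.i.d.
#' sample, where reweighting is a no-op by construction.
#'
#' @param M Number of sequences.
#' @return A \code{"seq_weights"} with all weights 1 and Meff = M.
#' @export
uniform_weights <- function(M) {
  structure(list(w = rep(1, M), theta = NA_real_, Meff = as.numeric(M)),
            class = "seq_weights")
}

#' Export sequence weights as a two-column TSV
#'
#' @param msa The \code{"encoded_msa"} the weights were computed from.
#' @param weights A \code{"seq_weights"}.
#' @param path Output path.
#' @export
write_weights <- function(msa, weights, path) {
  utils::write.table(
    data.frame(id = msa$ids, weight = weights$w),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
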
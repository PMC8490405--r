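#' Positional orders for autoregressive modelling
#'
#' The autoregressive factorization is valid for any permutation of the
#' sites, but the soft-max parameterization is not permutation-invariant:
#' different orders give different fitted models. The entropic order —
#' most conserved (lowest column entropy) sites first — is the practical
#' heuristic used by default.
#'
#' @param s Numeric vector of site entropies (nats), length L.
#' @return Class \code{"site_order"}: list with \code{perm} (1-based
#'   permutation; model position k corresponds to original column
#'   \code{perm[k]}) and \code{label}.
#' @examples
#' entropic_order(c(0.5, 0.1, 0.3))$perm  # 2 3 1
#' @export
entropic_order <- function(s) {
  stopifnot(all(is.finite(s)))
  new_site_order(order(s, seq_along(s)), "entropic")
}

#' @rdname entropic_order
#' @param L Alignment length.
#' @export
direct_order <- function(L) new_site_order(seq_len(L), "direct")

#' @rdname entropic_order
#' @param seed Integer seed for the random permutation.
#' @export
random_order <- function(L, seed = 1L) {
  new_site_order(with_seed(seed, sample.int(L)), "random")
}

#' @rdname entropic_order
#' @param perm Explicit 1-based permutation of \code{1:L}.
#' @export
custom_order <- function(perm) new_site_order(perm, "custom")

new_site_order <- function(perm, label) {
  perm <- as.integer(perm)
  if (!identical(sort(perm), seq_along(perm)))
    stop("perm is not a permutation of 1..L")
  structure(list(perm = perm, label = label), class = "site_order")
}

#' @export
print.site_order <- function(x, ...) {
  cat("Site order (", x$label, "): ", paste(x$perm, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Apply or invert a site order
#'
#' \code{apply_order} permutes the columns of an MSA into model order;
#' \code{invert_order} maps a per-model-position vector (or matrix rows)
#' back to original column coordinates, so that all user-facing per-site
#' output is reported in alignment coordinates.
#'
#' @param msa An \code{"encoded_msa"}.
#' @param order A \code{"site_order"} with matching L.
#' @return \code{apply_order}: the column-permuted MSA.
#' @export
apply_order <- function(msa, order) {
  stopifnot(inherits(order, "site_order"), length(order$perm) == msa$L)
  out <- msa
  out$codes <- msa$codes[, order$perm, drop = FALSE]
  out
}

#' @rdname apply_order
#' @param x Vector of length L (one entry per model position) or matrix
#'   with L rows.
#' @return \code{invert_order}: \code{x} re-indexed by original column.
#' @export
invert_order <- function(x, order) {
  stopifnot(inherits(order, "site_order"))
  inv <- base::order(order$perm)
  if (is.matrix(x)) {
    stopifnot(nrow(x) == length(order$perm))
    x[inv, , drop = FALSE]
  } else {
    stopifnot(length(x) == length(order$perm))
    x[inv]
  }
}

#' Write a site order as one-column text
#'
#' @param order A \code{"site_order"}.
#' @param path Output path.
#' @export
write_order <- function(order, path) {
  writeLines(as.character(order$perm), path)
  invisible(path)
}
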
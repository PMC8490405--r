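#' Profile (independent-site) baseline model
#'
#' The joint probability factorizes over columns:
#' \eqn{P(a_1, \ldots, a_L) = \prod_i f_i(a_i)}, with \eqn{f_i} the
#' (reweighted, pseudocount-smoothed) column frequencies. The default
#' pseudocount 0.01 keeps log-probabilities finite for states unseen in
#' the training columns.
#'
#' @param msa An \code{"encoded_msa"}.
#' @param weights Optional \code{"seq_weights"}; NULL for uniform.
#' @param pseudocount Mixing weight in \eqn{[0, 1)}; default 0.01.
#' @return Class \code{"profile_model"}: list with \code{f} (L x q row-
#'   normalized frequencies), \code{alphabet}, \code{L}, \code{q}.
#' @export
profile_fit <- function(msa, weights = NULL, pseudocount = 0.01) {
  ft <- empirical_frequencies(msa, weights, pseudocount, pair = FALSE)
  structure(
    list(f = ft$f1, alphabet = msa$alphabet, L = msa$L, q = msa$q,
         meta = list(pseudocount = pseudocount, Meff = ft$Meff)),
    class = "profile_model"
  )
}

#' Construct a profile model from explicit frequencies
#'
#' @param f L x q matrix of row-normalized frequencies.
#' @param alphabet An [aa_alphabet()] with q symbols.
#' @export
profile_model <- function(f, alphabet = aa_alphabet()) {
  stopifnot(ncol(f) == alphabet$q, all(f >= 0),
            all(abs(rowSums(f) - 1) < 1e-9))
  structure(
    list(f = f, alphabet = alphabet, L = nrow(f), q = ncol(f),
         meta = list()),
    class = "profile_model"
  )
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Profile (independent-site) model: L =", x$L, " q =", x$q, "\n")
  invisible(x)
}

#' @export
predict.profile_model <- function(object, newdata,
                                  type = c("logprob", "energy"), ...) {
  type <- match.arg(type)
  codes <- as_code_matrix(newdata, object)
  if (ncol(codes) != object$L) stop("sequence length != L")
  logf <- log(object$f)
  lp <- vapply(seq_len(nrow(codes)), function(m)
    sum(logf[cbind(seq_len(object$L), codes[m, ] + 1L)]), numeric(1))
  if (type == "energy") -lp else lp
}

#' @export
simulate.profile_model <- function(object, nsim = 1, seed = NULL, ...) {
  codes <- with_seed(seed, {
    out <- matrix(0L, nsim, object$L)
    for (i in seq_len(object$L))
      out[, i] <- sample.int(object$q, nsim, replace = TRUE,
                             prob = object$f[i, ]) - 1L
    out
  })
  new_encoded_msa(codes,
                  ids = sprintf("profile_sample_%d|seed=%s", seq_len(nsim),
                                if (is.null(seed)) "NA" else seed),
                  alphabet = object$alphabet)
}

#' Closed-form entropy of a profile model
#'
#' By independence the total entropy is the sum of column entropies,
#' \eqn{S = \sum_i s_i(f)}, with no sampling needed.
#'
#' @param model A \code{"profile_model"}.
#' @return Total entropy in nats.
#' @export
profile_entropy <- function(model) {
  sum(site_entropies(model$f))
}

#' Express a profile model as an autoregressive model
#'
#' Fields \eqn{h_i(a) = \log f_i(a)} and all couplings zero give an
#' \code{"ardca"} model with exactly the product distribution of the
#' profile; useful to exercise the autoregressive code paths against
#' independent-site closed forms.
#'
#' @param model A \code{"profile_model"}.
#' @return An \code{"ardca"} model (direct order).
#' @export
profile_as_ardca <- function(model) {
  L <- model$L; q <- model$q
  h <- log(pmax(model$f, 1e-300))
  J <- vector("list", L)
  for (i in seq_len(L)[-1]) J[[i]] <- array(0, dim = c(q, q, i - 1L))
  new_ardca(h, J, direct_order(L), model$alphabet,
            meta = list(source = "profile"))
}
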
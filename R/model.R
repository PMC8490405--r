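# The autoregressive model object. Parameters are stored in model (i.e.
# permuted) coordinates: h is an L x q matrix of fields, J[[i]] for model
# position i >= 2 is a q x q x (i-1) array with J[[i]][a, b, j] the directed
# coupling of target symbol a at position i to symbol b at earlier position
# j. The first position has fields only. All user-facing sequence data is
# in original alignment coordinates; the permutation is internal.

new_ardca <- function(h, J, order, alphabet, meta = list()) {
  L <- nrow(h); q <- ncol(h)
  stopifnot(length(J) == L, is.null(J[[1]]))
  for (i in seq_len(L)[-1]) {
    d <- dim(J[[i]])
    if (length(d) != 3L || any(d != c(q, q, i - 1)))
      stop("J block ", i, " has wrong shape")
  }
  stopifnot(all(is.finite(h)),
            all(vapply(J[-1], function(a) all(is.finite(a)), logical(1))))
  structure(
    list(L = L, q = q, h = h, J = J, order = order, alphabet = alphabet,
         meta = meta),
    class = "ardca"
  )
}

# Conditional logits for model position i given prefixes: `prefix` is an
# n x (i-1) matrix of 0-based codes in model coordinates (n x 0 for i = 1).
# Returns an n x q matrix.
cond_logits <- function(model, i, prefix) {
  n <- nrow(prefix)
  logits <- matrix(model$h[i, ], n, model$q, byrow = TRUE)
  if (i > 1L) {
    Ji <- model$J[[i]]
    for (j in seq_len(i - 1L)) {
      logits <- logits + t(Ji[, prefix[, j] + 1L, j])
    }
  }
  logits
}

#' Conditional distribution of one model position
#'
#' The soft-max conditional \eqn{P(a_i \mid a_{i-1}, \ldots, a_1) \propto
#' \exp\{h_i(a_i) + \sum_{j<i} J_{ij}(a_i, a_j)\}}, normalized by the local
#' partition function \eqn{z_i} (computed with max subtraction for
#' overflow safety).
#'
#' @param model An \code{"ardca"} model.
#' @param prefix Integer vector of 0-based codes for model positions
#'   \code{1..i-1}; an empty vector addresses the first position.
#' @return Length-q probability vector summing to 1.
#' @export
conditional_distribution <- function(model, prefix = integer(0)) {
  i <- length(prefix) + 1L
  if (i > model$L) stop("prefix longer than L - 1")
  softmax(drop(cond_logits(model, i, matrix(as.integer(prefix), nrow = 1))))
}

# Log-probabilities for a matrix of sequences given in ORIGINAL column
# coordinates (n x L, 0-based codes). Exactly normalized over q^L.
codes_logprob <- function(model, codes) {
  codes <- as.matrix(codes)
  if (ncol(codes) != model$L) stop("sequence length != L")
  stopifnot(all(codes >= 0L), all(codes < model$q))
  perm_codes <- codes[, model$order$perm, drop = FALSE]
  n <- nrow(perm_codes)
  lp <- numeric(n)
  for (i in seq_len(model$L)) {
    logits <- cond_logits(model, i, perm_codes[, seq_len(i - 1L), drop = FALSE])
    lp <- lp + logits[cbind(seq_len(n), perm_codes[, i] + 1L)] -
      row_logsumexp(logits)
  }
  lp
}

as_code_matrix <- function(x, model) {
  if (inherits(x, "encoded_msa")) x$codes
  else if (is.character(x)) encode_sequences(x, model$alphabet)
  else {
    m <- as.matrix(x)
    if (ncol(m) == 1L && model$L > 1L) m <- t(m)
    m
  }
}

#' Exact log-probability of sequences
#'
#' Sum of the conditional log-probabilities along the model order. Because
#' every conditional is individually normalized, the result is an exactly
#' normalized log-probability: \eqn{\sum_{\mathrm{seq}} P(\mathrm{seq}) = 1}
#' over all \eqn{q^L} sequences.
#'
#' @param model An \code{"ardca"} model.
#' @param sequences An \code{"encoded_msa"}, a character vector of
#'   sequences, or an integer code matrix (rows = sequences, original
#'   column coordinates).
#' @return Numeric vector of log-probabilities (nats).
#' @export
log_probability <- function(model, sequences) {
  codes_logprob(model, as_code_matrix(sequences, model))
}

#' Statistical energy of sequences
#'
#' \eqn{E(a_1, \ldots, a_L) = -\log P(a_1, \ldots, a_L)}. Low energy means
#' family-like; high energy means unrelated.
#'
#' @inheritParams log_probability
#' @return Numeric vector of energies (nats).
#' @export
energy <- function(model, sequences) -log_probability(model, sequences)

#' Ancestral sampling from the model
#'
#' Draws i.i.d. sequences position by position in model order — the first
#' position from its unconditional distribution, each later position from
#' its conditional given the already-sampled prefix — then maps the
#' columns back to original alignment coordinates.
#'
#' @param model An \code{"ardca"} model.
#' @param n Number of sequences.
#' @param seed Integer seed (NULL uses and advances the current RNG).
#' @return An \code{"encoded_msa"} with ids
#'   \code{"arDCA_sample_<k>|seed=<seed>"}.
#' @export
ar_sample <- function(model, n, seed = NULL) {
  stopifnot(n >= 1)
  codes <- with_seed(seed, {
    out <- matrix(0L, n, model$L)
    for (i in seq_len(model$L)) {
      logits <- cond_logits(model, i, out[, seq_len(i - 1L), drop = FALSE])
      out[, i] <- sample_rows(row_softmax(logits))
    }
    out
  })
  codes <- codes[, base::order(model$order$perm), drop = FALSE]
  new_encoded_msa(
    codes,
    ids = sprintf("arDCA_sample_%d|seed=%s", seq_len(n),
                  if (is.null(seed)) "NA" else seed),
    alphabet = model$alphabet
  )
}

#' Enumerate all q^L sequences
#'
#' Brute-force oracle support: the full code matrix of all \eqn{q^L}
#' sequences, first site fastest.
#'
#' @param L,q Dimensions.
#' @param cap Refuse enumerations larger than this many sequences.
#' @return Integer matrix (q^L x L), 0-based codes.
#' @export
enumerate_sequences <- function(L, q, cap = 1e6) {
  N <- q^L
  if (N > cap) stop("enumeration of ", N, " sequences exceeds cap ", cap)
  idx <- 0:(N - 1)
  m <- matrix(0L, N, L)
  for (i in seq_len(L)) m[, i] <- as.integer((idx %/% q^(i - 1)) %% q)
  m
}
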
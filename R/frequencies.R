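# Empirical statistics of an encoded MSA: one- and two-point frequencies,
# site entropies, connected two- and three-point correlations. Two-point
# tables are stored as an (L q) x (L q) matrix of q x q blocks; block (i, j)
# holds f_ij(a, b). Diagonal blocks are not meaningful pair statistics and
# are excluded from all comparisons.

block_idx <- function(i, q) ((i - 1L) * q + 1L):(i * q)

one_hot <- function(msa) {
  X <- matrix(0, msa$M, msa$L * msa$q)
  for (i in seq_len(msa$L)) {
    X[cbind(seq_len(msa$M), (i - 1L) * msa$q + msa$codes[, i] + 1L)] <- 1
  }
  X
}

#' Weighted empirical one- and two-point frequencies
#'
#' One-point frequencies are \eqn{f_i(a) = (1-\alpha)\,\sum_m w_m
#' \delta(a, a_i^m) / M_\mathrm{eff} + \alpha/q}; two-point frequencies use
#' \eqn{\alpha/q^2} analogously. With \eqn{\alpha = 0} the tables are the
#' raw reweighted counts and satisfy marginal consistency
#' \eqn{\sum_b f_{ij}(a,b) = f_i(a)}.
#'
#' @param msa An \code{"encoded_msa"}.
#' @param weights A \code{"seq_weights"}, or \code{NULL} for uniform.
#' @param pseudocount Mixing weight \eqn{\alpha \in [0, 1)}; default 0.
#' @param pair Compute the pairwise table too (can be skipped when only
#'   \code{f1} is needed)?
#' @return Class \code{"freq_tables"}: list with \code{f1} (L x q),
#'   \code{f2} ((Lq) x (Lq) block matrix or NULL), \code{s} (site
#'   entropies, nats), \code{Meff}, \code{pseudocount}, \code{L}, \code{q}.
#' @export
empirical_frequencies <- function(msa, weights = NULL, pseudocount = 0,
                                  pair = TRUE) {
  stopifnot(inherits(msa, "encoded_msa"))
  if (pseudocount < 0 || pseudocount >= 1)
    stop("pseudocount must be in [0, 1)")
  if (is.null(weights)) weights <- uniform_weights(msa$M)
  stopifnot(length(weights$w) == msa$M)
  L <- msa$L; q <- msa$q
  w <- weights$w / weights$Meff
  f1 <- matrix(0, L, q)
  for (i in seq_len(L)) {
    f1[i, ] <- vapply(seq_len(q) - 1L,
                      function(a) sum(w[msa$codes[, i] == a]), numeric(1))
  }
  a <- pseudocount
  f1 <- (1 - a) * f1 + a / q
  f2 <- NULL
  if (pair) {
    X <- one_hot(msa)
    f2 <- crossprod(X * w, X)
    f2 <- (1 - a) * f2 + a / q^2
  }
  structure(
    list(f1 = f1, f2 = f2, s = site_entropies(f1), Meff = weights$Meff,
         pseudocount = a, L = L, q = q),
    class = "freq_tables"
  )
}

#' @export
print.freq_tables <- function(x, ...) {
  cat("Frequency tables: L =", x$L, " q =", x$q,
      " Meff =", format(x$Meff, digits = 6),
      " pseudocount =", x$pseudocount, "\n")
  cat("Mean site entropy:", format(mean(x$s), digits = 4), "nats\n")
  invisible(x)
}

#' Per-site entropies from one-point frequencies
#'
#' \eqn{s_i = -\sum_a f_i(a) \log f_i(a)} in nats, with
#' \eqn{0 \log 0 = 0}. Conserved columns have low entropy; a column
#' uniform over all q states has entropy \eqn{\log q}.
#'
#' @param f1 L x q matrix of normalized one-point frequencies.
#' @return Numeric vector of length L.
#' @export
site_entropies <- function(f1) {
  lp <- ifelse(f1 > 0, log(f1), 0)
  -rowSums(f1 * lp)
}

#' Connected two-point correlations
#'
#' \eqn{C_{ij}(a,b) = f_{ij}(a,b) - f_i(a) f_j(b)}, returned as an
#' (Lq) x (Lq) block matrix with diagonal blocks zeroed (same-site
#' "correlations" are marginal artefacts, not pair statistics).
#'
#' @param ft A \code{"freq_tables"} with the pairwise table filled.
#' @return (Lq) x (Lq) numeric matrix, symmetric in the sense
#'   \eqn{C_{ij}(a,b) = C_{ji}(b,a)}.
#' @export
connected_c2 <- function(ft) {
  stopifnot(!is.null(ft$f2))
  v <- as.vector(t(ft$f1))
  c2 <- ft$f2 - outer(v, v)
  for (i in seq_len(ft$L)) c2[block_idx(i, ft$q), block_idx(i, ft$q)] <- 0
  c2
}

#' Seeded uniform sample of (i, j, k, a, b, c) tuples
#'
#' @param L,q Alignment length and alphabet size.
#' @param n Number of tuples.
#' @param seed Integer seed.
#' @return Integer matrix n x 6 with 0-based sites i < j < k and codes.
#' @export
sample_triplets <- function(L, q, n, seed = 1L) {
  stopifnot(L >= 3, n >= 1)
  with_seed(seed, {
    sites <- t(replicate(n, sort.int(sample.int(L, 3L)) - 1L))
    codes <- matrix(sample.int(q, 3L * n, replace = TRUE) - 1L, ncol = 3L)
    cbind(sites, codes)
  })
}

#' Connected three-point correlations on a tuple subset
#'
#' \eqn{C_{ijk}(a,b,c) = f_{ijk} - f_{ij} f_k - f_{ik} f_j - f_{jk} f_i +
#' 2 f_i f_j f_k}, evaluated only on the supplied tuples (the full tensor
#' is \eqn{O(L^3 q^3)} and a seeded uniform subsample gives a stable
#' Pearson comparison).
#'
#' @param msa An \code{"encoded_msa"}.
#' @param tuples Matrix from [sample_triplets()].
#' @param weights A \code{"seq_weights"} or NULL for uniform.
#' @return Numeric vector of C_ijk values, one per tuple.
#' @export
connected_c3 <- function(msa, tuples, weights = NULL) {
  if (is.null(weights)) weights <- uniform_weights(msa$M)
  f <- triplet_freqs(msa$codes, weights$w, tuples)
  f[, 7] - f[, 4] * f[, 3] - f[, 5] * f[, 2] - f[, 6] * f[, 1] +
    2 * f[, 1] * f[, 2] * f[, 3]
}

pair_mask <- function(L, q) {
  site <- rep(seq_len(L), each = q)
  outer(site, site, "<")
}

#' Compare the connected statistics of two alignments
#'
#' Computes one-point frequencies, connected two-point correlations over
#' all site pairs, and connected three-point correlations on a shared
#' seeded tuple subset for both alignments, and reports Pearson
#' correlations between the flattened statistics. Used to judge how well
#' model samples reproduce the statistics of natural data.
#'
#' @param msa_a,msa_b Two \code{"encoded_msa"} objects sharing L and q.
#' @param weights_a,weights_b Optional \code{"seq_weights"} for each side.
#' @param n_triplets Number of three-point tuples; default 1e5.
#' @param seed Seed for the tuple subsample.
#' @return Class \code{"correlation_comparison"}: list with
#'   \code{pearson_f1}, \code{pearson_c2}, \code{pearson_c3}, the
#'   underlying statistics and the tuple set.
#' @export
connected_correlations <- function(msa_a, msa_b,
                                   weights_a = NULL, weights_b = NULL,
                                   n_triplets = 1e5, seed = 1L) {
  if (msa_a$L != msa_b$L || msa_a$q != msa_b$q)
    stop("alignments must share L and q")
  if (n_triplets < 1) stop("n_triplets must be >= 1")
  ft_a <- empirical_frequencies(msa_a, weights_a)
  ft_b <- empirical_frequencies(msa_b, weights_b)
  c2a <- connected_c2(ft_a); c2b <- connected_c2(ft_b)
  mask <- pair_mask(msa_a$L, msa_a$q)
  tuples <- sample_triplets(msa_a$L, msa_a$q, n_triplets, seed)
  c3a <- connected_c3(msa_a, tuples, weights_a)
  c3b <- connected_c3(msa_b, tuples, weights_b)
  structure(
    list(
      pearson_f1 = stats::cor(as.vector(ft_a$f1), as.vector(ft_b$f1)),
      pearson_c2 = stats::cor(c2a[mask], c2b[mask]),
      pearson_c3 = stats::cor(c3a, c3b),
      f1_a = ft_a$f1, f1_b = ft_b$f1,
      c2_a = c2a, c2_b = c2b, c3_a = c3a, c3_b = c3b,
      tuples = tuples
    ),
    class = "correlation_comparison"
  )
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat("Pearson correlations between alignment statistics:\n")
  cat(sprintf("  f_i(a)        : %.4f\n", x$pearson_f1))
  cat(sprintf("  C_ij(a,b)     : %.4f\n", x$pearson_c2))
  cat(sprintf("  C_ijk(a,b,c)  : %.4f  (on %d sampled tuples)\n",
              x$pearson_c3, nrow(x$tuples)))
  invisible(x)
}
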
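#' Monte-Carlo entropy of the model distribution
#'
#' Because the model's log-probabilities are exactly normalized, the
#' entropy \eqn{S = -\sum_\mathrm{seq} P \log P = \langle E
#' \rangle_P} is the expected statistical energy under the model, which
#' is estimated by the empirical mean energy of n i.i.d. ancestral
#' samples. The standard error is the sample standard deviation of the
#' energies over \eqn{\sqrt n}.
#'
#' @param model An \code{"ardca"} model (or anything [simulate()]-able
#'   with an energy via [predict()]).
#' @param n_samples Number of Monte-Carlo samples; default 1e4.
#' @param seed Integer seed.
#' @return Class \code{"entropy_estimate"}: list with \code{S_total}
#'   (nats), \code{S_per_site}, \code{stderr}, \code{n_samples},
#'   \code{seed}, \code{log10_N} (= S_total / ln 10, the decimal log of
#'   the effective number of sequences).
#' @export
estimate_entropy <- function(model, n_samples = 1e4, seed = NULL) {
  stopifnot(n_samples >= 2)
  sampled <- simulate(model, nsim = n_samples, seed = seed)
  E <- predict(model, sampled, type = "energy")
  S <- mean(E)
  structure(
    list(S_total = S, S_per_site = S / model$L,
         stderr = stats::sd(E) / sqrt(n_samples),
         n_samples = n_samples, seed = seed, L = model$L,
         log10_N = S / log(10)),
    class = "entropy_estimate"
  )
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("Entropy estimate: S = %.4f +/- %.4f nats (%d samples)\n",
              x$S_total, x$stderr, x$n_samples))
  cat(sprintf("  S/site = %.4f nats; effective sequence count ~ 10^%.2f\n",
              x$S_per_site, x$log10_N))
  invisible(x)
}

#' Exact entropy by enumeration (oracle)
#'
#' \eqn{-\sum_\mathrm{seq} P \log P} over all \eqn{q^L} sequences.
#' Brute-force test oracle for [estimate_entropy()]; refuses problems
#' above the cap.
#'
#' @param model An \code{"ardca"} or \code{"profile_model"}.
#' @param cap Maximum number of sequences to enumerate; default 1e6.
#' @return Entropy in nats.
#' @export
exact_entropy <- function(model, cap = 1e6) {
  all_seqs <- enumerate_sequences(model$L, model$q, cap)
  lp <- predict(model, all_seqs, type = "logprob")
  -sum(exp(lp) * lp)
}

#' Sequence-space size arithmetic
#'
#' Converts an entropy per site into the decimal logarithm of the number
#' of family-compatible sequences, \eqn{\log_{10} N = L\, S_\mathrm{site}
#' / \ln 10}, compares it with all \eqn{q^L} sequences of the same
#' length, and reports the (log) fraction. All arithmetic is in log10,
#' so no overflow occurs for any protein length.
#'
#' @param S_per_site Entropy per site in nats.
#' @param L Sequence length.
#' @param q Alphabet size (21 for amino acids + gap).
#' @return Class \code{"sequence_space"}: list with \code{log10_N},
#'   \code{log10_total}, \code{log10_fraction}.
#' @examples
#' # a response-regulator-like family: S/L = 1.4 nats, L = 112, q = 21
#' sequence_space_report(1.4, 112, 21)
#' @export
sequence_space_report <- function(S_per_site, L, q) {
  stopifnot(S_per_site >= 0, L > 0, q > 1)
  log10_N <- L * S_per_site / log(10)
  log10_total <- L * log10(q)
  structure(
    list(S_per_site = S_per_site, L = L, q = q,
         log10_N = log10_N, log10_total = log10_total,
         log10_fraction = log10_N - log10_total),
    class = "sequence_space"
  )
}

#' @export
print.sequence_space <- function(x, ...) {
  cat(sprintf("Sequence space (L = %d, q = %d, S/site = %.3f nats):\n",
              x$L, x$q, x$S_per_site))
  cat(sprintf("  family-compatible sequences : ~ 10^%.2f\n", x$log10_N))
  cat(sprintf("  all q^L sequences           : ~ 10^%.2f\n", x$log10_total))
  cat(sprintf("  fraction                    : ~ 10^%.2f\n", x$log10_fraction))
  invisible(x)
}
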
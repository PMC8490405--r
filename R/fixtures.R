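# Synthetic ground-truth generators and brute-force oracles. Everything
# here is reproducible bit-exactly from its arguments and seed, so every
# downstream stage (training, sampling, entropy, contacts, subfamily
# classification) can be tested against a known truth without any
# external data.

#' Alphabet for synthetic fixtures
#'
#' The first q symbols of the standard 21-state alphabet (gap-last
#' semantics are not meaningful for reduced synthetic alphabets; the last
#' symbol simply plays the gap's structural role).
#'
#' @param q Alphabet size, 2..21.
#' @export
synthetic_alphabet <- function(q) {
  stopifnot(q >= 2, q <= 21)
  aa_alphabet(substr("ACDEFGHIKLMNPQRSTVWY-", 1L, q))
}

#' Random autoregressive ground-truth model
#'
#' Fields are centered Gaussian draws of scale \code{field_scale};
#' couplings are Gaussian of scale \code{coupling_scale} on the chosen
#' (model-position) pairs and zero elsewhere. Deterministic given the
#' seed.
#'
#' @param L,q Dimensions.
#' @param field_scale,coupling_scale Standard deviations of the draws.
#' @param coupled_pairs \code{"all"}, \code{"none"}, or a two-column
#'   matrix of model-position pairs (j < i) to receive couplings.
#' @param seed Integer seed.
#' @return An \code{"ardca"} model (direct order).
#' @export
random_armodel <- function(L, q, field_scale = 0.8, coupling_scale = 0.3,
                           coupled_pairs = "all", seed = 1L) {
  L <- as.integer(unname(L)); q <- as.integer(unname(q))
  with_seed(seed, {
    h <- matrix(stats::rnorm(L * q, sd = field_scale), L, q)
    J <- vector("list", L)
    for (i in seq_len(L)[-1]) J[[i]] <- array(0, dim = c(q, q, i - 1L))
    if (identical(coupled_pairs, "all")) {
      coupled_pairs <- which(lower.tri(matrix(0, L, L)), arr.ind = TRUE)
    } else if (identical(coupled_pairs, "none")) {
      coupled_pairs <- matrix(integer(0), 0, 2)
    }
    if (nrow(coupled_pairs) > 0 && coupling_scale > 0) {
      for (r in seq_len(nrow(coupled_pairs))) {
        i <- max(coupled_pairs[r, ]); j <- min(coupled_pairs[r, ])
        J[[i]][, , j] <- matrix(stats::rnorm(q * q, sd = coupling_scale), q, q)
      }
    }
    new_ardca(h, J, direct_order(L), synthetic_alphabet(q),
              meta = list(source = "random_armodel", seed = seed))
  })
}

#' Exactly sampled pairwise Potts fixture
#'
#' Builds a pairwise Potts distribution \eqn{P \propto \exp\{\sum_i
#' h_i(a_i) + \sum_{(i,j)} J_{ij}(a_i, a_j)\}} with couplings only on the
#' chosen pairs, enumerates all \eqn{q^L} probabilities, and draws M
#' sequences exactly from the enumerated distribution (no MCMC). The
#' true coupled pairs are returned as the contact ground truth.
#'
#' @param L,q Dimensions (\eqn{q^L \le cap}).
#' @param M Number of sequences to sample.
#' @param coupled_pairs Two-column matrix of coupled site pairs; NULL
#'   picks \code{n_pairs} disjoint pairs at random with separation
#'   \eqn{\ge 2}.
#' @param n_pairs Number of random coupled pairs when
#'   \code{coupled_pairs} is NULL; default 6.
#' @param coupling_scale,field_scale Gaussian scales of the parameters.
#' @param seed Integer seed.
#' @param cap Enumeration cap on \eqn{q^L}; default 2^26.
#' @return List with \code{msa} (\code{"encoded_msa"}),
#'   \code{true_contacts} (two-column matrix), \code{h}, \code{J}
#'   (list of q x q matrices keyed by pair row), \code{logZ}.
#' @export
random_potts_exact <- function(L, q, M, coupled_pairs = NULL, n_pairs = 6L,
                               coupling_scale = 1, field_scale = 0.3,
                               seed = 1L, cap = 2^26) {
  N <- q^L
  if (N > cap) stop("q^L = ", N, " exceeds enumeration cap ", cap)
  with_seed(seed, {
    if (is.null(coupled_pairs)) {
      cand <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
      cand <- cand[abs(cand[, 1] - cand[, 2]) >= 2, , drop = FALSE]
      coupled_pairs <- cand[sample.int(nrow(cand), n_pairs), , drop = FALSE]
    }
    coupled_pairs <- cbind(pmin(coupled_pairs[, 1], coupled_pairs[, 2]),
                           pmax(coupled_pairs[, 1], coupled_pairs[, 2]))
    h <- matrix(stats::rnorm(L * q, sd = field_scale), L, q)
    Js <- lapply(seq_len(nrow(coupled_pairs)), function(r)
      matrix(stats::rnorm(q * q, sd = coupling_scale), q, q))
    idx <- 0:(N - 1)
    dig <- function(s) as.integer((idx %/% q^(s - 1)) %% q)
    E <- numeric(N)
    for (i in seq_len(L)) E <- E + h[i, dig(i) + 1L]
    for (r in seq_len(nrow(coupled_pairs))) {
      di <- dig(coupled_pairs[r, 1]); dj <- dig(coupled_pairs[r, 2])
      E <- E + Js[[r]][di + q * dj + 1L]
    }
    mx <- max(E)
    wts <- exp(E - mx)
    cum <- cumsum(wts)
    total <- cum[N]
    logZ <- mx + log(total)
    picks <- findInterval(stats::runif(M) * total, cum) + 1L
    codes <- matrix(0L, M, L)
    pick0 <- picks - 1
    for (i in seq_len(L)) codes[, i] <- as.integer((pick0 %/% q^(i - 1)) %% q)
    msa <- new_encoded_msa(codes, alphabet = synthetic_alphabet(q))
    list(msa = msa, true_contacts = coupled_pairs, h = h, J = Js,
         logZ = logZ)
  })
}

#' Two-subfamily fixture for log-odds classification
#'
#' Two autoregressive ground truths sharing dimensions and coupling
#' topology but diverging in the fields at a subset of sites and in the
#' coupling values, emulating two subfamilies of one protein family with
#' distinct intra-subfamily covariation. Training and held-out samples
#' are disjoint by construction (separate draws from each truth).
#'
#' @param L,q Dimensions; defaults L = 12, q = 8.
#' @param M_train,M_test Sequences per subfamily for training / held-out
#'   evaluation; defaults 1500 / 500.
#' @param n_div Number of diverged sites; default 4.
#' @param field_delta Scale of the field perturbation at diverged sites;
#'   default 0.8.
#' @param n_pairs,coupling_scale Coupling topology shared by the two
#'   truths; coupling values are redrawn independently for subfamily 2.
#' @param seed Integer seed.
#' @return List with \code{train_1}, \code{train_2}, \code{held_out_1},
#'   \code{held_out_2} (\code{"encoded_msa"}), \code{model_1},
#'   \code{model_2} (ground truths), \code{diverged_sites}.
#' @export
two_subfamily_msa <- function(L = 12L, q = 8L, M_train = 1500L,
                              M_test = 500L, n_div = 4L, field_delta = 0.8,
                              n_pairs = 6L, coupling_scale = 0.6,
                              seed = 1L) {
  with_seed(seed, {
    cand <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    pairs <- cand[sample.int(nrow(cand), n_pairs), , drop = FALSE]
    pairs <- cbind(pmax(pairs[, 1], pairs[, 2]), pmin(pairs[, 1], pairs[, 2]))
    s1 <- sample.int(2^30, 6)
    m1 <- random_armodel(L, q, field_scale = 0.6,
                         coupling_scale = coupling_scale,
                         coupled_pairs = pairs, seed = s1[1])
    m2 <- random_armodel(L, q, field_scale = 0.6,
                         coupling_scale = coupling_scale,
                         coupled_pairs = pairs, seed = s1[2])
    # subfamily 2 = subfamily-1 fields everywhere except the diverged
    # sites, plus its own coupling values on the shared topology
    div <- sort(sample.int(L, n_div))
    h2 <- m1$h
    h2[div, ] <- h2[div, ] + matrix(stats::rnorm(n_div * q, sd = field_delta),
                                    n_div, q)
    m2$h <- h2
    list(
      train_1 = ar_sample(m1, M_train, seed = s1[3]),
      train_2 = ar_sample(m2, M_train, seed = s1[4]),
      held_out_1 = ar_sample(m1, M_test, seed = s1[5]),
      held_out_2 = ar_sample(m2, M_test, seed = s1[6]),
      model_1 = m1, model_2 = m2, diverged_sites = div
    )
  })
}

#' Two-cluster family fixture
#'
#' A 50/50 mixture of two sharply peaked profile models whose preferred
#' states differ at a fraction of the sites — the simplest family with
#' clustered structure in principal-component space. A profile model
#' fitted to the mixture averages the two clusters and samples near the
#' PC origin; a model that captures covariation reproduces the clusters.
#'
#' @param L,q Dimensions; defaults L = 20, q = 6.
#' @param M Total number of sequences; default 1000.
#' @param diff_frac Fraction of sites where the cluster centers differ;
#'   default 0.6.
#' @param eps Within-cluster noise: probability mass spread off the
#'   center state; default 0.25.
#' @param seed Integer seed.
#' @return List with \code{msa}, \code{labels} (1/2), and the two
#'   cluster \code{"profile_model"}s.
#' @export
two_cluster_msa <- function(L = 20L, q = 6L, M = 1000L, diff_frac = 0.6,
                            eps = 0.25, seed = 1L) {
  with_seed(seed, {
    center1 <- sample.int(q, L, replace = TRUE) - 1L
    center2 <- center1
    flip <- sample.int(L, round(diff_frac * L))
    center2[flip] <- (center1[flip] + sample.int(q - 1, length(flip),
                                                 replace = TRUE)) %% q
    peaked <- function(center) {
      f <- matrix(eps / (q - 1), L, q)
      f[cbind(seq_len(L), center + 1L)] <- 1 - eps
      profile_model(f, synthetic_alphabet(q))
    }
    p1 <- peaked(center1); p2 <- peaked(center2)
    n1 <- M %/% 2L
    s <- sample.int(2^30, 2)
    msa1 <- simulate(p1, nsim = n1, seed = s[1])
    msa2 <- simulate(p2, nsim = M - n1, seed = s[2])
    msa <- new_encoded_msa(rbind(msa1$codes, msa2$codes),
                           alphabet = synthetic_alphabet(q))
    list(msa = msa, labels = rep(c(1L, 2L), c(n1, M - n1)),
         cluster_1 = p1, cluster_2 = p2)
  })
}
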
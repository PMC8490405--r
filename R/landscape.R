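# Mutational-effect and contact prediction. All incremental energy
# computations exploit the autoregressive structure: a substitution at
# model position p leaves every conditional before p untouched, so only
# the logit at p and the local partition functions z_i for i > p need
# recomputation. Results are contractually equal to naive full-energy
# differences (asserted in the test suite).

# Precompute, for a reference sequence, the conditional logits G[i, a]
# given the reference prefix, the local log partition functions, and the
# reference energy. `ref` in original coordinates, 0-based codes.
reference_cache <- function(model, ref) {
  ref <- as.integer(ref)
  stopifnot(length(ref) == model$L, all(ref >= 0), all(ref < model$q))
  rp <- ref[model$order$perm]
  L <- model$L; q <- model$q
  G <- matrix(0, L, q)
  for (i in seq_len(L)) {
    g <- model$h[i, ]
    if (i > 1L) {
      Ji <- model$J[[i]]
      for (j in seq_len(i - 1L)) g <- g + Ji[, rp[j] + 1L, j]
    }
    G[i, ] <- g
  }
  logz <- apply(G, 1, logsumexp)
  E_ref <- sum(logz - G[cbind(seq_len(L), rp + 1L)])
  list(ref_perm = rp, G = G, logz = logz, E_ref = E_ref,
       pos_of = base::order(model$order$perm))
}

# Energy difference for a set of simultaneous substitutions, given as a
# list of (model position p, new 0-based code b). O((L - min p) q).
delta_energy_perm <- function(model, cache, pos, new) {
  stopifnot(length(pos) == length(new), !anyDuplicated(pos))
  o <- base::order(pos)
  pos <- as.integer(pos[o]); new <- as.integer(new[o])
  rp <- cache$ref_perm
  dE <- 0
  for (i in pos[1]:model$L) {
    g <- cache$G[i, ]
    if (i > 1L) {
      Ji <- model$J[[i]]
      for (k in seq_along(pos)) {
        p <- pos[k]
        if (p < i && new[k] != rp[p]) {
          g <- g + Ji[, new[k] + 1L, p] - Ji[, rp[p] + 1L, p]
        }
      }
    }
    ai <- if (i %in% pos) new[match(i, pos)] else rp[i]
    dE <- dE + (logsumexp(g) - g[ai + 1L]) -
      (cache$logz[i] - cache$G[i, rp[i] + 1L])
  }
  dE
}

resolve_reference <- function(model, reference, msa = NULL, ref_id = NULL) {
  if (!is.null(ref_id)) {
    stopifnot(!is.null(msa))
    m <- match(ref_id, msa$ids)
    if (is.na(m)) stop("reference id not found: ", ref_id)
    return(list(codes = msa$codes[m, ], id = ref_id))
  }
  if (is.null(reference)) {
    stopifnot(!is.null(msa))
    return(list(codes = msa$codes[1, ], id = msa$ids[1]))
  }
  if (is.character(reference) && length(reference) == 1L)
    return(list(codes = drop(encode_sequences(reference, model$alphabet)),
                id = "reference"))
  list(codes = as.integer(reference), id = "reference")
}

#' In-silico deep mutational scan
#'
#' Computes \eqn{\Delta E(a_i \to b) = E(\mathrm{mutant}) -
#' E(\mathrm{reference})} for every position i and every target state b,
#' with the mutant differing from the reference only at i. Negative
#' values predict beneficial substitutions. The scan is computed
#' incrementally (only conditionals downstream of the mutated model
#' position are re-evaluated) but equals the naive full-energy
#' difference.
#'
#' @param model An \code{"ardca"} model.
#' @param reference Reference sequence: 0-based code vector or single
#'   character string; or NULL to take the first sequence of \code{msa}.
#' @param msa Optional \code{"encoded_msa"} supplying the reference.
#' @param ref_id Optional record id selecting the reference from
#'   \code{msa}.
#' @return Class \code{"dms_scan"}: list with \code{delta_E} (L x q, rows
#'   in original column coordinates, exactly zero at the reference
#'   state), \code{reference} (codes), \code{reference_id}.
#' @export
dms_scan <- function(model, reference = NULL, msa = NULL, ref_id = NULL) {
  refinfo <- resolve_reference(model, reference, msa, ref_id)
  ref <- refinfo$codes
  cache <- reference_cache(model, ref)
  L <- model$L; q <- model$q
  rp <- cache$ref_perm
  dE_perm <- matrix(0, L, q)
  for (p in seq_len(L)) {
    # own-logit term: z_p is prefix-only, hence unchanged
    d <- cache$G[p, rp[p] + 1L] - cache$G[p, ]
    if (p < L) {
      for (i in (p + 1L):L) {
        Dm <- model$J[[i]][, , p] - model$J[[i]][, rp[p] + 1L, p]
        # all-target logits: row b holds G[i, ] + Dm[, b]
        lse <- row_logsumexp(sweep(t(Dm), 2L, cache$G[i, ], "+"))
        d <- d - Dm[rp[i] + 1L, ] + lse - cache$logz[i]
      }
    }
    dE_perm[p, ] <- d
  }
  delta_E <- dE_perm[cache$pos_of, , drop = FALSE]
  delta_E[cbind(seq_len(L), ref + 1L)] <- 0
  structure(
    list(delta_E = delta_E, reference = ref, reference_id = refinfo$id,
         alphabet = model$alphabet),
    class = "dms_scan"
  )
}

#' @export
print.dms_scan <- function(x, ...) {
  cat("Mutational scan:", nrow(x$delta_E), "positions x",
      ncol(x$delta_E), "states, reference =", x$reference_id, "\n")
  cat("  delta_E range:", format(range(x$delta_E), digits = 4), "\n")
  invisible(x)
}

#' Write a mutational scan as TSV
#'
#' Columns: 1-based position, wildtype state, mutant state, delta_E.
#' @param scan A \code{"dms_scan"}.
#' @param path Output path.
#' @export
write_dms <- function(scan, path) {
  L <- nrow(scan$delta_E); q <- ncol(scan$delta_E)
  syms <- scan$alphabet$symbols
  df <- data.frame(
    position = rep(seq_len(L), each = q),
    wt_aa = rep(syms[scan$reference + 1L], each = q),
    mut_aa = rep(syms, L),
    delta_E = as.vector(t(scan$delta_E))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Epistatic effect of a double mutation
#'
#' \eqn{\Delta\Delta E(b_i, b_j) = \Delta E(a_i \to b_i, a_j \to b_j) -
#' \Delta E(a_i \to b_i) - \Delta E(a_j \to b_j)}, all relative to the
#' same reference background. Symmetric in the two mutations; exactly
#' zero when either mutation is the identity or when all couplings
#' vanish.
#'
#' @param model An \code{"ardca"} model.
#' @param reference Reference sequence (codes or character).
#' @param i,j Original column positions (1-based), distinct.
#' @param b_i,b_j Target states, 0-based codes.
#' @return The scalar epistatic energy.
#' @export
epistasis <- function(model, reference, i, j, b_i, b_j) {
  if (i == j) stop("epistasis requires two distinct positions")
  ref <- resolve_reference(model, reference)$codes
  cache <- reference_cache(model, ref)
  pos <- cache$pos_of[c(i, j)]  # model positions of the original columns
  d12 <- delta_energy_perm(model, cache, pos, c(b_i, b_j))
  d1 <- delta_energy_perm(model, cache, pos[1], b_i)
  d2 <- delta_energy_perm(model, cache, pos[2], b_j)
  d12 - d1 - d2
}

#' Effective couplings from epistasis
#'
#' For every pair of original columns i < j, the q x q matrix
#' \eqn{K_{ij}(b_i, b_j) = \Delta\Delta E(b_i, b_j)} of double-mutation
#' epistatic effects relative to one reference sequence. Rows and columns
#' at the reference states are zero by construction. Computed by a
#' vectorized local-partition-function route that is equal to the
#' four-energy definition.
#'
#' @inheritParams dms_scan
#' @return Class \code{"effective_couplings"}: list with \code{K}
#'   (L x L x q x q array, filled for i != j with
#'   \code{K[i,j,b_i,b_j] = K[j,i,b_j,b_i]}), \code{reference},
#'   \code{reference_id}.
#' @export
effective_couplings <- function(model, reference = NULL, msa = NULL,
                                ref_id = NULL) {
  refinfo <- resolve_reference(model, reference, msa, ref_id)
  ref <- refinfo$codes
  cache <- reference_cache(model, ref)
  L <- model$L; q <- model$q
  rp <- cache$ref_perm
  K <- array(0, dim = c(L, L, q, q))  # original coordinates
  for (r in seq_len(L)[-1]) {
    Jr <- model$J[[r]]
    for (p in seq_len(r - 1L)) {
      # direct coupling term at position r (z terms cancel there)
      Dr <- Jr[, , p]
      Jcomb <- Dr - matrix(Dr[, rp[p] + 1L], q, q) -
        matrix(Dr[rp[r] + 1L, ], q, q, byrow = TRUE) + Dr[rp[r] + 1L, rp[p] + 1L]
      Kpr <- -t(Jcomb)  # index [b_p, b_r]
      if (r < L) {
        for (i in (r + 1L):L) {
          Ji <- model$J[[i]]
          dp <- Ji[, , p] - Ji[, rp[p] + 1L, p]  # [a, b_p]
          dr <- Ji[, , r] - Ji[, rp[r] + 1L, r]  # [a, b_r]
          Tm <- dp + cache$G[i, ]                 # [a, b_p]
          c1 <- max(Tm); c2 <- max(dr)
          z_both <- log(crossprod(exp(Tm - c1), exp(dr - c2))) + c1 + c2
          z_p <- log(colSums(exp(Tm - c1))) + c1
          Um <- dr + cache$G[i, ]
          c3 <- max(Um)
          z_r <- log(colSums(exp(Um - c3))) + c3
          Kpr <- Kpr + sweep(sweep(z_both, 1L, z_p, "-"), 2L, z_r, "-") +
            cache$logz[i]
        }
      }
      Kpr[rp[p] + 1L, ] <- 0
      Kpr[, rp[r] + 1L] <- 0
      io <- model$order$perm[p]; jo <- model$order$perm[r]
      K[io, jo, , ] <- Kpr
      K[jo, io, , ] <- t(Kpr)
    }
  }
  structure(
    list(K = K, reference = ref, reference_id = refinfo$id, L = L, q = q,
         alphabet = model$alphabet),
    class = "effective_couplings"
  )
}

zero_sum_gauge <- function(B) {
  B - rowMeans(B) - rep(colMeans(B), each = nrow(B)) + mean(B)
}

#' Contact scores from effective couplings
#'
#' Shifts each pair's coupling block to zero-sum gauge over the retained
#' states (the 20 amino acids by default; the gap state is excluded as in
#' standard DCA practice), takes the Frobenius norm, and applies the
#' average product correction (APC): \eqn{F^\mathrm{APC}_{ij} = F_{ij} -
#' \bar F_{i\cdot} \bar F_{\cdot j} / \bar F_{\cdot\cdot}}, with means
#' over off-diagonal entries. Pairs closer than \code{min_sep} along the
#' sequence are masked from the ranked output only.
#'
#' @param couplings An \code{"effective_couplings"} object.
#' @param min_sep Minimum |i - j| for ranked predictions; default 5.
#' @param exclude_gap Drop the gap state before the Frobenius norm?
#' @return Class \code{"ardca_contacts"}: list with \code{F},
#'   \code{F_apc} (L x L symmetric, zero diagonal), \code{pairs} (ranked
#'   data.frame with 1-based i < j, descending \code{F_apc}, ties broken
#'   lexicographically), \code{min_sep}.
#' @export
contact_scores <- function(couplings, min_sep = 5L, exclude_gap = TRUE) {
  L <- couplings$L; q <- couplings$q
  keep <- seq_len(q)
  if (exclude_gap && !is.null(couplings$alphabet$gap_code))
    keep <- setdiff(keep, couplings$alphabet$gap_code + 1L)
  Fmat <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      B <- zero_sum_gauge(couplings$K[i, j, keep, keep])
      Fmat[i, j] <- Fmat[j, i] <- sqrt(sum(B^2))
    }
  }
  F_apc <- apc_correct(Fmat)
  idx <- which(upper.tri(Fmat), arr.ind = TRUE)
  sep_ok <- abs(idx[, 1] - idx[, 2]) >= min_sep
  pairs <- data.frame(i = idx[sep_ok, 1], j = idx[sep_ok, 2],
                      F = Fmat[idx[sep_ok, , drop = FALSE]],
                      F_apc = F_apc[idx[sep_ok, , drop = FALSE]])
  pairs <- pairs[base::order(-pairs$F_apc, pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(F = Fmat, F_apc = F_apc, pairs = pairs, min_sep = min_sep,
         exclude_gap = exclude_gap, reference_id = couplings$reference_id,
         L = L),
    class = "ardca_contacts"
  )
}

# Average product correction with means over off-diagonal entries.
apc_correct <- function(Fmat) {
  L <- nrow(Fmat)
  off <- L - 1L
  rmean <- rowSums(Fmat) / off  # diagonal is zero
  gmean <- sum(Fmat) / (L * off)
  out <- Fmat - outer(rmean, rmean) / gmean
  diag(out) <- 0
  out
}

#' @export
print.ardca_contacts <- function(x, ...) {
  cat("Contact scores for L =", x$L, "positions (min_sep =", x$min_sep, ")\n")
  cat("Top pairs by APC-corrected Frobenius score:\n")
  print(utils::head(x$pairs, 10))
  invisible(x)
}

#' Write ranked contact predictions as TSV
#'
#' Columns: 1-based i, j, F_apc, F, sorted by descending F_apc.
#' @param contacts An \code{"ardca_contacts"}.
#' @param path Output path.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts$pairs[, c("i", "j", "F_apc", "F")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Positive predictive value curve
#'
#' \eqn{\mathrm{PPV}(n)} is the fraction of true contacts among the top n
#' ranked predicted pairs (ties broken by lexicographic (i, j) order,
#' which the ranking in [contact_scores()] already guarantees).
#'
#' @param contacts An \code{"ardca_contacts"}, or a ranked data.frame
#'   with columns i, j.
#' @param true_contacts Either a symmetric logical L x L matrix or a
#'   two-column matrix/data.frame of true pairs (1-based).
#' @return data.frame with rank, i, j, true, ppv.
#' @export
ppv_curve <- function(contacts, true_contacts) {
  pairs <- if (inherits(contacts, "ardca_contacts")) contacts$pairs else contacts
  is_true <- if (is.matrix(true_contacts) && is.logical(true_contacts)) {
    true_contacts[cbind(pairs$i, pairs$j)]
  } else {
    tc <- as.matrix(true_contacts)[, 1:2, drop = FALSE]
    key <- paste(pmin(tc[, 1], tc[, 2]), pmax(tc[, 1], tc[, 2]))
    paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j)) %in% key
  }
  data.frame(rank = seq_len(nrow(pairs)), i = pairs$i, j = pairs$j,
             true = is_true, ppv = cumsum(is_true) / seq_len(nrow(pairs)))
}
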
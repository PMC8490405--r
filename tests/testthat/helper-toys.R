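# Shared toy builders and brute-force oracles for the test suite.

toy_msa <- function(seqs, q = NULL) {
  ab <- if (is.null(q)) aa_alphabet() else synthetic_alphabet(q)
  encode_msa(seqs, ab)
}

msa_from_codes <- function(codes, q) {
  ardca:::new_encoded_msa(codes, alphabet = synthetic_alphabet(q))
}

# Direct double-loop connected correlation C_ij(a,b) for small instances.
c2_double_loop <- function(msa, w = NULL) {
  if (is.null(w)) w <- rep(1, msa$M)
  w <- w / sum(w)
  L <- msa$L; q <- msa$q
  out <- array(0, dim = c(L, L, q, q))
  f1 <- matrix(0, L, q)
  for (i in seq_len(L)) for (a in 0:(q - 1))
    f1[i, a + 1] <- sum(w[msa$codes[, i] == a])
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    for (a in 0:(q - 1)) for (b in 0:(q - 1)) {
      fij <- sum(w[msa$codes[, i] == a & msa$codes[, j] == b])
      out[i, j, a + 1, b + 1] <- fij - f1[i, a + 1] * f1[j, b + 1]
    }
  }
  out
}

# Central finite differences of a scalar function.
fd_gradient <- function(fn, par, h = 1e-5) {
  vapply(seq_along(par), function(k) {
    e <- rep(0, length(par)); e[k] <- h
    (fn(par + e) - fn(par - e)) / (2 * h)
  }, numeric(1))
}

# Naive full-energy mutational scan: recompute complete energies.
naive_dms <- function(model, ref) {
  L <- model$L; q <- model$q
  E0 <- energy(model, matrix(ref, 1))
  out <- matrix(0, L, q)
  for (i in seq_len(L)) for (b in 0:(q - 1)) {
    mut <- ref; mut[i] <- b
    out[i, b + 1] <- energy(model, matrix(mut, 1)) - E0
  }
  out
}
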
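test_that("alphabet has 21 distinct symbols, gap last, and round trips", {
  ab <- aa_alphabet()
  expect_equal(ab$q, 21L)
  expect_equal(ab$symbols[ab$gap_code + 1], "-")
  expect_false(anyDuplicated(ab$symbols) > 0)
  codes <- encode_sequences(ab$string, ab)
  expect_equal(drop(codes), 0:20)
  expect_equal(decode_sequences(codes, ab), ab$string)
})

test_that("encoding maps case, unknowns and dots per policy", {
  ab <- aa_alphabet()
  expect_equal(drop(encode_sequences("ACD-", ab)), c(0L, 1L, 2L, 20L))
  expect_equal(drop(encode_sequences("acx.", ab)), c(0L, 1L, 20L, 20L))
  expect_equal(drop(encode_sequences("BZ..", ab)), c(20L, 20L, 20L, 20L))
  expect_error(encode_msa(c(a = "ACDE", b = "ACDEF")), "mismatch.*b")
})

test_that("fasta reading preserves order and headers, errors on bad input", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "AC-", ">s2", "ACD"), f)
  rec <- read_fasta(f)
  expect_equal(rec$ids, c("s1 some description", "s2"))
  expect_equal(rec$seqs, c("AC-", "ACD"))

  writeLines(character(0), f)
  expect_error(read_fasta(f), "no sequences")

  writeLines(c("ACGT", ">s1", "AC-"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("fasta round trip through write_msa preserves sequences", {
  msa <- toy_msa(c(s1 = "ACDEFGHIKL", s2 = "ACDEF-HIKL"))
  f <- tempfile(fileext = ".fa")
  write_msa(msa, f)
  back <- encode_msa(read_fasta(f))
  expect_identical(back$codes, msa$codes)
  expect_identical(back$ids, msa$ids)
})

test_that("reweighting matches hand-enumerated neighbourhoods", {
  # three identical sequences share one neighbourhood of size 3
  m <- toy_msa(c("AAAA", "AAAA", "AAAA"))
  w <- compute_weights(m)
  expect_equal(w$w, rep(1 / 3, 3))
  expect_equal(w$Meff, 1)

  # identity 0.5 < 0.8: both stand alone
  m <- toy_msa(c("AACC", "AAWW"))
  w <- compute_weights(m, theta = 0.8)
  expect_equal(w$w, c(1, 1))
  expect_equal(w$Meff, 2)

  # pair (1,2) identical; all other pairwise identities 0.2 or 0
  # (enumerated by hand over the 5 columns)
  m <- toy_msa(c("AAAAA", "AAAAA", "ACCCC", "WWWWA"))
  w <- compute_weights(m, theta = 0.8)
  expect_equal(w$w, c(1 / 2, 1 / 2, 1, 1))
  expect_equal(w$Meff, 3)

  expect_error(compute_weights(m, theta = 0), "theta")
  expect_error(compute_weights(m, theta = 1.2), "theta")
})

test_that("Meff equals M exactly when all pairwise identities < theta", {
  set.seed(21)
  codes <- matrix(sample(0:9, 60, replace = TRUE), 6, 10)
  # resample until no pair reaches 0.5 identity, then check at theta 0.8
  m <- msa_from_codes(codes, 10)
  w <- compute_weights(m, theta = 0.8)
  ident <- function(x, y) mean(x == y)
  maxid <- max(apply(utils::combn(6, 2), 2, function(p)
    ident(codes[p[1], ], codes[p[2], ])))
  expect_lt(maxid, 0.8)
  expect_equal(w$Meff, 6)
})

test_that("empirical frequencies obey the pseudocount mixture and normalization", {
  m <- toy_msa(c("AA"))
  ft <- empirical_frequencies(m, pseudocount = 0)
  expect_equal(ft$f1[1, 1], 1)
  expect_equal(ft$f1[2, 1], 1)

  # alpha = 1 is rejected; alpha close to 1 pushes toward uniform
  expect_error(empirical_frequencies(m, pseudocount = 1), "pseudocount")
  expect_error(empirical_frequencies(m, pseudocount = -0.1), "pseudocount")

  m2 <- toy_msa(c("A", "C"))
  ft2 <- empirical_frequencies(m2, pseudocount = 0)
  expect_equal(ft2$f1[1, 1:2], c(0.5, 0.5))

  # rows sum to 1 for any alpha and weights
  m3 <- toy_msa(c("ACD", "A-D", "WCD", "ACY"))
  w3 <- compute_weights(m3, 0.6)
  for (a in c(0, 0.3, 0.9)) {
    ft3 <- empirical_frequencies(m3, w3, pseudocount = a)
    expect_true(all(abs(rowSums(ft3$f1) - 1) < 1e-9))
  }
})

test_that("pairwise marginals are consistent with one-point frequencies at alpha 0", {
  set.seed(4)
  m <- msa_from_codes(matrix(sample(0:3, 200, replace = TRUE), 40, 5), 4)
  w <- compute_weights(m, 0.9)
  ft <- empirical_frequencies(m, w, pseudocount = 0)
  q <- m$q
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    blk <- ft$f2[ardca:::block_idx(i, q), ardca:::block_idx(j, q)]
    expect_true(max(abs(rowSums(blk) - ft$f1[i, ])) < 1e-9)
  }
})

test_that("site entropies hit the analytic anchors", {
  f1 <- rbind(
    c(1, rep(0, 20)),
    rep(1 / 21, 21),
    c(0.5, 0.5, rep(0, 19))
  )
  s <- site_entropies(f1)
  expect_equal(s[1], 0)
  expect_equal(s[2], log(21))
  expect_equal(s[3], log(2))
  expect_true(all(s >= 0 & s <= log(21) + 1e-12))
})

test_that("connected correlations: self-comparison is perfect, one-hot matches double loop", {
  set.seed(9)
  m <- msa_from_codes(matrix(sample(0:3, 30 * 6, replace = TRUE), 30, 6), 4)
  cmp <- connected_correlations(m, m, n_triplets = 200, seed = 3)
  expect_equal(cmp$pearson_f1, 1)
  expect_equal(cmp$pearson_c2, 1)
  expect_equal(cmp$pearson_c3, 1)

  # oracle equivalence on a small instance
  ft <- empirical_frequencies(m)
  c2 <- connected_c2(ft)
  oracle <- c2_double_loop(m)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    blk <- c2[ardca:::block_idx(i, 4), ardca:::block_idx(j, 4)]
    expect_true(max(abs(blk - oracle[i, j, , ])) < 1e-10)
  }
})

test_that("two perfectly correlated columns give C(a,a) = f(1-f) exactly", {
  m <- toy_msa(c("AA", "AA", "CC"))
  ft <- empirical_frequencies(m)
  c2 <- connected_c2(ft)
  fA <- 2 / 3
  expect_equal(c2[1, 21 + 1], fA - fA^2)  # block (1,2), entry (A,A); q = 21
})

test_that("independent-site samples have vanishing connected correlations", {
  set.seed(31)
  f <- matrix(rgamma(5 * 4, 2), 5, 4); f <- f / rowSums(f)
  pm <- profile_model(f, synthetic_alphabet(4))
  s <- simulate(pm, nsim = 1e5, seed = 8)
  c2 <- connected_c2(empirical_frequencies(s))
  mask <- ardca:::pair_mask(5, 4)
  expect_lt(max(abs(c2[mask])), 5 / sqrt(1e5))
})

test_that("weights export as a two-column TSV", {
  m <- toy_msa(c(x = "AAAA", y = "AAAA"))
  f <- tempfile(fileext = ".tsv")
  write_weights(m, compute_weights(m), f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$id, c("x", "y"))
  expect_equal(tab$weight, c(0.5, 0.5))
})
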
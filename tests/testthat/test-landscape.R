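test_that("mutational scan identities: zero at reference, profile closed form, naive equality", {
  # identity substitution is exactly zero
  m <- random_armodel(L = 5, q = 4, coupling_scale = 0.5, seed = 21)
  ref <- c(0L, 1L, 2L, 3L, 0L)
  scan <- dms_scan(m, ref)
  expect_identical(scan$delta_E[cbind(1:5, ref + 1)], rep(0, 5))

  # independent-site model: delta E = log f_i(a_i) - log f_i(b)
  set.seed(22)
  f <- matrix(rgamma(5 * 4, 2), 5, 4); f <- f / rowSums(f)
  pm <- profile_as_ardca(profile_model(f, synthetic_alphabet(4)))
  scan_p <- dms_scan(pm, ref)
  for (i in 1:5) for (b in 0:3) {
    expect_equal(scan_p$delta_E[i, b + 1],
                 log(f[i, ref[i] + 1]) - log(f[i, b + 1]),
                 tolerance = 1e-10)
  }

  # incremental scan equals naive full-energy differences everywhere
  m6 <- random_armodel(L = 6, q = 3, coupling_scale = 0.7, seed = 23)
  ref6 <- ar_sample(m6, 1, seed = 1)$codes[1, ]
  scan6 <- dms_scan(m6, ref6)
  expect_lt(max(abs(scan6$delta_E - naive_dms(m6, ref6))), 1e-10)
})

test_that("a fitted model's scan respects the entropic (non-identity) permutation", {
  set.seed(24)
  gt <- random_armodel(L = 6, q = 3, coupling_scale = 0.6, seed = 25)
  s <- ar_sample(gt, 800, seed = 26)
  m <- ardca(s, order = "entropic", config = training_config(max_iter = 150),
             weights = uniform_weights(s$M))
  ref <- s$codes[3, ]
  scan <- dms_scan(m, ref)
  expect_lt(max(abs(scan$delta_E - naive_dms(m, ref))), 1e-10)
})

test_that("epistasis is symmetric, zero for identity or uncoupled models", {
  m <- random_armodel(L = 5, q = 3, coupling_scale = 0.8, seed = 27)
  ref <- c(0L, 2L, 1L, 0L, 2L)
  # identity mutation on either side
  expect_equal(epistasis(m, ref, 2, 4, ref[2], 1L), 0)
  expect_equal(epistasis(m, ref, 2, 4, 1L, ref[4]), 0)
  # symmetry under swapping the two mutations
  e12 <- epistasis(m, ref, 2, 5, 1L, 0L)
  e21 <- epistasis(m, ref, 5, 2, 0L, 1L)
  expect_equal(e12, e21, tolerance = 1e-10)
  expect_error(epistasis(m, ref, 3, 3, 1L, 2L), "distinct")

  # all couplings zero -> additive energies, zero epistasis everywhere
  prof <- random_armodel(L = 5, q = 3, coupling_scale = 0, seed = 28)
  for (b1 in 0:2) for (b2 in 0:2) {
    expect_equal(epistasis(prof, ref, 1, 4, b1, b2), 0, tolerance = 1e-12)
  }
})

test_that("effective couplings equal the four-energy epistasis definition", {
  m <- random_armodel(L = 5, q = 3, coupling_scale = 0.6, seed = 29)
  ref <- c(1L, 0L, 2L, 1L, 0L)
  K <- effective_couplings(m, ref)
  for (i in c(1, 2)) for (j in c(3, 5)) {
    for (bi in 0:2) for (bj in 0:2) {
      expect_equal(K$K[i, j, bi + 1, bj + 1],
                   epistasis(m, ref, i, j, bi, bj), tolerance = 1e-9)
    }
  }
  # wildtype rows/columns vanish identically
  expect_true(all(K$K[2, 4, ref[2] + 1, ] == 0))
  expect_true(all(K$K[2, 4, , ref[4] + 1] == 0))
})

test_that("on a 2-site model the effective coupling reduces to the J combination", {
  # position 2 last in order: the local partition functions cancel and
  # ddE(b1, b2) = -[J(b2,b1) - J(b2,a1) - J(a2,b1) + J(a2,a1)]
  set.seed(30)
  h <- matrix(rnorm(4, sd = 0.5), 2, 2)
  Jm <- matrix(rnorm(4, sd = 0.8), 2, 2)
  m <- ardca:::new_ardca(h, list(NULL, array(Jm, c(2, 2, 1))),
                         direct_order(2), synthetic_alphabet(2))
  ref <- c(0L, 0L)
  K <- effective_couplings(m, ref)
  for (b1 in 0:1) for (b2 in 0:1) {
    expected <- -(Jm[b2 + 1, b1 + 1] - Jm[b2 + 1, 1] -
                    Jm[1, b1 + 1] + Jm[1, 1])
    expect_equal(K$K[1, 2, b1 + 1, b2 + 1], expected, tolerance = 1e-12)
  }
})

test_that("zero-sum gauge and APC behave algebraically", {
  set.seed(31)
  B <- matrix(rnorm(25), 5, 5)
  G <- ardca:::zero_sum_gauge(B)
  expect_lt(max(abs(rowSums(G))), 1e-10)
  expect_lt(max(abs(colSums(G))), 1e-10)

  # rank-1 separable score matrix is annihilated by APC
  u <- runif(8, 0.5, 2)
  Fm <- outer(u, u); diag(Fm) <- 0
  # with a zero diagonal, F_ij = u_i u_j is not exactly rank one on the
  # off-diagonal; APC cancels the separable structure to first order
  apc <- ardca:::apc_correct(Fm)
  expect_lt(max(abs(apc)) / max(Fm), 0.15)
})

test_that("delta E depends on the sequence background when couplings exist", {
  m <- random_armodel(L = 4, q = 3, coupling_scale = 1, seed = 32)
  ref1 <- c(0L, 0L, 0L, 0L)
  ref2 <- c(2L, 2L, 0L, 2L)
  d1 <- dms_scan(m, ref1)$delta_E[3, 2]  # same substitution 0 -> 1 at site 3
  d2 <- dms_scan(m, ref2)$delta_E[3, 2]
  expect_gt(abs(d1 - d2), 1e-6)
})

test_that("ppv curve counts true positives with deterministic tie-breaking", {
  pairs <- data.frame(i = c(1, 2, 3, 4), j = c(6, 7, 8, 9))
  truth <- rbind(c(1, 6), c(2, 7), c(3, 8))
  ppv <- ppv_curve(pairs, truth)
  expect_equal(ppv$ppv, c(1, 1, 1, 0.75))
  none <- ppv_curve(pairs, rbind(c(5, 9)))
  expect_equal(none$ppv, rep(0, 4))
  all_true <- ppv_curve(pairs, as.matrix(pairs))
  expect_equal(all_true$ppv, rep(1, 4))
})

test_that("contact pipeline writes well-formed TSV outputs", {
  m <- random_armodel(L = 5, q = 3, coupling_scale = 0.6, seed = 33)
  ref <- c(0L, 1L, 2L, 0L, 1L)
  K <- effective_couplings(m, ref)
  cs <- contact_scores(K, min_sep = 1, exclude_gap = FALSE)
  expect_true(all(cs$F >= 0))
  expect_equal(cs$F, t(cs$F))
  expect_equal(diag(cs$F_apc), rep(0, 5))

  f <- tempfile(fileext = ".tsv")
  write_contacts(cs, f)
  tab <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("i", "j", "F_apc", "F"))
  expect_true(all(diff(tab$F_apc) <= 1e-12))

  scan <- dms_scan(m, ref)
  f2 <- tempfile(fileext = ".tsv")
  write_dms(scan, f2)
  tab2 <- utils::read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(tab2), 5 * 3)
  wt_rows <- tab2[tab2$wt_aa == tab2$mut_aa, ]
  expect_true(all(wt_rows$delta_E == 0))
})
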
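test_that("sequence-space arithmetic reproduces the analytic anchors", {
  rep112 <- sequence_space_report(1.4, 112, 21)
  expect_equal(rep112$log10_N, 112 * 1.4 / log(10), tolerance = 1e-12)
  expect_equal(rep112$log10_N, 68.10, tolerance = 0.01)
  expect_equal(rep112$log10_total, 112 * log10(21), tolerance = 1e-12)
  expect_equal(rep112$log10_total, 148.09, tolerance = 0.01)
  expect_equal(rep112$log10_fraction, -79.99, tolerance = 0.01)
  # exact log-space arithmetic: no overflow at any scale
  huge <- sequence_space_report(2, 1e6, 21)
  expect_true(is.finite(huge$log10_fraction))
})

test_that("Monte-Carlo entropy matches enumeration and closed forms", {
  # uniform model: S = L ln q exactly; estimate within 3 SE
  unif <- random_armodel(L = 4, q = 4, field_scale = 0, coupling_scale = 0,
                         seed = 1)
  est <- estimate_entropy(unif, n_samples = 2000, seed = 2)
  expect_equal(est$S_total, 4 * log(4), tolerance = 1e-9)  # energies constant
  expect_equal(exact_entropy(unif), 4 * log(4), tolerance = 1e-10)

  # random coupled model vs enumeration oracle
  m <- random_armodel(L = 5, q = 3, coupling_scale = 0.8, seed = 3)
  ex <- exact_entropy(m)
  est <- estimate_entropy(m, n_samples = 5000, seed = 4)
  expect_lt(abs(est$S_total - ex), 3 * est$stderr)
  expect_equal(est$log10_N, est$S_total / log(10))

  # delta model has (near) zero entropy
  h <- matrix(-30, 3, 2); h[, 1] <- 30
  J <- list(NULL, array(0, c(2, 2, 1)), array(0, c(2, 2, 2)))
  delta <- ardca:::new_ardca(h, J, direct_order(3), synthetic_alphabet(2))
  expect_lt(exact_entropy(delta), 1e-9)

  # L = 2 joint with hand-computed four-term entropy
  pt <- matrix(c(0.8, 0.2, 0.25, 0.75), 2, 2)  # P(a2 | a1) in columns
  p1 <- c(0.6, 0.4)
  m2 <- ardca:::new_ardca(
    rbind(log(p1), c(0, 0)),
    list(NULL, array(log(pt), c(2, 2, 1))),
    direct_order(2), synthetic_alphabet(2))
  joint <- c(p1[1] * pt[, 1], p1[2] * pt[, 2])
  expect_equal(exact_entropy(m2), -sum(joint * log(joint)), tolerance = 1e-10)

  expect_error(exact_entropy(random_armodel(8, 21, seed = 1)), "cap")
  expect_error(estimate_entropy(m, n_samples = 1), "n_samples")
})

test_that("entropy never exceeds the maximum-entropy bound", {
  for (s in 1:4) {
    m <- random_armodel(L = 4, q = 3, coupling_scale = 1, seed = s)
    est <- estimate_entropy(m, n_samples = 1000, seed = s + 10)
    expect_lte(est$S_total, 4 * log(3) + 3 * est$stderr)
  }
})

test_that("profile model: closed-form entropy, sampling, finite log-probabilities", {
  set.seed(41)
  msa <- toy_msa(c("AC", "AC", "AD"), q = 4)
  pm0 <- profile_fit(msa, pseudocount = 0)
  # the observed sequence has log-prob log(1 * 2/3); unseen states are
  # impossible at alpha = 0 but finite with the default pseudocount
  expect_equal(predict(pm0, "AC"), log(2 / 3))
  expect_equal(predict(pm0, "CC"), -Inf)
  pm <- profile_fit(msa, pseudocount = 0.01)
  expect_true(is.finite(predict(pm, "CC")))

  # uniform profile entropy = L ln q, and the closed form matches the
  # Monte-Carlo estimate on the equivalent autoregressive model
  f <- matrix(1 / 4, 6, 4)
  pu <- profile_model(f, synthetic_alphabet(4))
  expect_equal(profile_entropy(pu), 6 * log(4))

  f2 <- matrix(rgamma(5 * 4, 2), 5, 4); f2 <- f2 / rowSums(f2)
  p2 <- profile_model(f2, synthetic_alphabet(4))
  est <- estimate_entropy(profile_as_ardca(p2), n_samples = 4000, seed = 5)
  expect_lt(abs(est$S_total - profile_entropy(p2)), 3 * est$stderr)
  expect_equal(profile_entropy(p2), exact_entropy(p2), tolerance = 1e-10)
})

test_that("generative report: perfect on self, high f1 on memorized data", {
  set.seed(42)
  gt <- random_armodel(L = 6, q = 4, coupling_scale = 0.6, seed = 6)
  nat <- ar_sample(gt, 400, seed = 7)
  cmp <- connected_correlations(nat, nat, n_triplets = 300, seed = 8)
  expect_equal(cmp$pearson_f1, 1)

  # near-unregularized fit on data it can memorize: one-point statistics
  # are reproduced almost exactly by model samples
  m <- ardca(nat, config = training_config(lambda_J = 1e-8, lambda_h = 1e-8,
                                           max_iter = 400),
             weights = uniform_weights(nat$M))
  rep <- generative_report(nat, m, n_samples = 5000, n_triplets = 300,
                           seed = 9, weights = uniform_weights(nat$M))
  expect_gt(rep$pearson_f1, 0.99)

  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$pearson_f1, rep$pearson_f1, tolerance = 1e-12)
})

test_that("a fitted model recovers the correlations of its generating truth", {
  gt <- random_armodel(L = 8, q = 4, field_scale = 0.6, coupling_scale = 0.4,
                       seed = 10)
  nat <- ar_sample(gt, 2e4, seed = 11)
  m <- ardca(nat, config = training_config("generative"),
             weights = uniform_weights(nat$M))
  rep <- generative_report(nat, m, n_samples = 2e4, n_triplets = 500,
                           seed = 12, weights = uniform_weights(nat$M))
  expect_gt(rep$pearson_c2, 0.95)
})

test_that("PCA projection: centered natural data, orthonormal loadings, cluster separation", {
  fx <- two_cluster_msa(L = 16, q = 4, M = 600, seed = 13)
  w <- uniform_weights(fx$msa$M)
  pca <- pca_projection(fx$msa, weights = w)
  # weighted mean of the natural data projects to the origin
  ctr <- colSums(pca$projections$natural * w$w / w$Meff)
  expect_lt(max(abs(ctr)), 1e-10)
  expect_lt(abs(sum(pca$loadings[, 1] * pca$loadings[, 2])), 1e-10)
  expect_equal(colSums(pca$loadings^2), c(1, 1), tolerance = 1e-10)

  # PC1 separates the two planted clusters
  pc1 <- pca$projections$natural[, 1]
  m1 <- mean(pc1[fx$labels == 1]); m2 <- mean(pc1[fx$labels == 2])
  s12 <- max(sd(pc1[fx$labels == 1]), sd(pc1[fx$labels == 2]))
  expect_gt(abs(m1 - m2), 5 * s12)

  expect_error(pca_projection(fx$msa, w, toy_msa("ACDC", q = 4)), "dimension")
})

test_that("profile samples of a clustered family collapse toward the PC origin", {
  fx <- two_cluster_msa(L = 16, q = 4, M = 800, seed = 14)
  w <- uniform_weights(fx$msa$M)
  m <- ardca(fx$msa, config = training_config("generative"), weights = w)
  pm <- profile_fit(fx$msa, w)
  pca <- pca_projection(fx$msa, weights = w,
                        ar = simulate(m, 500, seed = 15),
                        profile = simulate(pm, 500, seed = 16))
  radius <- function(x) mean(sqrt(rowSums(x^2)))
  expect_lt(radius(pca$projections$profile),
            0.5 * radius(pca$projections$ar))
})

test_that("log-odds classification separates two planted subfamilies", {
  # identical models score everything zero
  m <- random_armodel(L = 5, q = 3, coupling_scale = 0.5, seed = 17)
  s <- ar_sample(m, 50, seed = 18)
  expect_equal(log_odds_classify(m, m, s), rep(0, 50))

  # samples from model 1 score positive on average (and symmetrically)
  m2 <- random_armodel(L = 5, q = 3, coupling_scale = 0.5, seed = 19)
  s1 <- ar_sample(m, 1000, seed = 20)
  s2 <- ar_sample(m2, 1000, seed = 21)
  expect_gt(mean(log_odds_classify(m, m2, s1)), 0)
  expect_gt(mean(log_odds_classify(m2, m, s2)), 0)

  expect_error(log_odds_classify(m, random_armodel(6, 3, seed = 1), s), "share L")
})
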
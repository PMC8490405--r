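# Regularized maximum-likelihood training. Each model position i is an
# independent soft-max regression of the symbol at i on the one-hot
# encoded prefix (positions 1..i-1 in model order): the likelihood
# factorizes, so the L per-site problems share nothing but the data and
# can be solved in any order with identical results. Gradients are exact
# data averages (no MCMC): the gradient of the mean log-likelihood in
# h_i(a) is f_i(a) - <P(a_i = a | prefix)>_D, and in J_ij(a,b) it is
# f_ij(a,b) - <P(a_i = a | prefix) d(b, a_j)>_D, with reweighted averages.

#' Training configuration
#'
#' Bundles the regularization strengths and optimizer settings. The two
#' presets follow the published convention: weak regularization
#' (\code{lambda_J = 1e-4}, \code{lambda_h = 1e-6}) for generative use,
#' stronger (\code{lambda_J = 1e-2}, \code{lambda_h = 1e-4}) for
#' mutational-effect and contact prediction, where large parameters hurt.
#' The likelihood is normalized by Meff (a weighted mean, not a sum), so
#' these strengths are comparable across family sizes; penalties are
#' \eqn{\lambda \sum \theta^2} without a 1/2 factor.
#'
#' @param preset \code{"generative"} or \code{"effects_contacts"}.
#' @param lambda_J,lambda_h Explicit L2 strengths (override the preset).
#' @param grad_tol Stop when the sup-norm of the gradient drops below
#'   this; default 1e-5.
#' @param max_iter Maximum L-BFGS iterations per site; default 500.
#' @param theta Reweighting identity threshold; default 0.8.
#' @param pseudocount Pseudocount for training-side statistics; default 0
#'   (the moment conditions are stated for raw frequencies).
#' @return A list of class \code{"training_config"}.
#' @export
training_config <- function(preset = c("generative", "effects_contacts"),
                            lambda_J = NULL, lambda_h = NULL,
                            grad_tol = 1e-5, max_iter = 500L,
                            theta = 0.8, pseudocount = 0) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    generative = c(1e-4, 1e-6),
    effects_contacts = c(1e-2, 1e-4)
  )
  if (is.null(lambda_J)) lambda_J <- defaults[1]
  if (is.null(lambda_h)) lambda_h <- defaults[2]
  stopifnot(lambda_J >= 0, lambda_h >= 0, grad_tol > 0)
  structure(
    list(preset = preset, lambda_J = lambda_J, lambda_h = lambda_h,
         grad_tol = grad_tol, max_iter = as.integer(max_iter),
         theta = theta, pseudocount = pseudocount),
    class = "training_config"
  )
}

# Objective and exact-gradient closures for the soft-max regression of
# model position i on positions 1..i-1. The objective is the NEGATIVE
# penalized mean log-likelihood (minimized); its gradient in the
# likelihood part is f - <P>_D, the moment-condition residual. One-hot
# prefix features and the empirical moments are precomputed once and
# shared across optimizer iterations; a small cache lets fn and gr share
# the logits of the last evaluated parameter vector.
site_objective <- function(i, codes, w, Meff, lambda_J, lambda_h, q) {
  M <- nrow(codes)
  y <- codes[, i] + 1L
  nprev <- i - 1L
  Yh <- matrix(0, M, q); Yh[cbind(seq_len(M), y)] <- 1
  fi <- colSums(Yh * w) / Meff
  Xs <- vector("list", nprev)
  fij <- vector("list", nprev)
  Yw <- Yh * w
  for (j in seq_len(nprev)) {
    Xj <- matrix(0, M, q)
    Xj[cbind(seq_len(M), codes[, j] + 1L)] <- 1
    Xs[[j]] <- Xj
    fij[[j]] <- crossprod(Yw, Xj) / Meff
  }
  npar <- q + nprev * q * q
  split_par <- function(par) {
    h <- par[seq_len(q)]
    Js <- if (nprev > 0L)
      lapply(seq_len(nprev), function(j)
        matrix(par[q + ((j - 1L) * q * q + 1L):(j * q * q)], q, q))
    else list()
    list(h = h, Js = Js)
  }
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  logits_of <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$logits)
    p <- split_par(par)
    logits <- matrix(p$h, M, q, byrow = TRUE)
    for (j in seq_len(nprev)) logits <- logits + Xs[[j]] %*% t(p$Js[[j]])
    cache$par <- par
    cache$logits <- logits
    cache$split <- p
    logits
  }
  fn <- function(par) {
    logits <- logits_of(par)
    ll <- sum(w * (logits[cbind(seq_len(M), y)] - row_logsumexp(logits))) / Meff
    p <- cache$split
    pen <- lambda_h * sum(p$h^2) +
      lambda_J * sum(vapply(p$Js, function(J) sum(J^2), numeric(1)))
    -ll + pen
  }
  gr <- function(par) {
    logits <- logits_of(par)
    P <- row_softmax(logits)
    Wp <- P * w
    p <- cache$split
    gh <- -(fi - colSums(Wp) / Meff) + 2 * lambda_h * p$h
    gJ <- numeric(0)
    for (j in seq_len(nprev)) {
      gJj <- -(fij[[j]] - crossprod(Wp, Xs[[j]]) / Meff) +
        2 * lambda_J * p$Js[[j]]
      gJ <- c(gJ, as.vector(gJj))
    }
    c(gh, gJ)
  }
  mean_ll <- function(par) {
    logits <- logits_of(par)
    sum(w * (logits[cbind(seq_len(M), y)] - row_logsumexp(logits))) / Meff
  }
  list(fn = fn, gr = gr, mean_ll = mean_ll, split_par = split_par,
       npar = npar, nprev = nprev)
}

# Run the optimizer on one site's objective and unpack the result.
site_softmax_fit <- function(i, codes, w, Meff, lambda_J, lambda_h,
                             grad_tol, max_iter, q) {
  obj <- site_objective(i, codes, w, Meff, lambda_J, lambda_h, q)
  res <- stats::optim(rep(0, obj$npar), obj$fn, obj$gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = grad_tol,
                                     factr = 10))
  if (!is.finite(res$value))
    stop("non-finite objective at model position ", i)
  g <- obj$gr(res$par)
  p <- obj$split_par(res$par)
  J <- if (obj$nprev > 0L)
    array(unlist(p$Js), dim = c(q, q, obj$nprev)) else NULL
  list(h = p$h, J = J,
       converged = max(abs(g)) < grad_tol * 10 || res$convergence == 0L,
       grad_norm = max(abs(g)), site_ll = obj$mean_ll(res$par),
       iterations = res$counts[1])
}

#' Fit one conditional distribution (model position i >= 2)
#'
#' Maximizes the reweighted mean conditional log-likelihood of position
#' \code{i} given positions \code{1..i-1} of the permuted alignment,
#' minus L2 penalties, by low-storage BFGS with the exact analytic
#' gradient.
#'
#' @param i Model position (2-based through L).
#' @param permuted_msa An \code{"encoded_msa"} already in model order.
#' @param weights A \code{"seq_weights"}.
#' @param config A [training_config()].
#' @return List with \code{h} (length q), \code{J} (q x q x (i-1)),
#'   \code{converged}, \code{grad_norm}, \code{site_ll}.
#' @export
fit_site <- function(i, permuted_msa, weights, config = training_config()) {
  stopifnot(i >= 2L, i <= permuted_msa$L)
  site_softmax_fit(i, permuted_msa$codes, weights$w, weights$Meff,
                   config$lambda_J, config$lambda_h,
                   config$grad_tol, config$max_iter, permuted_msa$q)
}

#' Fit the unconditioned first position
#'
#' With \code{lambda_h = 0} the maximum-likelihood fields have the closed
#' form \eqn{h_1(a) = \log f_1(a) + \mathrm{const}} (frequencies floored
#' at 1e-12); with \code{lambda_h > 0} the same optimizer as [fit_site()]
#' is used, restricted to fields.
#'
#' @inheritParams fit_site
#' @return List with \code{h} and convergence info.
#' @export
fit_first_site <- function(permuted_msa, weights, config = training_config()) {
  if (config$lambda_h == 0) {
    w <- weights$w / weights$Meff
    f <- vapply(seq_len(permuted_msa$q) - 1L,
                function(a) sum(w[permuted_msa$codes[, 1] == a]), numeric(1))
    h <- log(pmax(f, 1e-12))
    h <- h - mean(h)
    ll <- sum(w * h[permuted_msa$codes[, 1] + 1L]) - logsumexp(h)
    list(h = h, J = NULL, converged = TRUE, grad_norm = 0, site_ll = ll,
         iterations = 0L)
  } else {
    site_softmax_fit(1L, permuted_msa$codes, weights$w, weights$Meff,
                     config$lambda_J, config$lambda_h,
                     config$grad_tol, config$max_iter, permuted_msa$q)
  }
}

#' Fit an autoregressive model to a multiple sequence alignment
#'
#' The main fitting function. Computes sequence weights, the site order
#' (entropic by default: most conserved columns first), and then solves
#' the L independent per-site soft-max regressions by exact-gradient
#' L-BFGS. The result is identical to sequential execution regardless of
#' scheduling because the per-site problems share no parameters.
#'
#' @param msa An \code{"encoded_msa"} (see [encode_msa()]).
#' @param order \code{"entropic"}, \code{"direct"}, \code{"random"}, a
#'   \code{"site_order"} object, or an explicit 1-based permutation.
#' @param config A [training_config()]; or pass \code{preset} /
#'   \code{lambda_J} / \code{lambda_h} through \code{...}.
#' @param weights Optional precomputed \code{"seq_weights"} (e.g.
#'   [uniform_weights()] for data known to be i.i.d.); by default
#'   computed at the config's identity threshold.
#' @param order_seed Seed used when \code{order = "random"}.
#' @param verbose Print per-site progress?
#' @param ... Passed to [training_config()] when \code{config} is NULL.
#' @return An object of class \code{"ardca"} with a \code{fit} element
#'   (per-site convergence flags, gradient norms, total weighted mean
#'   log-likelihood, wall time) and training provenance in \code{meta}.
#' @examples
#' msa <- encode_msa(c("ACDA", "ACDC", "AADA", "ACCA", "ACDA"))
#' m <- ardca(msa, config = training_config(max_iter = 50))
#' logLik(m)
#' @export
ardca <- function(msa, order = "entropic", config = NULL, weights = NULL,
                  order_seed = 1L, verbose = FALSE, ...) {
  stopifnot(inherits(msa, "encoded_msa"))
  if (is.null(config)) config <- training_config(...)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(weights)) weights <- compute_weights(msa, config$theta)
  ord <- resolve_order(order, msa, weights, order_seed)
  pm <- apply_order(msa, ord)
  L <- msa$L; q <- msa$q
  h <- matrix(0, L, q)
  J <- vector("list", L)
  reports <- vector("list", L)
  first <- fit_first_site(pm, weights, config)
  h[1, ] <- first$h
  reports[[1]] <- first
  for (i in seq_len(L)[-1]) {
    fitted <- fit_site(i, pm, weights, config)
    h[i, ] <- fitted$h
    J[[i]] <- fitted$J
    reports[[i]] <- fitted
    if (verbose)
      message(sprintf("site %d/%d: ll = %.4f, |grad| = %.2e", i, L,
                      fitted$site_ll, fitted$grad_norm))
  }
  fit <- list(
    converged = vapply(reports, `[[`, logical(1), "converged"),
    grad_norms = vapply(reports, `[[`, numeric(1), "grad_norm"),
    site_ll = vapply(reports, `[[`, numeric(1), "site_ll"),
    logLik_mean = sum(vapply(reports, `[[`, numeric(1), "site_ll")),
    wall_time = proc.time()[["elapsed"]] - t0
  )
  model <- new_ardca(
    h, J, ord, msa$alphabet,
    meta = list(
      lambda_J = config$lambda_J, lambda_h = config$lambda_h,
      preset = config$preset, theta = config$theta,
      Meff = weights$Meff, M = msa$M, order_label = ord$label,
      likelihood_normalization = "mean"
    )
  )
  model$fit <- fit
  model
}

resolve_order <- function(order, msa, weights, order_seed) {
  if (inherits(order, "site_order")) {
    stopifnot(length(order$perm) == msa$L)
    return(order)
  }
  if (is.numeric(order)) return(custom_order(order))
  switch(match.arg(order, c("entropic", "direct", "random")),
    entropic = {
      ft <- empirical_frequencies(msa, weights, pseudocount = 0, pair = FALSE)
      entropic_order(ft$s)
    },
    direct = direct_order(msa$L),
    random = random_order(msa$L, order_seed)
  )
}
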
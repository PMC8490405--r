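#' Generative evaluation report
#'
#' Samples sequences from the model and compares one-point frequencies
#' and connected two- and three-point correlations against the natural
#' alignment via Pearson correlations. Natural-side statistics are
#' reweighted (the model's training target); the sampled side is i.i.d.
#' by construction and left unweighted. High correlations on statistics
#' the model does not fit explicitly are the key generative check.
#'
#' @param natural_msa The natural \code{"encoded_msa"}.
#' @param model An \code{"ardca"} or \code{"profile_model"}.
#' @param n_samples Number of sequences to sample; default 1e4.
#' @param n_triplets Number of three-point tuples; default 1e5.
#' @param seed Integer seed (drives both sampling and the tuple subset).
#' @param weights Optional \code{"seq_weights"} for the natural side;
#'   computed at 80\% identity when NULL.
#' @return Class \code{"generative_report"}: the
#'   \code{"correlation_comparison"} plus sampling metadata.
#' @export
generative_report <- function(natural_msa, model, n_samples = 1e4,
                              n_triplets = 1e5, seed = 1L, weights = NULL) {
  if (natural_msa$L != model$L || natural_msa$q != model$q)
    stop("model and alignment must share L and q")
  if (is.null(weights)) weights <- compute_weights(natural_msa)
  sampled <- simulate(model, nsim = n_samples, seed = seed)
  cmp <- connected_correlations(natural_msa, sampled,
                                weights_a = weights, weights_b = NULL,
                                n_triplets = n_triplets, seed = seed)
  out <- c(cmp, list(n_samples = n_samples, seed = seed,
                     Meff = weights$Meff))
  class(out) <- c("generative_report", "correlation_comparison")
  out
}

#' @export
print.generative_report <- function(x, ...) {
  cat("Generative evaluation (", x$n_samples, "model samples, seed =",
      x$seed, ")\n")
  NextMethod()
}

#' Export a generative report as JSON
#'
#' @param report A \code{"generative_report"}.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(pearson_f1 = report$pearson_f1,
         pearson_c2 = report$pearson_c2,
         pearson_c3 = report$pearson_c3,
         n_samples = report$n_samples,
         n_triplets = nrow(report$tuples),
         seed = report$seed,
         Meff = report$Meff),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Principal-component projection of alignments
#'
#' One-hot encodes the alignments (L q binary features, all q states
#' including the gap: gap patterns carry cluster structure), centers at
#' the weighted mean of the natural data, and projects every dataset on
#' the top two eigenvectors of the weighted covariance of the natural
#' data only. The sign of each loading is fixed so its largest-magnitude
#' entry is positive.
#'
#' @param natural_msa The natural \code{"encoded_msa"} defining the PC
#'   space.
#' @param weights Optional \code{"seq_weights"} for the natural data.
#' @param ... Further \code{"encoded_msa"} objects to project (model
#'   samples, profile samples, ...), optionally named.
#' @return Class \code{"ardca_pca"}: list with \code{loadings}
#'   (Lq x 2), \code{center}, \code{projections} (named list of n x 2
#'   coordinate matrices, first entry \code{natural}), \code{var_explained}.
#' @export
pca_projection <- function(natural_msa, weights = NULL, ...) {
  others <- list(...)
  if (length(others) && is.null(names(others)))
    names(others) <- paste0("dataset", seq_along(others))
  if (is.null(weights)) weights <- compute_weights(natural_msa)
  X <- one_hot(natural_msa)
  wn <- weights$w / weights$Meff
  center <- colSums(X * wn)
  Xc <- sweep(X, 2L, center)
  cov <- crossprod(Xc * wn, Xc)
  eig <- eigen(cov, symmetric = TRUE)
  loadings <- eig$vectors[, 1:2, drop = FALSE]
  for (k in 1:2) {
    peak <- which.max(abs(loadings[, k]))
    if (loadings[peak, k] < 0) loadings[, k] <- -loadings[, k]
  }
  project <- function(msa) {
    if (msa$L != natural_msa$L || msa$q != natural_msa$q)
      stop("dimension mismatch: alignments must share L and q")
    sweep(one_hot(msa), 2L, center) %*% loadings
  }
  projections <- c(list(natural = project(natural_msa)),
                   lapply(others, project))
  structure(
    list(loadings = loadings, center = center, projections = projections,
         var_explained = eig$values[1:2] / sum(pmax(eig$values, 0))),
    class = "ardca_pca"
  )
}

#' @export
print.ardca_pca <- function(x, ...) {
  cat("PCA projection on natural-data components",
      sprintf("(%.1f%% + %.1f%% variance)\n", 100 * x$var_explained[1],
              100 * x$var_explained[2]))
  for (nm in names(x$projections))
    cat(sprintf("  %-12s: %d sequences, mean radius %.3f\n", nm,
                nrow(x$projections[[nm]]),
                mean(sqrt(rowSums(x$projections[[nm]]^2)))))
  invisible(x)
}

#' Write PCA coordinates as TSV
#'
#' @param pca An \code{"ardca_pca"}.
#' @param path Output path.
#' @export
write_projection <- function(pca, path) {
  df <- do.call(rbind, lapply(names(pca$projections), function(nm) {
    p <- pca$projections[[nm]]
    data.frame(dataset = nm, pc1 = p[, 1], pc2 = p[, 2])
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-odds subfamily classification
#'
#' Scores each sequence by \eqn{\log P_1(\mathrm{seq}) -
#' \log P_2(\mathrm{seq})} using exact normalized log-probabilities,
#' which makes scores comparable across models — the decisive advantage
#' of autoregressive models over unnormalized sequence weights. Positive
#' scores assign the sequence to family 1.
#'
#' @param model_1,model_2 Two models of the same class (both
#'   \code{"ardca"} or both \code{"profile_model"}) sharing L and q.
#' @param sequences An \code{"encoded_msa"}, character vector, or code
#'   matrix.
#' @return Numeric vector of log-odds scores.
#' @export
log_odds_classify <- function(model_1, model_2, sequences) {
  if (model_1$L != model_2$L || model_1$q != model_2$q)
    stop("models must share L and q")
  predict(model_1, sequences, type = "logprob") -
    predict(model_2, sequences, type = "logprob")
}
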
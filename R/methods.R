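# S3 methods for fitted "ardca" models.

#' @export
print.ardca <- function(x, ...) {
  cat("Autoregressive sequence model (arDCA)\n")
  cat("  L =", x$L, " q =", x$q, " order =", x$order$label, "\n")
  if (!is.null(x$meta$lambda_J))
    cat("  lambda_J =", x$meta$lambda_J, " lambda_h =", x$meta$lambda_h, "\n")
  if (!is.null(x$meta$Meff))
    cat("  trained on M =", x$meta$M, "sequences, Meff =",
        format(x$meta$Meff, digits = 6), "\n")
  if (!is.null(x$fit))
    cat("  mean log-likelihood =", format(x$fit$logLik_mean, digits = 6),
        "nats/sequence\n")
  invisible(x)
}

#' @method summary ardca
#' @export
summary.ardca <- function(object, ...) {
  out <- list(
    L = object$L, q = object$q, order = object$order,
    meta = object$meta, fit = object$fit,
    n_parameters = object$L * object$q +
      object$q^2 * object$L * (object$L - 1) / 2
  )
  class(out) <- "summary.ardca"
  out
}

#' @export
print.summary.ardca <- function(x, ...) {
  cat("arDCA model summary\n")
  cat("  dimensions      : L =", x$L, ", q =", x$q, "\n")
  cat("  parameters      :", x$n_parameters,
      "(fields + strictly triangular directed couplings)\n")
  cat("  site order      :", x$order$label, "\n")
  if (!is.null(x$fit)) {
    cat("  mean logLik     :", format(x$fit$logLik_mean, digits = 6),
        "nats/sequence\n")
    cat("  sites converged :", sum(x$fit$converged), "/", length(x$fit$converged), "\n")
    cat("  max |gradient|  :", format(max(x$fit$grad_norms), digits = 3), "\n")
    cat("  wall time       :", format(x$fit$wall_time, digits = 3), "s\n")
  }
  invisible(x)
}

#' @method coef ardca
#' @export
coef.ardca <- function(object, ...) {
  list(h = object$h, J = object$J, order = object$order$perm)
}

#' Training log-likelihood
#'
#' The reweighted mean log-likelihood per sequence (nats) at the fitted
#' parameters; the weighted-data "nobs" is Meff. Comparable across site
#' orders fitted on the same data.
#' @param object A fitted \code{"ardca"} model.
#' @param ... Unused.
#' @method logLik ardca
#' @export
logLik.ardca <- function(object, ...) {
  if (is.null(object$fit)) stop("model has no stored fit report")
  val <- object$fit$logLik_mean
  attr(val, "df") <- object$L * object$q +
    object$q^2 * object$L * (object$L - 1) / 2
  attr(val, "nobs") <- object$meta$Meff
  class(val) <- "logLik"
  val
}

#' Predict log-probabilities or energies for sequences
#'
#' @param object A fitted \code{"ardca"} model.
#' @param newdata An \code{"encoded_msa"}, character vector of sequences,
#'   or 0-based code matrix.
#' @param type \code{"logprob"} (exact normalized log-probability, nats)
#'   or \code{"energy"} (its negative).
#' @param ... Unused.
#' @export
predict.ardca <- function(object, newdata, type = c("logprob", "energy"),
                          ...) {
  type <- match.arg(type)
  lp <- log_probability(object, newdata)
  if (type == "energy") -lp else lp
}

#' Simulate sequences from the model
#'
#' Ancestral sampling (see [ar_sample()]).
#'
#' @param object A fitted \code{"ardca"} model.
#' @param nsim Number of sequences.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return An \code{"encoded_msa"}.
#' @export
simulate.ardca <- function(object, nsim = 1, seed = NULL, ...) {
  ar_sample(object, nsim, seed)
}
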
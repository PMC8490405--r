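# Small internal numerics/RNG helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. With seed = NULL the current
# RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log(sum(exp(x))) with max subtraction, per row of a matrix.
row_logsumexp <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowSums(exp(x - m)))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax with max subtraction.
row_softmax <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Draw one categorical value per row of a probability matrix.
sample_rows <- function(p) {
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(nrow(p)) * cum[, ncol(p)]
  as.integer(rowSums(u > cum))  # 0-based code
}
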
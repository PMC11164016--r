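#' @useDynLib fmtomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate as.dist binomial coef cor cor.test cutree
#'   cmdscale dist glm hclust median optimize plogis prcomp qlogis quantile
#'   rbinom rgamma rlnorm rmultinom rnorm runif sd setNames uniroot var
#'   wilcox.test predict
#' @importFrom utils head modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Counter-based fan-out of one global seed into independent per-stage seeds,
# so toggling one pipeline stage does not shift another stage's stream.
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Dirichlet sampler (gamma normalization); alpha recycled to length n.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Stratified fold assignment: classes split separately so each fold keeps
# both classes whenever the event count allows it.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < n_folds) {
      stopf("cannot stratify %d folds: class '%s' has only %d observation(s)",
            n_folds, cls, length(idx))
    }
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}
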
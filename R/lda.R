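#' Fit a latent Dirichlet allocation topic model by variational EM
#'
#' Samples play the role of documents, genera of words, and read counts of
#' word counts. The E-step runs per-sample variational updates of topic
#' responsibilities and Dirichlet parameters (fully vectorized across
#' samples); the M-step updates the topic-term matrix with Dirichlet
#' smoothing `eta` (MAP estimate) and re-estimates the symmetric document
#' Dirichlet concentration `alpha` by safeguarded Newton iterations. The
#' tracked objective (variational bound plus the topic-term log prior) is
#' non-decreasing; convergence is declared when its relative change falls
#' below `tol`. Multiple random restarts are fitted and the best objective
#' kept.
#'
#' @param counts a genus-level [count_table()] or nonnegative integer
#'   matrix, samples in rows.
#' @param k number of topics (k = 1 is allowed and degenerate: the single
#'   topic equals the overall word frequency).
#' @param seed RNG seed (controls restart initializations).
#' @param tol relative-change convergence tolerance for the objective.
#' @param max_iter maximum EM iterations per restart.
#' @param restarts number of random restarts.
#' @param eta topic-term Dirichlet smoothing.
#' @param estimate_alpha re-estimate `alpha` each M-step?
#' @return Object of class `topic_model`: `k`, `topic_term` (k x G row
#'   stochastic), `sample_topics` (N x k row stochastic), `alpha`,
#'   `elbo_trace` (best restart), `converged`, `seed`.
#' @export
fit_lda <- function(counts, k, seed = 1, tol = 1e-6, max_iter = 100,
                    restarts = 5, eta = 0.1, estimate_alpha = TRUE) {
  X <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (any(X < 0)) stopf("counts must be nonnegative")
  if (k < 1) stopf("k must be >= 1")
  empty <- rowSums(X) == 0
  if (any(empty)) {
    warnf("dropping %d empty sample(s)", sum(empty))
    X <- X[!empty, , drop = FALSE]
  }
  if (k == 1) return(lda_k1(X, eta, seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(stage_seed(seed, 100 + r),
                     lda_vem_once(X, k, tol, max_iter, eta, estimate_alpha))
    if (is.null(best) || fit$objective > best$objective) best <- fit
  }
  structure(list(k = k, topic_term = best$beta, sample_topics = best$theta,
                 alpha = best$alpha, elbo_trace = best$trace,
                 converged = best$converged, seed = seed, eta = eta),
            class = "topic_model")
}

lda_k1 <- function(X, eta, seed) {
  beta <- matrix((colSums(X) + eta) / (sum(X) + eta * ncol(X)), 1,
                 dimnames = list("topic1", colnames(X)))
  theta <- matrix(1, nrow(X), 1, dimnames = list(rownames(X), "topic1"))
  ll <- sum(sweep(X, 2, log(as.vector(beta)), `*`))
  structure(list(k = 1L, topic_term = beta, sample_topics = theta, alpha = 1,
                 elbo_trace = ll, converged = TRUE, seed = seed, eta = eta),
            class = "topic_model")
}

lda_vem_once <- function(X, k, tol, max_iter, eta, estimate_alpha) {
  n <- nrow(X); G <- ncol(X)
  nd <- rowSums(X)
  alpha <- 1
  # init: perturbed, smoothed corpus frequencies per topic (strictly
  # positive even for genera with zero total count)
  beta <- matrix((colSums(X) + 0.5) / (sum(X) + 0.5 * G), k, G, byrow = TRUE) *
    matrix(rgamma(k * G, 20, 20), k, G)
  beta <- beta / rowSums(beta)
  gamma <- matrix(alpha + nd / k, n, k)
  trace <- numeric(0)
  converged <- FALSE
  obj_old <- -Inf
  # responsibilities are invariant to row scaling of exp(digamma(gamma)),
  # so subtract the row max before exponentiating to avoid underflow
  escale <- function(gamma) {
    dg <- digamma(gamma)
    mx <- dg[cbind(seq_len(nrow(dg)), max.col(dg))]
    exp(dg - mx)
  }
  for (it in seq_len(max_iter)) {
    # E-step: alternate optimal phi (implicit) and gamma to convergence
    for (inner in 1:5) {
      E <- escale(gamma)
      S <- E %*% beta
      R <- X / S
      gamma_new <- alpha + E * (R %*% t(beta))
      delta <- max(abs(gamma_new - gamma) / (1 + gamma))
      gamma <- gamma_new
      if (delta < 3e-4) break
    }
    E <- escale(gamma)
    S <- E %*% beta
    R <- X / S
    # M-step: MAP topic-term update
    C <- beta * (t(E) %*% R)
    beta <- (C + eta) / rowSums(C + eta)
    # alpha updates start after a burn-in: early concentration estimates
    # reflect the initialization, not the data, and can lock in a poor
    # hard assignment
    if (estimate_alpha && it > 10) alpha <- update_alpha(alpha, gamma, k)
    obj <- lda_objective(X, gamma, beta, alpha, eta, nd)
    trace <- c(trace, obj)
    if (is.finite(obj_old) && abs(obj - obj_old) < tol * abs(obj)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  theta <- gamma / rowSums(gamma)
  dimnames(theta) <- list(rownames(X), paste0("topic", seq_len(k)))
  dimnames(beta) <- list(paste0("topic", seq_len(k)), colnames(X))
  dimnames(gamma) <- dimnames(theta)
  list(beta = beta, theta = theta, gamma = gamma, alpha = alpha,
       trace = trace, objective = trace[length(trace)], converged = converged)
}

# Variational bound with phi at its optimum plus the MAP topic-term prior.
lda_objective <- function(X, gamma, beta, alpha, eta, nd) {
  k <- ncol(gamma)
  dg <- digamma(gamma)
  mx <- dg[cbind(seq_len(nrow(dg)), max.col(dg))]
  S <- exp(dg - mx) %*% beta
  gsum <- rowSums(gamma)
  word <- sum(X * ifelse(X > 0, log(S) + mx, 0)) - sum(nd * digamma(gsum))
  dg <- digamma(gamma) - digamma(gsum)
  theta_part <- nrow(X) * (lgamma(k * alpha) - k * lgamma(alpha)) -
    sum(lgamma(gsum)) + sum(lgamma(gamma)) + sum((alpha - gamma) * dg)
  word + theta_part + eta * sum(log(beta))
}

# Safeguarded Newton step(s) on the symmetric Dirichlet concentration.
update_alpha <- function(alpha, gamma, k) {
  n <- nrow(gamma)
  ss <- sum(digamma(gamma) - digamma(rowSums(gamma)))
  obj <- function(a) n * (lgamma(k * a) - k * lgamma(a)) + (a - 1) * ss
  for (i in 1:20) {
    g <- n * k * (digamma(k * alpha) - digamma(alpha)) + ss
    h <- n * k * (k * trigamma(k * alpha) - trigamma(alpha))
    step <- g / h
    a_new <- alpha - step
    halve <- 0
    while ((a_new <= 1e-3 || a_new > 1e3 || obj(a_new) < obj(alpha)) &&
           halve < 20) {
      step <- step / 2
      a_new <- alpha - step
      halve <- halve + 1
    }
    if (a_new <= 1e-3 || a_new > 1e3 || obj(a_new) < obj(alpha)) break
    if (abs(a_new - alpha) < 1e-8 * alpha) {
      alpha <- a_new
      break
    }
    alpha <- a_new
  }
  alpha
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("LDA topic model: k = %d, %d samples x %d taxa, alpha = %.3f\n",
              x$k, nrow(x$sample_topics), ncol(x$topic_term), x$alpha))
  cat(sprintf("  objective = %.2f after %d iterations (%s)\n",
              x$elbo_trace[length(x$elbo_trace)], length(x$elbo_trace),
              if (isTRUE(x$converged)) "converged" else "not converged"))
  tt <- top_taxa(x, n = min(5, ncol(x$topic_term)))
  for (t in seq_len(x$k))
    cat(sprintf("  topic %d: %s\n", t, paste(tt[[t]], collapse = ", ")))
  invisible(x)
}

#' Select the number of topics by the Cao density criterion
#'
#' Fits an LDA model for each k in `k_min:k_max` and scores it by the mean
#' pairwise cosine similarity between topic-term rows (the Cao 2009
#' "density" measure). The selected `k_star` minimizes the score; ties go
#' to the smaller k.
#'
#' @inheritParams fit_lda
#' @param k_min,k_max search range (the standard search is 2 to 10).
#' @param ... passed to [fit_lda()].
#' @return List with `k_star`, `scores` (data.frame of k and criterion),
#'   and `models` (the fitted models, named by k).
#' @export
select_k <- function(counts, k_min = 2, k_max = 10, seed = 1, ...) {
  if (k_min < 2 || k_max < k_min) stopf("need k_max >= k_min >= 2")
  ks <- k_min:k_max
  models <- lapply(ks, function(k) fit_lda(counts, k, seed = stage_seed(seed, k), ...))
  scores <- vapply(models, function(m) cao_score(m$topic_term), numeric(1))
  names(models) <- ks
  k_star <- ks[which.min(scores)]
  list(k_star = k_star,
       scores = data.frame(k = ks, cao = scores),
       models = models)
}

# Mean pairwise cosine similarity between topic-term rows.
cao_score <- function(beta) {
  k <- nrow(beta)
  if (k < 2) return(NA_real_)
  nb <- beta / sqrt(rowSums(beta^2))
  cs <- nb %*% t(nb)
  mean(cs[upper.tri(cs)])
}

#' Top contributing taxa per topic
#'
#' @param m a fitted `topic_model`.
#' @param n number of taxa per topic.
#' @return Named list (one character vector per topic) of the `n` taxa with
#'   highest topic-term probability, descending; ties broken
#'   lexicographically.
#' @export
top_taxa <- function(m, n = 5) {
  if (n > ncol(m$topic_term)) stopf("n exceeds the number of taxa")
  out <- lapply(seq_len(nrow(m$topic_term)), function(t) {
    p <- m$topic_term[t, ]
    ord <- order(-p, names(p))
    names(p)[ord][seq_len(n)]
  })
  names(out) <- rownames(m$topic_term)
  out
}

#' Per-sample topic (cluster) abundances
#'
#' Returns the sample-topic matrix as a composition suitable for
#' [clr_transform()], [permanova()] and plotting (each row sums to 1).
#'
#' @param m a fitted `topic_model`.
#' @return Numeric matrix, samples x topics.
#' @export
cluster_abundances <- function(m) {
  stopifnot(inherits(m, "topic_model"))
  m$sample_topics
}
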
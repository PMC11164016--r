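# Small programmatic fixtures shared across test files.

tiny_count_table <- function() {
  m <- matrix(c(5, 0, 2,
                3, 4, 0,
                0, 1, 7,
                2, 2, 2), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"),
                              c("asv1", "asv2", "asv3", "asv4")))
  tax <- data.frame(
    feature_id = c("asv1", "asv2", "asv3", "asv4"),
    genus = c("Blautia", "Blautia", NA, "Dorea"),
    family = c("Lachnospiraceae", "Lachnospiraceae", "Lachnospiraceae",
               "Lachnospiraceae"),
    stringsAsFactors = FALSE)
  count_table(m, taxonomy = tax)
}

rand_count_table <- function(n = 10, p = 20, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = runif(p, 0, max_count))[seq_len(n * p)],
              n, p, dimnames = list(sprintf("s%02d", seq_len(n)),
                                    sprintf("f%02d", seq_len(p))))
  count_table(m)
}

# Count data drawn from k topics with disjoint genus support blocks; the
# sharpest case for topic-recovery checks.
make_disjoint_topic_data <- function(n = 200, depth = 10000, genera_per_topic = 20,
                                     k = 3, seed = 1, theta_conc = 0.8) {
  set.seed(seed)
  G <- genera_per_topic * k
  gnames <- sprintf("g%03d", seq_len(G))
  topic_term <- matrix(0, k, G, dimnames = list(paste0("topic", 1:k), gnames))
  for (t in seq_len(k)) {
    block <- ((t - 1) * genera_per_topic + 1):(t * genera_per_topic)
    w <- rgamma(genera_per_topic, 1)
    topic_term[t, block] <- w / sum(w)
  }
  theta <- matrix(rgamma(n * k, theta_conc), n, k)
  theta <- theta / rowSums(theta)
  probs <- theta %*% topic_term
  counts <- t(vapply(seq_len(n), function(i) rmultinom(1, depth, probs[i, ])[, 1],
                     numeric(G)))
  dimnames(counts) <- list(sprintf("s%03d", seq_len(n)), gnames)
  list(counts = count_table(counts), topic_term = topic_term, theta = theta)
}

# Best topic-matching total-variation distance between two topic-term
# matrices (brute-force over topic permutations; k is small).
matched_tv <- function(est, truth) {
  k <- nrow(truth)
  perms <- matrix(unlist(combinat_perms(seq_len(k))), ncol = k, byrow = TRUE)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    tv <- max(vapply(seq_len(k), function(t)
      0.5 * sum(abs(est[perms[r, t], ] - truth[t, ])), numeric(1)))
    best <- min(best, tv)
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Two-batch metabolite fixture with known multiplicative batch factors.
make_batch_metab <- function(n_ref = 6, n_tgt = 5, n_anchor = 3, M = 8,
                             factors = NULL, seed = 1, zeros = 0) {
  set.seed(seed)
  if (is.null(factors)) factors <- exp(runif(M, -0.6, 0.6))
  ids_ref <- sprintf("R%02d", seq_len(n_ref))
  ids_tgt <- sprintf("T%02d", seq_len(n_tgt))
  base_ref <- matrix(rlnorm(n_ref * M, 10, 1), n_ref, M)
  base_tgt <- matrix(rlnorm(n_tgt * M, 10, 1), n_tgt, M)
  anchors <- ids_ref[seq_len(n_anchor)]
  rerun <- base_ref[seq_len(n_anchor), , drop = FALSE]
  x <- rbind(base_ref, sweep(base_tgt, 2, factors, `/`),
             sweep(rerun, 2, factors, `/`))
  rownames(x) <- c(ids_ref, ids_tgt, paste0(anchors, "_rr"))
  colnames(x) <- sprintf("M%02d", seq_len(M))
  if (zeros > 0) {
    set.seed(seed + 1)
    idx <- sample(length(x), zeros)
    x[idx] <- 0
  }
  metabolite_matrix(x, batch = rep(c("reference", "target"),
                                   c(n_ref, n_tgt + n_anchor)),
                    anchor_pairs = data.frame(reference = anchors,
                                              target = paste0(anchors, "_rr")))
}
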
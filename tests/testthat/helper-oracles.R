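# Exhaustive-enumeration oracles used to pin the inference machinery and
# the Gibbs sampler, plus small fixture builders. All fixtures are built in
# code.

# Exact distribution of the pairwise {-1,+1} observation model on a small
# graph: returns probabilities over the 2^V spin configurations, encoded as
# sum((x > 0) * 2^(0:(V-1))) + 1.
ising_exact <- function(network, weights) {
  V <- length(network$genes)
  stopifnot(V <= 15)
  cfg <- as.matrix(expand.grid(rep(list(c(-1, 1)), V)))
  i <- network$edges[, 1]
  j <- network$edges[, 2]
  logp <- (cfg[, i, drop = FALSE] * cfg[, j, drop = FALSE]) %*% weights
  p <- exp(logp - max(logp))
  p <- as.vector(p / sum(p))
  code <- as.integer((cfg > 0) %*% 2^(seq_len(V) - 1)) + 1L
  out <- numeric(2^V)
  out[code] <- p
  out
}

# Brute-force posterior over the joint (weight, category) trajectories of a
# single edge: w path in W^T, category path in H^(T-1). `logb` is a list of
# length T of 1 x W emission log-weight matrices, `alpha` a simplex over H
# categories, `Q_list` the H transition matrices. Uniform initial state.
brute_edge_posterior <- function(logb, alpha, Q_list) {
  Tn <- length(logb)
  W <- ncol(logb[[1]])
  H <- length(Q_list)
  b <- exp(vapply(seq_len(Tn), function(t) logb[[t]][1, ], numeric(W)))
  wp <- as.matrix(expand.grid(rep(list(seq_len(W)), Tn)))
  yp <- as.matrix(expand.grid(rep(list(seq_len(H)), Tn - 1L)))
  tot <- 0
  gamma <- matrix(0, Tn, W)
  xi <- array(0, c(Tn - 1L, W, W))
  cat_resp <- matrix(0, Tn - 1L, H)
  best <- -Inf
  best_path <- NULL
  for (iw in seq_len(nrow(wp))) {
    w <- wp[iw, ]
    pw <- prod(b[cbind(w, seq_len(Tn))]) / W
    # marginal over y for the viterbi criterion (max over w of sum over y)
    pmix <- pw
    for (t in seq_len(Tn - 1L))
      pmix <- pmix * sum(vapply(seq_len(H), function(h)
        alpha[h] * Q_list[[h]][w[t], w[t + 1]], numeric(1)))
    if (pmix > best) { best <- pmix; best_path <- w }
    for (iy in seq_len(nrow(yp))) {
      y <- yp[iy, ]
      p <- pw
      for (t in seq_len(Tn - 1L))
        p <- p * alpha[y[t]] * Q_list[[y[t]]][w[t], w[t + 1]]
      tot <- tot + p
      for (t in seq_len(Tn)) gamma[t, w[t]] <- gamma[t, w[t]] + p
      for (t in seq_len(Tn - 1L)) {
        xi[t, w[t], w[t + 1]] <- xi[t, w[t], w[t + 1]] + p
        cat_resp[t, y[t]] <- cat_resp[t, y[t]] + p
      }
    }
  }
  list(loglik = log(tot), gamma = gamma / tot, xi = xi / tot,
       cat_resp = cat_resp / tot, map = unname(best_path))
}

# Random row-stochastic matrix.
rand_stoch <- function(W) {
  m <- matrix(runif(W * W), W, W)
  m / rowSums(m)
}

# Random edge list (E distinct unordered pairs) on `V` labelled nodes.
rand_edges <- function(V, E) {
  genes <- sprintf("n%04d", seq_len(V))
  ut <- which(upper.tri(matrix(FALSE, V, V)))
  pr <- arrayInd(ut[sample(length(ut), E)], c(V, V))
  cbind(genes[pr[, 1]], genes[pr[, 2]])
}

# Total variation distance between two probability vectors.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
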
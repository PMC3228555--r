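# Vectorized inference engine. All per-edge W-state chains are processed in
# parallel: emissions are stored as a list over time of E x W matrices and
# each edge's transition matrix as a row of an E x W^2 matrix, flattened
# row-major (Q[i,j] -> column (i-1)*W + j).

# Emission log-weights from multi-strain expression data.
#
# For edge e = (i,j), strain s and time t the pairwise factor for state w is
# exp(Gamma_e^s * w * x_i^s(t) * x_j^s(t)), normalized over the W states
# within each strain (per-edge pseudo-likelihood; the global Ising
# normalizer is intractable and edge-coupled). Strains are conditionally
# independent given the shared trajectory, so their normalized factors
# multiply, i.e. log-weights add.
build_emissions <- function(network, dataset, gamma_edge, states) {
  E <- nrow(network$edges)
  Tn <- dataset$T
  i <- network$edges[, 1]
  j <- network$edges[, 2]
  cc <- matrix(0, E, Tn)
  lZ <- matrix(0, E, Tn)
  for (s in seq_along(dataset$strains)) {
    xs <- dataset$x[[s]]
    xx <- xs[i, , drop = FALSE] * xs[j, , drop = FALSE]
    a <- gamma_edge[, s] * xx
    cc <- cc + a
    lZ <- lZ + logsumexp_states(a, states)
  }
  lapply(seq_len(Tn), function(t) outer(cc[, t], states) - lZ[, t])
}

# Scaled forward-backward over all edges at once.
# Returns smoothed marginals, summed (and optionally per-step) pairwise
# joints, and the per-edge log-evidence under the pseudo-likelihood
# emissions.
fb_engine <- function(logb, QeFlat, W, want_xi = FALSE) {
  Tn <- length(logb)
  E <- nrow(QeFlat)
  if (Tn < 2L) stop("T must be >= 2")
  col_i <- rep(seq_len(W), each = W)   # state i of flat column k
  col_j <- rep(seq_len(W), times = W)  # state j of flat column k

  A <- vector("list", Tn)
  Bs <- vector("list", Tn)
  Ms <- vector("list", Tn)
  ll <- numeric(E)
  for (t in seq_len(Tn)) {
    Ms[[t]] <- row_max(logb[[t]])
    Bs[[t]] <- exp(logb[[t]] - Ms[[t]])
    if (any(rowSums(Bs[[t]]) == 0)) stop("degenerate emission")
  }
  u <- Bs[[1]] / W
  c1 <- rowSums(u)
  A[[1]] <- u / c1
  ll <- log(c1) + Ms[[1]]
  for (t in 2:Tn) {
    a <- A[[t - 1]]
    pred <- vapply(seq_len(W), function(jj)
      rowSums(a * QeFlat[, (seq_len(W) - 1L) * W + jj, drop = FALSE]),
      numeric(E))
    if (E == 1L) pred <- matrix(pred, nrow = 1)
    u <- pred * Bs[[t]]
    ct <- rowSums(u)
    if (any(ct == 0)) stop("degenerate emission")
    A[[t]] <- u / ct
    ll <- ll + log(ct) + Ms[[t]]
  }

  XiSum <- matrix(0, E, W * W)
  gamma <- vector("list", Tn)
  xi <- if (want_xi) vector("list", Tn - 1L) else NULL
  beta <- matrix(1, E, W)
  gamma[[Tn]] <- A[[Tn]]
  for (t in (Tn - 1L):1L) {
    w_next <- Bs[[t + 1]] * beta
    Xi <- QeFlat * A[[t]][, col_i, drop = FALSE] *
      w_next[, col_j, drop = FALSE]
    Xi <- Xi / rowSums(Xi)
    XiSum <- XiSum + Xi
    if (want_xi) xi[[t]] <- Xi
    gamma[[t]] <- vapply(seq_len(W), function(ii)
      rowSums(Xi[, (ii - 1L) * W + seq_len(W), drop = FALSE]), numeric(E))
    if (E == 1L) gamma[[t]] <- matrix(gamma[[t]], nrow = 1)
    bnew <- vapply(seq_len(W), function(ii)
      rowSums(QeFlat[, (ii - 1L) * W + seq_len(W), drop = FALSE] * w_next),
      numeric(E))
    if (E == 1L) bnew <- matrix(bnew, nrow = 1)
    beta <- bnew / row_max(bnew)
  }
  list(gamma = gamma, XiSum = XiSum, xi = xi, loglik = ll)
}

# Max-product (Viterbi) decoding over all edges at once. Ties are broken
# toward the state closest to 0, then toward the lower state index.
viterbi_engine <- function(logb, QeFlat, states) {
  W <- length(states)
  Tn <- length(logb)
  E <- nrow(QeFlat)
  pref <- order(abs(states), seq_along(states))
  lQ <- suppressWarnings(log(QeFlat))

  argmax_pref <- function(m) {
    mp <- m[, pref, drop = FALSE]
    mc <- max.col(mp, ties.method = "first")
    list(arg = pref[mc], val = mp[cbind(seq_len(nrow(m)), mc)])
  }

  d <- logb[[1]] - log(W)
  psi <- vector("list", Tn)
  for (t in 2:Tn) {
    val <- matrix(0, E, W)
    arg <- matrix(0L, E, W)
    for (jj in seq_len(W)) {
      cand <- d + lQ[, (seq_len(W) - 1L) * W + jj, drop = FALSE]
      am <- argmax_pref(cand)
      arg[, jj] <- am$arg
      val[, jj] <- am$val
    }
    d <- val + logb[[t]]
    psi[[t]] <- arg
  }
  path <- matrix(0L, E, Tn)
  am <- argmax_pref(d)
  path[, Tn] <- am$arg
  if (Tn >= 2L) for (t in (Tn - 1L):1L)
    path[, t] <- psi[[t + 1]][cbind(seq_len(E), path[, t + 1])]
  path
}

# MAP M-step with pseudo-count (posterior-mean style) Dirichlet updates:
# category transition rows get expected transition counts plus theta,
# per-edge mixtures get expected category usage plus their prior weight.
# Well-defined at lambda_o = 0 and support-preserving.
m_step_engine <- function(XiSum, QeFlat, QhFlat, alpha, pair_edge, pair_cat,
                          pair_lambda, theta_flat, W) {
  Hc <- nrow(QhFlat)
  ratio <- alpha * QhFlat[pair_cat, , drop = FALSE] /
    QeFlat[pair_edge, , drop = FALSE]
  contrib <- ratio * XiSum[pair_edge, , drop = FALSE]

  counts <- matrix(0, Hc, W * W)
  cs <- rowsum(contrib, pair_cat, reorder = TRUE)
  counts[as.integer(rownames(cs)), ] <- cs

  Qh_new <- counts + theta_flat
  for (ii in seq_len(W)) {
    block <- (ii - 1L) * W + seq_len(W)
    rs <- rowSums(Qh_new[, block, drop = FALSE])
    if (any(rs <= 0)) stop("unidentifiable row")
    Qh_new[, block] <- Qh_new[, block, drop = FALSE] / rs
  }

  usage <- rowSums(contrib)
  num <- usage + pair_lambda
  den <- as.vector(rowsum(num, pair_edge, reorder = TRUE))
  alpha_new <- num / den[pair_edge]
  Qe_new <- rowsum(alpha_new * Qh_new[pair_cat, , drop = FALSE], pair_edge,
                   reorder = TRUE)
  list(QhFlat = Qh_new, alpha = alpha_new, QeFlat = Qe_new)
}

# Penalized surrogate objective: data log-evidence plus the Dirichlet
# pseudo-count prior terms. Non-decreasing across EM iterations.
em_objective <- function(loglik, QhFlat, alpha, pair_lambda, theta_flat) {
  at <- ifelse(pair_lambda > 0, pair_lambda * log(alpha), 0)
  sum(loglik) + sum(theta_flat * log(QhFlat)) + sum(at)
}

flat_to_mat <- function(row, W, states) {
  m <- matrix(row, W, W, byrow = TRUE)
  dimnames(m) <- list(states, states)
  m
}

mat_to_flat <- function(m) as.vector(t(m))
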
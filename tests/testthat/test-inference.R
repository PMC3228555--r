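test_that("effective transition mixtures are exact convex combinations", {
  expect_equal(effective_transition(1, list(diag(3))), diag(3))
  got <- effective_transition(c(0.5, 0.5),
                              list(diag(2), matrix(0.5, 2, 2)))
  expect_equal(got, matrix(c(0.75, 0.25, 0.25, 0.75), 2))
  set.seed(51)
  Qs <- replicate(3, rand_stoch(4), simplify = FALSE)
  a <- c(0.2, 0.3, 0.5)
  expect_equal(rowSums(effective_transition(a, Qs)), rep(1, 4),
               tolerance = 1e-12)
  expect_error(effective_transition(c(0.5, 0.2), list(diag(2), diag(2))),
               "sum to 1")
})

test_that("emission log-weights respect zero-state, damping and sign symmetry", {
  states <- -2:2
  net <- build_network(rbind(c("a", "b")))
  x <- matrix(c(1, -1, 1, 1), 2, 2, dimnames = list(c("a", "b"), NULL))
  ds <- netgem_expression(list(s = x))
  logb <- netgem:::build_emissions(net, ds, matrix(1, 1, 1), states)
  # x_a x_b = -1 at t=1, +1 at t=2; uncorrelated state always at the
  # normalizer level, sign-symmetric pairs around it
  for (t in 1:2) {
    lb <- logb[[t]][1, ]
    expect_equal(lb[3] - lb[1], -(lb[3] - lb[5]))  # w = 0 midpoint
    expect_equal(abs(lb[5] - lb[1]), 4)            # +/-2 differ by 4|xx|
  }
  expect_gt(logb[[2]][1, 5], logb[[2]][1, 1])      # aligned obs favours +2
  expect_lt(logb[[1]][1, 5], logb[[1]][1, 1])
  # full damping: flat emission over states
  logb0 <- netgem:::build_emissions(net, ds, matrix(0, 1, 1), states)
  expect_true(all(abs(diff(logb0[[1]][1, ])) < 1e-12))
})

test_that("a fully damped edge falls back to its Markov prior", {
  set.seed(52)
  W <- 3
  states <- c(-1, 0, 1)
  Q <- rand_stoch(W)
  logb <- lapply(1:4, function(t) matrix(0, 1, W))  # flat emissions
  es <- netgem:::fb_engine(logb, matrix(as.vector(t(Q)), 1), W)
  # smoothed marginals equal the prior chain marginals from uniform init
  m <- rep(1 / W, W)
  for (t in 1:4) {
    expect_equal(es$gamma[[t]][1, ], m, tolerance = 1e-12)
    m <- as.vector(m %*% Q)
  }
})

test_that("forward-backward matches exhaustive enumeration on random instances", {
  set.seed(53)
  for (rep in 1:8) {
    W <- sample(2:3, 1); H <- 2; Tn <- sample(3:4, 1)
    Qs <- replicate(H, rand_stoch(W), simplify = FALSE)
    al <- as.vector(netgem:::rdirichlet1(rep(1, H)))
    logb <- lapply(seq_len(Tn), function(t) matrix(rnorm(W), 1, W))
    Qe <- Reduce(`+`, Map(`*`, al, Qs))
    es <- netgem:::fb_engine(logb, matrix(as.vector(t(Qe)), 1), W,
                             want_xi = TRUE)
    oracle <- brute_edge_posterior(logb, al, Qs)
    expect_equal(es$loglik, oracle$loglik, tolerance = 1e-10)
    for (t in seq_len(Tn))
      expect_equal(es$gamma[[t]][1, ], oracle$gamma[t, ],
                   tolerance = 1e-10)
    for (t in seq_len(Tn - 1L))
      expect_equal(matrix(es$xi[[t]][1, ], W, W, byrow = TRUE),
                   oracle$xi[t, , ], tolerance = 1e-10)
  }
})

test_that("viterbi decoding matches exhaustive path maximization and tie-breaks", {
  set.seed(54)
  states3 <- c(-1, 0, 1)
  for (rep in 1:8) {
    W <- 3; Tn <- 4
    Qe <- rand_stoch(W)
    logb <- lapply(seq_len(Tn), function(t) matrix(rnorm(W), 1, W))
    path <- netgem:::viterbi_engine(logb, matrix(as.vector(t(Qe)), 1),
                                    states3)[1, ]
    oracle <- brute_edge_posterior(logb, 1, list(Qe))
    expect_equal(path, oracle$map)
  }
  # exact ties: identity chain with flat emissions decodes to the state
  # closest to zero
  logb <- lapply(1:3, function(t) matrix(0, 1, 5))
  path <- netgem:::viterbi_engine(logb, matrix(as.vector(t(diag(5))), 1),
                                  -2:2)[1, ]
  expect_equal((-2:2)[path], rep(0, 3))
  # uniform transitions + strong emissions reduce to per-time argmax
  set.seed(55)
  lb <- lapply(1:4, function(t) matrix(10 * rnorm(5), 1, 5))
  path <- netgem:::viterbi_engine(lb, matrix(0.2, 1, 25), -2:2)[1, ]
  expect_equal(path, vapply(lb, which.max, integer(1)))
})

test_that("category responsibilities match the joint-trajectory posterior", {
  set.seed(56)
  b <- generate_benchmark(n_genes = 8, n_edges = 10, n_categories = 2,
                          T = 4, gibbs_sweeps = 5)
  fit <- netgem(b$data, b$network, b$annotation, seed = 1, max_iter = 5)
  for (e in c(1L, 5L)) {
    post <- edge_posterior(fit, e)
    sel <- fit$pairs$edge == e
    al <- fit$alpha$weight[sel]
    Qs <- fit$Q[fit$pairs$cat[sel]]
    logb1 <- lapply(fit$emissions, function(m) m[e, , drop = FALSE])
    oracle <- brute_edge_posterior(logb1, al, Qs)
    expect_equal(unname(post$loglik), oracle$loglik, tolerance = 1e-10)
    expect_equal(unname(post$gamma), oracle$gamma, tolerance = 1e-10)
    expect_equal(unname(post$cat_resp),
                 oracle$cat_resp / rowSums(oracle$cat_resp),
                 tolerance = 1e-10)
    expect_equal(post$map, fit$states[oracle$map])
  }
  # single-category support: responsibility identically 1
  b1 <- generate_benchmark(n_genes = 6, n_edges = 8, n_categories = 1,
                           T = 3, gibbs_sweeps = 3)
  f1 <- netgem(b1$data, b1$network, b1$annotation, seed = 1, max_iter = 3)
  p1 <- edge_posterior(f1, 1)
  expect_true(all(abs(p1$cat_resp - 1) < 1e-12))
})

test_that("m-step reduces to the prior with no data and preserves support", {
  W <- 3
  XiSum <- matrix(0, 2, W * W)
  QeF <- matrix(1 / W, 2, W * W)
  QhF <- matrix(1 / W, 2, W * W)
  theta <- matrix(c(1, 2, 3, 2, 2, 2, 3, 2, 1), 2, W * W, byrow = TRUE)
  ms <- netgem:::m_step_engine(XiSum, QeF, QhF, alpha = c(1, 1),
                               pair_edge = c(1L, 2L), pair_cat = c(1L, 2L),
                               pair_lambda = c(1, 1), theta_flat = theta,
                               W = W)
  for (h in 1:2) for (i in 1:W) {
    blk <- (i - 1) * W + 1:W
    expect_equal(ms$QhFlat[h, blk], theta[h, blk] / sum(theta[h, blk]))
  }
  expect_equal(ms$alpha, c(1, 1))
})

test_that("m-step is consistent on large simulated transition counts", {
  set.seed(57)
  W <- 4
  Q <- rand_stoch(W)
  n <- 200000
  counts <- matrix(0, W, W)
  for (i in seq_len(W)) counts[i, ] <- drop(stats::rmultinom(1, n, Q[i, ]))
  XiSum <- matrix(as.vector(t(counts)), 1)
  QeF <- matrix(as.vector(t(Q)), 1)
  ms <- netgem:::m_step_engine(XiSum, QeF, QeF, alpha = 1, pair_edge = 1L,
                               pair_cat = 1L, pair_lambda = 1,
                               theta_flat = matrix(0.5, 1, W * W), W = W)
  Qhat <- matrix(ms$QhFlat[1, ], W, W, byrow = TRUE)
  expect_lt(max(abs(Qhat - Q)), 5 / sqrt(n))
})

test_that("EM converges monotonically, deterministically, and stops early at tol = Inf", {
  set.seed(58)
  b <- generate_benchmark(n_genes = 12, n_edges = 20, n_categories = 3,
                          T = 5, gibbs_sweeps = 5)
  f1 <- netgem(b$data, b$network, b$annotation, seed = 3)
  expect_true(all(diff(f1$objective) >= -1e-8 * (abs(f1$objective[-1]) + 1)))
  f2 <- netgem(b$data, b$network, b$annotation, seed = 3)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$trajectories, f2$trajectories)
  expect_identical(f1$objective, f2$objective)
  f3 <- netgem(b$data, b$network, b$annotation, seed = 3, tol = Inf)
  expect_equal(f3$n_iter, 1L)
  for (Q in f3$Q) expect_equal(unname(rowSums(Q)), rep(1, 5), tolerance = 1e-10)
  al <- tapply(f3$alpha$weight, f3$alpha$edge, sum)
  expect_true(all(abs(al - 1) < 1e-10))
})

test_that("fitting without annotation uses one shared background category", {
  set.seed(59)
  b <- generate_benchmark(n_genes = 10, n_edges = 14, n_categories = 2,
                          T = 4, gibbs_sweeps = 5)
  fit <- netgem(b$data, b$network, annotation = NULL, seed = 1,
                max_iter = 10)
  expect_equal(names(fit$Q), ".background")
  expect_true(all(fit$alpha$weight == 1))
})

test_that("edges lacking expression are dropped with a message", {
  set.seed(60)
  b <- generate_benchmark(n_genes = 10, n_edges = 14, n_categories = 2,
                          T = 4, gibbs_sweeps = 5)
  x <- b$data$x[[1]]
  x <- x[-1, , drop = FALSE]  # drop one gene
  expect_message(
    fit <- netgem(list(s = x), b$network, b$annotation, seed = 1,
                  max_iter = 3),
    "dropping")
  expect_lt(nrow(fit$trajectories), 14L)
})

test_that("strong uniform transition priors dominate the recovered dynamics", {
  set.seed(61)
  b <- generate_benchmark(n_genes = 10, n_edges = 14, n_categories = 2,
                          T = 4, gibbs_sweeps = 5)
  fit <- netgem(b$data, b$network, b$annotation, seed = 1, theta = 1e6,
                max_iter = 20)
  for (Q in fit$Q) expect_lt(max(abs(Q - 0.2)), 1e-3)
})
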
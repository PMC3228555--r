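test_that("trace-class transition matrices satisfy their class constraint", {
  set.seed(41)
  W <- 5
  for (k in 1:25) {
    Q0 <- sample_transition_matrix(W, "H0")
    Q1 <- sample_transition_matrix(W, "H1")
    expect_equal(rowSums(Q0), rep(1, W), tolerance = 1e-12)
    expect_equal(rowSums(Q1), rep(1, W), tolerance = 1e-12)
    expect_gt(sum(diag(Q0)), 0.5 * W)
    expect_lte(sum(diag(Q1)), 0.5 * W)
  }
  # the identity matrix is the extreme H0 member: trace = W
  expect_equal(trace_test(diag(W)), "H0")
  expect_error(sample_transition_matrix(1, "H0"), "W must be")
})

test_that("category assignment follows the membership-size histogram", {
  set.seed(42)
  a1 <- assign_categories(50, 1)
  expect_true(all(lengths(a1$membership) == 1L))
  a2 <- assign_categories(100, 200, size_dist = c(`2` = 1))
  expect_true(all(lengths(a2$membership) == 2L))
  # law of large numbers on the default histogram
  a3 <- assign_categories(4000, 200)
  m <- mean(lengths(a3$membership))
  mu <- sum(1:4 * c(0.5, 0.3, 0.15, 0.05))
  expect_lt(abs(m - mu), 3 * sqrt(0.8) / sqrt(4000))
  # k clipped to H
  a4 <- assign_categories(30, 2, size_dist = c(`4` = 1))
  expect_true(all(lengths(a4$membership) == 2L))
})

test_that("weight trajectories follow their Markov law", {
  set.seed(43)
  W <- 5
  # absorbing identity chain: constant at the start state
  tr <- simulate_weight_trajectories(diag(W), T = 10, n_edges = 50)
  expect_true(all(tr == tr[, 1]))
  # uniform chain: long-run occupancy ~ 1/W
  tr2 <- simulate_weight_trajectories(matrix(1 / W, W, W), T = 2000,
                                      n_edges = 1)
  freq <- table(factor(tr2, levels = -2:2)) / length(tr2)
  expect_true(all(abs(freq - 0.2) < 0.035))
  expect_error(simulate_weight_trajectories(diag(W), T = 1), "T must be")
})

test_that("field-free Gibbs spins are fair and independent", {
  set.seed(44)
  net <- build_network(rbind(c("a", "b"), c("b", "c")))
  s <- gibbs_expression(net, c(0, 0), n_sweeps = 5, n_keep = 20000)
  expect_true(all(abs(colMeans(s)) < 0.025))
  expect_lt(abs(cor(s[, 1], s[, 2])), 0.025)
})

test_that("two-spin Gibbs matches the exact partition function", {
  set.seed(45)
  net <- build_network(rbind(c("a", "b")))
  s <- gibbs_expression(net, 2, n_sweeps = 10, n_keep = 50000)
  expect_lt(abs(mean(s[, 1] == s[, 2]) - exp(2) / (exp(2) + exp(-2))),
            0.005)
})

test_that("small-graph Gibbs distribution matches exact enumeration", {
  set.seed(46)
  net <- build_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                             c("d", "a")))
  w <- rep(1, 4)
  ex <- ising_exact(net, w)
  smp <- gibbs_expression(net, w, n_sweeps = 50, n_keep = 60000, thin = 2)
  enc <- as.integer((smp > 0) %*% 2^(0:3)) + 1L
  emp <- tabulate(enc, 16) / nrow(smp)
  expect_lt(tv_dist(emp, ex), 0.02)
})

test_that("gibbs sampling is deterministic under a seed", {
  net <- build_network(rbind(c("a", "b"), c("b", "c")))
  set.seed(7); s1 <- gibbs_expression(net, c(1, -1), n_keep = 10)
  set.seed(7); s2 <- gibbs_expression(net, c(1, -1), n_keep = 10)
  expect_identical(s1, s2)
})

test_that("generate_benchmark produces a structurally valid miniature", {
  set.seed(47)
  b <- generate_benchmark(n_genes = 10, n_edges = 15, n_categories = 3,
                          T = 4)
  expect_s3_class(b$network, "netgem_network")
  expect_equal(nrow(b$network$edges), 15L)
  expect_equal(b$data$T, 4L)
  expect_true(all(unlist(b$data$x) %in% c(-1, 1)))
  for (Q in b$truth$Q_h)
    expect_equal(rowSums(Q), rep(1, 5), tolerance = 1e-12)
  # trace classes hold for every sampled matrix
  for (h in names(b$truth$Q_h)) {
    tr <- sum(diag(b$truth$Q_h[[h]]))
    if (b$truth$category_class[h] == "H0") expect_gt(tr, 2.5)
    else expect_lte(tr, 2.5)
  }
  # alpha rows are simplices over candidate categories
  al <- b$truth$alpha
  sums <- tapply(al$weight, al$edge, sum)
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_true(all(b$truth$trajectories %in% -2:2))
  expect_error(generate_benchmark(n_genes = 5, n_edges = 100),
               "more edges")
})

test_that("benchmark generation is bit-identical under a seed", {
  set.seed(9); b1 <- generate_benchmark(n_genes = 12, n_edges = 18,
                                        n_categories = 3, T = 3,
                                        gibbs_sweeps = 5)
  set.seed(9); b2 <- generate_benchmark(n_genes = 12, n_edges = 18,
                                        n_categories = 3, T = 3,
                                        gibbs_sweeps = 5)
  expect_identical(b1$data$x, b2$data$x)
  expect_identical(b1$truth$trajectories, b2$truth$trajectories)
  expect_identical(b1$truth$Q_h, b2$truth$Q_h)
})

test_that("the independent-edge benchmark model samples classes evenly", {
  set.seed(48)
  b <- generate_benchmark(n_genes = 40, n_edges = 200, n_categories = 4,
                          T = 3, model = "independent", gibbs_sweeps = 5)
  expect_null(b$truth$alpha)
  frac <- mean(b$truth$edge_class == "H1")
  expect_gt(frac, 0.35); expect_lt(frac, 0.65)
})

test_that("the full generative process honours supports, damping and strains", {
  set.seed(49)
  net <- build_network(rand_edges(12, 20))
  annot <- assign_categories(net$genes, 4)
  sim <- sample_generative_process(
    net, annot, T = 4,
    knockouts = list(reference = character(0), mut = net$genes[1]),
    gibbs_sweeps = 5)
  expect_equal(sim$data$strains, c("reference", "mut"))
  # lambda_o = 0: alpha supported only on candidate categories
  for (r in seq_len(nrow(sim$truth$alpha))) {
    e <- match(sim$truth$alpha$edge[r], net$edge_names)
    expect_true(sim$truth$alpha$category[r] %in%
                edge_candidate_categories(net, annot, e))
  }
  # knockout-incident edges are fully damped in the mutant
  inc <- net$edges[, 1] == 1L | net$edges[, 2] == 1L
  expect_true(all(sim$damping$edge[inc, "mut"] == 0))
  expect_true(all(sim$damping$edge[, "reference"] == 1))
  # category trajectories come from the candidate sets
  expect_true(all(sim$truth$category_traj %in% annot$categories))
  expect_warning(
    sample_generative_process(net, annot, T = 3,
                              knockouts = list(a = character(0),
                                               b = character(0)),
                              gibbs_sweeps = 2),
    "no knockouts")
})
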
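#' Sample a transition matrix from a trace class
#'
#' Draws a W x W row-stochastic matrix conditioned on its trace class:
#' `H0` (sluggish dynamics, `tr(Q) > 0.5 W`) or `H1` (significant dynamics,
#' `tr(Q) <= 0.5 W`). Rows are drawn from a symmetric Dirichlet; for `H0`
#' each row is additionally mixed toward the corresponding identity row
#' with a mixing weight drawn from U(0.5, 1), which concentrates diagonal
#' mass so the rejection step terminates quickly. The returned matrix
#' satisfies the class inequality exactly.
#'
#' @param W number of states (>= 2).
#' @param class `"H0"` or `"H1"`.
#' @param concentration symmetric Dirichlet concentration (> 0).
#' @return W x W row-stochastic matrix.
#' @export
sample_transition_matrix <- function(W, class = c("H0", "H1"),
                                     concentration = 1) {
  class <- match.arg(class)
  if (W < 2L) stop("W must be >= 2")
  for (try in seq_len(10000L)) {
    Q <- rdirichlet_rows(matrix(concentration, W, W))
    if (class == "H0") {
      m <- runif(1, 0.5, 1)
      Q <- m * diag(W) + (1 - m) * Q
    }
    tr <- sum(diag(Q))
    ok <- if (class == "H0") tr > 0.5 * W else tr <= 0.5 * W
    if (ok) return(Q)
  }
  stop("class sampling failed")
}

#' Randomly assign genes to functional categories
#'
#' Each gene receives `k` categories sampled uniformly without replacement,
#' with `k` drawn from a histogram over membership counts. The default
#' histogram (50% of genes in 1 category, 30% in 2, 15% in 3, 5% in 4) is a
#' stand-in for the empirical membership-size distribution of yeast FunCat
#' annotations and is fully configurable.
#'
#' @param genes character vector of gene ids, or a gene count.
#' @param categories character vector of category ids, or a count H.
#' @param size_dist named numeric vector: membership size -> probability.
#' @return a `netgem_annotation` covering every gene.
#' @export
assign_categories <- function(genes, categories,
                              size_dist = c(`1` = 0.5, `2` = 0.3,
                                            `3` = 0.15, `4` = 0.05)) {
  if (is.numeric(genes)) genes <- sprintf("g%04d", seq_len(genes))
  if (is.numeric(categories)) categories <- sprintf("C%03d", seq_len(categories))
  H <- length(categories)
  sizes <- as.integer(names(size_dist))
  if (any(is.na(sizes)) || any(sizes < 1L)) stop("invalid membership sizes")
  k <- sizes[sample.int(length(sizes), length(genes), replace = TRUE,
                        prob = size_dist / sum(size_dist))]
  k <- pmin(k, H)
  membership <- lapply(k, function(ki) sample.int(H, ki))
  names(membership) <- genes
  structure(list(categories = categories,
                 membership = membership),
            class = "netgem_annotation")
}

#' Simulate discrete weight trajectories from Markov chains
#'
#' Each edge's interaction strength starts uniformly at random over the
#' state set and then follows its own transition matrix.
#'
#' @param Q a single W x W matrix (shared by all edges), a list of such
#'   matrices, or an E x W^2 row-flattened matrix (rows
#'   `Q[i,j] -> column (i-1)*W+j`).
#' @param T number of time points (>= 2).
#' @param states weight state set (default `-2:2`).
#' @param n_edges number of trajectories when `Q` is a single matrix.
#' @return E x T matrix of state values.
#' @export
simulate_weight_trajectories <- function(Q, T, states = -2:2, n_edges = NULL) {
  states <- weight_states(states)
  W <- length(states)
  if (T < 2L) stop("T must be >= 2")
  if (is.list(Q)) Q <- do.call(rbind, lapply(Q, function(q) as.vector(t(q))))
  else if (is.matrix(Q) && nrow(Q) == W && ncol(Q) == W) {
    E <- n_edges %||% 1L
    Q <- matrix(rep(as.vector(t(Q)), each = E), nrow = E)
  }
  if (ncol(Q) != W * W) stop("Q has wrong dimension for the state space")
  E <- nrow(Q)
  idx <- matrix(0L, E, T)
  idx[, 1] <- sample.int(W, E, replace = TRUE)
  for (t in 2:T) {
    off <- (idx[, t - 1] - 1L) * W
    P <- vapply(seq_len(W),
                function(j) Q[cbind(seq_len(E), off + j)], numeric(E))
    if (E == 1L) P <- matrix(P, nrow = 1)
    idx[, t] <- sample_rows(P)
  }
  matrix(states[idx], E, T)
}

# Internal: compressed adjacency (0-based) for the C++ Gibbs sweep.
csr_adjacency <- function(network) {
  deg <- network$degree
  ptr <- c(0L, cumsum(deg))
  nbr <- unlist(network$adj, use.names = FALSE) - 1L
  eid <- unlist(network$adj_edge, use.names = FALSE)
  list(ptr = as.integer(ptr), nbr = as.integer(nbr), eid = as.integer(eid))
}

#' Gibbs-sample node observations from the pairwise observation model
#'
#' Draws node values in `{-1,+1}` from
#' `p(x | w) = exp(sum_e w_e x_i x_j) / Z` by single-site Gibbs sampling
#' (fixed sweep order, conditional
#' `p(x_i = +1 | rest) = 1/(1+exp(-2 sum_j w_ij x_j))`), which sidesteps the
#' intractable normalization constant Z.
#'
#' @param network a `netgem_network`.
#' @param weights numeric edge weights (possibly damped, real-valued), in
#'   edge order.
#' @param n_sweeps burn-in sweeps before the sample is taken (>= 1).
#' @param n_keep number of samples to return.
#' @param thin sweeps between kept samples.
#' @param init optional initial spin vector in `{-1,+1}`.
#' @return if `n_keep == 1` (default) a named spin vector, else an
#'   `n_keep` x V spin matrix.
#' @export
gibbs_expression <- function(network, weights, n_sweeps = 50L,
                             n_keep = 1L, thin = 1L, init = NULL) {
  if (length(weights) != nrow(network$edges))
    stop("need one weight per edge")
  if (n_sweeps < 1L) stop("n_sweeps must be >= 1")
  adj <- csr_adjacency(network)
  V <- length(network$genes)
  if (is.null(init))
    init <- sample(c(-1L, 1L), V, replace = TRUE)
  out <- ising_gibbs_chain(adj$ptr, adj$nbr, as.numeric(weights)[adj$eid],
                           as.integer(init), as.integer(n_sweeps),
                           as.integer(n_keep), as.integer(thin))
  colnames(out) <- network$genes
  if (n_keep == 1L) out[1, ] else out
}

#' Generate the synthetic evaluation benchmark
#'
#' Builds an Erdos-Renyi graph, assigns genes to functional categories,
#' samples category transition matrices half/half from the two trace
#' classes, simulates edge-weight trajectories and draws `{-1,+1}` node
#' observations from the pairwise observation model by Gibbs sampling.
#' The defaults are the benchmark scale: 1000 genes, 5961 edges, 200
#' categories, 5 weight states, 8 time points.
#'
#' Under `model = "category"` each edge's transition matrix is the convex
#' mixture `Q_e = sum_h alpha_eh Q_h` over its candidate categories, with
#' `alpha_e` drawn from the uniform Dirichlet on the candidate set; under
#' `model = "independent"` each edge's `Q_e` is sampled directly from the
#' two classes with equal probability.
#'
#' @param n_genes,n_edges,n_categories,T benchmark dimensions.
#' @param states weight state set.
#' @param model `"category"` or `"independent"`.
#' @param size_dist membership-size histogram (see [assign_categories()]).
#' @param concentration Dirichlet concentration for class sampling.
#' @param gibbs_sweeps burn-in sweeps per time point.
#' @return list of class `netgem_benchmark` with `network`, `annotation`,
#'   `truth` and `data` (`netgem_expression`). `truth` holds the category
#'   matrices `Q_h` (list), their classes `category_class`, the per-edge
#'   mixtures `alpha` (long data frame), true trajectories (E x T),
#'   `edge_trace` (trace of each true `Q_e`) and `edge_class`.
#' @export
generate_benchmark <- function(n_genes = 1000L, n_edges = 5961L,
                               n_categories = 200L, states = -2:2, T = 8L,
                               model = c("category", "independent"),
                               size_dist = c(`1` = 0.5, `2` = 0.3,
                                             `3` = 0.15, `4` = 0.05),
                               concentration = 1, gibbs_sweeps = 50L) {
  model <- match.arg(model)
  states <- weight_states(states)
  W <- length(states)
  if (n_edges > n_genes * (n_genes - 1) / 2)
    stop("more edges than a simple graph on n_genes nodes admits")

  genes <- sprintf("g%04d", seq_len(n_genes))
  # G(n, m): n_edges distinct unordered pairs, uniformly
  npairs <- n_genes * (n_genes - 1) / 2
  pick <- sample(npairs, n_edges)
  ut <- which(upper.tri(matrix(FALSE, n_genes, n_genes)))
  pr <- arrayInd(ut[pick], c(n_genes, n_genes))
  network <- build_network(cbind(genes[pr[, 1]], genes[pr[, 2]]))
  E <- nrow(network$edges)

  annot <- assign_categories(network$genes, n_categories, size_dist)
  H <- n_categories

  cls_h <- sample(rep(c("H0", "H1"), length.out = H))
  Qh <- lapply(cls_h, function(cl)
    sample_transition_matrix(W, cl, concentration))
  names(Qh) <- annot$categories

  ec <- edge_candidates_all(network, annot)
  if (ec$has_background) {  # all genes are annotated by construction
    stop("internal error: unannotated genes in benchmark")
  }
  QhFlat <- do.call(rbind, lapply(Qh, function(q) as.vector(t(q))))

  if (model == "category") {
    pair_edge <- rep.int(seq_len(E), lengths(ec$cand))
    pair_cat <- unlist(ec$cand, use.names = FALSE)
    alpha <- unlist(lapply(lengths(ec$cand),
                           function(k) rdirichlet1(rep(1, k))), use.names = FALSE)
    QeFlat <- rowsum(alpha * QhFlat[pair_cat, , drop = FALSE],
                     pair_edge, reorder = TRUE)
    alpha_df <- data.frame(edge = network$edge_names[pair_edge],
                           category = ec$categories[pair_cat],
                           weight = alpha, stringsAsFactors = FALSE)
  } else {
    cls_e <- sample(c("H0", "H1"), E, replace = TRUE)
    QeFlat <- do.call(rbind, lapply(cls_e, function(cl)
      as.vector(t(sample_transition_matrix(W, cl, concentration)))))
    alpha_df <- NULL
  }
  edge_trace <- rowSums(QeFlat[, (seq_len(W) - 1L) * W + seq_len(W),
                               drop = FALSE])
  edge_class <- ifelse(edge_trace <= 0.5 * W, "H1", "H0")

  traj <- simulate_weight_trajectories(QeFlat, T, states)
  rownames(traj) <- network$edge_names

  x <- matrix(0, length(network$genes), T,
              dimnames = list(network$genes, paste0("t", seq_len(T))))
  for (t in seq_len(T))
    x[, t] <- gibbs_expression(network, traj[, t], n_sweeps = gibbs_sweeps)

  structure(list(
    network = network, annotation = annot,
    truth = list(Q_h = Qh, category_class = stats::setNames(cls_h, annot$categories),
                 alpha = alpha_df, trajectories = traj,
                 edge_trace = edge_trace,
                 edge_class = stats::setNames(edge_class, network$edge_names),
                 model = model, states = states),
    data = netgem_expression(list(reference = x))
  ), class = "netgem_benchmark")
}

#' @export
print.netgem_benchmark <- function(x, ...) {
  cat("Synthetic benchmark (", x$truth$model, " model): ",
      length(x$network$genes), " genes, ", nrow(x$network$edges), " edges, ",
      length(x$annotation$categories), " categories, T = ", x$data$T,
      "\n", sep = "")
  invisible(x)
}

#' Run the full generative process (multi-strain, with damping)
#'
#' Executes the model's generative process end to end: category transition
#' matrices are drawn from their Dirichlet priors (or supplied), per-edge
#' mixing proportions from the candidate-set Dirichlet prior, a functional
#' category is drawn for every edge and transition, weights evolve through
#' the chosen category's matrix, and each strain observes `{-1,+1}` node
#' values Gibbs-sampled from the pairwise model with its knockout-damped
#' weights `Gamma_e^s * w_e(t)`.
#'
#' @param network a `netgem_network`.
#' @param annot a `netgem_annotation`.
#' @param states weight state set.
#' @param T number of time points.
#' @param knockouts named list strain -> knocked-out genes (empty vector for
#'   the reference strain); a single unnamed empty list gives one reference
#'   strain.
#' @param Q optional named list of true category transition matrices; when
#'   `NULL` each is drawn from the prior (uniform random rows, normalized).
#' @param lambda_p,lambda_o Dirichlet prior weights on candidate /
#'   non-candidate categories (defaults 1 and 0).
#' @param damping_mode,beta see [compute_damping()].
#' @param gibbs_sweeps burn-in sweeps per strain and time point.
#' @return list with `truth` (as in [generate_benchmark()], plus
#'   `category_traj`, the E x (T-1) matrix of generating categories) and
#'   `data` (`netgem_expression` over the strains), `damping`.
#' @export
sample_generative_process <- function(network, annot, states = -2:2, T = 8L,
                                      knockouts = list(reference = character(0)),
                                      Q = NULL, lambda_p = 1, lambda_o = 0,
                                      damping_mode = "distance", beta = 0.5,
                                      gibbs_sweeps = 50L) {
  states <- weight_states(states)
  W <- length(states)
  if (T < 2L) stop("T must be >= 2")
  if (lambda_o != 0)
    warning("lambda_o > 0 is ignored during generation: candidate supports are used")
  ec <- edge_candidates_all(network, annot)
  Hc <- length(ec$categories)
  E <- nrow(network$edges)

  if (is.null(Q)) {
    Q <- lapply(seq_len(Hc), function(h)
      row_normalize(matrix(runif(W * W), W, W)))
    names(Q) <- ec$categories
  } else {
    if (!all(ec$categories %in% names(Q)))
      stop("Q must supply a matrix for every category",
           if (ec$has_background) " including '.background'" else "")
    Q <- Q[ec$categories]
  }
  QhFlat <- do.call(rbind, lapply(Q, function(q) as.vector(t(q))))

  pair_edge <- rep.int(seq_len(E), lengths(ec$cand))
  pair_cat <- unlist(ec$cand, use.names = FALSE)
  alpha <- unlist(lapply(lengths(ec$cand),
                         function(k) rdirichlet1(rep(lambda_p, k))),
                  use.names = FALSE)
  alpha_df <- data.frame(edge = network$edge_names[pair_edge],
                         category = ec$categories[pair_cat],
                         weight = alpha, stringsAsFactors = FALSE)

  # per-transition category draw, then weight transition through Q_{y}
  alpha_list <- split(alpha, pair_edge)
  cand_list <- ec$cand
  idx <- matrix(0L, E, T)
  ycat <- matrix(0L, E, T - 1L)
  idx[, 1] <- sample.int(W, E, replace = TRUE)
  for (t in 2:T) {
    y <- vapply(seq_len(E), function(e) {
      k <- cand_list[[e]]
      if (length(k) == 1L) k else k[sample.int(length(k), 1L,
                                               prob = alpha_list[[e]])]
    }, integer(1))
    ycat[, t - 1L] <- y
    off <- (idx[, t - 1] - 1L) * W
    P <- vapply(seq_len(W),
                function(j) QhFlat[cbind(y, off + j)], numeric(E))
    if (E == 1L) P <- matrix(P, nrow = 1)
    idx[, t] <- sample_rows(P)
  }
  traj <- matrix(states[idx], E, T)
  rownames(traj) <- network$edge_names

  if (!is.list(knockouts)) knockouts <- list(knockouts)
  S <- length(knockouts)
  if (is.null(names(knockouts)))
    names(knockouts) <- c("reference", paste0("mutant", seq_len(S)))[seq_len(S)]
  if (S >= 2L && all(lengths(knockouts) == 0L))
    warning("multiple strains but no knockouts: strains differ only by observation noise")
  damping <- compute_damping(network, knockouts, mode = damping_mode,
                             beta = beta)

  xs <- lapply(seq_len(S), function(s) {
    x <- matrix(0, length(network$genes), T,
                dimnames = list(network$genes, paste0("t", seq_len(T))))
    for (t in seq_len(T))
      x[, t] <- gibbs_expression(network, damping$edge[, s] * traj[, t],
                                 n_sweeps = gibbs_sweeps)
    x
  })
  names(xs) <- names(knockouts)

  QeFlat <- rowsum(alpha * QhFlat[pair_cat, , drop = FALSE], pair_edge,
                   reorder = TRUE)
  edge_trace <- rowSums(QeFlat[, (seq_len(W) - 1L) * W + seq_len(W),
                               drop = FALSE])
  list(
    truth = list(Q_h = Q, alpha = alpha_df, trajectories = traj,
                 category_traj = matrix(ec$categories[ycat], E, T - 1L),
                 edge_trace = edge_trace,
                 edge_class = stats::setNames(
                   ifelse(edge_trace <= 0.5 * W, "H1", "H0"),
                   network$edge_names),
                 states = states),
    data = netgem_expression(xs),
    damping = damping
  )
}
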
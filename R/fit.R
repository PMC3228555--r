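#' Fit the temporal interaction model to expression data
#'
#' Estimates, by expectation-maximization, the functional-category
#' transition matrices `Q_h` and the per-edge mixing proportions
#' `alpha_e` of a hidden Markov model in which each network edge carries a
#' discrete interaction strength `w_e(t)` evolving under the effective
#' transition matrix `Q_e = sum_h alpha_eh Q_h`. Observed expression enters
#' through the pairwise potential `exp(Gamma_e^s w x_i x_j)` (normalized
#' over states per edge, time and strain); knockout strains share the
#' evolution law but see damped weights. After convergence the most
#' probable state sequence of every edge is decoded by the Viterbi
#' algorithm.
#'
#' The E-step runs a scaled forward-backward recursion per edge (linear in
#' the number of time points); the M-step applies Dirichlet pseudo-count
#' updates: transition rows get expected transition counts plus `theta`,
#' mixtures get expected category usage plus `lambda_p` (`lambda_o` off the
#' candidate set). `Q_h` is initialized from the prior (uniform random
#' rows, normalized) and `alpha_e` from the candidate-set Dirichlet; both
#' draws honour `seed`.
#'
#' @param data a `netgem_expression`, a gene x time matrix, or a named list
#'   of such matrices (one per strain).
#' @param network a `netgem_network`. Edges whose genes lack expression
#'   rows are dropped with a message.
#' @param annotation a `netgem_annotation`, or `NULL` to fit a single
#'   shared background category.
#' @param knockouts named list strain -> knocked-out genes; strains absent
#'   from the list are unperturbed.
#' @param states ordered weight state set (default `-2:2`).
#' @param lambda_p,lambda_o Dirichlet prior weight on candidate /
#'   non-candidate categories (`lambda_p > lambda_o >= 0`; defaults 1, 0).
#'   With `lambda_o = 0` mixtures stay supported on the candidate set.
#' @param theta Dirichlet pseudo-count for transition rows: a positive
#'   scalar (per cell) or a W x W matrix.
#' @param damping_mode,beta see [compute_damping()].
#' @param max_iter,tol EM controls: iteration cap and relative
#'   objective-change threshold.
#' @param seed optional integer seed for the initialization draws.
#' @param verbose print the objective per iteration.
#' @return An object of class `netgem`: list with `Q` (named list of W x W
#'   category transition matrices, including `".background"` when any edge
#'   has no annotated endpoint), `alpha` (long data frame `edge`,
#'   `category`, `weight`), `trajectories` (E x T decoded states),
#'   `posterior` (list over time of E x W smoothed marginals),
#'   `edge_loglik`, `objective` (per-iteration trace), `n_iter`,
#'   `converged`, `network`, `annotation`, `states`, `damping`, `call`.
#' @seealso [netgem_scores()], [edge_posterior()], [generate_benchmark()]
#' @examples
#' set.seed(1)
#' bench <- generate_benchmark(n_genes = 30, n_edges = 60, n_categories = 4,
#'                             T = 6)
#' fit <- netgem(bench$data, bench$network, bench$annotation, seed = 1)
#' fit
#' head(fitted(fit))
#' @export
netgem <- function(data, network, annotation = NULL, knockouts = NULL,
                   states = -2:2, lambda_p = 1, lambda_o = 0, theta = 1,
                   damping_mode = c("distance", "diffusion"), beta = 0.5,
                   max_iter = 200L, tol = 1e-6, seed = NULL,
                   verbose = FALSE) {
  damping_mode <- match.arg(damping_mode)
  states <- weight_states(states)
  W <- length(states)
  if (!(lambda_p > lambda_o && lambda_o >= 0))
    stop("need lambda_p > lambda_o >= 0")
  if (!inherits(data, "netgem_expression")) data <- netgem_expression(data)
  if (data$T < 2L) stop("need at least two time points")
  if (!is.null(seed)) set.seed(seed)

  missing_genes <- setdiff(network$genes, data$genes)
  if (length(missing_genes)) {
    keep <- !(network$edges[, 1] %in% match(missing_genes, network$genes) |
              network$edges[, 2] %in% match(missing_genes, network$genes))
    if (!any(keep)) stop("no network edge has expression for both genes")
    message(sprintf("dropping %d edge(s) lacking expression data",
                    sum(!keep)))
    ep <- cbind(network$genes[network$edges[keep, 1]],
                network$genes[network$edges[keep, 2]])
    network <- build_network(ep)
  }
  # align expression rows to network gene order
  data$x <- lapply(data$x, function(m) m[network$genes, , drop = FALSE])
  data$genes <- network$genes

  if (is.null(annotation))
    annotation <- structure(list(categories = character(0),
                                 membership = stats::setNames(list(), character(0))),
                            class = "netgem_annotation")
  ec <- edge_candidates_all(network, annotation)
  Hc <- length(ec$categories)
  E <- nrow(network$edges)
  Tn <- data$T

  ko <- stats::setNames(rep(list(character(0)), length(data$strains)),
                        data$strains)
  if (!is.null(knockouts)) {
    if (is.null(names(knockouts))) stop("knockouts must be a named list")
    unknown <- setdiff(names(knockouts), data$strains)
    if (length(unknown)) stop("knockout strain(s) not in data: ",
                              paste(unknown, collapse = ", "))
    ko[names(knockouts)] <- lapply(knockouts, as.character)
  }
  damping <- compute_damping(network, ko, mode = damping_mode, beta = beta)

  # candidate-category support (full support if lambda_o > 0)
  if (lambda_o > 0) {
    pair_edge <- rep.int(seq_len(E), rep.int(Hc, E))
    pair_cat <- rep.int(seq_len(Hc), E)
    in_cand <- logical(length(pair_cat))
    off <- 0L
    for (e in seq_len(E)) {
      in_cand[off + ec$cand[[e]]] <- TRUE
      off <- off + Hc
    }
    pair_lambda <- ifelse(in_cand, lambda_p, lambda_o)
  } else {
    pair_edge <- rep.int(seq_len(E), lengths(ec$cand))
    pair_cat <- unlist(ec$cand, use.names = FALSE)
    pair_lambda <- rep(lambda_p, length(pair_cat))
  }

  if (is.matrix(theta)) {
    if (!all(dim(theta) == W)) stop("theta matrix must be W x W")
    if (any(theta <= 0)) stop("theta entries must be > 0")
    theta_flat <- matrix(mat_to_flat(theta), Hc, W * W, byrow = TRUE)
  } else {
    if (theta <= 0) stop("theta must be > 0")
    theta_flat <- matrix(theta, Hc, W * W)
  }

  logb <- build_emissions(network, data, damping$edge, states)

  # initialization: Q_h from the prior draw, alpha from the support Dirichlet
  QhFlat <- t(vapply(seq_len(Hc), function(h)
    mat_to_flat(row_normalize(matrix(runif(W * W), W, W))),
    numeric(W * W)))
  if (Hc == 1L) QhFlat <- matrix(QhFlat, nrow = 1)
  g <- rgamma(length(pair_lambda), shape = pmax(pair_lambda, 1e-2))
  den <- as.vector(rowsum(g, pair_edge))
  alpha <- g / den[pair_edge]
  QeFlat <- rowsum(alpha * QhFlat[pair_cat, , drop = FALSE], pair_edge,
                   reorder = TRUE)

  objective <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  es <- NULL
  for (iter in seq_len(max_iter)) {
    es <- fb_engine(logb, QeFlat, W)
    J <- em_objective(es$loglik, QhFlat, alpha, pair_lambda, theta_flat)
    objective <- c(objective, J)
    if (verbose) message(sprintf("iter %3d  objective %.6f", iter, J))
    if (iter > 1L &&
        abs(J - objective[iter - 1L]) <=
          tol * (abs(objective[iter - 1L]) + 1e-10)) {
      converged <- TRUE
      break
    }
    ms <- m_step_engine(es$XiSum, QeFlat, QhFlat, alpha, pair_edge,
                        pair_cat, pair_lambda, theta_flat, W)
    QhFlat <- ms$QhFlat
    alpha <- ms$alpha
    QeFlat <- ms$QeFlat
    n_iter <- iter
  }
  if (!converged) es <- fb_engine(logb, QeFlat, W)

  path <- viterbi_engine(logb, QeFlat, states)
  traj <- matrix(states[path], E, Tn,
                 dimnames = list(network$edge_names,
                                 colnames(data$x[[1]]) %||%
                                   paste0("t", seq_len(Tn))))

  Q <- lapply(seq_len(Hc), function(h) flat_to_mat(QhFlat[h, ], W, states))
  names(Q) <- ec$categories
  alpha_df <- data.frame(edge = network$edge_names[pair_edge],
                         category = ec$categories[pair_cat],
                         weight = alpha, stringsAsFactors = FALSE)
  gamma <- lapply(es$gamma, function(gm) {
    dimnames(gm) <- list(network$edge_names, states)
    gm
  })

  structure(list(
    Q = Q, alpha = alpha_df, trajectories = traj, posterior = gamma,
    edge_loglik = stats::setNames(es$loglik, network$edge_names),
    objective = objective, n_iter = n_iter, converged = converged,
    network = network, annotation = annotation, states = states,
    damping = damping, data_dim = c(E = E, T = Tn, S = length(data$strains)),
    hyper = list(lambda_p = lambda_p, lambda_o = lambda_o, theta = theta,
                 tol = tol, max_iter = max_iter),
    emissions = logb, QeFlat = QeFlat,
    pairs = list(edge = pair_edge, cat = pair_cat, lambda = pair_lambda),
    seed = seed, call = match.call()
  ), class = "netgem")
}

#' @export
print.netgem <- function(x, ...) {
  d <- x$data_dim
  cat("Temporal interaction model fit\n")
  cat(sprintf("  %d edges, %d time points, %d strain(s), %d categor%s\n",
              d["E"], d["T"], d["S"], length(x$Q),
              if (length(x$Q) == 1) "y" else "ies"))
  cat(sprintf("  EM: %d iteration(s), %sconverged, objective %.3f\n",
              x$n_iter, if (x$converged) "" else "not ",
              x$objective[length(x$objective)]))
  cat(sprintf("  log-evidence (pseudo-likelihood): %.3f\n",
              sum(x$edge_loglik)))
  invisible(x)
}

#' @export
coef.netgem <- function(object, type = c("transition", "mixture"), ...) {
  type <- match.arg(type)
  if (type == "transition") object$Q else object$alpha
}

#' @export
fitted.netgem <- function(object, ...) object$trajectories

#' @export
logLik.netgem <- function(object, ...) {
  W <- length(object$states)
  k_e <- lengths(split(object$pairs$cat, object$pairs$edge))
  df <- length(object$Q) * W * (W - 1) + sum(k_e - 1)
  structure(sum(object$edge_loglik), df = df,
            nobs = object$data_dim[["E"]] * object$data_dim[["T"]] *
              object$data_dim[["S"]],
            class = "logLik")
}

#' @export
summary.netgem <- function(object, p = 0.05, ...) {
  sc <- netgem_scores(object, p = p)
  structure(list(fit = object, scores = sc, p = p),
            class = "summary.netgem")
}

#' @export
print.summary.netgem <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$scores)
  ce <- x$scores$categories
  top <- utils::head(ce[order(-ce$change_prob), ], 5L)
  cat("\nTop categories by total change probability of Q_h:\n")
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
plot.netgem <- function(x, which = c("objective", "scores"), ...) {
  which <- match.arg(which)
  if (which == "objective") {
    graphics::plot(seq_along(x$objective), x$objective, type = "b",
                   xlab = "EM iteration", ylab = "penalized objective",
                   main = "EM convergence", ...)
  } else {
    s <- change_score(x$trajectories)
    graphics::hist(s, breaks = 30, xlab = "edge change score",
                   main = "Edge change scores", ...)
  }
  invisible(x)
}

#' Simulate new data from a fitted model
#'
#' Draws fresh edge-weight trajectories from the fitted effective
#' transition matrices and `{-1,+1}` node observations from the pairwise
#' observation model (the benchmark observation regime), one dataset per
#' `nsim`.
#'
#' @param object a fitted `netgem` model.
#' @param nsim number of datasets.
#' @param seed optional seed.
#' @param gibbs_sweeps burn-in sweeps per time point.
#' @param ... unused.
#' @return list of length `nsim`; each element has `trajectories` and
#'   `data` (a `netgem_expression` for the fitted strains, with fitted
#'   knockout damping applied).
#' @export
simulate.netgem <- function(object, nsim = 1, seed = NULL,
                            gibbs_sweeps = 50L, ...) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- object$data_dim[["T"]]
  net <- object$network
  lapply(seq_len(nsim), function(k) {
    traj <- simulate_weight_trajectories(object$QeFlat, Tn, object$states)
    rownames(traj) <- net$edge_names
    xs <- lapply(seq_along(object$damping$strains), function(s) {
      x <- matrix(0, length(net$genes), Tn,
                  dimnames = list(net$genes, paste0("t", seq_len(Tn))))
      for (t in seq_len(Tn))
        x[, t] <- gibbs_expression(net, object$damping$edge[, s] * traj[, t],
                                   n_sweeps = gibbs_sweeps)
      x
    })
    names(xs) <- object$damping$strains
    list(trajectories = traj, data = netgem_expression(xs))
  })
}
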
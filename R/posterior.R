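#' Detailed posterior for a single edge
#'
#' Re-runs the forward-backward and Viterbi recursions for one edge under
#' the fitted parameters and returns the full smoothed posterior: state
#' marginals, pairwise transition joints, the per-transition responsibility
#' of each candidate functional category
#' (`P(y_t = h | data) propto alpha_eh Q_h(i,j)` averaged under the
#' transition posterior), and the decoded state sequence.
#'
#' @param fit a fitted `netgem` model.
#' @param edge edge index or `"geneA--geneB"` name.
#' @return list with `gamma` (T x W marginals), `xi` (list of T-1 W x W
#'   joint matrices), `cat_resp` ((T-1) x k category responsibilities),
#'   `map` (decoded state values) and `loglik`.
#' @export
edge_posterior <- function(fit, edge) {
  e <- if (is.character(edge)) match(edge, fit$network$edge_names)
       else as.integer(edge)
  if (is.na(e) || e < 1L || e > nrow(fit$network$edges))
    stop("unknown edge")
  W <- length(fit$states)
  logb1 <- lapply(fit$emissions, function(m) m[e, , drop = FALSE])
  Qe1 <- fit$QeFlat[e, , drop = FALSE]
  es <- fb_engine(logb1, Qe1, W, want_xi = TRUE)
  Tn <- length(logb1)

  gamma <- do.call(rbind, lapply(es$gamma, function(g) g[1, ]))
  dimnames(gamma) <- list(paste0("t", seq_len(Tn)), fit$states)
  xi <- lapply(es$xi, function(x) flat_to_mat(x[1, ], W, fit$states))

  sel <- fit$pairs$edge == e
  cats <- fit$pairs$cat[sel]
  a_e <- fit$alpha$weight[sel]
  QhFlat <- do.call(rbind, lapply(fit$Q[cats], mat_to_flat))
  cat_resp <- t(vapply(seq_len(Tn - 1L), function(t) {
    xr <- es$xi[[t]][1, ]
    r <- as.vector((QhFlat %*% (xr / Qe1[1, ])) * a_e)
    r / sum(r)
  }, numeric(length(cats))))
  if (length(cats) == 1L) cat_resp <- matrix(cat_resp, ncol = 1L)
  colnames(cat_resp) <- names(fit$Q)[cats]

  path <- viterbi_engine(logb1, Qe1, fit$states)
  list(gamma = gamma, xi = xi, cat_resp = cat_resp,
       map = fit$states[path[1, ]], loglik = es$loglik)
}

#' Effective transition matrix of an edge
#'
#' The convex mixture `Q_e = sum_h alpha_eh Q_h` over the edge's candidate
#' categories; row-stochastic by convexity.
#'
#' @param alpha_e numeric simplex over the categories in `Q_list`.
#' @param Q_list list of W x W row-stochastic matrices.
#' @return W x W matrix.
#' @examples
#' effective_transition(c(0.5, 0.5), list(diag(2), matrix(0.5, 2, 2)))
#' @export
effective_transition <- function(alpha_e, Q_list) {
  if (length(alpha_e) != length(Q_list))
    stop("one mixture weight per matrix required")
  if (abs(sum(alpha_e) - 1) > 1e-8) stop("mixture weights must sum to 1")
  Reduce(`+`, Map(`*`, alpha_e, Q_list))
}
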
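#' Change score of decoded weight trajectories
#'
#' Mean absolute successive change of the interaction strength,
#' `s_T(e) = (1/(T-1)) * sum_t |w(t+1) - w(t)|`. The magnitude of a change
#' matters: a jump from strongly repressing (-2) to strongly inducing (+2)
#' outweighs a step from -2 to uncorrelated (0). Constant trajectories
#' score 0.
#'
#' @param traj numeric state sequence, or an edge x time matrix (one score
#'   per row).
#' @param aggregate `"mean"` (default), `"sum"` or `"squared"` aggregation
#'   of the successive differences.
#' @return non-negative score(s), named when `traj` has row names.
#' @examples
#' change_score(c(-2, 2))      # 4
#' change_score(c(-2, 0, 0))   # 1
#' @export
change_score <- function(traj, aggregate = c("mean", "sum", "squared")) {
  aggregate <- match.arg(aggregate)
  if (!is.matrix(traj)) traj <- matrix(traj, nrow = 1)
  Tn <- ncol(traj)
  if (Tn < 2L) stop("need at least two time points")
  d <- abs(traj[, -1L, drop = FALSE] - traj[, -Tn, drop = FALSE])
  s <- switch(aggregate,
              mean = rowMeans(d),
              sum = rowSums(d),
              squared = rowMeans(d^2))
  if (nrow(traj) == 1L && is.null(rownames(traj))) unname(s[1]) else s
}

#' Category-level change score
#'
#' The mixture-weighted mean of edge change scores,
#' `s_T^h = sum_e alpha_eh s_T(e) / sum_e alpha_eh`, taken over the edges
#' whose candidate set contains the category. Categories carrying no
#' mixture weight score 0.
#'
#' @param edge_scores named numeric vector of edge change scores.
#' @param alpha long data frame with columns `edge`, `category`, `weight`
#'   (as in a fitted model's `$alpha`).
#' @param categories optional full category vector; defaults to those
#'   present in `alpha`.
#' @return named numeric vector of category scores.
#' @export
category_change_score <- function(edge_scores, alpha,
                                  categories = NULL) {
  if (is.null(categories)) categories <- sort(unique(alpha$category))
  s <- edge_scores[alpha$edge]
  num <- tapply(alpha$weight * s, alpha$category, sum)
  den <- tapply(alpha$weight, alpha$category, sum)
  out <- stats::setNames(numeric(length(categories)), categories)
  ok <- names(num)[!is.na(den) & den > 0]
  out[ok] <- num[ok] / den[ok]
  out
}

#' Total change probability of a transition matrix
#'
#' `W - tr(Q_h)`: the total off-diagonal mass, used to rank functional
#' categories by how much change their dynamics admit.
#'
#' @param Q row-stochastic W x W matrix.
#' @return value in `[0, W]`.
#' @export
category_change_prob <- function(Q) nrow(Q) - sum(diag(Q))

#' Trace hypothesis test on a transition matrix
#'
#' `H1` (significant dynamics) iff the matrix carries at most a fraction
#' `P` of its mass on the diagonal, `tr(Q) <= P * W`; else `H0`. The
#' boundary belongs to `H1`.
#'
#' @param Q row-stochastic W x W matrix.
#' @param P diagonal mass fraction in (0, 1], default 0.5.
#' @return `"H0"` or `"H1"`.
#' @export
trace_test <- function(Q, P = 0.5) {
  if (P <= 0 || P > 1) stop("P must lie in (0,1]")
  if (sum(diag(Q)) <= P * nrow(Q)) "H1" else "H0"
}

#' Exponential-tail critical value
#'
#' Fits an exponential distribution to non-negative scores by maximum
#' likelihood (`rate = 1/mean`) and returns the critical value whose upper
#' tail has mass `p`: `s* = mean * log(1/p)`. Scores strictly above `s*`
#' are selected.
#'
#' @param scores non-negative scores, not all zero.
#' @param p upper tail mass in (0, 1).
#' @return the critical value `s*`.
#' @examples
#' exponential_tail_threshold(rep(1, 10), 0.05)  # log(20)
#' @export
exponential_tail_threshold <- function(scores, p) {
  if (p <= 0 || p >= 1) {
    if (p == 1) return(0)
    stop("p must lie in (0,1)")
  }
  if (any(scores < 0)) stop("scores must be non-negative")
  m <- mean(scores)
  if (m == 0) stop("degenerate score distribution")
  m * log(1 / p)
}

#' Change scores and significance calls for a fitted model
#'
#' Computes per-edge change scores from the decoded trajectories and
#' category change scores from the fitted mixtures, fits an exponential
#' tail to each score distribution and calls `d1` (temporally significant)
#' for scores strictly above the top-`p` critical value `s*`.
#'
#' @param fit a fitted `netgem` model.
#' @param p upper tail mass (default 0.05, the top-5% tail).
#' @return An object of class `netgem_scores`: list with `edges`
#'   (data frame `edge`, `score`, `call`), `categories` (data frame
#'   `category`, `score`, `change_prob`, `call`), `s_star` (edge and
#'   category critical values) and `p`.
#' @export
netgem_scores <- function(fit, p = 0.05) {
  es <- change_score(fit$trajectories)
  s_star_e <- exponential_tail_threshold(es, p)
  cs <- category_change_score(es, fit$alpha, names(fit$Q))
  s_star_c <- exponential_tail_threshold(cs, p)
  cp <- vapply(fit$Q, category_change_prob, numeric(1))
  structure(list(
    edges = data.frame(edge = names(es), score = unname(es),
                       call = ifelse(es > s_star_e, "d1", "d0"),
                       row.names = NULL, stringsAsFactors = FALSE),
    categories = data.frame(category = names(cs), score = unname(cs),
                            change_prob = unname(cp[names(cs)]),
                            call = ifelse(cs > s_star_c, "d1", "d0"),
                            row.names = NULL, stringsAsFactors = FALSE),
    s_star = c(edge = s_star_e, category = s_star_c), p = p
  ), class = "netgem_scores")
}

#' @export
print.netgem_scores <- function(x, ...) {
  cat(sprintf(paste0(
    "Change scores (top-%g%% exponential tail):\n",
    "  edges:      %d of %d called significant (s* = %.4f)\n",
    "  categories: %d of %d called significant (s* = %.4f)\n"),
    100 * x$p,
    sum(x$edges$call == "d1"), nrow(x$edges), x$s_star["edge"],
    sum(x$categories$call == "d1"), nrow(x$categories),
    x$s_star["category"]))
  invisible(x)
}

#' Select temporally significant edges and categories
#'
#' @param scores a `netgem_scores` object.
#' @param level `"edge"` or `"category"`.
#' @return character vector of significant edge or category identifiers.
#' @export
select_significant <- function(scores, level = c("edge", "category")) {
  level <- match.arg(level)
  if (level == "edge") scores$edges$edge[scores$edges$call == "d1"]
  else scores$categories$category[scores$categories$call == "d1"]
}
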
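#' ROC curve for change-score detection
#'
#' Sweeps the critical value `s*` over all distinct score values (plus
#' infinities); a case is called positive when its score strictly exceeds
#' `s*`, and the positive class is `H1` (significant dynamics). The area
#' under the curve is computed by the trapezoidal rule, which equals the
#' Mann-Whitney rank statistic with ties counted half.
#'
#' @param scores named or plain numeric scores.
#' @param truth parallel labels, `"H0"`/`"H1"` (or a logical vector with
#'   `TRUE` = `H1`).
#' @return An object of class `netgem_roc`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, truth) {
  if (is.logical(truth)) truth <- ifelse(truth, "H1", "H0")
  truth <- as.character(truth)
  if (length(truth) != length(scores)) stop("scores and truth differ in length")
  if (!all(truth %in% c("H0", "H1"))) stop("labels must be H0 or H1")
  pos <- truth == "H1"
  if (!any(pos) || all(pos)) stop("degenerate labels")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(s) mean(scores[pos] > s), numeric(1))
  fpr <- vapply(thr, function(s) mean(scores[!pos] > s), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "netgem_roc")
}

#' @export
print.netgem_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.netgem_roc <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$fpr, x$tpr, ...)
  else graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1),
                      ylim = c(0, 1), xlab = "false positive rate",
                      ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Synthetic ROC experiment
#'
#' One replicate of the synthetic detection experiment: generate a
#' category-model benchmark, fit the model by EM, decode trajectories,
#' compute edge and category change scores, label the truth by the trace
#' class of the generating matrices (`tr <= 0.5 W` is `H1`; edges use the
#' trace of their true mixture matrix), and return both ROC curves. The
#' defaults are the benchmark scale (1000 genes, 5961 edges, 200
#' categories, 5 states, 8 time points), for which detection of dynamic
#' functional categories is substantially more accurate than detection of
#' individual dynamic edges.
#'
#' @param seed integer seed for the replicate (generation and fitting).
#' @param n_genes,n_edges,n_categories,states,T benchmark dimensions (see
#'   [generate_benchmark()]).
#' @param gibbs_sweeps burn-in sweeps per time point during generation.
#' @param ... further arguments passed to [netgem()] (e.g. `max_iter`,
#'   `tol`).
#' @return list with `category` and `edge` (`netgem_roc` objects) and
#'   `auc` (named vector).
#' @export
run_roc_experiment <- function(seed, n_genes = 1000L, n_edges = 5961L,
                               n_categories = 200L, states = -2:2, T = 8L,
                               gibbs_sweeps = 50L, ...) {
  set.seed(seed)
  bench <- generate_benchmark(n_genes = n_genes, n_edges = n_edges,
                              n_categories = n_categories, states = states,
                              T = T, model = "category",
                              gibbs_sweeps = gibbs_sweeps)
  fit <- netgem(bench$data, bench$network, bench$annotation,
                states = states, ...)
  es <- change_score(fit$trajectories)
  cs <- category_change_score(es, fit$alpha, names(fit$Q))

  cat_truth <- bench$truth$category_class[names(cs)]
  roc_cat <- roc_curve(cs, cat_truth)
  roc_edge <- roc_curve(es, bench$truth$edge_class[names(es)])
  list(category = roc_cat, edge = roc_edge,
       auc = c(category = roc_cat$auc, edge = roc_edge$auc))
}
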
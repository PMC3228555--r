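#' Multi-strain temporal expression dataset
#'
#' Container for per-strain expression matrices (genes x time points). All
#' strains must share the gene set and the number of time points.
#'
#' @param x a numeric gene x time matrix with row names, or a named list of
#'   such matrices (one per strain).
#' @return An object of class `netgem_expression`: list with `genes`,
#'   `strains`, `T` and `x` (named list of matrices).
#' @export
netgem_expression <- function(x) {
  if (is.matrix(x)) x <- list(reference = x)
  if (!is.list(x) || length(x) == 0L) stop("need at least one strain matrix")
  if (is.null(names(x))) names(x) <- paste0("strain", seq_along(x))
  x <- lapply(x, function(m) {
    m <- as.matrix(m)
    if (is.null(rownames(m))) stop("expression matrices need gene row names")
    storage.mode(m) <- "double"
    m
  })
  g1 <- rownames(x[[1]]); T1 <- ncol(x[[1]])
  for (m in x) {
    if (!identical(rownames(m), g1)) stop("strains must share the gene set")
    if (ncol(m) != T1) stop("strains must share the number of time points")
    if (any(!is.finite(m))) stop("expression values must be finite")
  }
  structure(list(genes = g1, strains = names(x), T = T1, x = x),
            class = "netgem_expression")
}

#' @export
print.netgem_expression <- function(x, ...) {
  cat("Expression dataset:", length(x$genes), "genes,", x$T,
      "time points,", length(x$strains), "strain(s):",
      paste(x$strains, collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression table
#'
#' Tab-separated file with a header line; first column gene identifier,
#' remaining columns the time points in order.
#'
#' @param path file path.
#' @return numeric gene x time matrix with gene row names.
#' @export
read_expression_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("expression table needs a gene column and >=1 time column")
  genes <- tab[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene id: ", genes[duplicated(genes)][1])
  m <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L,
              dimnames = list(genes, colnames(tab)[-1]))
  for (j in 2:ncol(tab)) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value in row %d, column %d of %s",
                   bad[1], j, path))
    m[, j - 1L] <- v
  }
  if (any(is.na(m))) stop("missing values in expression table ", path)
  m
}

#' Write an expression matrix as TSV
#' @param m gene x time numeric matrix with row names.
#' @param path file path.
#' @export
write_expression_table <- function(m, path) {
  cn <- colnames(m) %||% paste0("t", seq_len(ncol(m)))
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("gene", cn)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-strain expression normalization
#'
#' Centers each strain's expression independently of the others. The default
#' subtracts, per strain, each gene's mean over time from that gene's series
#' (`method = "gene"`), which makes the sign of the centered value — and
#' hence the sign of the pairwise product entering the observation model —
#' meaningful. `method = "grand"` subtracts the strain-wide grand mean
#' instead.
#'
#' @param dataset a `netgem_expression`, a list of matrices, or one matrix.
#' @param method `"gene"` (per-gene time mean) or `"grand"` (strain grand
#'   mean).
#' @return object of the same shape with centered values.
#' @export
normalize_expression <- function(dataset, method = c("gene", "grand")) {
  method <- match.arg(method)
  ctr <- function(m) {
    if (method == "gene") m - rowMeans(m) else m - mean(m)
  }
  if (is.matrix(dataset)) return(ctr(dataset))
  if (inherits(dataset, "netgem_expression")) {
    dataset$x <- lapply(dataset$x, ctr)
    return(dataset)
  }
  lapply(dataset, ctr)
}

#' Map expression values to their sign
#'
#' Optional preprocessing mimicking the `{-1,+1}` synthetic observation
#' regime: non-negative values map to `+1`, negative to `-1`.
#'
#' @param dataset as in [normalize_expression()].
#' @return object of the same shape with values in `{-1, 1}`.
#' @export
binarize_expression <- function(dataset) {
  f <- function(m) { m[] <- ifelse(m >= 0, 1, -1); m }
  if (is.matrix(dataset)) return(f(dataset))
  if (inherits(dataset, "netgem_expression")) {
    dataset$x <- lapply(dataset$x, f)
    return(dataset)
  }
  lapply(dataset, f)
}

#' Export decoded edge states for Cytoscape
#'
#' Writes a Cytoscape-style edge-attribute table for one time point: each
#' edge is mapped to its decoded interaction strength and to the five-level
#' colour class used to draw interaction networks (-2 strong repressing,
#' -1 low repressing, 0 no effect, +1 low inducing, +2 strong inducing).
#'
#' @param traj edge x time matrix of decoded states (rows named
#'   `"geneA--geneB"`), e.g. `fitted(fit)`.
#' @param t time index to export.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_cytoscape_edges <- function(traj, t, path) {
  if (t < 1L || t > ncol(traj)) stop("time index out of range")
  st <- traj[, t]
  lab <- c(`-2` = "strong repressing", `-1` = "low repressing",
           `0` = "no effect", `1` = "low inducing", `2` = "strong inducing")
  cls <- lab[as.character(st)]
  if (any(is.na(cls))) stop("states outside {-2..2} cannot be classified")
  ends <- do.call(rbind, strsplit(rownames(traj), "--", fixed = TRUE))
  df <- data.frame(edge = sprintf("%s (pp) %s", ends[, 1], ends[, 2]),
                   state = st, class = cls, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a Cytoscape edge-attribute table
#' @param path file written by [write_cytoscape_edges()].
#' @return data frame with `edge`, `state`, `class` columns.
#' @export
read_cytoscape_edges <- function(path) {
  read.table(path, sep = "\t", header = TRUE, quote = "",
             comment.char = "", stringsAsFactors = FALSE)
}
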
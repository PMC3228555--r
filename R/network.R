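#' Build an undirected gene-interaction network
#'
#' Constructs the fixed network topology that all interaction dynamics live
#' on. Reversed duplicates are merged (`(a,b)` and `(b,a)` are the same
#' undirected edge) and self-loops are dropped with a warning giving the
#' count.
#'
#' @param edge_pairs a two-column matrix or data frame of gene identifiers,
#'   or a character vector of length 2 for a single edge.
#' @return An object of class `netgem_network`: a list with components
#'   `genes` (ordered gene identifiers), `edges` (E x 2 integer matrix of
#'   indices into `genes`, smaller index first), `edge_names`
#'   (`"geneA--geneB"` labels), `adj` (adjacency list of gene indices),
#'   `adj_edge` (parallel list of edge indices) and `degree`.
#' @examples
#' net <- build_network(rbind(c("a", "b"), c("b", "a"), c("b", "c")))
#' net$edge_names  # "a--b" "b--c"
#' @export
build_network <- function(edge_pairs) {
  if (is.vector(edge_pairs) && length(edge_pairs) == 2L)
    edge_pairs <- matrix(edge_pairs, ncol = 2)
  ep <- as.matrix(edge_pairs)
  if (length(ep) == 0L || nrow(ep) == 0L) stop("empty network")
  if (ncol(ep) != 2L) stop("edge_pairs must have two columns")
  mode(ep) <- "character"
  if (any(is.na(ep)) || any(!nzchar(ep)))
    stop("gene identifiers must be non-empty strings")

  self <- ep[, 1] == ep[, 2]
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s)", sum(self)))
    ep <- ep[!self, , drop = FALSE]
  }
  if (nrow(ep) == 0L) stop("empty network")

  genes <- sort(unique(as.vector(ep)))
  i <- match(ep[, 1], genes)
  j <- match(ep[, 2], genes)
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  edges <- cbind(lo[keep], hi[keep])
  o <- order(edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  dimnames(edges) <- NULL

  E <- nrow(edges)
  V <- length(genes)
  adj <- vector("list", V)
  adj_edge <- vector("list", V)
  ends <- c(edges[, 1], edges[, 2])
  other <- c(edges[, 2], edges[, 1])
  eid <- rep.int(seq_len(E), 2L)
  sp_n <- split(other, ends)
  sp_e <- split(eid, ends)
  idx <- as.integer(names(sp_n))
  adj[idx] <- sp_n
  adj_edge[idx] <- sp_e
  nul <- vapply(adj, is.null, logical(1))
  adj[nul] <- list(integer(0))
  adj_edge[nul] <- list(integer(0))

  structure(list(
    genes = genes,
    edges = edges,
    edge_names = paste(genes[edges[, 1]], genes[edges[, 2]], sep = "--"),
    adj = adj,
    adj_edge = adj_edge,
    degree = lengths(adj)
  ), class = "netgem_network")
}

#' @export
print.netgem_network <- function(x, ...) {
  cat("Gene interaction network:", length(x$genes), "genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Weight state space of the interaction chain
#'
#' Validates the ordered set of discrete interaction strengths. The default
#' `{-2,-1,0,1,2}` spans strongly repressing to strongly inducing with the
#' uncorrelated level 0 in the middle.
#'
#' @param states strictly increasing integer-valued vector containing 0.
#' @return the validated numeric state vector.
#' @export
weight_states <- function(states = -2:2) {
  states <- as.numeric(states)
  if (length(states) < 2L) stop("need at least two weight states")
  if (any(diff(states) <= 0)) stop("states must be strictly increasing")
  if (!any(states == 0)) stop("state set must contain 0 (uncorrelated level)")
  states
}

#' Gene-to-functional-category annotation
#'
#' @param membership a two-column data frame (gene, category) with one row
#'   per membership, or a named list mapping genes to character vectors of
#'   category identifiers. Genes may belong to zero, one or many categories;
#'   identifiers (e.g. MIPS FunCat IDs such as `"32.01.04"`) are opaque
#'   strings.
#' @param categories optional ordered character vector of all category
#'   identifiers; defaults to the sorted set referenced by `membership`.
#' @return An object of class `netgem_annotation` with components
#'   `categories` and `membership` (named list of integer indices into
#'   `categories`).
#' @export
category_annotation <- function(membership, categories = NULL) {
  if (is.data.frame(membership) || is.matrix(membership)) {
    m <- as.data.frame(membership)
    if (ncol(m) < 2L) stop("membership table needs gene and category columns")
    membership <- split(as.character(m[[2]]), as.character(m[[1]]))
  }
  membership <- lapply(membership, function(v) unique(as.character(v)))
  used <- unique(unlist(membership, use.names = FALSE))
  if (is.null(categories)) categories <- sort(used)
  categories <- as.character(categories)
  if (length(categories) < 1L) stop("need at least one category")
  if (anyDuplicated(categories)) stop("duplicate category identifiers")
  if (!all(used %in% categories))
    stop("membership references categories absent from the category list")
  structure(list(
    categories = categories,
    membership = lapply(membership, function(v) match(v, categories))
  ), class = "netgem_annotation")
}

#' @export
print.netgem_annotation <- function(x, ...) {
  cat("Functional annotation:", length(x$categories), "categories,",
      length(x$membership), "annotated genes\n")
  invisible(x)
}

#' Candidate functional categories of an edge
#'
#' The mixture over category transition matrices for an edge is supported on
#' the union of the functional-category memberships of its two endpoint
#' genes (the Dirichlet prior puts `lambda_p` there and `lambda_o`
#' elsewhere). Unannotated endpoints contribute nothing; an edge whose two
#' endpoints are both unannotated has an empty candidate set and falls back
#' to the shared background category during fitting.
#'
#' @param network a `netgem_network`.
#' @param annot a `netgem_annotation`.
#' @param e an edge index, or a length-2 character vector of gene names.
#' @return character vector of category identifiers (possibly empty).
#' @export
edge_candidate_categories <- function(network, annot, e) {
  if (is.character(e)) {
    i <- match(e[1], network$genes); j <- match(e[2], network$genes)
    if (is.na(i) || is.na(j)) stop("edge endpoint not in network")
    gi <- e[1]; gj <- e[2]
  } else {
    ed <- network$edges[e, ]
    gi <- network$genes[ed[1]]; gj <- network$genes[ed[2]]
  }
  idx <- sort(unique(c(annot$membership[[gi]], annot$membership[[gj]])))
  annot$categories[idx]
}

# Internal: candidate category index list per edge, adding a background
# category (index H+1) for edges with fully unannotated endpoints.
# Returns list(cand = list per edge, categories = chr, has_background = lgl).
edge_candidates_all <- function(network, annot) {
  memb <- annot$membership
  gi <- network$genes[network$edges[, 1]]
  gj <- network$genes[network$edges[, 2]]
  cand <- mapply(function(a, b) sort(unique(c(a, b))),
                 memb[gi], memb[gj], SIMPLIFY = FALSE)
  names(cand) <- NULL
  empty <- lengths(cand) == 0L
  categories <- annot$categories
  has_background <- any(empty)
  if (has_background) {
    categories <- c(categories, ".background")
    cand[empty] <- list(length(categories))
  }
  list(cand = cand, categories = categories, has_background = has_background)
}

#' Read an edge list file
#'
#' Accepts a two-column tab-separated file (`geneA<TAB>geneB`) or a SIF file
#' (`geneA<TAB>relation<TAB>geneB`); lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return two-column character matrix of gene pairs (pass to
#'   [build_network()]).
#' @export
read_edge_list <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = "character", quote = "")
  if (ncol(tab) == 3L) tab <- tab[, c(1L, 3L)]  # SIF: geneA pp geneB
  if (ncol(tab) != 2L) stop("edge list must have 2 (TSV) or 3 (SIF) columns")
  as.matrix(tab)
}

#' Write an edge list as two-column TSV
#' @param network a `netgem_network`.
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  ep <- cbind(network$genes[network$edges[, 1]],
              network$genes[network$edges[, 2]])
  write.table(ep, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-to-category map
#'
#' Two-column tab-separated file (`gene<TAB>category`), several rows per
#' gene allowed, `#` comments skipped.
#'
#' @param path file path.
#' @param categories optional full category list (see
#'   [category_annotation()]).
#' @return a `netgem_annotation`.
#' @export
read_category_map <- function(path, categories = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    colClasses = "character", quote = "")
  if (ncol(tab) != 2L) stop("category map must have 2 columns")
  category_annotation(tab, categories = categories)
}

#' Write a gene-to-category map as TSV
#' @param annot a `netgem_annotation`.
#' @param path file path.
#' @export
write_category_map <- function(annot, path) {
  genes <- rep(names(annot$membership), lengths(annot$membership))
  cats <- annot$categories[unlist(annot$membership, use.names = FALSE)]
  write.table(cbind(genes, cats), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
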
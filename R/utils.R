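# Internal numeric helpers shared across the package.

# Row-wise maximum of a numeric matrix.
row_max <- function(m) do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))

# One Dirichlet draw per row of the shape matrix `alpha` (n x k).
rdirichlet_rows <- function(alpha) {
  g <- matrix(rgamma(length(alpha), shape = as.numeric(alpha), rate = 1),
              nrow = nrow(alpha))
  # shape 0 => exact 0 mass (used for lambda_o = 0 supports)
  g[alpha == 0] <- 0
  s <- rowSums(g)
  if (any(s <= 0)) stop("degenerate Dirichlet draw: all-zero shape row")
  g / s
}

rdirichlet1 <- function(alpha) drop(rdirichlet_rows(matrix(alpha, nrow = 1)))

# Row-normalize a non-negative matrix.
row_normalize <- function(m) {
  s <- rowSums(m)
  if (any(s <= 0)) stop("cannot normalize a row with non-positive sum")
  m / s
}

# log(sum(exp(v))) over the states dimension for each entry of the E x T
# matrix `a`, where the summand is exp(a * w) over the weights w in `states`.
logsumexp_states <- function(a, states) {
  m <- a * states[1]
  for (w in states[-1]) m <- pmax(m, a * w)
  acc <- 0
  for (w in states) acc <- acc + exp(a * w - m)
  m + log(acc)
}

# Sample one categorical outcome per row of the row-stochastic matrix `p`.
sample_rows <- function(p) {
  E <- nrow(p); W <- ncol(p)
  cs <- p
  if (W > 1) for (j in 2:W) cs[, j] <- cs[, j - 1] + p[, j]
  u <- runif(E)
  pmin.int(1L + rowSums(cs < u), W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
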
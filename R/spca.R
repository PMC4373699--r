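#' Neighbour-by-distance connection network
#'
#' Binary adjacency over colonies: i and j are neighbours when their
#' pairwise distance is at or below `threshold`. Works identically on
#' planar coordinates (2-D spatial network) and on depths (1-D depth
#' network) — the two separate analyses the sPCA machinery expects. The
#' row-standardized weight matrix `W` (rows sum to 1 where the node has
#' neighbours) drives both the sPCA spatial term and lagged scores.
#'
#' @param values Coordinates (2-column matrix/data frame) or scalar depths.
#' @param threshold Neighbour distance limit (> 0), e.g. from
#'   [neighbor_threshold()].
#' @param labels Optional node labels.
#' @return A `connection_network`: list with `A` (0/1 adjacency), `W`
#'   (row-standardized), `degree`, `threshold`.
#' @export
build_network <- function(values, threshold, labels = NULL) {
  stopifnot(threshold > 0)
  D <- unclass(distance_matrix(values, labels))
  A <- (D <= threshold) * 1
  diag(A) <- 0
  deg <- rowSums(A)
  if (all(deg == 0)) warning("threshold yields an empty graph")
  else if (all(A[upper.tri(A)] == 1)) warning("threshold yields a complete graph")
  if (any(deg == 0) && !all(deg == 0))
    warning(sum(deg == 0), " isolated node(s); degree range ",
            paste(range(deg), collapse = "-"))
  W <- A / ifelse(deg > 0, deg, 1)
  structure(list(A = A, W = W, degree = deg, threshold = threshold),
            class = "connection_network")
}

#' @export
print.connection_network <- function(x, ...) {
  cat("Connection network:", nrow(x$A), "nodes, threshold", x$threshold,
      "; degree", paste(range(x$degree), collapse = "-"),
      sprintf("(mean %.1f)\n", mean(x$degree)))
  invisible(x)
}

#' Spatial principal component analysis
#'
#' Eigen-decomposition of `H = X' (W + W') X / (2n)` for a column-centred
#' individual allele-frequency matrix `X` and row-standardized connection
#' weights `W`. Each axis maximizes the product of the genetic variance of
#' its scores and their Moran's I over the network: positive eigenvalues are
#' global structures (clines — neighbours alike), negative eigenvalues local
#' structures (patches — neighbours unlike). For every axis the identity
#' `lambda = var(s) * I(s)` with `var(s) = s's/n` and
#' `I(s) = s'Ws / s's` is verified internally.
#'
#' @param X Column-centred matrix from
#'   [individual_allele_matrix()]`(tab, center = TRUE)`.
#' @param net A `connection_network` over the same individuals.
#' @return An `spca_result`: `eigenvalues` (descending), `loadings`
#'   (unit-norm columns), `scores`, `var`, `moran`, `lagged` (`W %*% scores`).
#' @export
spca <- function(X, net) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 individuals")
  if (all(X == 0)) stop("allele matrix is identically zero")
  stopifnot(nrow(net$W) == n)
  W <- net$W
  H <- crossprod(X, (W + t(W)) %*% X) / (2 * n)
  H <- (H + t(H)) / 2
  eig <- eigen(H, symmetric = TRUE)
  lam <- eig$values
  V <- eig$vectors
  S <- X %*% V
  v <- colSums(S^2) / n
  ssq <- colSums(S^2)
  mor <- ifelse(ssq > 1e-12, colSums(S * (W %*% S)) / ssq, NA_real_)
  chk <- v * mor
  bad <- which(is.finite(chk) & abs(chk - lam) > 1e-6 * max(1, abs(lam)))
  if (length(bad)) warning("eigenvalue decomposition identity off on axis ",
                           bad[1])
  colnames(V) <- colnames(S) <- paste0("Axis", seq_along(lam))
  structure(list(eigenvalues = lam, loadings = V, scores = S,
                 var = v, moran = mor, lagged = W %*% S, n = n),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  np <- sum(x$eigenvalues > 1e-10)
  nn <- sum(x$eigenvalues < -1e-10)
  cat("sPCA:", x$n, "individuals;", np, "positive (global) and", nn,
      "negative (local) eigenvalues\n")
  cat("  leading lambda:", signif(utils::head(x$eigenvalues, 3), 4),
      "... trailing:", signif(utils::tail(x$eigenvalues, 2), 4), "\n")
  invisible(x)
}

#' Lagged (de-noisified) scores
#'
#' Neighbour-mean scores `W %*% s`: each individual is assigned the average
#' score of its network neighbours, smoothing out individual noise when
#' scores are mapped back onto the reef. Isolated nodes keep their own
#' score (flagged in the `isolated` attribute).
#'
#' @param result An `spca_result`.
#' @param net The `connection_network` used for the analysis.
#' @return Matrix of lagged scores (same shape as `result$scores`).
#' @export
lagged_scores <- function(result, net) {
  lag <- net$W %*% result$scores
  iso <- net$degree == 0
  if (any(iso)) lag[iso, ] <- result$scores[iso, ]
  attr(lag, "isolated") <- which(iso)
  lag
}

#' Moran's eigenvector map filters
#'
#' Eigenvectors of the doubly-centred adjacency
#' `(I - 11'/n) A (I - 11'/n)`: vectors with positive eigenvalues are
#' global (smooth, cline-like) spatial filters, negative ones local filters.
#' Near-zero eigenvalues (below `1e-10 * max|eigenvalue|`) are dropped. All
#' filters are mutually orthogonal and orthogonal to the constant vector.
#'
#' @param net A `connection_network`.
#' @return List of class `mem_filters`: `global` and `local` (matrices of
#'   unit eigenvectors, possibly 0 columns), `values_global`, `values_local`.
#' @export
mem_filters <- function(net) {
  A <- net$A
  n <- nrow(A)
  if (all(A == 0)) stop("empty graph: no eigenvector maps")
  Ac <- A - matrix(rowMeans(A), n, n)
  Ac <- Ac - matrix(colMeans(Ac), n, n, byrow = TRUE)
  Ac <- (Ac + t(Ac)) / 2
  eig <- eigen(Ac, symmetric = TRUE)
  tol <- 1e-10 * max(abs(eig$values))
  pos <- eig$values > tol
  neg <- eig$values < -tol
  structure(list(global = eig$vectors[, pos, drop = FALSE],
                 local = eig$vectors[, neg, drop = FALSE],
                 values_global = eig$values[pos],
                 values_local = eig$values[neg]),
            class = "mem_filters")
}

#' Global / local structure randomization test
#'
#' Tests whether individual allele frequencies align with the global
#' (cline) or local (patch) spatial filters of a connection network. The
#' statistic is the mean, over allele columns, of the R-squared from
#' projecting each centred column onto the filter subspace (`stat = "max"`
#' uses the maximum column R-squared instead). The null distribution comes
#' from permuting the rows of `X` with the network fixed;
#' `p = (hits + 1) / (n_perm + 1)`.
#'
#' @param X Column-centred allele matrix.
#' @param filters Matrix of filter vectors (one MEM set: global or local).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional RNG seed.
#' @param stat `"mean"` (default) or `"max"` column R-squared.
#' @return A `structure_test`: `statistic`, `p`, `n_perm`, `stat`.
#' @export
global_local_test <- function(X, filters, n_perm = 9999, seed = NULL,
                              stat = c("mean", "max")) {
  stat <- match.arg(stat)
  X <- as.matrix(X)
  if (NCOL(filters) < 1L) stop("need >= 1 filter")
  keep <- apply(X, 2L, stats::var) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance column(s) skipped")
    X <- X[, keep, drop = FALSE]
  }
  Q <- qr.Q(qr(filters))
  agg <- if (stat == "mean") mean else max
  stat_fn <- function(M) {
    proj <- crossprod(Q, M)
    agg(colSums(proj^2) / colSums(M^2))
  }
  obs <- stat_fn(X)
  if (!is.null(seed)) set.seed(seed)
  null <- replicate(n_perm, stat_fn(X[sample.int(nrow(X)), , drop = FALSE]))
  p <- (sum(null >= obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = obs, p = p, n_perm = n_perm, stat = stat),
            class = "structure_test")
}

#' @export
print.structure_test <- function(x, ...) {
  cat(sprintf("MEM randomization test: statistic = %.4f (%s R^2), p = %.4g (%d permutations)\n",
              x$statistic, x$stat, x$p, x$n_perm))
  invisible(x)
}
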
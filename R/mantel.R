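#' Pairwise distance matrix
#'
#' Euclidean distances between colonies on a scalar variable (depth, an
#' interpolated thermal index) or planar coordinates.
#'
#' @param values Numeric vector (scalar variable) or 2-column matrix/data
#'   frame of `x, y` coordinates.
#' @param labels Colony ids (row/column names of the result).
#' @param kind Matrix kind tag (e.g. `"space-distance"`, `"depth-distance"`).
#' @return Symmetric matrix with zero diagonal, class `pairwise_matrix`,
#'   attribute `kind`.
#' @export
distance_matrix <- function(values, labels = NULL, kind = "distance") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (is.matrix(values)) {
    if (anyNA(values))
      stop("missing coordinate for colony ",
           if (is.null(labels)) which(rowSums(is.na(values)) > 0)[1]
           else labels[which(rowSums(is.na(values)) > 0)[1]])
    d <- as.matrix(stats::dist(values))
  } else {
    if (anyNA(values))
      stop("missing value for colony ",
           if (is.null(labels)) which(is.na(values))[1]
           else labels[which(is.na(values))[1]])
    d <- abs(outer(values, values, "-"))
  }
  if (nrow(d) < 2L) stop("need >= 2 colonies")
  dimnames(d) <- if (is.null(labels)) NULL else list(labels, labels)
  structure(d, kind = kind, class = c("pairwise_matrix", "matrix"))
}

offdiag <- function(m) m[lower.tri(m)]

# embed off-diagonal ranks back into a symmetric matrix so that label
# permutation + extraction yields the permuted rank vector directly
rank_embed <- function(m) {
  v <- rank(offdiag(m), ties.method = "average")
  out <- matrix(0, nrow(m), ncol(m))
  out[lower.tri(out)] <- v
  out + t(out)
}

resid_on <- function(y, x) {
  vx <- stats::var(x)
  if (vx == 0) return(y - mean(y))
  y - mean(y) - stats::cov(x, y) / vx * (x - mean(x))
}

perm_pvalue <- function(r_obs, r_perm, tail, exact) {
  eps <- 1e-12
  hits <- switch(tail,
    "two-sided" = sum(abs(r_perm) >= abs(r_obs) - eps),
    upper       = sum(r_perm >= r_obs - eps),
    lower       = sum(r_perm <= r_obs + eps))
  if (exact) hits / length(r_perm) else (hits + 1) / (length(r_perm) + 1)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

check_pair <- function(A, B) {
  stopifnot(nrow(A) == ncol(A), all(dim(A) == dim(B)))
  la <- rownames(A); lb <- rownames(B)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("matrix labels differ")
}

mantel_result <- function(r, p, n_perm, tail, controlled_for, method) {
  structure(list(r = r, p = p, n_perm = n_perm, tail = tail,
                 controlled_for = controlled_for, method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test%s: r = %.4f, p = %.4g (%s, %d permutations)\n",
              if (is.na(x$controlled_for)) "Simple" else "Partial",
              if (is.na(x$controlled_for)) ""
              else paste0(" (controlling for ", x$controlled_for, ")"),
              x$r, x$p, x$tail, x$n_perm))
  invisible(x)
}

#' Simple Mantel test
#'
#' Correlation between the off-diagonal elements of two pairwise matrices,
#' with significance from a Monte-Carlo null built by simultaneous
#' row/column permutation of `B`. With `ranked = TRUE` (default) both
#' vectors are rank-transformed first, giving the Spearman analogue used
#' throughout reef-scale landscape genetics (pairwise distances are heavily
#' right-skewed).
#'
#' @param A,B Symmetric pairwise matrices over the same colonies.
#' @param n_perm Number of permutations (default 9999; p-values carry the
#'   +1 correction, so the smallest attainable p is `1/(n_perm+1)`).
#' @param ranked Use average-tie ranks (Spearman analogue)?
#' @param tail `"two-sided"` (default), `"upper"` or `"lower"`.
#' @param seed Optional RNG seed.
#' @param exact Enumerate all `n!` relabelings instead of sampling
#'   (only for small n; p is then the exact permutation tail fraction,
#'   identity included).
#' @return A `mantel_result`.
#' @export
simple_mantel <- function(A, B, n_perm = 9999, ranked = TRUE,
                          tail = c("two-sided", "upper", "lower"),
                          seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  check_pair(A, B)
  n <- nrow(A)
  if (n < 4L) stop("need n >= 4")
  if (exact && n > 8L) stop("exact enumeration limited to n <= 8")
  Ae <- if (ranked) rank_embed(A) else (A + t(A)) / 2
  Be <- if (ranked) rank_embed(B) else (B + t(B)) / 2
  va <- offdiag(Ae); vb <- offdiag(Be)
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stop("constant matrix: correlation undefined")
  r_obs <- stats::cor(va, vb)
  if (!is.null(seed)) set.seed(seed)
  perms <- if (exact) all_permutations(n) else
    t(replicate(n_perm, sample.int(n)))
  pair <- which(lower.tri(A), arr.ind = TRUE)
  ii <- pair[, 1L]; jj <- pair[, 2L]
  va_c <- va - mean(va)
  ssa <- sum(va_c^2)
  r_perm <- apply(perms, 1L, function(p) {
    vb_p <- Be[p[ii] + (p[jj] - 1L) * n]
    vb_pc <- vb_p - mean(vb_p)
    sum(va_c * vb_pc) / sqrt(ssa * sum(vb_pc^2))
  })
  mantel_result(r_obs, perm_pvalue(r_obs, r_perm, tail, exact),
                nrow(perms), tail, NA_character_,
                if (ranked) "spearman" else "pearson")
}

#' Partial Mantel test
#'
#' Correlation between `A` and `B` after removing the effect of a third
#' matrix `C`: all three off-diagonal vectors are rank-transformed, `A` and
#' `B` are each regressed on `C`, and `r` is the Pearson correlation of the
#' two residual vectors. The null permutes the rows/columns of `A` (the
#' response matrix, typically relatedness) and repeats the residual
#' procedure — a scheme that stays valid when the covariates are themselves
#' spatially autocorrelated.
#'
#' If `C` is constant the test degenerates to [simple_mantel()] (with a
#' warning).
#'
#' @inheritParams simple_mantel
#' @param C Conditioning matrix (e.g. spatial distance).
#' @return A `mantel_result` with `controlled_for` set from `C`'s kind.
#' @export
partial_mantel <- function(A, B, C, n_perm = 9999,
                           tail = c("two-sided", "upper", "lower"),
                           seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  check_pair(A, B); check_pair(A, C)
  n <- nrow(A)
  if (n < 5L) stop("need n >= 5")
  if (exact && n > 8L) stop("exact enumeration limited to n <= 8")
  vc_raw <- offdiag(C)
  if (stats::var(vc_raw) == 0) {
    warning("conditioning matrix is constant; falling back to a simple Mantel test")
    res <- simple_mantel(A, B, n_perm = n_perm, tail = tail, seed = seed,
                         exact = exact)
    res$controlled_for <- attr(C, "kind") %||% "C"
    return(res)
  }
  Ae <- rank_embed(A)
  vb <- rank(offdiag(B), ties.method = "average")
  vc <- rank(vc_raw, ties.method = "average")
  res_b <- resid_on(vb, vc)
  if (sum(res_b^2) < 1e-12 * length(res_b)) {
    warning("B is (rank-)identical to C: nothing left to correlate after control")
    return(mantel_result(0, 1, 0L, tail, attr(C, "kind") %||% "C", "spearman"))
  }
  va <- offdiag(Ae)
  r_obs <- stats::cor(resid_on(va, vc), res_b)
  if (!is.null(seed)) set.seed(seed)
  perms <- if (exact) all_permutations(n) else
    t(replicate(n_perm, sample.int(n)))
  pair <- which(lower.tri(A), arr.ind = TRUE)
  ii <- pair[, 1L]; jj <- pair[, 2L]
  vc_c <- vc - mean(vc)
  ssc <- sum(vc_c^2)
  ssb <- sum(res_b^2)
  r_perm <- apply(perms, 1L, function(p) {
    va_p <- Ae[p[ii] + (p[jj] - 1L) * n]
    # residual of the permuted (ranked) response on the conditioning ranks
    ra <- va_p - mean(va_p) - sum(vc_c * va_p) / ssc * vc_c
    sum(ra * res_b) / sqrt(sum(ra^2) * ssb)
  })
  mantel_result(r_obs, perm_pvalue(r_obs, r_perm, tail, exact),
                nrow(perms), tail, attr(C, "kind") %||% "C", "spearman")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Size-class bin definitions
#'
#' The small bin collects colonies below `small_upper` cm^2 (recent
#' recruits); each "large" bin collects colonies above one of
#' `large_lowers` — deliberately overlapping, reflecting the growing age
#' variance of large colonies.
#'
#' @param small_upper Upper area bound of the recruit bin (cm^2).
#' @param large_lowers Lower bounds of the large bins (cm^2).
#' @return List of bins, each `list(label, lower, upper)`.
#' @export
make_size_bins <- function(small_upper = 10, large_lowers = c(30, 40, 60, 90)) {
  c(list(list(label = paste0("<", small_upper), lower = -Inf, upper = small_upper)),
    lapply(large_lowers, function(b)
      list(label = paste0(">", b), lower = b, upper = Inf)))
}

#' Per-size-class partial Mantel tests
#'
#' For each size bin, partial Mantel tests of relatedness against depth,
#' Hotspots and Hothours distances (each controlling for space) and against
#' space (controlling for depth), on the bin's submatrices. Colonies without
#' an area measurement are excluded; bins with fewer than `min_n` members
#' are skipped with a warning.
#'
#' @param tab A `colony_table` with `area`.
#' @param rel Relatedness matrix over the same colonies.
#' @param dists Named list of `pairwise_matrix` objects: `space`, `depth`,
#'   and optionally `hotspots`, `hothours`.
#' @param bins Bin list from [make_size_bins()].
#' @param n_perm,tail,seed Passed to [partial_mantel()].
#' @param min_n Minimum bin membership (default 10).
#' @return Data frame of class `size_class_table`: one row per bin per test,
#'   columns `bin, N, variable, controlling, r, p`.
#' @export
size_class_tests <- function(tab, rel, dists, bins = make_size_bins(),
                             n_perm = 9999, tail = "two-sided", seed = NULL,
                             min_n = 10) {
  stopifnot("space" %in% names(dists), "depth" %in% names(dists))
  has_area <- !is.na(tab$area)
  specs <- list(c("depth", "space"), c("space", "depth"))
  for (v in intersect(c("hotspots", "hothours"), names(dists)))
    specs <- c(specs, list(c(v, "space")))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (b in bins) {
    # small bin: area < upper; large bins: area > lower (strict, overlapping)
    sel <- if (is.finite(b$upper)) which(has_area & tab$area < b$upper)
           else which(has_area & tab$area > b$lower)
    if (length(sel) < min_n) {
      warning("size bin ", b$label, " has N = ", length(sel),
              " < ", min_n, "; skipped")
      next
    }
    for (sp in specs) {
      res <- partial_mantel(rel[sel, sel], dists[[sp[1]]][sel, sel],
                            dists[[sp[2]]][sel, sel],
                            n_perm = n_perm, tail = tail)
      rows[[length(rows) + 1L]] <-
        data.frame(bin = b$label, N = length(sel), variable = sp[1],
                   controlling = sp[2], r = res$r, p = res$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("size_class_table", "data.frame"))
}

#' Distance-binned relatedness autocorrelogram
#'
#' Mean pairwise relatedness in distance bins chosen at empirical quantiles
#' of the pairwise distances, so every bin holds approximately the same
#' number of pairs. The 95% envelope comes from permuting colony locations
#' (equivalently, the relatedness matrix labels) and recomputing the bin
#' means.
#'
#' @param rel Relatedness matrix.
#' @param dst A `pairwise_matrix` of distances over the same colonies.
#' @param n_bins Number of equal-count bins (default 10).
#' @param n_perm Number of location permutations (default 200).
#' @param seed Optional RNG seed.
#' @param probs Envelope percentiles (default 2.5% and 97.5%).
#' @return Data frame of class `autocorrelogram`: `bin, mean_dist, mean_rel,
#'   n_pairs, lo, hi`.
#' @export
autocorrelogram <- function(rel, dst, n_bins = 10, n_perm = 200, seed = NULL,
                            probs = c(0.025, 0.975)) {
  check_pair(rel, dst)
  if (n_bins < 3L) stop("need >= 3 bins")
  n <- nrow(rel)
  vd <- offdiag(dst)
  edges <- unique(stats::quantile(vd, seq(0, 1, length.out = n_bins + 1L)))
  if (length(edges) < n_bins + 1L)
    warning("heavy distance ties: using ", length(edges) - 1L,
            " as-equal-as-possible bins")
  bin <- cut(vd, edges, include.lowest = TRUE, labels = FALSE)
  Re <- (rel + t(rel)) / 2; diag(Re) <- 0
  vr <- offdiag(Re)
  mean_rel <- tapply(vr, bin, mean)
  mean_dist <- tapply(vd, bin, mean)
  n_pairs <- tabulate(bin)
  if (!is.null(seed)) set.seed(seed)
  pair <- which(lower.tri(Re), arr.ind = TRUE)
  ii <- pair[, 1L]; jj <- pair[, 2L]
  counts <- tabulate(bin)
  perm_means <- matrix(NA_real_, n_perm, length(mean_rel))
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    vr_p <- Re[p[ii] + (p[jj] - 1L) * n]
    perm_means[k, ] <- rowsum(vr_p, bin)[, 1L] / counts
  }
  env <- apply(perm_means, 2L, stats::quantile, probs = probs)
  out <- data.frame(bin = seq_along(mean_rel),
                    mean_dist = as.numeric(mean_dist),
                    mean_rel = as.numeric(mean_rel),
                    n_pairs = n_pairs[seq_along(mean_rel)],
                    lo = env[1L, ], hi = env[2L, ])
  rownames(out) <- NULL
  structure(out, n_perm = n_perm, class = c("autocorrelogram", "data.frame"))
}

#' Neighbour distance threshold from an autocorrelogram
#'
#' The mean distance of the largest (farthest) bin whose mean relatedness
#' exceeds the upper permutation envelope — the upper distance limit for
#' "neighbours" when building sPCA connection networks.
#'
#' @param acorr An `autocorrelogram`.
#' @return Threshold distance (same units as the distances binned).
#' @export
neighbor_threshold <- function(acorr) {
  sig <- acorr$mean_rel > acorr$hi
  if (!any(sig))
    stop("no distance bin shows significant positive autocorrelation; ",
         "set a neighbour threshold manually")
  max(acorr$mean_dist[sig])
}
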
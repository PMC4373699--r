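#' Allele-mismatch genotype distances
#'
#' Pairwise number of allele differences between diploid 6-locus genotypes
#' under the infinite-allele model: per locus, `2 - |shared alleles|`
#' (multiset match, so AB vs BA is 0 and AA vs AB is 1), summed over loci.
#' These counts serve as squared molecular distances in the AMOVA.
#'
#' @param tab A `colony_table` (or anything with the 12 genotype columns).
#' @return Symmetric integer matrix of mismatch counts.
#' @export
genotype_distance <- function(tab) {
  n <- nrow(tab)
  d <- matrix(0, n, n)
  for (l in 1:6) {
    a1 <- tab[[paste0("L", l, ".1")]]
    a2 <- tab[[paste0("L", l, ".2")]]
    alleles <- sort(unique(c(a1, a2)))
    cnt <- outer(a1, alleles, "==") + outer(a2, alleles, "==")
    # multiset mismatch = sum |c_i - c_j| / 2 over alleles
    for (k in seq_along(alleles)) {
      d <- d + abs(outer(cnt[, k], cnt[, k], "-")) / 2
    }
  }
  dimnames(d) <- list(tab$colony_id, tab$colony_id)
  d
}

amova_fst <- function(d2, grp) {
  N <- length(grp)
  G <- length(unique(grp))
  ss_total <- sum(d2[lower.tri(d2)]) / N
  ss_within <- 0
  ng <- integer(G)
  for (g in seq_len(G)) {
    sel <- which(grp == g)
    ng[g] <- length(sel)
    sub <- d2[sel, sel, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / ng[g]
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1L
  df_within <- N - G
  ms_among <- ss_among / df_among
  sigma_within <- ss_within / df_within
  n0 <- (N - sum(ng^2) / N) / df_among
  sigma_among <- (ms_among - sigma_within) / n0
  fst <- sigma_among / (sigma_among + sigma_within)
  list(fst = fst, sigma_among = sigma_among, sigma_within = sigma_within,
       ss_among = ss_among, ss_within = ss_within)
}

#' Pairwise AMOVA F(ST) between two groups
#'
#' Two-level analysis of molecular variance (among groups / individuals
#' within groups) on allele-mismatch distances, after removing repeated
#' multi-locus genotypes *within each group* (a genet present in both
#' overlapping size bins legitimately appears once in each). Significance
#' is one-tailed: individuals are permuted between groups and large F(ST)
#' values count as extreme. The raw (possibly slightly negative) variance
#' components and F(ST) are reported as-is; clamping at zero is applied
#' only inside the permutation comparison.
#'
#' @param g1,g2 `colony_table`s (or subsets) for the two groups.
#' @param n_perm Number of permutations (default 9999).
#' @param dedup Remove repeated MLGs within each group first (default TRUE)?
#' @param seed Optional RNG seed.
#' @param min_n Minimum genets per group after deduplication (default 5).
#' @return An `fst_result`: `fst`, `fst_clamped`, `p`, `n_perm`, `n1`, `n2`,
#'   `sigma_among`, `sigma_within`.
#' @export
pairwise_fst <- function(g1, g2, n_perm = 9999, dedup = TRUE, seed = NULL,
                         min_n = 5) {
  if (dedup) {
    g1 <- g1[!duplicated(identify_mlgs(g1)$genet), , drop = FALSE]
    g2 <- g2[!duplicated(identify_mlgs(g2)$genet), , drop = FALSE]
  }
  n1 <- nrow(g1); n2 <- nrow(g2)
  if (n1 < min_n || n2 < min_n)
    stop("need >= ", min_n, " genets per group after deduplication (got ",
         n1, ", ", n2, ")")
  both <- rbind(as.data.frame(g1), as.data.frame(g2))
  both$colony_id <- make.unique(as.character(both$colony_id))
  d2 <- genotype_distance(both)
  grp <- rep(1:2, c(n1, n2))
  obs <- amova_fst(d2, grp)
  if (!is.null(seed)) set.seed(seed)
  # one-tailed on the raw statistic: clamping both sides at zero would pile
  # ties at p = 1 and destroy the uniform null distribution
  hits <- 0L
  for (k in seq_len(n_perm)) {
    f <- amova_fst(d2, grp[sample.int(n1 + n2)])$fst
    if (f >= obs$fst - 1e-12) hits <- hits + 1L
  }
  structure(list(fst = obs$fst, fst_clamped = max(0, obs$fst),
                 p = (hits + 1) / (n_perm + 1), n_perm = n_perm,
                 n1 = n1, n2 = n2,
                 sigma_among = obs$sigma_among,
                 sigma_within = obs$sigma_within),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("AMOVA F(ST) = %.4f (raw; clamped %.4f), p = %.4g (%d permutations; n = %d, %d genets)\n",
              x$fst, x$fst_clamped, x$p, x$n_perm, x$n1, x$n2))
  invisible(x)
}
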
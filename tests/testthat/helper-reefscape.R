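# shared helpers: small builders and independent (naive) oracles

# colony table with 6 loci from an n x 12 allele matrix
toy_table <- function(geno, x = NULL, y = NULL, depth = NULL, area = NA_real_) {
  n <- nrow(geno)
  colony_table(sprintf("t%02d", seq_len(n)),
               x = x %||% seq_len(n), y = y %||% rep(0, n),
               depth = depth %||% rep(1, n), genotypes = geno, area = area)
}

# n x 12 matrix: two polymorphic loci as given, loci 3-6 monomorphic
pad_monomorphic <- function(l1, l2) {
  n <- nrow(l1)
  cbind(l1, l2, matrix(rep(c(901L, 901L), each = n), n, 8))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive Spearman Mantel statistic straight from the definition
naive_mantel_r <- function(A, B) {
  va <- A[lower.tri(A)]; vb <- B[lower.tri(B)]
  stats::cor(va, vb, method = "spearman")
}

# naive partial statistic: correlation of rank residuals via lm()
naive_partial_r <- function(A, B, C) {
  ra <- rank(A[lower.tri(A)]); rb <- rank(B[lower.tri(B)])
  rc <- rank(C[lower.tri(C)])
  stats::cor(stats::residuals(stats::lm(ra ~ rc)),
             stats::residuals(stats::lm(rb ~ rc)))
}

# recursive full enumeration of permutations (independent of the package's)
perms_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

random_genotypes <- function(n, alleles = 4L) {
  matrix(sample(seq_len(alleles) * 2L + 100L, n * 12L, replace = TRUE), n, 12L)
}
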
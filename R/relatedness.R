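#' Reference allele frequencies
#'
#' Sample allele frequencies per locus, `p = count / 2n`, computed over all
#' colonies (ramets included) by default — clones carry their ecological
#' weight in the reference, matching an exhaustively mapped reef. Set
#' `dedup = TRUE` to count each multi-locus genotype once (sensitivity
#' analysis).
#'
#' @param tab A `colony_table`.
#' @param dedup Collapse repeated multi-locus genotypes first?
#' @return Data frame of class `allele_freqs`: `locus, allele, freq`.
#' @export
allele_frequencies <- function(tab, dedup = FALSE) {
  if (nrow(tab) == 0L) stop("empty colony table")
  if (dedup) {
    mlg <- identify_mlgs(tab)
    tab <- tab[!duplicated(mlg$genet), , drop = FALSE]
  }
  out <- do.call(rbind, lapply(1:6, function(l) {
    al <- c(tab[[paste0("L", l, ".1")]], tab[[paste0("L", l, ".2")]])
    tt <- table(al)
    data.frame(locus = l, allele = as.integer(names(tt)),
               freq = as.numeric(tt) / length(al))
  }))
  rownames(out) <- NULL
  structure(out, class = c("allele_freqs", "data.frame"))
}

#' Individual allele-frequency (dosage) matrix
#'
#' One row per colony, one column per (locus, allele); entries are half the
#' allele dosage, i.e. 0, 0.5 or 1. This is both the input to the pairwise
#' relationship estimator and, centred, the matrix analysed by [spca()].
#'
#' @param tab A `colony_table`.
#' @param freqs An `allele_freqs` fixing the column set and centring values;
#'   computed from `tab` if missing.
#' @param center Subtract the reference frequency from each column?
#' @return Numeric matrix `n x (total alleles)`, column names `L<l>_<allele>`,
#'   with the uncentred reference frequencies in attribute `freq`.
#' @export
individual_allele_matrix <- function(tab, freqs = allele_frequencies(tab),
                                     center = FALSE) {
  n <- nrow(tab)
  cols <- lapply(seq_len(nrow(freqs)), function(k) {
    l <- freqs$locus[k]; a <- freqs$allele[k]
    (as.numeric(tab[[paste0("L", l, ".1")]] == a) +
     as.numeric(tab[[paste0("L", l, ".2")]] == a)) / 2
  })
  X <- matrix(unlist(cols), nrow = n)
  colnames(X) <- paste0("L", freqs$locus, "_", freqs$allele)
  rownames(X) <- tab$colony_id
  attr(X, "freq") <- freqs$freq
  if (center) X <- sweep(X, 2L, freqs$freq)
  X
}

#' Pairwise Moran's-I coefficients of relationship
#'
#' Multilocus relationship between individuals i and j:
#' \deqn{r_{ij} = \frac{\sum_l \sum_a (x_{ila} - p_{la})(x_{jla} - p_{la})}
#'                     {\sum_l \sum_a p_{la}(1 - p_{la})}}
#' where `x_ila` is i's half-dosage of allele a at locus l (0, 0.5, 1) and
#' `p_la` the reference frequency. This is the allele-dosage covariance
#' standardized by the expected heterozygosity sum — the Moran's-I family of
#' relationship coefficients used for individual-level spatial genetics.
#' Clonemates attain the dataset maximum among pairs; under panmixia the
#' mean off-diagonal value is close to `-1/(n-1)`.
#'
#' @param tab A `colony_table` (>= 2 colonies, >= 1 polymorphic locus).
#' @param freqs Reference `allele_freqs` (defaults to sample frequencies
#'   over all ramets).
#' @return Symmetric `n x n` matrix of class `relatedness_matrix`
#'   (diagonal set to `NA`; it is not a self-relatedness estimate), with
#'   attributes `kind = "relatedness"` and `denominator`.
#' @export
moran_relationship <- function(tab, freqs = allele_frequencies(tab)) {
  if (nrow(tab) < 2L) stop("need >= 2 colonies")
  den <- sum(freqs$freq * (1 - freqs$freq))
  if (den <= 0) stop("all loci monomorphic: estimator denominator is zero")
  Xc <- individual_allele_matrix(tab, freqs, center = TRUE)
  r <- tcrossprod(Xc) / den
  diag(r) <- NA_real_
  dimnames(r) <- list(tab$colony_id, tab$colony_id)
  structure(r, kind = "relatedness", denominator = den,
            class = c("relatedness_matrix", "matrix"))
}

#' Identify repeated multi-locus genotypes
#'
#' Partitions colonies into genets: two colonies belong to the same genet iff
#' every locus carries the same unordered allele pair. Used both to flag
#' clonal ramets and to deduplicate size-class bins before AMOVA.
#'
#' @param tab A `colony_table`.
#' @return List of class `mlg_partition`: `genet` (integer label per colony,
#'   named by colony_id), `n_genets`, `ramet_counts` (table per genet).
#' @export
identify_mlgs <- function(tab) {
  keys <- vapply(seq_len(nrow(tab)), function(i) {
    paste(vapply(1:6, function(l) {
      al <- sort(c(tab[[paste0("L", l, ".1")]][i], tab[[paste0("L", l, ".2")]][i]))
      paste(al, collapse = "/")
    }, character(1)), collapse = "|")
  }, character(1))
  genet <- as.integer(factor(keys, levels = unique(keys)))
  names(genet) <- tab$colony_id
  structure(list(genet = genet, n_genets = max(genet),
                 ramet_counts = table(genet)),
            class = "mlg_partition")
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat("MLG partition:", length(x$genet), "ramets in", x$n_genets, "genets;",
      sum(x$ramet_counts > 1L), "genet(s) with repeats\n")
  invisible(x)
}
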
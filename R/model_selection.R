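#' Assemble the pairwise regression data
#'
#' Stacks the off-diagonal elements of the relatedness matrix (response) and
#' any number of pairwise distance matrices (predictors) into one data frame
#' with `n(n-1)/2` rows.
#'
#' @param rel Relatedness matrix.
#' @param dists Named list of `pairwise_matrix` predictors.
#' @return Data frame with column `relatedness` plus one column per predictor.
#' @export
pairwise_model_data <- function(rel, dists) {
  Re <- (rel + t(rel)) / 2
  out <- data.frame(relatedness = offdiag(Re))
  for (nm in names(dists)) {
    check_pair(rel, dists[[nm]])
    out[[nm]] <- offdiag(dists[[nm]])
  }
  out
}

#' Fit one pairwise-distance regression
#'
#' Ordinary least squares of pairwise relatedness on the chosen pairwise
#' distance predictors, with the Gaussian log-likelihood at the ML variance
#' estimate. The parameter count is `K = |predictors| + 2` (intercept and
#' residual variance), the convention under which the depth+space model
#' reports K = 4. Pairwise observations are treated as independent in the
#' likelihood; AIC differences are therefore comparative indices, not
#' calibrated evidence (the pairs share colonies).
#'
#' @param data Data frame from [pairwise_model_data()].
#' @param predictors Character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @return A `model_fit`: list with `predictors`, `K`, `logL`, `AIC`, `fit`.
#' @export
fit_distance_lm <- function(data, predictors) {
  stopifnot(all(predictors %in% names(data)))
  K <- length(predictors) + 2L
  if (nrow(data) < K + 1L) stop("need more observations than parameters")
  form <- stats::reformulate(if (length(predictors)) predictors else "1",
                             response = "relatedness")
  fit <- stats::lm(form, data = data)
  if (length(predictors) && any(is.na(stats::coef(fit))))
    stop("exact collinearity among predictors: ",
         paste(predictors, collapse = ", "))
  n <- nrow(data)
  sigma2 <- sum(stats::residuals(fit)^2) / n
  if (sigma2 < 1e-25) {
    warning("zero residual variance; log-likelihood floored")
    logL <- -n / 2 * (log(2 * pi * 1e-25) + 1)
  } else {
    logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  }
  structure(list(predictors = predictors, K = K, logL = logL,
                 AIC = 2 * K - 2 * logL, fit = fit),
            class = "model_fit")
}

#' Fit every linear combination of the predictors
#'
#' All non-empty subsets of the four pairwise predictors: 4 bivariate plus
#' 11 multivariate models = 15 fits. The intercept-only null model is
#' excluded by default (set `include_null = TRUE` to add it).
#'
#' @param data Data frame from [pairwise_model_data()].
#' @param predictors Predictor pool (default the four landscape variables
#'   present in `data`).
#' @param include_null Include the intercept-only model?
#' @return List of `model_fit` objects, class `model_fit_set`.
#' @export
fit_all_models <- function(data,
                           predictors = setdiff(names(data), "relatedness"),
                           include_null = FALSE) {
  subsets <- unlist(lapply(seq_along(predictors), function(k)
    utils::combn(predictors, k, simplify = FALSE)), recursive = FALSE)
  if (include_null) subsets <- c(list(character(0)), subsets)
  fits <- lapply(subsets, function(s) fit_distance_lm(data, s))
  structure(fits, class = "model_fit_set")
}

#' Rank models by AIC and compute Akaike weights
#'
#' `dAIC` is taken from unrounded AICs; weights
#' `w_i = exp(-dAIC_i/2) / sum_j exp(-dAIC_j/2)` are normalized over the
#' *full* model set, and models with `dAIC >= support_cutoff` are flagged as
#' poorly supported (dropped from further interpretation, never from the
#' weight normalization).
#'
#' @param fits A `model_fit_set` (or list of `model_fit`).
#' @param support_cutoff dAIC cutoff for retention (default 5).
#' @return Data frame of class `model_ranking`, sorted by AIC: `model, K,
#'   logL, AIC, dAIC, w, retained`.
#' @export
rank_models <- function(fits, support_cutoff = 5) {
  stopifnot(length(fits) >= 1L)
  tab <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$predictors)) paste(f$predictors, collapse = "+")
      else "(intercept)", character(1)),
    K = vapply(fits, `[[`, integer(1), "K"),
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    stringsAsFactors = FALSE)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$w <- exp(-tab$dAIC / 2) / sum(exp(-tab$dAIC / 2))
  tab$retained <- tab$dAIC < support_cutoff
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  structure(tab, class = c("model_ranking", "data.frame"))
}

#' Predictor (summed Akaike) weights
#'
#' `w_plus(v)`: the sum of Akaike weights over every model containing
#' predictor `v`, computed on the full model set — the multi-model measure
#' of variable importance used to rank landscape predictors.
#'
#' @param fits A `model_fit_set`.
#' @param predictors Predictor pool (defaults to the union over models).
#' @return Named numeric vector of `w_plus`, sorted decreasing.
#' @export
predictor_weights <- function(fits, predictors = NULL) {
  rk <- rank_models(fits)
  preds <- lapply(fits, `[[`, "predictors")
  if (is.null(predictors)) predictors <- unique(unlist(preds))
  w <- vapply(fits, function(f) NA_real_, numeric(1))
  # align weights to fits via the model label
  lab <- vapply(fits, function(f)
    if (length(f$predictors)) paste(f$predictors, collapse = "+")
    else "(intercept)", character(1))
  w <- rk$w[match(lab, rk$model)]
  out <- vapply(predictors, function(v)
    sum(w[vapply(preds, function(p) v %in% p, logical(1))]), numeric(1))
  sort(out, decreasing = TRUE)
}

#' @export
print.model_ranking <- function(x, digits = 4, ...) {
  cat("Model ranking (", nrow(x), " models, weights sum to ",
      format(sum(x$w), digits = 3), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
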
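#' Empirical semivariogram
#'
#' Classical Matheron estimator: for each lag bin,
#' `gamma(h) = sum (z_i - z_j)^2 / (2 N(h))` over station pairs whose
#' separation falls in the bin. Bins are equal-width up to `max_lag`
#' (default half the maximum station separation); empty bins are omitted.
#'
#' @param x,y Station coordinates (m).
#' @param values Observed values at the stations.
#' @param n_bins Number of lag bins (default 12).
#' @param max_lag Maximum lag distance (m).
#' @return Data frame of class `empirical_variogram`: `lag` (mean pair
#'   distance in bin), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(x, y, values, n_bins = 12, max_lag = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(values), n_bins >= 2)
  if (length(x) < 3L) stop("need >= 3 stations")
  d <- as.vector(stats::dist(cbind(x, y)))
  if (max(d) == 0) stop("all stations are co-located")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  g <- as.vector(stats::dist(values))^2 / 2
  keep <- d <= max_lag & d > 0
  bin <- cut(d[keep], breaks = seq(0, max_lag, length.out = n_bins + 1L),
             include.lowest = TRUE)
  lag <- tapply(d[keep], bin, mean)
  gam <- tapply(g[keep], bin, mean)
  np <- tapply(g[keep], bin, length)
  ok <- !is.na(gam)
  out <- data.frame(lag = as.numeric(lag[ok]), gamma = as.numeric(gam[ok]),
                    n_pairs = as.integer(np[ok]))
  structure(out, class = c("empirical_variogram", "data.frame"),
            max_lag = max_lag)
}

#' Theoretical variogram models
#'
#' Semivariance `gamma(h)` for the spherical, exponential and gaussian
#' families. `gamma(0) = 0` by convention; the nugget is the limit from
#' above. For the exponential and gaussian families `range_param` is the
#' *practical* range (distance at ~95% of the sill), matching the common
#' gstat parameterization users expect.
#'
#' @param h Distances (m).
#' @param model `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget,psill,range_param Model parameters (nugget >= 0,
#'   partial sill >= 0, range > 0).
#' @return Semivariances, same length as `h`.
#' @export
variogram_gamma <- function(h, model, nugget, psill, range_param) {
  stopifnot(nugget >= 0, psill >= 0, range_param > 0)
  core <- switch(model,
    spherical   = ifelse(h >= range_param, 1,
                         1.5 * h / range_param - 0.5 * (h / range_param)^3),
    exponential = 1 - exp(-3 * h / range_param),
    gaussian    = 1 - exp(-3 * (h / range_param)^2),
    stop("unknown variogram model: ", model))
  out <- nugget + psill * core
  out[h == 0] <- 0
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Minimizes `sum_k w_k (gamma_hat_k - gamma(h_k; theta))^2` with Cressie-style
#' weights `w_k = N(h_k) / h_k^2`, using bounded L-BFGS-B from several
#' starting points. Parameters are bounded below at 0 (nugget, partial sill)
#' and a small positive range.
#'
#' @param emp An `empirical_variogram`.
#' @param model Model family name.
#' @return A `variogram_model`: list with `model`, `nugget`, `psill`,
#'   `range_param`, `objective`, `convergence`.
#' @export
fit_variogram <- function(emp, model = c("spherical", "exponential", "gaussian")) {
  model <- match.arg(model)
  if (nrow(emp) < 3L) stop("need >= 3 non-empty variogram bins")
  w <- emp$n_pairs / emp$lag^2
  obj <- function(par) {
    g <- variogram_gamma(emp$lag, model, par[1], par[2], par[3])
    sum(w * (emp$gamma - g)^2)
  }
  span <- max(emp$lag)
  sill0 <- max(emp$gamma)
  starts <- list(c(0, sill0, span / 2),
                 c(min(emp$gamma), max(sill0 - min(emp$gamma), 1e-8), span / 3),
                 c(sill0 / 2, sill0 / 2, span))
  best <- NULL
  trace <- numeric(0)
  for (p0 in starts) {
    fit <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                            lower = c(0, 0, 1e-6 * span),
                            upper = c(Inf, Inf, 10 * span)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    trace <- c(trace, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("variogram fit failed to converge; objective trace: ",
         paste(signif(trace, 4), collapse = ", "))
  structure(list(model = model, nugget = best$par[1], psill = best$par[2],
                 range_param = best$par[3], objective = best$value,
                 convergence = best$convergence),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, partial sill %.4g, range %.4g m (WLS obj %.4g)\n",
              x$model, x$nugget, x$psill, x$range_param, x$objective))
  invisible(x)
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction at target locations from station values,
#' with weights solving the ordinary-kriging system built from the fitted
#' variogram (covariance `C(h) = nugget + psill - gamma(h)`, plus a Lagrange
#' multiplier constraining weights to sum to 1). Stations sharing exact
#' coordinates are value-averaged before solving so the system stays
#' non-singular.
#'
#' @param vm A `variogram_model`.
#' @param stations Data frame or matrix with columns `x`, `y`.
#' @param values Station values.
#' @param targets Data frame or matrix with columns `x`, `y`.
#' @return A `kriged_field`: data.frame `x, y, pred, krige_var` with the
#'   weight matrix in attribute `weights` (targets x stations).
#' @export
ordinary_krige <- function(vm, stations, values, targets) {
  stations <- as.data.frame(stations)
  targets <- as.data.frame(targets)
  stopifnot(nrow(stations) == length(values), nrow(stations) >= 2L)
  key <- paste(stations$x, stations$y)
  if (anyDuplicated(key)) {
    values <- as.numeric(tapply(values, key, mean)[unique(key)])
    stations <- stations[!duplicated(key), , drop = FALSE]
  }
  n <- nrow(stations)
  sill <- vm$nugget + vm$psill
  D <- as.matrix(stats::dist(stations[, c("x", "y")]))
  C <- sill - matrix(variogram_gamma(as.vector(D), vm$model, vm$nugget,
                                     vm$psill, vm$range_param), n, n)
  diag(C) <- sill
  K <- rbind(cbind(C, 1), c(rep(1, n), 0))
  Dt <- sqrt(outer(targets$x, stations$x, "-")^2 +
             outer(targets$y, stations$y, "-")^2)
  c0 <- sill - matrix(variogram_gamma(as.vector(Dt), vm$model, vm$nugget,
                                      vm$psill, vm$range_param),
                      nrow(targets), n)
  rhs <- rbind(t(c0), 1)
  sol <- try(solve(K, rhs), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("singular kriging matrix; check for (near-)duplicate stations at ",
         paste(utils::head(stations$x, 3), utils::head(stations$y, 3),
               collapse = "; "))
  wts <- t(sol[seq_len(n), , drop = FALSE])
  mu <- sol[n + 1L, ]
  pred <- as.vector(wts %*% values)
  kv <- pmax(0, sill - rowSums(wts * c0) - mu)
  structure(data.frame(x = targets$x, y = targets$y, pred = pred,
                       krige_var = kv),
            weights = wts, class = c("kriged_field", "data.frame"))
}

#' Krige station values onto colony locations
#'
#' Fits a variogram to station values and interpolates onto each colony,
#' the standard route for layering logger-derived surfaces (depth,
#' Hotspots, Hothours) under a colony map.
#'
#' @param loggers A `logger_set`.
#' @param values One value per station (same order as `loggers$stations`).
#' @param colonies A `colony_table`.
#' @param model Variogram family.
#' @param n_bins Lag bins for the empirical variogram.
#' @return List with `field` (a `kriged_field`, one row per colony) and
#'   `variogram` (the fitted `variogram_model`).
#' @export
krige_to_colonies <- function(loggers, values, colonies,
                              model = "spherical", n_bins = 12) {
  st <- loggers$stations
  emp <- empirical_variogram(st$x, st$y, values, n_bins = n_bins)
  vm <- fit_variogram(emp, model)
  field <- ordinary_krige(vm, st[, c("x", "y")], values,
                          colonies[, c("x", "y")])
  list(field = field, variogram = vm)
}
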
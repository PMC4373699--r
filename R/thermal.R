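#' Relative Hotspots index
#'
#' Fraction of time a station is at least one standard deviation hotter than
#' the reef-wide reference. By default the reference is computed per
#' timestamp: at each time t the cross-station mean and SD are taken and a
#' station is "hot" at t when `T >= mean_t + sd_t`. This per-timestamp
#' construction removes the shared seasonal and diurnal cycles, so the index
#' captures persistent *spatial* anomalies and stays independent of depth
#' unless depth itself structures the anomalies. A scalar reference (single
#' mean/SD over all stations and times) is available via `baseline =
#' "scalar"`.
#'
#' Timestamps where the cross-station SD is zero contribute no hot flags.
#'
#' @param loggers A `logger_set` with at least two stations.
#' @param baseline `"per-timestamp"` (default) or `"scalar"`.
#' @return Data frame `station_id, hotspots, n_timestamps_used`.
#' @export
hotspots_index <- function(loggers, baseline = c("per-timestamp", "scalar")) {
  baseline <- match.arg(baseline)
  tm <- loggers$temp
  if (ncol(tm) < 2L)
    stop("hotspots index needs >= 2 stations (cross-station SD undefined)")
  if (baseline == "per-timestamp") {
    m <- rowMeans(tm)
    s <- sqrt(rowSums((tm - m)^2) / (ncol(tm) - 1L))
    thr <- m + s
    hot <- (tm >= thr - 1e-12) & (s > 0)
  } else {
    m <- mean(tm)
    s <- stats::sd(as.vector(tm))
    hot <- (tm >= m + s - 1e-12) & (s > 0)
  }
  data.frame(station_id = loggers$stations$station_id,
             hotspots = colMeans(hot),
             n_timestamps_used = nrow(tm),
             stringsAsFactors = FALSE)
}

#' Relative Hothours index
#'
#' Fraction of eligible timestamps at which a station is at least one
#' standard deviation hotter than its own mean over the trailing `window`
#' hours. The trailing window excludes the current reading; the first
#' `window` hours of the series are excluded from the denominator. The index
#' is strictly local: it uses only that station's series, so warm episodes
#' are judged against the site's own recent history.
#'
#' @param loggers A `logger_set`.
#' @param window Trailing window length in hours (default 12); must be a
#'   multiple of the sampling step and shorter than the series.
#' @return Data frame `station_id, hothours, n_timestamps_used`.
#' @export
hothours_index <- function(loggers, window = 12) {
  step <- loggers$step
  k <- window / step
  if (abs(k - round(k)) > 1e-8)
    stop("window (", window, " h) is not a multiple of the sampling step (",
         step, " h)")
  k <- as.integer(round(k))
  if (k < 2L) stop("window must span at least 2 readings")
  tm <- loggers$temp
  n <- nrow(tm)
  if (n <= k) stop("series length must exceed the window")
  idx <- (k + 1L):n
  # trailing mean/sd over readings t-k .. t-1 via cumulative sums
  cs <- rbind(0, apply(tm, 2L, cumsum))
  cq <- rbind(0, apply(tm^2, 2L, cumsum))
  sum_w <- cs[idx, , drop = FALSE] - cs[idx - k, , drop = FALSE]
  ssq_w <- cq[idx, , drop = FALSE] - cq[idx - k, , drop = FALSE]
  m <- sum_w / k
  v <- pmax(0, (ssq_w - k * m^2) / (k - 1L))
  s <- sqrt(v)
  hot <- (tm[idx, , drop = FALSE] >= m + s - 1e-12) & (s > 1e-12)
  data.frame(station_id = loggers$stations$station_id,
             hothours = colMeans(hot),
             n_timestamps_used = length(idx),
             stringsAsFactors = FALSE)
}

#' Station-level thermal indices
#'
#' Convenience wrapper returning both indices on one table.
#'
#' @inheritParams hotspots_index
#' @inheritParams hothours_index
#' @return Data frame `station_id, hotspots, hothours, n_timestamps_used`
#'   (`n_timestamps_used` is the Hothours eligible count).
#' @export
station_indices <- function(loggers, window = 12,
                            baseline = c("per-timestamp", "scalar")) {
  hs <- hotspots_index(loggers, baseline)
  hh <- hothours_index(loggers, window)
  data.frame(station_id = hs$station_id, hotspots = hs$hotspots,
             hothours = hh$hothours, n_timestamps_used = hh$n_timestamps_used,
             stringsAsFactors = FALSE)
}
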
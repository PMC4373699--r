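#' Run the full landscape-genetics pipeline
#'
#' Chains every stage from inputs to result tables: thermal indices from
#' the logger grid, variogram fitting and ordinary kriging of depth and
#' both indices onto colonies, pairwise relatedness, simple and partial
#' Mantel tests (whole data set and per size class), AIC multi-model
#' inference with predictor weights, equal-count autocorrelograms with
#' neighbour thresholds, sPCA over space and depth networks with MEM
#' global/local randomization tests, and pairwise size-class AMOVA. All
#' numeric outputs are written as CSV into `out_dir` together with a
#' `manifest.json` recording every parameter; a fixed `seed` makes the run
#' byte-reproducible.
#'
#' The YAML config requires `seed` and either a `synthetic:` block
#' (parameters for [reef_config()]) or an `inputs:` block naming
#' `colony_file`, `logger_series` and `logger_stations`. Optional blocks
#' and their defaults: `permutations:` (`mantel` 9999, `amova` 9999,
#' `spca` 9999, `autocorrelogram` 200), `size_bins:` (`small_upper` 10,
#' `large_lowers` [30,40,60,90]), `variogram:` (`model` spherical,
#' `n_bins` 12), `autocorrelogram_bins` 10, `tail` two-sided,
#' `min_bin_n` 10.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  cf <- if (is.character(config)) yaml::read_yaml(config) else config
  need <- "seed"
  missing_keys <- setdiff(need, names(cf))
  if (!("synthetic" %in% names(cf)) && !("inputs" %in% names(cf)))
    missing_keys <- c(missing_keys, "synthetic|inputs")
  if (length(missing_keys))
    stop("config is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cf$seed)

  perms <- utils::modifyList(list(mantel = 9999, amova = 9999, spca = 9999,
                                  autocorrelogram = 200),
                             cf$permutations %||% list())
  vg <- utils::modifyList(list(model = "spherical", n_bins = 12),
                          cf$variogram %||% list())
  sb <- utils::modifyList(list(small_upper = 10,
                               large_lowers = c(30, 40, 60, 90)),
                          cf$size_bins %||% list())
  acor_bins <- cf$autocorrelogram_bins %||% 10
  tail <- cf$tail %||% "two-sided"
  min_bin_n <- cf$min_bin_n %||% 10

  if ("synthetic" %in% names(cf)) {
    syn <- cf$synthetic %||% list()
    syn$seed <- NULL  # pipeline seed governs all randomness
    reef <- generate_reef(do.call(reef_config, syn))
    colonies <- reef$colonies
    loggers <- reef$loggers
  } else {
    inp <- cf$inputs
    miss <- setdiff(c("colony_file", "logger_series", "logger_stations"),
                    names(inp))
    if (length(miss))
      stop("config is missing required key(s): ",
           paste(paste0("inputs.", miss), collapse = ", "))
    colonies <- read_colony_table(inp$colony_file)
    loggers <- read_logger_series(inp$logger_series, inp$logger_stations)
  }
  wr <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                            row.names = FALSE)

  idx <- station_indices(loggers)
  wr(idx, "station_indices.csv")

  kriged <- list()
  for (v in c("depth", "hotspots", "hothours")) {
    vals <- if (v == "depth") loggers$stations$depth else idx[[v]]
    kr <- krige_to_colonies(loggers, vals, colonies,
                            model = vg$model, n_bins = vg$n_bins)
    kriged[[v]] <- kr
    colonies[[paste0("kriged_", v)]] <- kr$field$pred
  }
  colonies$hotspots <- pmin(1, pmax(0, colonies$kriged_hotspots))
  colonies$hothours <- pmin(1, pmax(0, colonies$kriged_hothours))
  wr(as.data.frame(colonies), "colonies_kriged.csv")

  rel <- moran_relationship(colonies)
  dists <- list(
    space = distance_matrix(colonies[, c("x", "y")], colonies$colony_id,
                            "space-distance"),
    depth = distance_matrix(colonies$depth, colonies$colony_id,
                            "depth-distance"),
    hotspots = distance_matrix(colonies$hotspots, colonies$colony_id,
                               "hotspots-distance"),
    hothours = distance_matrix(colonies$hothours, colonies$colony_id,
                               "hothours-distance"))

  # Table 1 analog: simple + partial Mantel per variable + predictor weights
  control_of <- c(depth = "space", space = "depth", hotspots = "space",
                  hothours = "space")
  t1 <- do.call(rbind, lapply(names(control_of), function(v) {
    sm <- simple_mantel(rel, dists[[v]], n_perm = perms$mantel, tail = tail)
    pm <- partial_mantel(rel, dists[[v]], dists[[control_of[[v]]]],
                         n_perm = perms$mantel, tail = tail)
    data.frame(variable = v, mantel_r = sm$r, mantel_p = sm$p,
               controlling = control_of[[v]], partial_r = pm$r,
               partial_p = pm$p, stringsAsFactors = FALSE)
  }))
  fits <- fit_all_models(pairwise_model_data(rel, dists))
  ranking <- rank_models(fits)
  wp <- predictor_weights(fits)
  t1$w_plus <- wp[t1$variable]
  wr(t1, "table1_mantel.csv")
  wr(ranking, "table3_model_selection.csv")
  wr(data.frame(variable = names(wp), w_plus = wp), "predictor_weights.csv")

  # Table 2 analog + AMOVA, if areas exist
  t2 <- NULL
  fst_tab <- NULL
  if (any(!is.na(colonies$area))) {
    bins <- make_size_bins(sb$small_upper, sb$large_lowers)
    t2 <- size_class_tests(colonies, rel, dists, bins,
                           n_perm = perms$mantel, tail = tail,
                           min_n = min_bin_n)
    wr(t2, "table2_size_classes.csv")
    small <- colonies[!is.na(colonies$area) &
                        colonies$area < sb$small_upper, ]
    fst_rows <- list()
    for (b in sb$large_lowers) {
      big <- colonies[!is.na(colonies$area) & colonies$area > b, ]
      res <- try(pairwise_fst(small, big, n_perm = perms$amova), silent = TRUE)
      if (inherits(res, "try-error")) next
      fst_rows[[length(fst_rows) + 1L]] <-
        data.frame(small = paste0("<", sb$small_upper), large = paste0(">", b),
                   fst = res$fst, p = res$p, n1 = res$n1, n2 = res$n2)
    }
    if (length(fst_rows)) {
      fst_tab <- do.call(rbind, fst_rows)
      wr(fst_tab, "amova_fst.csv")
    }
  } else message("no size data: size-class and AMOVA stages skipped")

  # autocorrelograms, neighbour thresholds, sPCA on both networks
  X <- individual_allele_matrix(colonies, center = TRUE)
  spca_out <- list()
  for (net_var in c("space", "depth")) {
    ac <- autocorrelogram(rel, dists[[net_var]], n_bins = acor_bins,
                          n_perm = perms$autocorrelogram)
    wr(ac, paste0("autocorrelogram_", net_var, ".csv"))
    thr <- try(neighbor_threshold(ac), silent = TRUE)
    if (inherits(thr, "try-error")) {
      # fall back: connect the closest decile of pairs
      thr <- as.numeric(stats::quantile(offdiag(dists[[net_var]]), 0.1))
      message(net_var, " autocorrelogram shows no significant bin; ",
              "neighbour threshold set to the 10% distance quantile")
    }
    net <- build_network(if (net_var == "space") colonies[, c("x", "y")]
                         else colonies$depth, thr, colonies$colony_id)
    sp <- spca(X, net)
    flt <- mem_filters(net)
    gl <- if (ncol(flt$global)) global_local_test(X, flt$global,
                                                  n_perm = perms$spca)
    lc <- if (ncol(flt$local)) global_local_test(X, flt$local,
                                                 n_perm = perms$spca)
    spca_out[[net_var]] <- list(threshold = thr, network = net, spca = sp,
                                global = gl, local = lc)
    wr(data.frame(axis = seq_along(sp$eigenvalues),
                  eigenvalue = sp$eigenvalues, var = sp$var,
                  moran = sp$moran),
       paste0("spca_", net_var, "_eigen.csv"))
    wr(data.frame(colony_id = colonies$colony_id, x = colonies$x,
                  y = colonies$y, score1 = sp$scores[, 1],
                  lagged1 = sp$lagged[, 1]),
       paste0("spca_", net_var, "_scores.csv"))
    wr(data.frame(kind = c("global", "local"),
                  statistic = c(if (is.null(gl)) NA else gl$statistic,
                                if (is.null(lc)) NA else lc$statistic),
                  p = c(if (is.null(gl)) NA else gl$p,
                        if (is.null(lc)) NA else lc$p)),
       paste0("spca_", net_var, "_tests.csv"))
  }

  manifest <- list(seed = cf$seed, permutations = perms, variogram = vg,
                   size_bins = sb, autocorrelogram_bins = acor_bins,
                   tail = tail, min_bin_n = min_bin_n,
                   n_colonies = nrow(colonies),
                   n_stations = nrow(loggers$stations),
                   synthetic = cf$synthetic %||% NULL,
                   inputs = cf$inputs %||% NULL,
                   partial_mantel_scheme = "permute relatedness (response) matrix",
                   caveat = "pairwise observations treated as independent in AIC likelihoods")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(colonies = colonies, indices = idx, kriged = kriged,
                 relatedness = rel, dists = dists, table1 = t1,
                 table2 = t2, ranking = ranking, predictor_weights = wp,
                 fst = fst_tab, spca = spca_out))
}
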
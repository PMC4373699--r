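#' Read a colony table
#'
#' Reads a delimited text file of coral colonies: one row per colony with
#' planar coordinates, tide-standardized depth, planar surface area and a
#' 6-locus diploid microsatellite genotype stored as 12 integer allele
#' columns (locus-major, SPAGeDi-style: `L1.1, L1.2, ..., L6.2`).
#'
#' Rows with any missing allele call (the `missing` sentinel, 0 by default)
#' are dropped and the drop count reported via [message()]. Area may be
#' missing (`NA`); such colonies are retained but excluded later from
#' size-class analyses.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator (default `","`).
#' @param missing Sentinel allele value marking a failed call (default `0`).
#' @param genotype_prefix Prefix of the 12 genotype columns (default `"L"`,
#'   matching names `L<locus>.<1|2>`).
#' @return A `data.frame` of class `colony_table` with columns `colony_id`,
#'   `x`, `y`, `depth`, `area` and the 12 allele columns. Attribute
#'   `n_dropped` records how many incomplete genotypes were removed.
#' @export
read_colony_table <- function(path, sep = ",", missing = 0, genotype_prefix = "L") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("colony_id", "x", "y", "depth")
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("colony table is missing required column(s): ", paste(absent, collapse = ", "))
  gcols <- grep(paste0("^", genotype_prefix, "[0-9]+\\.[12]$"), names(raw), value = TRUE)
  if (length(gcols) != 12L)
    stop("expected 12 genotype columns '", genotype_prefix,
         "<locus>.<1|2>', found ", length(gcols))
  gcols <- gcols[order(as.integer(sub("\\..*$", "", sub(paste0("^", genotype_prefix), "", gcols))),
                       as.integer(sub("^.*\\.", "", gcols)))]

  dup <- raw$colony_id[duplicated(raw$colony_id)]
  if (length(dup))
    stop("duplicate colony_id: ", paste(unique(dup), collapse = ", "))

  num_or_die <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(is.na(raw[[col]]) | raw[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           ": '", raw[[col]][bad[1]], "'")
    v
  }
  tab <- data.frame(colony_id = raw$colony_id,
                    x = num_or_die("x"), y = num_or_die("y"),
                    depth = num_or_die("depth"),
                    area = if ("area" %in% names(raw)) num_or_die("area") else NA_real_,
                    stringsAsFactors = FALSE)
  if (anyNA(tab$x) || anyNA(tab$y))
    stop("missing coordinate at row ", which(is.na(tab$x) | is.na(tab$y))[1])
  geno <- vapply(gcols, num_or_die, numeric(nrow(raw)))
  if (nrow(raw) == 1L) geno <- matrix(geno, nrow = 1L, dimnames = list(NULL, gcols))
  colnames(geno) <- paste0("L", rep(1:6, each = 2), ".", rep(1:2, 6))

  complete <- rowSums(is.na(geno) | geno == missing) == 0L
  n_drop <- sum(!complete)
  if (n_drop) message(n_drop, " colony(ies) dropped for incomplete genotypes")
  tab <- cbind(tab[complete, , drop = FALSE], as.data.frame(geno[complete, , drop = FALSE]))
  rownames(tab) <- NULL
  validate_colony_table(tab)
  structure(tab, n_dropped = n_drop, class = c("colony_table", "data.frame"))
}

#' Write a colony table
#'
#' Inverse of [read_colony_table()]; round-trips exactly for valid tables.
#'
#' @param tab A `colony_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_colony_table <- function(tab, path, sep = ",") {
  utils::write.table(as.data.frame(tab), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

genotype_columns <- function(tab) paste0("L", rep(1:6, each = 2), ".", rep(1:2, 6))

validate_colony_table <- function(tab) {
  if (anyDuplicated(tab$colony_id)) stop("duplicate colony_id")
  if (any(tab$depth < 0, na.rm = TRUE)) stop("negative depth")
  if (any(tab$area <= 0, na.rm = TRUE)) stop("non-positive area")
  gc <- genotype_columns(tab)
  if (!all(gc %in% names(tab))) stop("genotype columns missing")
  for (f in c("hotspots", "hothours"))
    if (f %in% names(tab) && any(tab[[f]] < 0 | tab[[f]] > 1, na.rm = TRUE))
      stop(f, " outside [0,1]")
  invisible(tab)
}

#' Construct a colony table from components
#'
#' @param colony_id Character vector of unique ids.
#' @param x,y Planar coordinates in metres.
#' @param depth Tide-standardized depth in metres, positive down.
#' @param genotypes Integer matrix `n x 12` of allele labels, locus-major.
#' @param area Planar surface area in cm^2 (`NA` allowed).
#' @return A `colony_table`.
#' @export
colony_table <- function(colony_id, x, y, depth, genotypes, area = NA_real_) {
  genotypes <- as.matrix(genotypes)
  stopifnot(ncol(genotypes) == 12L, nrow(genotypes) == length(colony_id))
  colnames(genotypes) <- paste0("L", rep(1:6, each = 2), ".", rep(1:2, 6))
  tab <- data.frame(colony_id = as.character(colony_id), x = x, y = y,
                    depth = depth, area = area, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(genotypes))
  validate_colony_table(tab)
  structure(tab, class = c("colony_table", "data.frame"))
}

#' Read temperature-logger series
#'
#' Reads a long-format series file (`station_id, timestamp, temperature`) and
#' a station metadata file (`station_id, x, y, depth`) and aligns all stations
#' onto the common regular timestamp grid. Timestamps may be numeric (hours)
#' or parseable date-times; internally they are hours from the first reading.
#'
#' Stations missing more than `max_missing` of the grid are rejected (with a
#' message); the aligned collection is then restricted to timestamps present
#' for every retained station, so downstream cross-station statistics never
#' mix incomplete rows.
#'
#' @param series_path Long-format readings file.
#' @param stations_path Station metadata file.
#' @param sep Field separator.
#' @param max_missing Maximum tolerated fraction of missing readings per
#'   station (default 0.1).
#' @return A `logger_set`: list with `stations` (data.frame), `time` (hours),
#'   `temp` (matrix, time x station) and `step` (hours).
#' @export
read_logger_series <- function(series_path, stations_path, sep = ",",
                               max_missing = 0.1) {
  ser <- utils::read.table(series_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  st <- utils::read.table(stations_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("station_id", "timestamp", "temperature") %in% names(ser)),
            all(c("station_id", "x", "y", "depth") %in% names(st)))
  unknown <- setdiff(unique(ser$station_id), st$station_id)
  if (length(unknown))
    stop("series contains unknown station(s): ", paste(unknown, collapse = ", "))
  ts <- ser$timestamp
  if (!is.numeric(ts)) {
    tt <- as.POSIXct(ts, tz = "UTC")
    if (anyNA(tt)) stop("unparseable timestamps")
    ts <- as.numeric(difftime(tt, min(tt), units = "hours"))
  }
  grid <- sort(unique(ts))
  steps <- diff(grid)
  if (length(grid) < 2L) stop("need at least 2 timestamps")
  step <- stats::median(steps)
  if (any(abs(steps - step) > 1e-6 * max(step, 1)))
    stop("irregular timestamp step: observed steps ",
         paste(signif(sort(unique(round(steps, 6))), 4), collapse = ", "))
  logger_set_from_long(ser$station_id, ts, ser$temperature, st, grid, step,
                       max_missing)
}

logger_set_from_long <- function(ids, ts, temp, stations, grid, step, max_missing) {
  keep <- character(0)
  cols <- list()
  for (sid in stations$station_id) {
    sel <- ids == sid
    v <- rep(NA_real_, length(grid))
    v[match(ts[sel], grid)] <- temp[sel]
    miss <- mean(is.na(v))
    if (miss > max_missing) {
      message("station ", sid, " rejected: ", round(100 * miss, 1),
              "% of readings missing")
      next
    }
    keep <- c(keep, sid)
    cols[[sid]] <- v
  }
  if (!length(keep)) stop("no station passed the completeness threshold")
  temp_mat <- do.call(cbind, cols)
  ok <- rowSums(is.na(temp_mat)) == 0L
  temp_mat <- temp_mat[ok, , drop = FALSE]
  grid <- grid[ok]
  logger_set(stations[match(keep, stations$station_id), , drop = FALSE],
             grid, temp_mat, step)
}

#' Construct a logger set
#'
#' @param stations Data frame with `station_id, x, y, depth`.
#' @param time Numeric timestamp grid (hours), strictly increasing, constant step.
#' @param temp Temperature matrix, `length(time)` rows x `nrow(stations)` columns.
#' @param step Grid step in hours (inferred if missing).
#' @return A `logger_set`.
#' @export
logger_set <- function(stations, time, temp, step = NULL) {
  temp <- as.matrix(temp)
  stopifnot(nrow(temp) == length(time), ncol(temp) == nrow(stations))
  if (is.unsorted(time, strictly = TRUE)) stop("timestamps must be strictly increasing")
  if (is.null(step)) step <- stats::median(diff(time))
  colnames(temp) <- stations$station_id
  structure(list(stations = as.data.frame(stations), time = as.numeric(time),
                 temp = temp, step = step),
            class = "logger_set")
}

#' @export
print.logger_set <- function(x, ...) {
  cat("Logger set:", ncol(x$temp), "stations,", nrow(x$temp),
      "timestamps at", x$step, "h step\n")
  invisible(x)
}

#' @export
print.colony_table <- function(x, ...) {
  cat("Colony table:", nrow(x), "colonies, 6 loci; depth",
      paste(signif(range(x$depth), 3), collapse = "-"), "m\n")
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}
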
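#' Construct a trap array
#'
#' A trap array is the ordered set of camera stations (detectors) of a
#' survey. Coordinates are planar metres in an already-projected coordinate
#' system; all distances in the package are Euclidean, so geographic
#' lat/long must be projected before use. The row order is stable and
#' defines the column order of capture histories.
#'
#' @param id character vector of unique detector identifiers.
#' @param x,y numeric detector coordinates in metres.
#' @return A `trap_array`: a data frame with columns `id`, `x`, `y`.
#' @examples
#' traps <- trap_array(c("S01", "S02"), x = c(0, 2000), y = c(0, 0))
#' @export
trap_array <- function(id, x, y) {
  id <- as.character(id)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(id) < 1) stop("a trap array needs at least one detector")
  if (length(x) != length(id) || length(y) != length(id))
    stop("id, x and y must have equal length")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate detector id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("trap coordinates must be finite numbers")
  out <- data.frame(id = id, x = x, y = y, stringsAsFactors = FALSE)
  class(out) <- c("trap_array", "data.frame")
  out
}

#' Regular rectangular trap grid
#'
#' Convenience constructor for an `nx` by `ny` grid of stations at fixed
#' spacing, the canonical layout of a systematic camera-trap survey.
#'
#' @param nx,ny number of columns and rows of stations.
#' @param spacing distance between neighbouring stations in metres.
#' @param origin numeric length-2 vector, coordinates of the first station.
#' @return A [trap_array()].
#' @export
trap_grid <- function(nx, ny, spacing = 2000, origin = c(0, 0)) {
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  trap_array(sprintf("S%02d", seq_len(nrow(g))),
             x = origin[1] + g$ix * spacing,
             y = origin[2] + g$iy * spacing)
}

#' @export
print.trap_array <- function(x, ...) {
  cat("Trap array:", nrow(x), "detectors\n")
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Construct a deduplicated detection record set
#'
#' Detection records are individual-by-detector-by-day camera records.
#' Multiple photographs of the same individual at the same station on the
#' same day carry no extra spatial information under a daily proximity
#' detector, so they are collapsed to a single record on construction; the
#' number of rows removed is kept in the `duplicates_removed` attribute.
#'
#' @param records data frame with columns `individual`, `sex`, `detector`,
#'   `day` (1-based integer occasion index).
#' @param traps the [trap_array()] the records refer to.
#' @param total_days length of the survey in daily occasions.
#' @return A `detection_records` data frame (one row per unique
#'   individual/detector/day) with attributes `total_days`,
#'   `duplicates_removed` and `traps`.
#' @export
detection_records <- function(records, traps, total_days) {
  stopifnot(inherits(traps, "trap_array"))
  total_days <- as.integer(total_days)
  if (is.na(total_days) || total_days < 1) stop("total_days must be >= 1")
  need <- c("individual", "sex", "detector", "day")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  rec <- data.frame(individual = as.character(records$individual),
                    sex = normalize_sex(records$sex),
                    detector = as.character(records$detector),
                    day = as.integer(records$day),
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(rec$detector), traps$id)
  if (length(bad))
    stop("detector id(s) not in trap array: ", paste(bad, collapse = ", "))
  if (nrow(rec) && (any(rec$day < 1) || any(rec$day > total_days)))
    stop("day outside [1, ", total_days, "]")
  dup <- duplicated(rec[c("individual", "detector", "day")])
  out <- rec[!dup, , drop = FALSE]
  out <- out[order(out$individual, out$day, out$detector), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            total_days = total_days,
            duplicates_removed = sum(dup),
            traps = traps,
            class = c("detection_records", "data.frame"))
}

# map arbitrary sex labels onto male / female / unknown
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep("unknown", length(s))
  out[s %in% c("m", "male")] <- "male"
  out[s %in% c("f", "female")] <- "female"
  out
}

#' @export
as.data.frame.detection_records <- function(x, ...) {
  strip_to_data_frame(x)
}

# drop subclass and bookkeeping attributes, keep the columns
strip_to_data_frame <- function(x) {
  out <- x
  attributes(out) <- list(names = names(x),
                          row.names = attr(x, "row.names"),
                          class = "data.frame")
  out
}

#' @export
print.detection_records <- function(x, ...) {
  cat("Detection records:", nrow(x), "unique individual/station/day records\n")
  cat("  individuals:", length(unique(x$individual)),
      " survey days:", attr(x, "total_days"),
      " duplicates removed on ingest:", attr(x, "duplicates_removed"), "\n")
  invisible(x)
}

#' Read a trap layout file
#'
#' Comma-delimited text with header `id,x,y`; coordinates in projected
#' metres. File order is preserved.
#'
#' @param path file path.
#' @return A [trap_array()].
#' @export
read_traps <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "x", "y") %in% names(d)))
    stop("trap file must have header id,x,y")
  x <- suppressWarnings(as.numeric(d$x))
  y <- suppressWarnings(as.numeric(d$y))
  if (anyNA(x) || anyNA(y)) stop("non-numeric coordinate in trap file")
  trap_array(d$id, x, y)
}

#' Write a trap layout file
#' @param traps a [trap_array()].
#' @param path file path.
#' @export
write_traps <- function(traps, path) {
  utils::write.csv(format_num_df(as.data.frame(traps)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a capture (detection) file
#'
#' Expects header `individual,sex,detector,day`, or
#' `individual,sex,detector,date` with ISO-8601 dates plus a `start_date`,
#' in which case `day = date - start_date + 1`. Records are deduplicated to
#' one per individual/detector/day on ingest.
#'
#' @param path file path.
#' @param traps the [trap_array()] the records refer to.
#' @param total_days survey length in days.
#' @param start_date optional `Date` (or ISO string) mapping dates to
#'   occasion indices.
#' @return A [detection_records()] set.
#' @export
read_captures <- function(path, traps, total_days, start_date = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("individual", "sex", "detector") %in% names(d)))
    stop("capture file must have columns individual,sex,detector and day (or date)")
  if (!"day" %in% names(d)) {
    if (!"date" %in% names(d))
      stop("capture file must have a day or date column")
    if (is.null(start_date))
      stop("a date column needs start_date to define occasion 1")
    d$day <- as.integer(as.Date(d$date) - as.Date(start_date)) + 1L
  }
  detection_records(d, traps, total_days)
}

#' Write a capture file
#' @param records a [detection_records()] set.
#' @param path file path.
#' @export
write_captures <- function(records, path) {
  utils::write.csv(as.data.frame(records)[c("individual", "sex", "detector", "day")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read GPS tracks
#'
#' Expects header `animal,day,x,y` (metres). Returns one track per animal
#' with fixes sorted by day; an empty file yields an empty list.
#'
#' @param path file path.
#' @return Named list of `track` data frames (`animal`, `day`, `x`, `y`).
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("animal", "day", "x", "y") %in% names(d)))
    stop("track file must have header animal,day,x,y")
  if (nrow(d) == 0) return(structure(list(), names = character(0)))
  x <- suppressWarnings(as.numeric(d$x))
  y <- suppressWarnings(as.numeric(d$y))
  if (anyNA(x) || anyNA(y)) stop("non-numeric coordinate in track file")
  d$x <- x; d$y <- y
  lapply(split(d, d$animal), function(td) {
    track(td$animal[1], day = td$day, x = td$x, y = td$y)
  })
}

#' Construct a GPS track
#' @param animal animal identifier.
#' @param day integer day index of each fix.
#' @param x,y fix coordinates in metres.
#' @return A `track` data frame sorted by day.
#' @export
track <- function(animal, day, x, y) {
  if (length(day) < 1) stop("a track needs at least one fix")
  o <- order(day)
  out <- data.frame(animal = as.character(animal), day = as.integer(day)[o],
                    x = as.numeric(x)[o], y = as.numeric(y)[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("track", "data.frame")
  out
}

#' Write GPS tracks
#' @param tracks a single `track` or list of tracks.
#' @param path file path.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "track")) tracks <- list(tracks)
  d <- do.call(rbind, lapply(tracks, as.data.frame))
  utils::write.csv(format_num_df(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# write.csv via format() loses digits; force full precision on numerics
format_num_df <- function(d) {
  for (j in seq_along(d))
    if (is.double(d[[j]])) d[[j]] <- formatC(d[[j]], digits = 15, format = "g")
  d
}

#' Write per-session results
#'
#' One row per session: window endpoints, density (per km^2) with 95% CI,
#' g0 and sigma (metres) with 95% CIs, log-likelihood, convergence flag and
#' the sample-size summaries. Numeric fields survive a write/read
#' round-trip to at least 10 significant digits.
#'
#' @param x a `session_series` (see [batch_fit()]) or a single [fit_scr()]
#'   result.
#' @param path file path.
#' @export
write_results <- function(x, path) {
  d <- results_frame(x)
  utils::write.csv(format_num_df(d), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results file written by [write_results()]
#' @param path file path.
#' @return Data frame with the results columns.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

results_frame <- function(x) {
  cols <- c("start", "end", "D", "D_lo", "D_hi", "g0", "g0_lo", "g0_hi",
            "sigma", "sigma_lo", "sigma_hi", "logLik", "converged",
            "n_individuals", "n_detections", "n_spatial_recaptures")
  if (inherits(x, "session_series")) {
    d <- as.data.frame(x)
    d$n_individuals <- d$n_fitted
    d$n_detections <- d$det_fitted
    d$n_spatial_recaptures <- d$spatial_recaptures
    return(d[cols])
  }
  if (inherits(x, "scr_fit")) {
    ci <- x$ci95
    d <- data.frame(start = NA_integer_, end = NA_integer_,
                    D = x$params$D, D_lo = ci["D", 1], D_hi = ci["D", 2],
                    g0 = x$params$g0, g0_lo = ci["g0", 1], g0_hi = ci["g0", 2],
                    sigma = x$params$sigma,
                    sigma_lo = ci["sigma", 1], sigma_hi = ci["sigma", 2],
                    logLik = x$logLik, converged = x$converged,
                    n_individuals = x$n, n_detections = sum(x$counts),
                    n_spatial_recaptures = sum(rowSums(x$counts > 0) - 1L))
    if (!is.null(x$window)) { d$start <- x$window[1]; d$end <- x$window[2] }
    return(d[cols])
  }
  stop("write_results expects a session_series or scr_fit")
}

#' @export
as.data.frame.trap_array <- function(x, ...) strip_to_data_frame(x)

#' @export
as.data.frame.track <- function(x, ...) strip_to_data_frame(x)
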
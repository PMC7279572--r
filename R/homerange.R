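#' 100% minimum convex polygon home range
#'
#' The convex hull of all fixes, with area by the polygon shoelace formula.
#' Fewer than three distinct fixes, or collinear fixes, give a degenerate
#' range of area zero.
#'
#' @param fixes a [track()], or a matrix/data frame with `x`, `y` columns
#'   in metres.
#' @param animal optional label (taken from the track when present).
#' @return A `home_range` list: `animal`, `area_km2`, `vertices`
#'   (counter-clockwise hull polygon, metres), `n_fixes`, `degenerate`.
#' @examples
#' sq <- cbind(x = c(0, 0, 1000, 1000), y = c(0, 1000, 0, 1000))
#' mcp_area(sq)$area_km2  # 1
#' @export
mcp_area <- function(fixes, animal = NA_character_) {
  if (inherits(fixes, "track") && is.na(animal)) animal <- fixes$animal[1]
  xy <- as.matrix(as.data.frame(fixes)[, c("x", "y")])
  storage.mode(xy) <- "double"
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  n <- nrow(xy)
  if (n < 3) {
    return(structure(list(animal = animal, area_km2 = 0,
                          vertices = xy, n_fixes = n, degenerate = TRUE),
                     class = "home_range"))
  }
  h <- grDevices::chull(xy)          # clockwise vertex indices
  v <- xy[rev(h), , drop = FALSE]    # counter-clockwise
  area <- shoelace_area(v) / 1e6
  structure(list(animal = animal, area_km2 = area, vertices = v,
                 n_fixes = n, degenerate = area == 0),
            class = "home_range")
}

# signed shoelace area of a counter-clockwise polygon, m^2
shoelace_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' @export
print.home_range <- function(x, ...) {
  cat("100% MCP", if (!is.na(x$animal)) paste0("(", x$animal, ")"), ":",
      signif(x$area_km2, 4), "km^2 from", x$n_fixes, "fixes",
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' Rolling-window MCP home ranges
#'
#' MCPs over the same shifting windows as the density estimates: windows of
#' `L` days stepped by `step` across the track's day span, `span - L + 1`
#' windows for step 1. Windows with fewer than three usable fixes yield
#' degenerate zero-area entries.
#'
#' @param track a [track()].
#' @param L window length in days (default 90).
#' @param step window step (default 1).
#' @return List of [mcp_area()] results, one per window, each carrying a
#'   `window` element `c(start, end)` in the track's day indexing.
#' @export
rolling_mcp <- function(track, L = 90, step = 1) {
  stopifnot(inherits(track, "track"))
  d0 <- min(track$day)
  span <- max(track$day) - d0 + 1L
  if (span < L) stop("track spans fewer days than the window length")
  windows <- make_windows(span, L, step)
  lapply(seq_len(nrow(windows)), function(w) {
    lo <- d0 + windows$start[w] - 1L
    hi <- d0 + windows$end[w] - 1L
    hr <- mcp_area(track[track$day >= lo & track$day <= hi, , drop = FALSE],
                   animal = track$animal[1])
    hr$window <- c(lo, hi)
    hr
  })
}

#' Sigma equivalent of a circular home-range area
#'
#' Under a half-normal detection function and a roughly circular home
#' range with a single activity centre, home-range area relates to the SCR
#' spatial scale as `A = 18.86 sigma^2`; this inverts that relation,
#' `sigma = sqrt(A / 18.86)`.
#'
#' @param area home-range area in km^2.
#' @return Sigma in km.
#' @examples
#' sigma_from_area(150)  # ~2.8 km
#' @export
sigma_from_area <- function(area) {
  if (any(area < 0)) stop("area must be >= 0")
  sqrt(area / 18.86)
}

#' Circular home-range area equivalent of sigma
#'
#' The forward transform `A = 18.86 sigma^2`; exact inverse of
#' [sigma_from_area()].
#'
#' @param sigma SCR spatial scale in km.
#' @return Area in km^2.
#' @export
area_from_sigma <- function(sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  18.86 * sigma^2
}

#' Maximum between-station movement per individual
#'
#' For every individual detected at two or more distinct detectors, the
#' maximum pairwise Euclidean distance between those detectors, ranked
#' descending (rank 1 = widest-ranging; ties share the smaller rank).
#' Individuals seen at a single station carry no movement information and
#' are excluded. Distances are between detector coordinates, a lower bound
#' on the animal's true displacement.
#'
#' @param records a [detection_records()] set.
#' @param traps the [trap_array()].
#' @param sex `"male"`, `"female"` or `"all"`.
#' @return Data frame `individual`, `max_km`, `rank`, sorted by rank.
#' @export
max_station_distances <- function(records, traps,
                                  sex = c("male", "female", "all")) {
  sex <- match.arg(sex)
  stopifnot(inherits(records, "detection_records"))
  r <- as.data.frame(records)
  if (sex != "all") r <- r[r$sex == sex, , drop = FALSE]
  per <- lapply(split(r$detector, r$individual), unique)
  per <- per[lengths(per) >= 2]
  if (length(per) == 0)
    return(data.frame(individual = character(0), max_km = numeric(0),
                      rank = integer(0)))
  maxd <- vapply(per, function(det) {
    k <- match(det, traps$id)
    max(stats::dist(cbind(traps$x[k], traps$y[k]))) / 1000
  }, numeric(1))
  out <- data.frame(individual = names(maxd), max_km = unname(maxd))
  out$rank <- as.integer(rank(-out$max_km, ties.method = "min"))
  out <- out[order(out$rank, out$individual), , drop = FALSE]
  rownames(out) <- NULL
  out
}
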
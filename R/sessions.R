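#' Rolling session windows
#'
#' Windows `(d, d + L - 1)` for `d = 1, 1 + step, ...` while the window
#' fits inside the record: `floor((total_days - L) / step) + 1` windows.
#' With step 1 a 365-day record yields 276 90-day and 186 180-day windows.
#'
#' @param total_days length of the record in days.
#' @param L window length in days.
#' @param step shift between consecutive windows (default 1 day).
#' @return Data frame with columns `start`, `end`, `L`.
#' @examples
#' nrow(make_windows(365, 90))   # 276
#' nrow(make_windows(365, 180))  # 186
#' @export
make_windows <- function(total_days, L, step = 1) {
  total_days <- as.integer(total_days); L <- as.integer(L)
  step <- as.integer(step)
  if (L < 1 || L > total_days)
    stop("window length must satisfy 1 <= L <= total_days")
  if (step < 1) stop("step must be >= 1")
  start <- seq.int(1L, total_days - L + 1L, by = step)
  data.frame(start = start, end = start + L - 1L, L = L)
}

#' Spatial recaptures in a window
#'
#' A spatial recapture is a detection of an individual at a detector beyond
#' its first: per individual, (number of distinct detectors with at least
#' one in-window detection) minus one, floored at zero. Repeated detections
#' at a single station carry no spatial information and never count.
#'
#' @param records a [detection_records()] set.
#' @param window integer `c(start, end)`, or `NULL` for the whole record.
#' @param sex `"male"`, `"female"` or `"all"`.
#' @return List with `total` and named vector `per_individual`.
#' @export
spatial_recaptures <- function(records, window = NULL,
                               sex = c("male", "female", "all")) {
  sex <- match.arg(sex)
  stopifnot(inherits(records, "detection_records"))
  r <- as.data.frame(records)
  if (!is.null(window))
    r <- r[r$day >= window[1] & r$day <= window[2], , drop = FALSE]
  if (sex != "all") r <- r[r$sex == sex, , drop = FALSE]
  if (nrow(r) == 0)
    return(list(total = 0L, per_individual = stats::setNames(integer(0), character(0))))
  per <- vapply(split(r$detector, r$individual),
                function(d) length(unique(d)) - 1L, integer(1))
  list(total = sum(per), per_individual = per)
}

#' Demographic summary of a session window
#'
#' Counts of individuals and (deduplicated) detections by sex within the
#' window, plus total and mean-per-male spatial recaptures.
#'
#' @param records a [detection_records()] set.
#' @param window integer `c(start, end)`, inclusive.
#' @return One-row data frame: `start`, `end`, `n_male`, `n_female`,
#'   `det_male`, `det_female`, `spatial_recaptures` (male total),
#'   `mean_spatial_recaptures_per_male`.
#' @export
summarize_session <- function(records, window) {
  stopifnot(inherits(records, "detection_records"))
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2] || window[1] < 1)
    stop("window must be c(start, end) with 1 <= start <= end")
  r <- as.data.frame(records)
  r <- r[r$day >= window[1] & r$day <= window[2], , drop = FALSE]
  cnt <- function(sx) {
    rs <- r[r$sex == sx, , drop = FALSE]
    c(n = length(unique(rs$individual)), det = nrow(rs))
  }
  m <- cnt("male"); f <- cnt("female")
  sr <- spatial_recaptures(records, window, "male")
  nmale <- length(sr$per_individual)
  data.frame(start = window[1], end = window[2],
             n_male = unname(m["n"]), n_female = unname(f["n"]),
             det_male = unname(m["det"]), det_female = unname(f["det"]),
             spatial_recaptures = sr$total,
             mean_spatial_recaptures_per_male =
               if (nmale > 0) sr$total / nmale else 0)
}

#' Batch-fit the SCR model over rolling windows
#'
#' Builds the habitat mask once from the trap array, then for every rolling
#' window collapses the (sex-filtered) histories and fits the SCR model.
#' Sessions whose fit fails (no detections, sigma unidentifiable, optimizer
#' failure) appear in the series with `NA` estimates and the error message
#' in `error` — gaps are visible, never silently dropped. Each fit after
#' the first is warm-started from the previous optimum, which the rolling
#' design makes a near-optimal start.
#'
#' @param records a [detection_records()] set spanning the survey.
#' @param traps the [trap_array()].
#' @param L session length in days (90 and 180 are the conventional short
#'   and extended survey lengths).
#' @param sex sex whose density is estimated (default `"male"`).
#' @param buffer,spacing mask settings passed to [build_mask()].
#' @param step window step in days.
#' @param se compute SEs/CIs per session (disable for large simulation
#'   batches where only point estimates matter).
#' @return A `session_series` data frame: one row per window with the
#'   [summarize_session()] columns, the fitted-subset sizes (`n_fitted`,
#'   `det_fitted`), estimates `D` (per km^2), `g0`, `sigma` (m) with 95%
#'   CIs, `logLik`, `converged` and `error`. Attributes record `L`,
#'   `total_days`, `sex` and the mask settings.
#' @export
batch_fit <- function(records, traps, L, sex = "male", buffer = 30000,
                      spacing = 300, step = 1, se = TRUE) {
  stopifnot(inherits(records, "detection_records"))
  total_days <- attr(records, "total_days")
  if (total_days < L) stop("record is shorter than the session length")
  windows <- make_windows(total_days, L, step)
  mask <- build_mask(traps, buffer = buffer, spacing = spacing)

  rows <- vector("list", nrow(windows))
  prev <- NULL
  for (w in seq_len(nrow(windows))) {
    win <- c(windows$start[w], windows$end[w])
    smry <- summarize_session(records, win)
    hist <- collapse_histories(records, win, sex)
    # warm-started windows refit by BFGS alone; fall back to the full
    # simplex + BFGS route from fresh starts if that does not converge
    fit <- tryCatch(fit_scr(hist, traps, mask, start = prev, se = se,
                            simplex = is.null(prev)),
                    error = function(e) conditionMessage(e))
    if (inherits(fit, "scr_fit") && !fit$converged && !is.null(prev))
      fit <- tryCatch(fit_scr(hist, traps, mask, se = se),
                      error = function(e) conditionMessage(e))
    if (inherits(fit, "scr_fit")) {
      prev <- c(D = fit$params$D, g0 = fit$params$g0, sigma = fit$params$sigma)
      est <- data.frame(
        n_fitted = hist$n, det_fitted = sum(hist$counts),
        D = fit$params$D, D_lo = fit$ci95["D", 1], D_hi = fit$ci95["D", 2],
        g0 = fit$params$g0, g0_lo = fit$ci95["g0", 1],
        g0_hi = fit$ci95["g0", 2],
        sigma = fit$params$sigma, sigma_lo = fit$ci95["sigma", 1],
        sigma_hi = fit$ci95["sigma", 2],
        logLik = fit$logLik, converged = fit$converged,
        error = NA_character_)
    } else {
      est <- data.frame(
        n_fitted = hist$n, det_fitted = sum(hist$counts),
        D = NA_real_, D_lo = NA_real_, D_hi = NA_real_,
        g0 = NA_real_, g0_lo = NA_real_, g0_hi = NA_real_,
        sigma = NA_real_, sigma_lo = NA_real_, sigma_hi = NA_real_,
        logLik = NA_real_, converged = FALSE, error = fit)
    }
    rows[[w]] <- cbind(smry, est)
  }
  out <- do.call(rbind, rows)
  if (all(!is.na(out$error)))
    stop("all ", nrow(out), " sessions failed to fit; first error: ",
         out$error[1])
  out$session <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, L = L, total_days = total_days, sex = sex,
            mask_buffer = buffer, mask_spacing = spacing, step = step,
            class = c("session_series", "data.frame"))
}

#' @export
print.session_series <- function(x, ...) {
  d <- x$D * 100
  cat("Session series:", nrow(x), "windows of", attr(x, "L"),
      "days (step", attr(x, "step"), ") over", attr(x, "total_days"),
      "days;", attr(x, "sex"), "density\n")
  ok <- !is.na(d)
  cat(sprintf("  fitted: %d/%d; D per 100 km^2: mean %.2f, range %.2f-%.2f\n",
              sum(ok), nrow(x), mean(d[ok]), min(d[ok]), max(d[ok])))
  invisible(x)
}

#' @export
as.data.frame.session_series <- function(x, ...) {
  out <- x
  attributes(out) <- list(names = names(x),
                          row.names = attr(x, "row.names"),
                          class = "data.frame")
  out
}
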
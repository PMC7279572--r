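#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation on pairwise-complete observations; the
#' two-sided p-value comes from the t transform with n - 2 degrees of
#' freedom. Note that on overlapping rolling-window series these p-values
#' are anticonservative (consecutive sessions share most of their data);
#' they are reported at face value, as is conventional for such series
#' summaries, and should be read descriptively.
#'
#' @param x,y numeric vectors of equal length.
#' @return List `r`, `p`, `n` (pairs used).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Polynomial regression R-squared
#'
#' Ordinary least-squares fit of `y` on a degree-1 (linear) or degree-2
#' (curvilinear, i.e. quadratic) polynomial in `x`, with
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x,y numeric vectors.
#' @param degree 1 or 2.
#' @return List `r2`, `coefficients` (intercept first), `n`.
#' @export
fit_polynomial_r2 <- function(x, y, degree = 1) {
  if (!degree %in% 1:2) stop("degree must be 1 or 2")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) <= degree + 1) stop("need n > degree + 1 points")
  if (stats::sd(x) == 0) stop("degenerate design: x has zero variance")
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  list(r2 = summary(fit)$r.squared,
       coefficients = unname(stats::coef(fit)), n = length(x))
}

#' Precision (95% CI width) of the density series
#'
#' Per-session precision is the width of the 95% confidence interval for
#' density on the per-100-km^2 scale, `hi - lo`; the summary gives its
#' mean, minimum and maximum over sessions with available CIs.
#'
#' @param series a `session_series` from [batch_fit()].
#' @return List `widths` (per session, NA where the fit or its CI is
#'   missing), `mean`, `min`, `max`, `n`.
#' @export
precision_summary <- function(series) {
  stopifnot(inherits(series, "session_series"))
  w <- (series$D_hi - series$D_lo) * 100
  if (all(is.na(w))) stop("no sessions with confidence intervals")
  list(widths = w, mean = mean(w, na.rm = TRUE),
       min = min(w, na.rm = TRUE), max = max(w, na.rm = TRUE),
       n = sum(!is.na(w)))
}

series_variables <- c("D", "g0", "sigma", "n_male", "n_female",
                      "det_male", "det_female", "spatial_recaptures",
                      "mean_spatial_recaptures_per_male")

series_variable <- function(series, name) {
  if (!name %in% series_variables)
    stop("unknown series variable '", name, "'; choose from: ",
         paste(series_variables, collapse = ", "))
  v <- series[[name]]
  # report density per 100 km^2 and sigma in km, the conventional scales
  if (name == "D") v <- v * 100
  if (name == "sigma") v <- v / 1000
  v
}

#' Association table over a session series
#'
#' For each requested (x, y) variable pair: Pearson r with its p-value and
#' the linear and quadratic R^2, optionally restricted to a session index
#' subset (e.g. the first 160 sessions). Available variables: `D` (per
#' 100 km^2), `g0`, `sigma` (km), `n_male`, `n_female`, `det_male`,
#' `det_female`, `spatial_recaptures`,
#' `mean_spatial_recaptures_per_male`.
#'
#' @param series a `session_series` from [batch_fit()].
#' @param pairs list of character length-2 vectors `c(x, y)`, or a single
#'   such vector.
#' @param subset optional integer `c(first, last)` session index range.
#' @return Data frame: `x`, `y`, `n`, `pearson_r`, `p_value`, `linear_r2`,
#'   `quadratic_r2`, `subset_lo`, `subset_hi`.
#' @export
association_table <- function(series, pairs, subset = NULL) {
  stopifnot(inherits(series, "session_series"))
  if (is.character(pairs)) pairs <- list(pairs)
  idx <- seq_len(nrow(series))
  if (!is.null(subset)) {
    if (length(subset) != 2 || subset[1] < 1 || subset[2] > nrow(series) ||
        subset[1] > subset[2])
      stop("subset must be c(first, last) within the series")
    idx <- subset[1]:subset[2]
  }
  sub <- series[idx, , drop = FALSE]
  class(sub) <- class(series)
  rows <- lapply(pairs, function(pr) {
    x <- series_variable(sub, pr[1])
    y <- series_variable(sub, pr[2])
    pe <- pearson(x, y)
    lin <- fit_polynomial_r2(x, y, 1)
    qua <- fit_polynomial_r2(x, y, 2)
    data.frame(x = pr[1], y = pr[2], n = pe$n,
               pearson_r = pe$r, p_value = pe$p,
               linear_r2 = lin$r2, quadratic_r2 = qua$r2,
               subset_lo = idx[1], subset_hi = idx[length(idx)])
  })
  do.call(rbind, rows)
}
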
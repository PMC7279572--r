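#' Build a habitat mask
#'
#' The mask is a regular grid of candidate activity-centre locations over
#' which the SCR likelihood integrates. Points sit at the centres of
#' `spacing x spacing` cells tiling the trap bounding box expanded by
#' `buffer` on every side; each point represents a cell of area
#' `spacing^2 / 1e6` km^2. The buffer should be large enough (roughly 4
#' sigma) that individuals centred beyond it have negligible detection
#' probability.
#'
#' @param traps a [trap_array()].
#' @param buffer metres added around the trap bounding box (default 30 km,
#'   a conservative home-range radius allowance for a wide-ranging felid).
#' @param spacing grid step in metres (default 300 m).
#' @return A `habitat_mask`: data frame of `x`, `y` with attributes
#'   `spacing`, `buffer` and `area` (cell area, km^2).
#' @export
build_mask <- function(traps, buffer = 30000, spacing = 300) {
  stopifnot(inherits(traps, "trap_array"))
  if (buffer <= 0 || spacing <= 0) stop("buffer and spacing must be > 0")
  if (spacing > buffer)
    warning("mask spacing exceeds the buffer; the mask will be very coarse")
  x0 <- min(traps$x) - buffer; x1 <- max(traps$x) + buffer
  y0 <- min(traps$y) - buffer; y1 <- max(traps$y) + buffer
  nx <- ceiling((x1 - x0) / spacing)
  ny <- ceiling((y1 - y0) / spacing)
  g <- expand.grid(x = x0 + (seq_len(nx) - 0.5) * spacing,
                   y = y0 + (seq_len(ny) - 0.5) * spacing)
  structure(g, spacing = spacing, buffer = buffer,
            area = spacing^2 / 1e6,
            class = c("habitat_mask", "data.frame"))
}

#' @export
print.habitat_mask <- function(x, ...) {
  cat("Habitat mask:", nrow(x), "points, spacing", attr(x, "spacing"),
      "m, cell area", attr(x, "area"), "km^2, buffer",
      attr(x, "buffer"), "m\n")
  invisible(x)
}

#' Half-normal detection function
#'
#' `p(d) = g0 exp(-d^2 / (2 sigma^2))`: the per-occasion detection
#' probability for a detector at distance `d` from the activity centre.
#'
#' @param d distance in metres (vectorized).
#' @param g0 detection probability at distance zero.
#' @param sigma spatial scale in metres.
#' @return Probabilities in `[0, g0]`.
#' @examples
#' halfnormal_p(0, 0.06, 3600)      # g0 itself
#' halfnormal_p(3600, 0.06, 3600)   # g0 * exp(-1/2)
#' @export
halfnormal_p <- function(d, g0, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (any(d < 0)) stop("distances must be >= 0")
  g0 * exp(-d^2 / (2 * sigma^2))
}

#' Session detection probability p.(s)
#'
#' Probability that an individual with activity centre `s` is detected at
#' least once over `T` daily occasions on the whole trap array:
#' `1 - prod_k (1 - p_k(s))^T`. Summed over mask cells (times cell area)
#' this gives the effective sampling area linking the detected count to
#' density.
#'
#' @param s matrix or data frame of centre coordinates (columns x, y,
#'   metres); a length-2 vector is taken as one point.
#' @param traps a [trap_array()].
#' @param g0,sigma half-normal detection parameters.
#' @param T number of daily occasions.
#' @return Numeric vector of probabilities, one per point.
#' @export
pdot <- function(s, traps, g0, sigma, T) {
  if (T < 1) stop("T must be >= 1")
  if (is.null(dim(s))) s <- matrix(s, ncol = 2)
  s <- as.matrix(s)[, 1:2, drop = FALSE]
  d2 <- outer(s[, 1], traps$x, "-")^2 + outer(s[, 2], traps$y, "-")^2
  p <- pmin(halfnormal_p(sqrt(d2), g0, sigma), 1 - 1e-12)
  1 - exp(T * rowSums(log1p(-p)))
}

#' Collapse detection records to session capture histories
#'
#' Builds the n x K matrix of collapsed counts `n_ik`: the number of
#' distinct days within the window on which individual `i` was recorded at
#' detector `k`. Because the daily detection probability is constant within
#' a session, these binomial counts are sufficient for the likelihood.
#' Individuals with no in-window detection are excluded.
#'
#' @param records a [detection_records()] set.
#' @param window integer `c(start_day, end_day)`, inclusive.
#' @param sex `"male"`, `"female"` or `"all"`.
#' @return A `session_histories` list: `counts` (n x K matrix, rows named
#'   by individual, columns ordered as the trap array), `T`, `K`, `n`,
#'   `window`, `sex`.
#' @export
collapse_histories <- function(records, window, sex = c("male", "female", "all")) {
  sex <- match.arg(sex)
  stopifnot(inherits(records, "detection_records"))
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2] || window[1] < 1)
    stop("window must be c(start, end) with 1 <= start <= end")
  if (window[2] > attr(records, "total_days"))
    stop("window extends past total_days")
  traps <- attr(records, "traps")
  r <- records[records$day >= window[1] & records$day <= window[2], , drop = FALSE]
  if (sex != "all") r <- r[r$sex == sex, , drop = FALSE]
  ids <- sort(unique(r$individual))
  counts <- matrix(0L, nrow = length(ids), ncol = nrow(traps),
                   dimnames = list(ids, traps$id))
  if (nrow(r)) {
    tab <- table(factor(r$individual, levels = ids),
                 factor(r$detector, levels = traps$id))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, T = window[2] - window[1] + 1L,
                 K = nrow(traps), n = length(ids),
                 window = window, sex = sex),
            class = "session_histories")
}

#' @export
print.session_histories <- function(x, ...) {
  cat("Session histories: n =", x$n, "individuals, K =", x$K,
      "detectors, T =", x$T, "occasions (days", x$window[1], "to",
      x$window[2], ",", x$sex, ")\n")
  invisible(x)
}

# squared detector-to-mask-point distances, K x M
trap_mask_d2 <- function(traps, mask) {
  outer(traps$x, mask$x, "-")^2 + outer(traps$y, mask$y, "-")^2
}

#' SCR negative log-likelihood on the link scale
#'
#' Full (unconditional) likelihood of the closed-population SCR model with
#' Poisson-distributed number of detected individuals, half-normal
#' detection and a discretized habitat mask:
#' \deqn{\log L = \sum_i \log\left(D a \sum_m \Pr(\omega_i \mid s_m)\right)
#'   - D a \sum_m p_\cdot(s_m)}
#' with \eqn{\Pr(\omega_i \mid s) = \prod_k p_k(s)^{n_{ik}}
#' (1-p_k(s))^{T-n_{ik}}}. The additive `log(n!)` constant is dropped; this
#' convention is recorded in [fit_scr()] output metadata.
#'
#' @param par numeric length 3: `log(D)`, `logit(g0)`, `log(sigma)`.
#' @param hist a [collapse_histories()] result with `n >= 1`.
#' @param traps the [trap_array()].
#' @param mask a [build_mask()] result (or precomputed distances via `d2`).
#' @param d2 optional precomputed K x M squared-distance matrix, reused
#'   across repeated evaluations of the same geometry.
#' @return The negative log-likelihood value.
#' @export
scr_negloglik <- function(par, hist, traps, mask, d2 = NULL) {
  if (is.null(d2)) {
    if (nrow(mask) == 0) stop("habitat mask is empty")
    d2 <- trap_mask_d2(traps, mask)
  }
  scr_nll_cpp(as.numeric(par), hist$counts + 0, d2, hist$T, attr(mask, "area"))
}

link_transform <- function(par) {
  c(D = exp(par[1]), g0 = stats::plogis(par[2]), sigma = exp(par[3]))
}

# method-of-moments style starting values on the natural scale
scr_start_values <- function(hist, traps, mask) {
  counts <- hist$counts
  # half the mean per-individual maximum distance between its detectors
  maxd <- vapply(seq_len(nrow(counts)), function(i) {
    k <- which(counts[i, ] > 0)
    if (length(k) < 2) return(NA_real_)
    max(stats::dist(cbind(traps$x[k], traps$y[k])))
  }, numeric(1))
  dtr <- as.matrix(stats::dist(cbind(traps$x, traps$y)))
  diag(dtr) <- Inf
  nn <- mean(apply(dtr, 1, min))
  sigma0 <- suppressWarnings(max(mean(maxd, na.rm = TRUE) / 2, nn / 2, na.rm = TRUE))
  if (!is.finite(sigma0)) sigma0 <- sqrt(mean(trap_mask_d2(traps, mask))) / 2
  dpos <- dtr[is.finite(dtr)]
  decay <- if (length(dpos)) mean(exp(-dpos^2 / (2 * sigma0^2))) else 1
  g00 <- sum(counts) / (hist$n * hist$K * hist$T * decay)
  if (!is.finite(g00)) g00 <- 0.05
  g00 <- min(max(g00, 0.001), 0.5)
  a <- attr(mask, "area")
  esa <- a * sum(pdot(as.matrix(mask), traps, g00, sigma0, hist$T))
  D0 <- max(hist$n / esa, 1e-6)
  c(D = D0, g0 = g00, sigma = sigma0)
}

# central-difference Hessian of fn at par (step h on the link scale)
fd_hessian <- function(fn, par, h = 1e-4) {
  p <- length(par)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(par)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h)
    H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / h^2
    if (i < p) for (j in (i + 1):p) {
      ej <- replace(numeric(p), j, h)
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) -
         fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h^2)
    }
  }
  H
}

fd_gradient <- function(fn, par, h = 1e-3) {
  vapply(seq_along(par), function(i) {
    ei <- replace(numeric(length(par)), i, h)
    (fn(par + ei) - fn(par - ei)) / (2 * h)
  }, numeric(1))
}

#' Fit the SCR model by maximum likelihood
#'
#' Maximizes the full SCR likelihood over the link scale (`log D`,
#' `logit g0`, `log sigma`) with a derivative-free simplex start followed
#' by a quasi-Newton (BFGS) polish with numeric gradients. Standard errors
#' come from the inverse of a central-difference Hessian at the optimum;
#' 95% confidence intervals are Wald intervals on the link scale
#' back-transformed to the natural scale (lognormal-style for D and sigma,
#' logit-interval for g0).
#'
#' @param hist a [collapse_histories()] result. Needs at least one
#'   individual, and at least one individual detected at two or more
#'   detectors (otherwise sigma is unidentifiable).
#' @param traps the [trap_array()].
#' @param mask a [build_mask()] result.
#' @param start optional named vector `c(D, g0, sigma)` of natural-scale
#'   starting values; defaults to cheap method-of-moments analogues.
#' @param se if `FALSE`, skip the Hessian (no SEs or CIs); useful in large
#'   batch simulations where only point estimates are needed.
#' @param simplex if `FALSE`, skip the simplex stage and run BFGS directly
#'   from `start`; only sensible when `start` is already near the optimum,
#'   as in warm-started rolling-window refits.
#' @return An `scr_fit` list: `params` (`D` per km^2, `g0`, `sigma` m),
#'   `link` (estimates and SEs on the link scale), `ci95` (3 x 2 matrix),
#'   `logLik` (with `log(n!)` dropped, see `loglik_convention`),
#'   `converged`, `n`, `K`, `T`, `counts`, `window`, mask settings.
#' @export
fit_scr <- function(hist, traps, mask, start = NULL, se = TRUE,
                    simplex = TRUE) {
  stopifnot(inherits(hist, "session_histories"))
  if (hist$n == 0) stop("no detections: cannot fit SCR model")
  if (!any(rowSums(hist$counts > 0) >= 2))
    stop("sigma unidentifiable: no individual detected at >= 2 detectors")
  if (nrow(mask) == 0) stop("habitat mask is empty")
  d2 <- trap_mask_d2(traps, mask)
  a <- attr(mask, "area")
  counts <- hist$counts + 0  # numeric for the C++ kernel
  nll <- function(p) scr_nll_cpp(p, counts, d2, hist$T, a)
  # value + analytic gradient in one pass, cached for optim's fn/gr pairing
  last_par <- NULL; last <- NULL
  both <- function(p) {
    if (is.null(last_par) || !identical(p, last_par)) {
      last <<- scr_nll_grad_cpp(p, counts, d2, hist$T, a)
      last_par <<- p
    }
    last
  }
  nll_c <- function(p) both(p)$value
  gr_c <- function(p) both(p)$gradient

  if (is.null(start)) start <- scr_start_values(hist, traps, mask)
  p0 <- c(log(start[["D"]]), stats::qlogis(start[["g0"]]), log(start[["sigma"]]))

  if (simplex) {
    nm <- stats::optim(p0, nll, method = "Nelder-Mead",
                       control = list(reltol = 1e-6, maxit = 500))
    from <- nm$par
  } else {
    nm <- NULL
    from <- p0
  }
  qn <- tryCatch(
    stats::optim(from, nll_c, gr = gr_c, method = "BFGS",
                 control = list(reltol = 1e-8, maxit = 200)),
    error = function(e) nm)
  if (is.null(qn)) stop("BFGS failed from the supplied start")
  best <- if (!is.null(nm) && nm$value < qn$value) nm else qn

  grad <- gr_c(best$par)
  # gradient tolerance scaled to the objective magnitude: the attainable
  # gradient at a numerically converged optimum grows with |logLik|
  gtol <- max(0.01, 1e-4 * abs(best$value))
  converged <- (best$convergence == 0) && all(is.finite(grad)) &&
    max(abs(grad)) < gtol

  est <- link_transform(best$par)
  link_se <- rep(NA_real_, 3)
  ci <- matrix(NA_real_, 3, 2, dimnames = list(c("D", "g0", "sigma"),
                                               c("lo", "hi")))
  if (se) {
    H <- fd_hessian(nll, best$par)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      link_se <- sqrt(diag(V))
      lo <- best$par - 1.96 * link_se
      hi <- best$par + 1.96 * link_se
      ci[, 1] <- link_transform(lo)
      ci[, 2] <- link_transform(hi)
    } else {
      warning("Hessian not positive definite; SEs and CIs unavailable")
    }
  }

  structure(list(params = as.list(est),
                 link = list(estimate = stats::setNames(best$par,
                               c("logD", "logit_g0", "log_sigma")),
                             se = stats::setNames(link_se,
                               c("logD", "logit_g0", "log_sigma"))),
                 ci95 = ci, logLik = -best$value,
                 loglik_convention = "log(n!) dropped",
                 converged = converged, max_abs_gradient = max(abs(grad)),
                 n = hist$n, K = hist$K, T = hist$T,
                 counts = hist$counts, window = hist$window,
                 mask_spacing = attr(mask, "spacing"),
                 mask_buffer = attr(mask, "buffer")),
            class = "scr_fit")
}

#' @export
print.scr_fit <- function(x, ...) {
  cat("SCR fit (half-normal, full likelihood):",
      x$n, "individuals,", x$K, "detectors,", x$T, "occasions\n")
  est <- c(x$params$D * 100, x$params$g0, x$params$sigma / 1000)
  ci <- x$ci95
  tab <- data.frame(
    estimate = signif(est, 4),
    lo95 = signif(c(ci["D", 1] * 100, ci["g0", 1], ci["sigma", 1] / 1000), 4),
    hi95 = signif(c(ci["D", 2] * 100, ci["g0", 2], ci["sigma", 2] / 1000), 4),
    row.names = c("D (/100 km^2)", "g0 (/day)", "sigma (km)"))
  print(tab, ...)
  cat("logLik:", format(x$logLik), "(", x$loglik_convention, ")",
      if (x$converged) " converged\n" else " NOT converged\n")
  invisible(x)
}

#' Density on the per-100-km^2 scale
#'
#' @param fit an [fit_scr()] result.
#' @return Named vector `c(estimate, lo, hi)` of density per 100 km^2.
#' @export
density_per_100km2 <- function(fit) {
  stopifnot(inherits(fit, "scr_fit"))
  c(estimate = fit$params$D * 100,
    lo = unname(fit$ci95["D", 1]) * 100,
    hi = unname(fit$ci95["D", 2]) * 100)
}
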
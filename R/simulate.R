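#' Define a simulation scenario
#'
#' A scenario holds the population and detection-process parameters used to
#' generate synthetic camera-trap data: a homogeneous Poisson population of
#' activity centres over a rectangular region, daily Bernoulli detection at
#' proximity detectors under a half-normal detection function, and optional
#' multiplicative temporal modulation of `sigma` and `g0` emulating
#' seasonal changes in ranging behaviour and trail use.
#'
#' @param D individuals per km^2 (all sexes combined).
#' @param g0 daily detection probability for a detector at the activity
#'   centre, in `[0, 1)` (0 is the degenerate no-detection limit).
#' @param sigma half-normal spatial scale in metres.
#' @param sex_ratio_male fraction of individuals that are male.
#' @param total_days survey length in daily occasions.
#' @param region numeric `c(xmin, xmax, ymin, ymax)` in metres, the
#'   rectangle over which activity centres are placed. If `NULL` it is
#'   derived at simulation time from the trap bounding box expanded by
#'   `sim_buffer` on all sides.
#' @param sim_buffer metres by which the trap bounding box is expanded when
#'   `region` is `NULL`. The default 15 km is about 4 sigma for a
#'   wide-ranging felid, beyond which detection is negligible.
#' @param m_sigma,m_g0 optional functions of the day index returning a
#'   positive multiplier applied to `sigma` / `g0` on that day.
#' @param seed optional integer seed making all simulation from this
#'   scenario reproducible.
#' @return A `sim_scenario` list.
#' @seealso [scenario_jaguar()] for a ready-made trail-grid scenario.
#' @export
sim_scenario <- function(D, g0, sigma, sex_ratio_male = 0.5,
                         total_days = 365, region = NULL,
                         sim_buffer = 15000, m_sigma = NULL, m_g0 = NULL,
                         seed = NULL) {
  if (!is.null(D) && D < 0) stop("D must be >= 0")
  if (g0 < 0 || g0 >= 1) stop("g0 must lie in [0, 1)")
  if (sigma <= 0) stop("sigma must be > 0")
  if (sex_ratio_male < 0 || sex_ratio_male > 1)
    stop("sex_ratio_male must lie in [0, 1]")
  if (total_days < 1) stop("total_days must be >= 1")
  if (!is.null(region)) {
    if (length(region) != 4 || region[2] <= region[1] || region[4] <= region[3])
      stop("region must be c(xmin, xmax, ymin, ymax) with positive area")
  }
  for (f in list(m_sigma, m_g0)) {
    if (!is.null(f)) {
      if (!is.function(f)) stop("modulation must be a function of day")
      if (any(f(seq_len(total_days)) <= 0))
        stop("modulation multipliers must be > 0 for every day")
    }
  }
  structure(list(D = D, g0 = g0, sigma = sigma,
                 sex_ratio_male = sex_ratio_male, total_days = total_days,
                 region = region, sim_buffer = sim_buffer,
                 m_sigma = m_sigma, m_g0 = m_g0, seed = seed),
            class = "sim_scenario")
}

#' Trail-grid jaguar survey scenario
#'
#' A ready-made scenario emulating a year-long camera survey of a
#' low-density, wide-ranging felid on a trail grid: a 4 x 5 station grid at
#' 2 km spacing (20 detectors over roughly 120 km^2 with buffer), 365 daily
#' occasions, male density 2.0 per 100 km^2, `g0 = 0.06` per day and
#' `sigma = 3600` m. The overall density and male fraction are set so that
#' the male component has density exactly 0.02/km^2 while the simulated
#' male:female head-count ratio is about 21:12. Optional sinusoidal
#' modulation of sigma with a 365-day period emulates seasonal swings in
#' male ranging behaviour.
#'
#' @param modulation_amplitude amplitude `A` of
#'   `m_sigma(t) = 1 + A sin(2 pi t / 365)`; 0 disables modulation.
#' @param seed optional integer seed stored in the scenario.
#' @return List with elements `scenario` ([sim_scenario()]) and `traps`
#'   ([trap_array()], K = 20).
#' @examples
#' sc <- scenario_jaguar(seed = 1)
#' nrow(sc$traps)  # 20 stations
#' @export
scenario_jaguar <- function(modulation_amplitude = 0, seed = NULL) {
  traps <- trap_grid(nx = 4, ny = 5, spacing = 2000)
  m_sigma <- NULL
  if (modulation_amplitude != 0) {
    if (abs(modulation_amplitude) >= 1)
      stop("modulation_amplitude must have magnitude < 1")
    A <- modulation_amplitude
    m_sigma <- function(day) 1 + A * sin(2 * pi * day / 365)
  }
  sc <- sim_scenario(D = 0.02 * 33 / 21, g0 = 0.06, sigma = 3600,
                     sex_ratio_male = 21 / 33, total_days = 365,
                     sim_buffer = 15000, m_sigma = m_sigma, seed = seed)
  list(scenario = sc, traps = traps)
}

# run expr under a scenario/explicit seed, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

scenario_region <- function(scenario, traps = NULL) {
  if (!is.null(scenario$region)) return(scenario$region)
  if (is.null(traps)) stop("scenario has no region; supply a trap array")
  b <- scenario$sim_buffer
  c(min(traps$x) - b, max(traps$x) + b, min(traps$y) - b, max(traps$y) + b)
}

#' Simulate a population of activity centres
#'
#' Draws `N ~ Poisson(D x area)` individuals with activity centres placed
#' independently and uniformly over the scenario region, and sexes drawn
#' Bernoulli(`sex_ratio_male`).
#'
#' @param scenario a [sim_scenario()].
#' @param traps trap array used to derive the region when the scenario does
#'   not fix one.
#' @return A `population` data frame with columns `id`, `sex`, `x`, `y`.
#' @export
simulate_population <- function(scenario, traps = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  r <- scenario_region(scenario, traps)
  area_km2 <- (r[2] - r[1]) * (r[4] - r[3]) / 1e6
  if (area_km2 <= 0) stop("region has zero area")
  with_sim_seed(scenario$seed, {
    N <- stats::rpois(1, scenario$D * area_km2)
    pop <- data.frame(
      id = if (N > 0) sprintf("J%03d", seq_len(N)) else character(0),
      sex = ifelse(stats::runif(N) < scenario$sex_ratio_male, "male", "female"),
      x = stats::runif(N, r[1], r[2]),
      y = stats::runif(N, r[3], r[4]),
      stringsAsFactors = FALSE)
    class(pop) <- c("population", "data.frame")
    attr(pop, "region") <- r
    pop
  })
}

#' Simulate camera-trap detections of a population
#'
#' Each individual `i`, detector `k` and day `t` yields an independent
#' Bernoulli detection with probability
#' `min(1, g0 m_g0(t)) * exp(-d_ik^2 / (2 (sigma m_sigma(t))^2))`, and at
#' most one record per individual/detector/day (proximity-detector
#' convention, the daily deduplication applied to camera photo records).
#'
#' @param pop a [simulate_population()] result.
#' @param traps the [trap_array()] of the survey.
#' @param scenario the [sim_scenario()] (supplies g0, sigma, modulation,
#'   total_days and the seed).
#' @return A [detection_records()] set spanning `total_days` occasions.
#' @export
simulate_detections <- function(pop, traps, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"), inherits(traps, "trap_array"))
  T <- scenario$total_days
  ms <- if (is.null(scenario$m_sigma)) rep(1, T) else scenario$m_sigma(seq_len(T))
  mg <- if (is.null(scenario$m_g0)) rep(1, T) else scenario$m_g0(seq_len(T))
  g0t <- pmin(1, scenario$g0 * mg)
  sig2t <- (scenario$sigma * ms)^2
  recs <- with_sim_seed(scenario$seed, {
    if (nrow(pop) == 0) NULL else {
      d2 <- outer(pop$x, traps$x, "-")^2 + outer(pop$y, traps$y, "-")^2
      out <- vector("list", nrow(pop) * nrow(traps))
      z <- 0L
      for (i in seq_len(nrow(pop))) {
        for (k in seq_len(nrow(traps))) {
          # per-day probability series for this individual/detector pair
          p <- g0t * exp(-d2[i, k] / (2 * sig2t))
          if (max(p) * T < 1e-10) next
          hit <- which(stats::runif(T) < p)
          if (length(hit)) {
            z <- z + 1L
            out[[z]] <- data.frame(individual = pop$id[i], sex = pop$sex[i],
                                   detector = traps$id[k], day = hit,
                                   stringsAsFactors = FALSE)
          }
        }
      }
      if (z == 0L) NULL else do.call(rbind, out[seq_len(z)])
    }
  })
  if (is.null(recs))
    recs <- data.frame(individual = character(0), sex = character(0),
                       detector = character(0), day = integer(0))
  detection_records(recs, traps, T)
}

#' Simulate a GPS collar track
#'
#' Fixes are the activity centre plus independent bivariate normal
#' displacements with per-axis standard deviation `sigma_move`, a
#' stationary central-place model of space use matching the half-normal
#' detection assumption.
#'
#' @param centre numeric length-2 activity centre (metres).
#' @param animal animal identifier.
#' @param n_days number of tracking days.
#' @param fixes_per_day GPS fixes per day.
#' @param sigma_move per-axis displacement standard deviation in metres.
#' @param seed optional integer seed.
#' @return A [track()] with `n_days * fixes_per_day` fixes.
#' @export
simulate_track <- function(centre, animal = "M1", n_days = 348,
                           fixes_per_day = 4, sigma_move = 2500,
                           seed = NULL) {
  if (n_days < 1 || fixes_per_day < 1) stop("n_days and fixes_per_day must be >= 1")
  if (sigma_move < 0) stop("sigma_move must be >= 0")
  n <- n_days * fixes_per_day
  with_sim_seed(seed, {
    track(animal,
          day = rep(seq_len(n_days), each = fixes_per_day),
          x = centre[1] + stats::rnorm(n, 0, sigma_move),
          y = centre[2] + stats::rnorm(n, 0, sigma_move))
  })
}
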
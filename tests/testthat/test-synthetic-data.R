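test_that("population generator is Poisson with uniform centres", {
  region <- c(0, 50000, 0, 50000)  # 2500 km^2
  sc <- sim_scenario(D = 0.02, g0 = 0.06, sigma = 3600, region = region)
  Ns <- vapply(1:4000, function(s) {
    sc$seed <- s
    nrow(simulate_population(sc))
  }, numeric(1))
  # Poisson(50): sample mean within 3 SE, variance/mean ratio near 1
  se <- sqrt(50 / length(Ns))
  expect_lt(abs(mean(Ns) - 50), 3 * se)
  expect_gt(var(Ns) / mean(Ns), 0.8)
  expect_lt(var(Ns) / mean(Ns), 1.25)

  sc$seed <- 77
  p1 <- simulate_population(sc)
  p2 <- simulate_population(sc)
  expect_identical(p1, p2)
  # centres stay inside the region
  expect_true(all(p1$x >= region[1] & p1$x <= region[2]))
  expect_true(all(p1$y >= region[3] & p1$y <= region[4]))

  sc0 <- sim_scenario(D = 0, g0 = 0.06, sigma = 3600, region = region, seed = 1)
  expect_equal(nrow(simulate_population(sc0)), 0)
  expect_error(sim_scenario(D = 0.02, g0 = 0.06, sigma = 3600,
                            region = c(0, 0, 0, 1)), "region")
})

test_that("detection counts follow the daily Bernoulli half-normal model", {
  traps <- trap_array("S01", 0, 0)
  # individual centred exactly on the detector: Binomial(T, g0)
  counts <- vapply(1:3000, function(s) {
    sc <- sim_scenario(D = 0.02, g0 = 0.06, sigma = 3600,
                       region = c(-1, 1, -1, 1), total_days = 90, seed = s)
    pop <- structure(data.frame(id = "A", sex = "male", x = 0, y = 0),
                     class = c("population", "data.frame"))
    nrow(simulate_detections(pop, traps, sc))
  }, numeric(1))
  expected <- 90 * 0.06
  se <- sqrt(90 * 0.06 * 0.94 / length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # zero g0 yields zero records
  sc0 <- sim_scenario(D = 0.02, g0 = 0, sigma = 3600,
                      region = c(-1, 1, -1, 1), total_days = 90, seed = 1)
  pop <- structure(data.frame(id = "A", sex = "male", x = 0, y = 0),
                   class = c("population", "data.frame"))
  expect_equal(nrow(simulate_detections(pop, traps, sc0)), 0)
})

test_that("empirical detection frequency follows the half-normal law in d", {
  # individuals pinned at distances 0, sigma/2, sigma, 2 sigma from one trap;
  # chi-square GOF across ~1e4 simulated individual-days per distance
  g0 <- 0.06; sigma <- 3600
  traps <- trap_array("S01", 0, 0)
  dists <- c(0, sigma / 2, sigma, 2 * sigma)
  pop <- structure(data.frame(id = sprintf("I%d", seq_along(dists)),
                              sex = "male", x = dists, y = 0),
                   class = c("population", "data.frame"))
  sc <- sim_scenario(D = 0.02, g0 = g0, sigma = sigma,
                     region = c(-1, 8000, -1, 1), total_days = 365, seed = 42)
  nrep <- 30
  hits <- numeric(length(dists))
  for (s in seq_len(nrep)) {
    sc$seed <- s
    rec <- simulate_detections(pop, traps, sc)
    tab <- table(factor(rec$individual, levels = pop$id))
    hits <- hits + as.numeric(tab)
  }
  ndays <- nrep * 365
  p_exp <- halfnormal_p(dists, g0, sigma)
  # frequency at distance sigma matches g0 exp(-1/2) within Monte Carlo error
  se_sig <- sqrt(p_exp[3] * (1 - p_exp[3]) / ndays)
  expect_lt(abs(hits[3] / ndays - g0 * exp(-0.5)), 3 * se_sig)
  chisq <- sum((hits - ndays * p_exp)^2 /
                 (ndays * p_exp * (1 - p_exp)))
  expect_gt(stats::pchisq(chisq, df = length(dists)), 0.01)
})

test_that("simulated detections are reproducible and carry modulation", {
  sc <- scenario_jaguar(modulation_amplitude = 0.3, seed = 8)
  sc$scenario$total_days <- 120
  pop <- simulate_population(sc$scenario, sc$traps)
  r1 <- simulate_detections(pop, sc$traps, sc$scenario)
  r2 <- simulate_detections(pop, sc$traps, sc$scenario)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_error(scenario_jaguar(modulation_amplitude = 1.2), "magnitude")
  # modulation must stay positive
  expect_error(sim_scenario(D = .02, g0 = .06, sigma = 3600,
                            m_sigma = function(d) d - 100), "multipliers")
})

test_that("paper-like scenario has the survey's geometry and sample sizes", {
  sc <- scenario_jaguar()
  expect_equal(nrow(sc$traps), 20)
  # mean nearest-neighbour spacing 2 km
  dm <- as.matrix(dist(cbind(sc$traps$x, sc$traps$y)))
  diag(dm) <- Inf
  expect_equal(mean(apply(dm, 1, min)), 2000)
  expect_equal(sc$scenario$total_days, 365)
  # male component density is 2.0 per 100 km^2
  expect_equal(sc$scenario$D * sc$scenario$sex_ratio_male, 0.02)

  # detected male head-counts per 90-day window are of the magnitude a
  # year-long trail survey of this design yields (low teens on average)
  n_male <- vapply(1:12, function(s) {
    sj <- scenario_jaguar(seed = s)
    sj$scenario$total_days <- 90
    pop <- simulate_population(sj$scenario, sj$traps)
    rec <- simulate_detections(pop, sj$traps, sj$scenario)
    summarize_session(rec, c(1, 90))$n_male
  }, numeric(1))
  expect_gt(mean(n_male), 8)
  expect_lt(mean(n_male), 18)
})

test_that("simulated tracks are centred normal displacements", {
  t0 <- simulate_track(c(1000, 2000), n_days = 10, fixes_per_day = 2,
                       sigma_move = 1e-9, seed = 1)
  expect_equal(mcp_area(t0)$area_km2, 0, tolerance = 1e-12)
  expect_equal(mean(t0$x), 1000, tolerance = 1e-3)

  tA <- simulate_track(c(0, 0), n_days = 348, fixes_per_day = 4,
                       sigma_move = sqrt(150 / 18.86) * 1000, seed = 4)
  expect_identical(simulate_track(c(0, 0), n_days = 348, fixes_per_day = 4,
                                  sigma_move = sqrt(150 / 18.86) * 1000,
                                  seed = 4), tA)
  a_full <- mcp_area(tA)$area_km2
  # MCP of a finite normal sample: order 1e2 km^2 for this sigma_move
  expect_gt(a_full, 50)
  expect_lt(a_full, 900)
  # hull area grows with the number of fixes
  a_half <- mcp_area(tA[seq_len(nrow(tA) / 2), ])$area_km2
  expect_lte(a_half, a_full)
})
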
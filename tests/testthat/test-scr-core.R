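test_that("mask construction follows the cell-tiling arithmetic", {
  one <- trap_array("S01", 0, 0)
  m <- build_mask(one, buffer = 1000, spacing = 1000)
  expect_equal(nrow(m), 4)  # ceil(2000/1000)^2
  expect_equal(attr(m, "area"), 1)

  traps <- trap_grid(4, 5, spacing = 2000)
  m1 <- build_mask(traps, buffer = 6000, spacing = 500)
  m2 <- build_mask(traps, buffer = 6000, spacing = 1000)
  # doubling the spacing quarters the count up to one row/column of edge
  expect_lt(abs(nrow(m1) / 4 - nrow(m2)), max(nrow(m2) * 0.1, 40))

  m3 <- build_mask(traps, buffer = 30000, spacing = 300)
  # every trap is within half a cell diagonal of some mask point
  dmin <- vapply(seq_len(nrow(traps)), function(k) {
    min(sqrt((m3$x - traps$x[k])^2 + (m3$y - traps$y[k])^2))
  }, numeric(1))
  expect_true(all(dmin <= 300 * sqrt(2) / 2 + 1e-9))

  expect_error(build_mask(traps, buffer = -1), "buffer")
  expect_warning(build_mask(traps, buffer = 500, spacing = 1000), "coarse")
})

test_that("half-normal detection function has its closed-form values", {
  expect_equal(halfnormal_p(0, 0.06, 3600), 0.06)
  expect_equal(halfnormal_p(3600 * sqrt(2 * log(2)), 0.06, 3600), 0.03)
  expect_equal(halfnormal_p(3600, 0.06, 3600), 0.06 * exp(-0.5))
  d <- seq(0, 20000, by = 500)
  expect_true(all(diff(halfnormal_p(d, 0.06, 3600)) <= 0))
  expect_error(halfnormal_p(100, 0.06, -1), "sigma")
})

test_that("pdot matches its closed form and a simulation oracle", {
  one <- trap_array("S01", 0, 0)
  expect_equal(pdot(c(0, 0), one, g0 = 0.05, sigma = 1000, T = 2),
               1 - 0.95^2)
  expect_equal(pdot(c(0, 0), one, g0 = 1e-12, sigma = 1000, T = 5), 0,
               tolerance = 1e-9)
  # increasing in T
  expect_true(all(diff(vapply(1:6, function(T)
    pdot(c(1500, 0), one, 0.05, 1000, T), numeric(1))) > 0))

  # Monte-Carlo detection frequency at a fixed activity centre
  traps <- tiny_traps()
  s <- c(1000, 800)
  p_theory <- pdot(s, traps, g0 = 0.1, sigma = 1500, T = 10)
  hits <- vapply(1:2000, function(seed) {
    sc <- sim_scenario(D = 0.01, g0 = 0.1, sigma = 1500,
                       region = c(0, 2000, 0, 2000), total_days = 10,
                       seed = seed)
    pop <- structure(data.frame(id = "A", sex = "male", x = s[1], y = s[2]),
                     class = c("population", "data.frame"))
    nrow(simulate_detections(pop, traps, sc)) > 0
  }, logical(1))
  se <- sqrt(p_theory * (1 - p_theory) / length(hits))
  expect_lt(abs(mean(hits) - p_theory), 3 * se)
})

test_that("capture histories collapse to in-window daily counts", {
  traps <- tiny_traps()
  rec <- records_from_rows(list(
    c("A", "m", "S01", "5"), c("A", "m", "S01", "6"), c("A", "m", "S02", "7"),
    c("B", "f", "S01", "8"), c("C", "m", "S03", "200")), traps, 365)
  h <- collapse_histories(rec, c(1, 90), "male")
  expect_equal(h$n, 1)
  expect_equal(h$T, 90)
  expect_equal(unname(h$counts["A", c("S01", "S02", "S03")]), c(2L, 1L, 0L))

  # all records outside the window: empty but valid
  h0 <- collapse_histories(rec, c(300, 365), "male")
  expect_equal(h0$n, 0)
  expect_error(collapse_histories(rec, c(90, 1)), "window")

  # consecutive windows differ only through the dropped/added day
  sc <- scenario_jaguar(seed = 21)
  sc$scenario$total_days <- 120
  pop <- simulate_population(sc$scenario, sc$traps)
  resim <- simulate_detections(pop, sc$traps, sc$scenario)
  h1 <- collapse_histories(resim, c(1, 90), "male")
  h2 <- collapse_histories(resim, c(2, 91), "male")
  d <- as.data.frame(resim)
  edge <- d[d$sex == "male" & d$day %in% c(1, 91), ]
  delta <- sum(h2$counts) - sum(h1$counts)
  expect_equal(delta, sum(edge$day == 91) - sum(edge$day == 1))
})

test_that("likelihood equals the nested-loop oracle and the hand value", {
  h1 <- structure(list(counts = matrix(1, 1, 1), T = 1),
                  class = "session_histories")
  m1 <- structure(data.frame(x = 0, y = 0), area = 1)
  v <- scr_negloglik(c(log(1), qlogis(0.5), log(1000)), h1, NULL, m1,
                     d2 = matrix(0, 1, 1))
  expect_equal(-v, -0.5 + log(0.5), tolerance = 1e-12)

  set.seed(101)
  for (r in 1:25) {
    inst <- random_nll_instance()
    v1 <- nll_package(inst$par, inst$counts, inst$d2, inst$T, inst$a)
    v2 <- nll_bruteforce(inst$par, inst$counts, inst$d2, inst$T, inst$a)
    expect_equal(v1, v2, tolerance = 1e-12)
  }

  # quadrature invariance: doubling every mask point while halving the
  # cell area leaves the likelihood unchanged
  inst <- random_nll_instance()
  v_once <- nll_package(inst$par, inst$counts, inst$d2, inst$T, inst$a)
  v_twice <- nll_package(inst$par, inst$counts, cbind(inst$d2, inst$d2),
                         inst$T, inst$a / 2)
  expect_equal(v_once, v_twice, tolerance = 1e-10)
})

test_that("analytic gradient agrees with central differences", {
  set.seed(55)
  for (r in 1:10) {
    inst <- random_nll_instance()
    g <- rollscr:::scr_nll_grad_cpp(inst$par, inst$counts + 0, inst$d2,
                                    inst$T, inst$a)
    fd <- vapply(1:3, function(i) {
      h <- 1e-6; e <- replace(numeric(3), i, h)
      (nll_package(inst$par + e, inst$counts, inst$d2, inst$T, inst$a) -
       nll_package(inst$par - e, inst$counts, inst$d2, inst$T, inst$a)) / (2 * h)
    }, numeric(1))
    expect_equal(as.numeric(g$gradient), fd, tolerance = 1e-4)
    expect_equal(g$value,
                 nll_package(inst$par, inst$counts, inst$d2, inst$T, inst$a),
                 tolerance = 1e-12)
  }
})

test_that("fit_scr finds the grid-search optimum on a tiny instance", {
  traps <- tiny_traps()
  rec <- records_from_rows(list(
    c("A", "m", "S01", "1"), c("A", "m", "S02", "3"), c("A", "m", "S01", "5"),
    c("B", "m", "S02", "2"), c("B", "m", "S03", "4"),
    c("C", "m", "S02", "6"), c("C", "m", "S02", "8"), c("C", "m", "S03", "9")),
    traps, 10)
  h <- collapse_histories(rec, c(1, 10), "male")
  mask <- build_mask(traps, buffer = 4000, spacing = 1500)
  fit <- fit_scr(h, traps, mask)
  expect_true(is.finite(fit$logLik))

  grid <- expand.grid(logD = seq(-9, -2, length.out = 16),
                      lg0 = seq(qlogis(0.01), qlogis(0.6), length.out = 16),
                      lsig = seq(log(300), log(8000), length.out = 16))
  vals <- apply(grid, 1, function(p) scr_negloglik(p, h, traps, mask))
  bestg <- grid[which.min(vals), ]
  # the optimizer must do at least as well as the best grid node, and land
  # within one grid step of it
  expect_lte(-fit$logLik, min(vals) + 1e-8)
  expect_lt(abs(fit$link$estimate[1] - bestg$logD), diff(range(grid$logD)) / 15)
  expect_lt(abs(fit$link$estimate[2] - bestg$lg0), diff(range(grid$lg0)) / 15)
  expect_lt(abs(fit$link$estimate[3] - bestg$lsig), diff(range(grid$lsig)) / 15)
})

test_that("fit_scr enforces its identifiability preconditions", {
  traps <- tiny_traps()
  rec <- records_from_rows(list(
    c("A", "m", "S01", "1"), c("A", "m", "S01", "2"),
    c("B", "m", "S02", "3")), traps, 10)
  h <- collapse_histories(rec, c(1, 10), "male")
  mask <- build_mask(traps, buffer = 3000, spacing = 1500)
  expect_error(fit_scr(h, traps, mask), "sigma unidentifiable")

  h0 <- collapse_histories(rec, c(5, 10), "female")
  expect_error(fit_scr(h0, traps, mask), "no detections")
})

test_that("density converts exactly to the per-100-km^2 scale", {
  fit <- structure(list(params = list(D = 0.02, g0 = 0.06, sigma = 3600),
                        ci95 = matrix(c(0.011, 0.005, 2000, 0.036, 0.2, 5000),
                                      3, 2,
                                      dimnames = list(c("D", "g0", "sigma"),
                                                      c("lo", "hi")))),
                   class = "scr_fit")
  d <- density_per_100km2(fit)
  expect_equal(unname(d["estimate"]), 2.0)
  expect_equal(unname(d["lo"]), 1.1)
  expect_equal(unname(d["hi"]), 3.6)
  expect_lt(d["lo"], d["hi"])
})

test_that("estimates are insensitive to buffer and mask spacing", {
  sc <- scenario_jaguar(seed = 14)
  sc$scenario$total_days <- 90
  pop <- simulate_population(sc$scenario, sc$traps)
  rec <- simulate_detections(pop, sc$traps, sc$scenario)
  h <- collapse_histories(rec, c(1, 90), "male")
  base <- fit_scr(h, sc$traps, build_mask(sc$traps, 15000, 1000), se = FALSE)
  wide <- fit_scr(h, sc$traps, build_mask(sc$traps, 30000, 1000), se = FALSE)
  expect_lt(abs(wide$params$D - base$params$D) / base$params$D, 0.01)
  # quadrature refinement: halving 600 m to 300 m moves D by < 1%
  m600 <- fit_scr(h, sc$traps, build_mask(sc$traps, 15000, 600), se = FALSE)
  m300 <- fit_scr(h, sc$traps, build_mask(sc$traps, 15000, 300), se = FALSE)
  expect_lt(abs(m300$params$D - m600$params$D) / m600$params$D, 0.01)
})
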
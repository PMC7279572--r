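# Independent oracles used across the suite. These deliberately avoid the
# package's own computational routes: the likelihood is explicit nested
# loops, the convex hull is Andrew's monotone chain.

# SCR negative log-likelihood by brute force (n! dropped)
nll_bruteforce <- function(par, counts, d2, T, a) {
  D <- exp(par[1]); g0 <- plogis(par[2]); sigma <- exp(par[3])
  M <- ncol(d2); K <- nrow(d2); n <- nrow(counts)
  esa <- 0
  for (m in seq_len(M)) {
    prodq <- 1
    for (k in seq_len(K)) {
      p <- g0 * exp(-d2[k, m] / (2 * sigma^2))
      prodq <- prodq * (1 - p)^T
    }
    esa <- esa + 1 - prodq
  }
  ll <- -D * a * esa
  for (i in seq_len(n)) {
    s <- 0
    for (m in seq_len(M)) {
      pr <- 1
      for (k in seq_len(K)) {
        p <- g0 * exp(-d2[k, m] / (2 * sigma^2))
        pr <- pr * p^counts[i, k] * (1 - p)^(T - counts[i, k])
      }
      s <- s + pr
    }
    ll <- ll + log(D * a * s)
  }
  -ll
}

# evaluate the package likelihood on raw matrices
nll_package <- function(par, counts, d2, T, a) {
  hist <- structure(list(counts = counts, T = T), class = "session_histories")
  mask <- structure(data.frame(x = numeric(ncol(d2)), y = numeric(ncol(d2))),
                    area = a)
  scr_negloglik(par, hist, NULL, mask, d2 = d2)
}

# random small likelihood instance
random_nll_instance <- function() {
  n <- sample(1:4, 1); K <- sample(1:3, 1); M <- sample(1:25, 1)
  T <- sample(2:40, 1)
  counts <- matrix(rbinom(n * K, 4, 0.3), n, K)
  if (all(counts == 0)) counts[1, 1] <- 1L
  list(par = c(log(runif(1, 0.005, 0.2)), qlogis(runif(1, 0.02, 0.4)),
               log(runif(1, 500, 5000))),
       counts = counts,
       d2 = matrix(runif(K * M, 0, 6e7), K, M),
       T = T, a = runif(1, 0.1, 2))
}

# Andrew's monotone chain convex hull; returns hull area in the input units
hull_area_oracle <- function(xy) {
  xy <- unique(as.data.frame(xy)[, c("x", "y")])
  xy <- xy[order(xy$x, xy$y), ]
  n <- nrow(xy)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(unlist(xy[h[length(h) - 1], ]),
                   unlist(xy[h[length(h)], ]),
                   unlist(xy[i, ])) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  h <- c(lower[-length(lower)], upper[-length(upper)])
  v <- as.matrix(xy[h, ])
  j <- c(seq_len(nrow(v))[-1], 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# small shared fixtures
tiny_traps <- function() trap_array(c("S01", "S02", "S03"),
                                    x = c(0, 2000, 4000), y = c(0, 0, 0))

records_from_rows <- function(rows, traps, total_days) {
  detection_records(
    data.frame(individual = vapply(rows, `[[`, "", 1),
               sex = vapply(rows, `[[`, "", 2),
               detector = vapply(rows, `[[`, "", 3),
               day = as.integer(vapply(rows, `[[`, "", 4)),
               stringsAsFactors = FALSE),
    traps, total_days)
}
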
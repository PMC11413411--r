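# Independent oracles used to cross-check the implementation by a
# second route. They deliberately avoid the package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# great-circle distance via the spherical law of cosines (km)
oracle_slc_km <- function(p1, p2) {
  R <- 6371.0088
  la1 <- p1[1] * pi / 180
  la2 <- p2[1] * pi / 180
  dlo <- (p2[2] - p1[2]) * pi / 180
  ang <- sin(la1) * sin(la2) + cos(la1) * cos(la2) * cos(dlo)
  R * acos(pmin(1, pmax(-1, ang)))
}

# two-sided Fisher exact P by full enumeration over the hypergeometric
# support, probability-mass rule with 1e-7 relative slack
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  kcol <- a + c
  support <- max(0, kcol - m2):min(kcol, m1)
  probs <- dhyper(support, m1, m2, kcol)
  p_obs <- dhyper(a, m1, m2, kcol)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^2) double-loop semivariogram (same distance function as the
# implementation; independent binning and averaging)
oracle_variogram <- function(sites, z, lag_width, cutoff) {
  n <- nrow(sites)
  sums <- list()
  counts <- list()
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      d <- haversine_km(
        c(sites$lat[i], sites$lon[i]),
        c(sites$lat[k], sites$lon[k])
      )
      if (d <= 0 || d > cutoff) next
      j <- as.character(ceiling(d / lag_width - 1e-12))
      sums[[j]] <- (sums[[j]] %||% 0) + (z[i] - z[k])^2
      counts[[j]] <- (counts[[j]] %||% 0L) + 1L
    }
  }
  bins <- sort(as.integer(names(sums)))
  tibble::tibble(
    lag_center = (bins - 0.5) * lag_width,
    gamma_hat = vapply(
      as.character(bins),
      function(j) sums[[j]] / (2 * counts[[j]]), numeric(1),
      USE.NAMES = FALSE
    ),
    n_pairs = vapply(as.character(bins), function(j) counts[[j]], integer(1),
      USE.NAMES = FALSE
    )
  )
}

# ordinary kriging by an independently assembled dense system, solved
# with qr.solve; distances by the law-of-cosines oracle
oracle_krige <- function(C0, C1, b, sites, z, target) {
  gam <- function(r) ifelse(r == 0, 0, C0 + C1 * (1 - exp(-3 * r / b)))
  n <- nrow(sites)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i != k) {
        G[i, k] <- gam(oracle_slc_km(
          c(sites$lat[i], sites$lon[i]),
          c(sites$lat[k], sites$lon[k])
        ))
      }
    }
  }
  g0 <- vapply(seq_len(n), function(i) {
    gam(oracle_slc_km(c(sites$lat[i], sites$lon[i]), target))
  }, numeric(1))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  sol <- qr.solve(A, c(g0, 1))
  w <- sol[seq_len(n)]
  list(
    weights = w,
    z_hat = sum(w * z),
    krig_var = sum(w * g0) + sol[n + 1]
  )
}

# random site table over a bounding box (test-local, seeded by caller)
random_sites <- function(n, lat = c(35, 60), lon = c(-5, 40)) {
  tibble::tibble(
    lat = runif(n, lat[1], lat[2]),
    lon = runif(n, lon[1], lon[2])
  )
}

# the sample-size law of the default simulator, restated for
# Monte-Carlo expectations (normalised probabilities)
sample_size_pool_mc <- function() {
  base <- c(12, 12, 12, 12, 12, 12, 9, 10, 12, 2, 12, 12, 11, 5)
  tail <- c(1, 8, 16, 20, 26, 34, 45, 56, 68)
  prob <- c(rep(1, length(base)), rep(0.15, length(tail)))
  list(sizes = c(base, tail), prob = prob / sum(prob))
}

table1_path <- function() {
  system.file("extdata", "table1_populations.csv", package = "wolbtrace")
}
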
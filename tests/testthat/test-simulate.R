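test_that("site simulation is seeded, bounded, and clusters when asked", {
  cfg <- sim_config(n_sites = 100, seed = 5)
  s1 <- simulate_sites(cfg)
  s2 <- simulate_sites(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$lat >= 34 & s1$lat <= 71))
  expect_true(all(s1$lon >= -11 & s1$lon <= 61))
  expect_equal(nrow(simulate_sites(sim_config(n_sites = 0))), 0)
  # clustered layouts have smaller nearest-neighbour distances
  nn_mean <- function(sites) {
    d <- distance_matrix(sites)
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  nn_u <- vapply(1:5, function(r) {
    nn_mean(simulate_sites(sim_config(n_sites = 100, seed = r)))
  }, numeric(1))
  nn_c <- vapply(1:5, function(r) {
    nn_mean(simulate_sites(sim_config(n_sites = 100, site_mode = "clustered", seed = r)))
  }, numeric(1))
  expect_lt(mean(nn_c), mean(nn_u))
})

test_that("the latent field has the configured mean, covariance and links", {
  sites <- tibble::tibble(lat = c(45, 45.05), lon = c(10, 10))
  # degenerate model: field is exactly the mean
  flat <- simulate_latent_field(sites, list(C0 = 0, C1 = 0, b = 600), mean_p = 0.3)
  expect_equal(flat, c(0.3, 0.3))
  # replicate correlation between two sites: ~exp(-0.3) when d = b/10
  # with no nugget, ~0 when far apart
  d <- haversine_km(c(45, 10), c(45.05, 10))
  b_near <- 10 * d
  reps <- vapply(1:2000, function(r) {
    simulate_latent_field(sites, list(C0 = 0, C1 = 0.04, b = b_near),
      mean_p = 0.5, seed = r
    )
  }, numeric(2))
  expect_equal(cor(reps[1, ], reps[2, ]), exp(-0.3), tolerance = 0.05)
  far <- tibble::tibble(lat = c(40, 65), lon = c(-5, 55))
  reps_far <- vapply(1:2000, function(r) {
    simulate_latent_field(far, list(C0 = 0, C1 = 0.04, b = 600),
      mean_p = 0.5, seed = 10000 + r
    )
  }, numeric(2))
  expect_lt(abs(cor(reps_far[1, ], reps_far[2, ])), 0.05)
  # links keep frequencies in [0, 1]
  withr::local_seed(2)
  ss <- random_sites(50)
  for (link in c("truncate", "logit")) {
    p <- simulate_latent_field(ss, list(C0 = 0.05, C1 = 0.2, b = 600),
      link = link, seed = 3
    )
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("truncation attenuates the marginal variance as Monte-Carlo predicts", {
  # marginal law at each site is N(mean_p, C0 + C1) clamped to [0, 1];
  # the across-site variance should approach the clamped-normal variance
  model <- list(C0 = 0.05, C1 = 0.2, b = 600)
  mc <- withr::with_seed(1, {
    x <- pmin(1, pmax(0, rnorm(2e5, 0.5, sqrt(0.25))))
    stats::var(x)
  })
  vars <- vapply(1:30, function(r) {
    sites <- simulate_sites(sim_config(n_sites = 200, seed = 500 + r))
    stats::var(simulate_latent_field(sites, model, seed = 600 + r))
  }, numeric(1))
  expect_equal(mean(vars), mc, tolerance = 0.2)
  expect_lt(mean(vars), 0.25) # attenuated below the nominal total sill
})

test_that("binomial sampling matches its moments and boundary cases", {
  expect_true(all(simulate_counts(rep(0, 50), 12, seed = 1)$k == 0))
  cnt1 <- simulate_counts(rep(1, 50), 12, seed = 2)
  expect_true(all(cnt1$k == cnt1$n))
  big <- simulate_counts(rep(0.5, 1e4), 12, seed = 3)
  expect_equal(mean(big$k), 6, tolerance = 0.1 / 6)
  # empirical sample-size law: mean ~12, range within 1-68
  sizes <- simulate_counts(rep(0.5, 2e4), "empirical", seed = 4)$n
  expect_gte(min(sizes), 1)
  expect_lte(max(sizes), 68)
  expect_equal(mean(sizes), 12.2, tolerance = 0.1)
})

test_that("generate_dataset emits a valid, byte-reproducible table with truth", {
  cfg <- sim_config(n_sites = 238, seed = 9)
  sim <- generate_dataset(cfg)
  expect_equal(nrow(sim$table), 238)
  expect_silent(validate_population_table(sim$table))
  expect_equal(sim$truth$latent_p >= 0, rep(TRUE, 238))
  # identical seed -> byte-identical CSV
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_population_table(sim$table, f1)
  write_population_table(generate_dataset(cfg)$table, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("binomial sampling inflates the fitted nugget above the latent-field fit", {
  model <- list(C0 = 0.03, C1 = 0.2, b = 600)
  diffs <- vapply(1:12, function(r) {
    cfg <- sim_config(
      n_sites = 200, C0 = model$C0, C1 = model$C1, b = model$b,
      sample_size_law = 12, seed = 300 + r
    )
    sites <- simulate_sites(cfg)
    latent <- simulate_latent_field(sites, model, seed = 400 + r)
    counts <- simulate_counts(latent, 12, seed = 450 + r)
    fit_latent <- fit_exponential(empirical_variogram(sites, latent))
    fit_counts <- fit_exponential(empirical_variogram(sites, counts$k / counts$n))
    fit_counts$C0 - fit_latent$C0
  }, numeric(1))
  expect_gt(stats::median(diffs), 0)
})
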
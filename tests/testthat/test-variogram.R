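test_that("two-site and constant-field variograms take their closed forms", {
  # two sites ~50 km apart with z = (0, 1): single bin, gamma = 0.5
  sites <- tibble::tibble(lat = c(47, 47.45), lon = c(10, 10))
  v <- empirical_variogram(sites, c(0, 1), lag_width = 60, cutoff = 2000)
  expect_equal(nrow(v), 1)
  expect_equal(v$gamma_hat, 0.5)
  expect_equal(v$n_pairs, 1L)
  expect_equal(v$lag_center, 30)
  # constant field has zero semivariance everywhere
  withr::local_seed(2)
  s <- random_sites(20)
  vc <- empirical_variogram(s, rep(0.7, 20))
  expect_true(all(vc$gamma_hat == 0))
  # every pair beyond the cutoff is an error
  far <- tibble::tibble(lat = c(0, 60), lon = c(0, 0))
  expect_error(
    empirical_variogram(far, c(0, 1), cutoff = 100),
    class = "wolb_empty_variogram_error"
  )
})

test_that("binned semivariances match the O(n^2) double-loop oracle", {
  withr::local_seed(31)
  for (rep in 1:10) {
    sites <- random_sites(30)
    z <- runif(30)
    v <- empirical_variogram(sites, z, lag_width = 120, cutoff = 3000)
    o <- oracle_variogram(sites, z, lag_width = 120, cutoff = 3000)
    expect_equal(v$lag_center, o$lag_center)
    expect_equal(v$n_pairs, o$n_pairs)
    expect_equal(v$gamma_hat, o$gamma_hat, tolerance = 1e-12)
  }
})

test_that("semivariance is shift-invariant and scales quadratically", {
  withr::local_seed(8)
  sites <- random_sites(25)
  z <- runif(25)
  v <- empirical_variogram(sites, z)
  v_shift <- empirical_variogram(sites, z + 0.37)
  v_scale <- empirical_variogram(sites, 3 * z)
  expect_equal(v_shift$gamma_hat, v$gamma_hat)
  expect_equal(v_scale$gamma_hat, 9 * v$gamma_hat)
})

test_that("directional sectors partition pairs; meridian sites load the 0-degree axis", {
  withr::local_seed(13)
  sites <- random_sites(40)
  z <- runif(40)
  dv <- directional_variograms(sites, z)
  omni <- empirical_variogram(sites, z)
  # pair totals across sectors equal the omnidirectional count
  expect_equal(sum(dv$n_pairs), sum(omni$n_pairs))
  # omnidirectional gamma is the pair-weighted average of directions
  recomb <- dplyr::summarise(
    dplyr::group_by(dv, lag_center),
    gamma_hat = sum(gamma_hat * n_pairs) / sum(n_pairs),
    n_pairs = sum(n_pairs), .groups = "drop"
  )
  merged <- dplyr::inner_join(
    recomb, tibble::as_tibble(omni),
    by = "lag_center", suffix = c("_dir", "_omni")
  )
  expect_equal(nrow(merged), nrow(omni))
  expect_equal(merged$gamma_hat_dir, merged$gamma_hat_omni, tolerance = 1e-12)
  expect_equal(merged$n_pairs_dir, merged$n_pairs_omni)
  # sites on one meridian: the north-south sector carries every pair
  mer <- tibble::tibble(lat = seq(40, 49, 1), lon = 10)
  zm <- runif(10)
  dm <- directional_variograms(mer, zm)
  ns_sector <- dm[dm$angle == 0, ]
  omni_mer <- empirical_variogram(mer, zm)
  expect_equal(ns_sector$lag_center, omni_mer$lag_center)
  expect_equal(ns_sector$gamma_hat, omni_mer$gamma_hat)
  expect_equal(ns_sector$n_pairs, omni_mer$n_pairs)
  expect_equal(sum(dm$n_pairs[dm$angle != 0]), 0L)
  # overlapping sectors are a configuration error
  expect_error(
    directional_variograms(sites, z, angles = c(0, 30), tol = 22.5),
    class = "wolb_config_error"
  )
})

test_that("the variogram map is centrally symmetric and flags anisotropy", {
  withr::local_seed(17)
  sites <- random_sites(60, lat = c(44, 54), lon = c(0, 20))
  # two sites -> two mirrored nonempty cells
  vm2 <- variogram_map(sites[1:2, ], c(0, 1), cell_size = 100, cutoff = 5000)
  expect_equal(nrow(vm2), 2)
  expect_equal(sort(vm2$dx_center), sort(-vm2$dx_center))
  # central symmetry holds exactly for a larger map
  z <- runif(60)
  vm <- variogram_map(sites, z, cell_size = 150)
  mirrored <- dplyr::inner_join(
    vm,
    dplyr::mutate(vm, dx_center = -dx_center, dy_center = -dy_center),
    by = c("dx_center", "dy_center")
  )
  expect_equal(nrow(mirrored), nrow(vm))
  expect_equal(mirrored$gamma_hat.x, mirrored$gamma_hat.y)
  # field with range stretched 3x along east-west: low-semivariance ridge
  # along the x axis relative to the y axis at comparable separations
  withr::local_seed(99)
  ss <- random_sites(150, lat = c(44, 52), lon = c(0, 24))
  mid <- mean(ss$lat) * pi / 180
  dx <- outer(ss$lon, ss$lon, "-") * pi / 180 * cos(mid) * 6371.0088
  dy <- outer(ss$lat, ss$lat, "-") * pi / 180 * 6371.0088
  d_aniso <- sqrt((dx / 3)^2 + dy^2)
  Sigma <- 0.2 * exp(-3 * d_aniso / 300)
  diag(Sigma) <- 0.2 + 1e-8
  zf <- drop(crossprod(chol(Sigma), rnorm(150)))
  vma <- variogram_map(ss, zf, cell_size = 150, cutoff = 1500)
  along_x <- vma$gamma_hat[abs(vma$dy_center) < 150 & abs(vma$dx_center) > 150 &
    abs(vma$dx_center) < 600]
  along_y <- vma$gamma_hat[abs(vma$dx_center) < 150 & abs(vma$dy_center) > 150 &
    abs(vma$dy_center) < 600]
  expect_lt(mean(along_x), mean(along_y))
})

test_that("the exponential model has the right limits and 95% point", {
  m <- list(C0 = 0.05, C1 = 0.2, b = 600)
  expect_equal(exponential_gamma(m, 0), 0) # conventionally zero at the origin
  expect_equal(exponential_gamma(m, 1e-9), 0.05, tolerance = 1e-6) # nugget limit
  expect_equal(exponential_gamma(m, 1e9), 0.25) # sill
  expect_equal(
    exponential_gamma(m, 600), 0.05 + 0.2 * (1 - exp(-3))
  )
  # practical range: closed form against a numerical root of
  # gamma(r) = 0.95 * (C0 + C1)
  pr <- practical_range(m)
  root <- stats::uniroot(
    function(r) exponential_gamma(m, r) - 0.95 * 0.25,
    c(1, 1e5), tol = 1e-10
  )$root
  expect_equal(pr$range95, root, tolerance = 1e-6)
  expect_equal(pr$b, 600)
  # zero nugget: range95 ~ b within 0.5%, and doubles with b
  m0 <- list(C0 = 0, C1 = 0.2, b = 600)
  pr0 <- practical_range(m0)
  expect_equal(pr0$range95 / 600, -log(0.05) / 3, tolerance = 1e-12)
  expect_lt(abs(pr0$range95 - 600) / 600, 0.005)
  expect_equal(
    practical_range(list(C0 = 0, C1 = 0.2, b = 1200))$range95,
    2 * pr0$range95
  )
  expect_error(
    practical_range(list(C0 = 0.1, C1 = 0, b = 600)),
    class = "wolb_undefined_range_error"
  )
})

test_that("noiseless exponential bins are inverted to the generating parameters", {
  truth <- list(C0 = 0.05, C1 = 0.20, b = 600)
  h <- seq(30, 1980, by = 60)
  emp <- tibble::tibble(
    lag_center = h,
    gamma_hat = exponential_gamma(truth, h),
    n_pairs = 50L
  )
  class(emp) <- c("wolb_variogram", class(emp))
  fit <- fit_exponential(emp)
  expect_equal(fit$C0, truth$C0, tolerance = 1e-6)
  expect_equal(fit$C1, truth$C1, tolerance = 1e-6)
  expect_equal(fit$b, truth$b, tolerance = 1e-6)
  expect_true(fit$range_identifiable)
  # the optimiser never ends worse than a user-supplied starting point
  init <- list(C0 = 0.1, C1 = 0.1, b = 200)
  sse_init <- sum((emp$n_pairs / emp$lag_center^2) *
    (emp$gamma_hat - exponential_gamma(init, emp$lag_center))^2)
  fit2 <- fit_exponential(emp, init = init)
  expect_lte(fit2$sse, sse_init)
})

test_that("a flat semivariogram fits as pure nugget with unidentifiable range", {
  h <- seq(30, 930, by = 60)
  emp <- tibble::tibble(lag_center = h, gamma_hat = rep(0.12, length(h)), n_pairs = 20L)
  class(emp) <- c("wolb_variogram", class(emp))
  fit <- fit_exponential(emp)
  expect_equal(fit$C0, 0.12, tolerance = 1e-4)
  expect_equal(fit$C1, 0)
  expect_false(fit$range_identifiable)
  expect_error(fit_exponential(emp[1:2, ]), class = "wolb_fit_error")
})

test_that("range estimates sharpen as site count grows (consistency)", {
  truth <- list(C0 = 0.02, C1 = 0.2, b = 600)
  median_abs_err <- vapply(c(60, 240, 960), function(n_sites) {
    errs <- vapply(1:8, function(r) {
      cfg <- sim_config(
        n_sites = n_sites, C0 = truth$C0, C1 = truth$C1, b = truth$b,
        seed = 1000 + r
      )
      sites <- simulate_sites(cfg)
      z <- simulate_latent_field(sites, truth, mean_p = 0.5, seed = 2000 + r)
      fit <- fit_exponential(empirical_variogram(sites, z))
      abs(fit$b - truth$b)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(median_abs_err) < 0))
})

test_that("tidy and glance summarise a variogram fit", {
  withr::local_seed(3)
  sites <- random_sites(80)
  z <- simulate_latent_field(sites, list(C0 = 0.05, C1 = 0.2, b = 600), seed = 4)
  fit <- fit_exponential(empirical_variogram(sites, z))
  td <- tidy(fit)
  expect_equal(td$term, c("C0", "C1", "b"))
  gl <- glance(fit)
  expect_equal(gl$sill_total, fit$C0 + fit$C1)
  expect_true(gl$converged)
  expect_s3_class(plot_variogram(fit$empirical, fit), "ggplot")
  expect_s3_class(autoplot(fit), "ggplot")
})
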
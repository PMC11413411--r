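#' Empirical semivariogram of a spatial variable
#'
#' Bins site pairs by great-circle separation and estimates the
#' semivariance in each lag bin as
#' \deqn{\hat\gamma(h_j) = \frac{1}{2 N_j} \sum_{(i,k) \in j} (z_i - z_k)^2,}
#' where the sum runs over the \eqn{N_j} pairs whose distance falls in
#' \eqn{((j-1)w, jw]} for lag width \eqn{w}. Pairs beyond `cutoff` are
#' discarded and empty bins are omitted. For infection frequencies the
#' semivariance is the distance-dependent population variance of the
#' regionalised frequency.
#'
#' @param sites Data frame with `lat`, `lon` columns (>= 2 rows).
#' @param z Numeric vector of the variable (e.g. infection frequency),
#'   one value per site.
#' @param lag_width Lag bin width in km; default 60.
#' @param cutoff Maximum pair distance in km; default 2000. Beyond this
#'   distance additional pairs no longer improve the variance estimate
#'   for this study system; pass the full sampling span (~6300 km) for a
#'   whole-range variogram.
#' @return A tibble of class `wolb_variogram` with columns `lag_center`,
#'   `gamma_hat`, `n_pairs`; `lag_width` and `cutoff` stored as
#'   attributes.
#' @export
empirical_variogram <- function(sites, z, lag_width = 60, cutoff = 2000) {
  stopifnot(lag_width > 0, cutoff > 0)
  n <- nrow(sites)
  if (n < 2 || length(z) != n) {
    abort("need >= 2 sites and one z value per site", class = "wolb_domain_error")
  }
  d <- distance_matrix(sites)
  iu <- which(upper.tri(d))
  dist_pair <- d[iu]
  row_i <- row(d)[iu]
  col_k <- col(d)[iu]
  keep <- dist_pair > 0 & dist_pair <= cutoff
  if (!any(keep)) {
    abort("no site pairs within the cutoff distance", class = "wolb_empty_variogram_error")
  }
  dist_pair <- dist_pair[keep]
  sqdiff <- (z[row_i[keep]] - z[col_k[keep]])^2
  bin <- ceiling(dist_pair / lag_width - 1e-12)
  out <- tibble(bin = bin, sqdiff = sqdiff) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      gamma_hat = sum(.data$sqdiff) / (2 * dplyr::n()),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(lag_center = (.data$bin - 0.5) * lag_width) |>
    dplyr::select("lag_center", "gamma_hat", "n_pairs")
  attr(out, "lag_width") <- lag_width
  attr(out, "cutoff") <- cutoff
  class(out) <- c("wolb_variogram", class(out))
  out
}

# bearing (degrees in [0, 180)) of each pair on the local tangent plane;
# equirectangular approximation, adequate at sub-continental separations
pair_bearings <- function(sites, row_i, col_k) {
  lat1 <- sites$lat[row_i]
  lat2 <- sites$lat[col_k]
  lon1 <- sites$lon[row_i]
  lon2 <- sites$lon[col_k]
  mid <- (lat1 + lat2) / 2 * pi / 180
  dx <- (lon2 - lon1) * cos(mid)
  dy <- lat2 - lat1
  (atan2(dx, dy) * 180 / pi) %% 180
}

#' Directional semivariograms
#'
#' Splits pairs by bearing into angular sectors and computes one
#' empirical variogram per direction — the standard anisotropy check.
#' Each sector is the half-open interval `[angle - tol, angle + tol)`
#' (mod 180); with the default four axes at 45 degree spacing and
#' `tol = 22.5` the sectors partition the half-circle, so every pair is
#' used exactly once.
#'
#' @inheritParams empirical_variogram
#' @param angles Sector centre bearings in degrees (0 = north-south).
#' @param tol Half-width of each sector in degrees.
#' @return A tibble of class `wolb_directional_variogram`: the per-sector
#'   variograms stacked with a leading `angle` column.
#' @export
directional_variograms <- function(sites, z, angles = c(0, 45, 90, 135),
                                   tol = 22.5, lag_width = 60, cutoff = 2000) {
  stopifnot(tol > 0)
  if (length(angles) > 1) {
    a <- sort(angles %% 180)
    gaps <- diff(c(a, a[1] + 180))
    if (any(gaps < 2 * tol - 1e-9)) {
      abort("angle sectors overlap: spacing must be >= 2 * tol",
        class = "wolb_config_error"
      )
    }
  }
  n <- nrow(sites)
  d <- distance_matrix(sites)
  iu <- which(upper.tri(d))
  dist_pair <- d[iu]
  row_i <- row(d)[iu]
  col_k <- col(d)[iu]
  keep <- dist_pair > 0 & dist_pair <= cutoff
  bearing <- pair_bearings(sites, row_i[keep], col_k[keep])
  dist_pair <- dist_pair[keep]
  sqdiff <- (z[row_i[keep]] - z[col_k[keep]])^2
  out <- purrr::map(angles, function(ang) {
    delta <- (bearing - ang) %% 180
    in_sector <- delta < tol | delta >= 180 - tol
    # half-open [-tol, tol): drop the upper edge to avoid double counting
    in_sector[delta == (180 - tol)] <- TRUE
    in_sector[delta == tol] <- FALSE
    if (!any(in_sector)) {
      return(tibble(
        angle = ang, lag_center = numeric(0),
        gamma_hat = numeric(0), n_pairs = integer(0)
      ))
    }
    bin <- ceiling(dist_pair[in_sector] / lag_width - 1e-12)
    tibble(bin = bin, sqdiff = sqdiff[in_sector]) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(
        gamma_hat = sum(.data$sqdiff) / (2 * dplyr::n()),
        n_pairs = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::arrange(.data$bin) |>
      dplyr::mutate(angle = ang, lag_center = (.data$bin - 0.5) * lag_width) |>
      dplyr::select("angle", "lag_center", "gamma_hat", "n_pairs")
  }) |> purrr::list_rbind()
  attr(out, "lag_width") <- lag_width
  attr(out, "cutoff") <- cutoff
  attr(out, "tol") <- tol
  class(out) <- c("wolb_directional_variogram", class(out))
  out
}

#' Variogram map
#'
#' Bins pair separation vectors (east-west, north-south displacement in
#' km on the local tangent plane) into square cells and averages the
#' semivariance within each. Each pair contributes to both its cell and
#' the centrally mirrored cell, so the map is centrally symmetric by
#' construction. A ridge of low semivariance along an axis indicates
#' geometric anisotropy.
#'
#' @inheritParams empirical_variogram
#' @param cell_size Cell edge length in km.
#' @return A tibble with `dx_center`, `dy_center` (km), `gamma_hat`,
#'   `n_pairs`.
#' @export
variogram_map <- function(sites, z, cell_size = 200, cutoff = 2000) {
  stopifnot(cell_size > 0)
  d <- distance_matrix(sites)
  iu <- which(upper.tri(d))
  keep <- d[iu] > 0 & d[iu] <= cutoff
  row_i <- row(d)[iu][keep]
  col_k <- col(d)[iu][keep]
  lat1 <- sites$lat[row_i]; lat2 <- sites$lat[col_k]
  lon1 <- sites$lon[row_i]; lon2 <- sites$lon[col_k]
  mid <- (lat1 + lat2) / 2 * pi / 180
  dx <- (lon2 - lon1) * pi / 180 * cos(mid) * EARTH_RADIUS_KM
  dy <- (lat2 - lat1) * pi / 180 * EARTH_RADIUS_KM
  half_sq <- (z[row_i] - z[col_k])^2 / 2
  # duplicate with mirrored displacement for central symmetry
  tibble(
    cx = floor(c(dx, -dx) / cell_size),
    cy = floor(c(dy, -dy) / cell_size),
    hs = c(half_sq, half_sq)
  ) |>
    dplyr::group_by(.data$cx, .data$cy) |>
    dplyr::summarise(
      gamma_hat = mean(.data$hs),
      n_pairs = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dx_center = (.data$cx + 0.5) * cell_size,
      dy_center = (.data$cy + 0.5) * cell_size
    ) |>
    dplyr::select("dx_center", "dy_center", "gamma_hat", "n_pairs")
}

#' Exponential variogram model
#'
#' Semivariance of the exponential model
#' \deqn{\gamma(r) = C_0 + C_1 (1 - e^{-3r/b}), \quad r > 0,}
#' with \eqn{\gamma(0) = 0} by convention. `C0` is the nugget (variance
#' not spatially structured, including binomial sampling noise), `C1`
#' the partial sill (spatially structured variance), and `b` the
#' practical range: the distance at which the curve reaches
#' \eqn{1 - e^{-3} \approx 95\%} of the partial sill above the nugget.
#'
#' @param model A list or one-row data frame with `C0`, `C1`, `b`.
#' @param r Distances in km (vectorised), `r >= 0`.
#' @return Semivariance values.
#' @export
exponential_gamma <- function(model, r) {
  stopifnot(all(r >= 0))
  m <- as.list(model)
  ifelse(r == 0, 0, m$C0 + m$C1 * (1 - exp(-3 * r / m$b)))
}

variogram_weights <- function(emp, weight_mode) {
  switch(weight_mode,
    npairs_over_h2 = emp$n_pairs / emp$lag_center^2,
    npairs = as.numeric(emp$n_pairs),
    equal = rep(1, nrow(emp)),
    abort("unknown weight_mode", class = "wolb_config_error")
  )
}

#' Fit the exponential variogram model by weighted least squares
#'
#' Minimises \eqn{\sum_j w_j (\hat\gamma_j - \gamma(h_j; C_0, C_1, b))^2}
#' subject to \eqn{C_0, C_1 \ge 0}, \eqn{b > 0}. Default weights
#' \eqn{w_j = N_j / h_j^2} favour well-populated short lags. The
#' objective is multimodal in `b`, so the optimiser (bounded
#' quasi-Newton) is restarted from five deterministic initial ranges —
#' \eqn{\{1/4, 1/2, 1, 2, 4\}\times} the distance at which the empirical
#' semivariance first reaches 80% of its maximum — and ties are broken
#' by lowest weighted SSE, then smallest `b`.
#'
#' @param emp An empirical variogram from [empirical_variogram()] (>= 3
#'   nonempty bins).
#' @param weight_mode `"npairs_over_h2"` (default), `"npairs"`, or
#'   `"equal"`.
#' @param init Optional starting model: list with `C0`, `C1`, `b`.
#' @return An object of class `wolb_variogram_fit`: a list with `C0`,
#'   `C1`, `b`, the weighted `sse`, `weight_mode`, `converged`,
#'   `range_identifiable` (FALSE for a pure-nugget fit, where `b` is
#'   meaningless), and the empirical variogram used.
#' @export
fit_exponential <- function(emp, weight_mode = c("npairs_over_h2", "npairs", "equal"),
                            init = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (nrow(emp) < 3) {
    abort("need at least 3 nonempty lag bins to fit", class = "wolb_fit_error")
  }
  h <- emp$lag_center
  g <- emp$gamma_hat
  w <- variogram_weights(emp, weight_mode)

  sse <- function(par) {
    gam <- par[1] + par[2] * (1 - exp(-3 * h / par[3]))
    sum(w * (g - gam)^2)
  }

  g_max <- max(g)
  g_min <- min(g)
  d80 <- h[which(g >= 0.8 * g_max)[1]]
  starts <- purrr::map(c(0.25, 0.5, 1, 2, 4) * d80, function(b0) {
    c(C0 = max(g_min, 1e-8), C1 = max(g_max - g_min, 1e-6), b = b0)
  })
  if (!is.null(init)) {
    init <- as.list(init)
    starts <- c(starts, list(c(C0 = init$C0, C1 = max(init$C1, 1e-10), b = init$b)))
  }

  fits <- purrr::map(starts, function(p0) {
    tryCatch(
      optim(p0, sse,
        method = "L-BFGS-B",
        lower = c(0, 0, 1e-6),
        upper = c(Inf, Inf, 1e7),
        control = list(maxit = 1000, factr = 1e2, pgtol = 1e-14, parscale = c(
          max(g_max, 1e-3), max(g_max, 1e-3), max(d80, 1)
        ))
      ),
      error = function(e) NULL
    )
  }) |> purrr::compact()
  if (length(fits) == 0) {
    abort("variogram fit failed to converge from all starts", class = "wolb_fit_error")
  }
  values <- vapply(fits, function(f) f$value, numeric(1))
  bs <- vapply(fits, function(f) f$par[3], numeric(1))
  best <- order(values, bs)[1]
  fit <- fits[[best]]

  # Levenberg-Marquardt polish: the WLS objective is nearly flat close
  # to the optimum (exactly zero residuals on noiseless bins), where
  # quasi-Newton stalls; LM on the weighted residuals sharpens the
  # solution to solver precision.
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = fit$par,
      fn = function(par) {
        sqrt(w) * (g - (par[1] + par[2] * (1 - exp(-3 * h / par[3]))))
      },
      lower = c(0, 0, 1e-6), upper = c(Inf, Inf, 1e7),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (!is.null(polish) && sum(polish$fvec^2) <= fit$value) {
    fit$par <- setNames(polish$par, names(fit$par))
    fit$value <- sum(polish$fvec^2)
    fit$convergence <- 0L
  }

  par <- fit$par
  total <- par[1] + par[2]
  # partial sill indistinguishable from zero: flat semivariogram, the
  # range is meaningless
  identifiable <- par[2] > 1e-8 && par[2] > 1e-3 * max(total, 1e-12)
  if (!identifiable) par[2] <- 0

  structure(
    list(
      C0 = unname(par[1]),
      C1 = unname(par[2]),
      b = unname(par[3]),
      sse = fit$value,
      weight_mode = weight_mode,
      converged = fit$convergence == 0,
      range_identifiable = identifiable,
      empirical = emp
    ),
    class = "wolb_variogram_fit"
  )
}

#' @export
print.wolb_variogram_fit <- function(x, ...) {
  cat("Exponential variogram fit\n")
  cat(sprintf(
    "  nugget C0 = %.5g, partial sill C1 = %.5g, range b = %.5g km\n",
    x$C0, x$C1, x$b
  ))
  cat(sprintf(
    "  weighted SSE = %.5g (weights: %s)%s\n",
    x$sse, x$weight_mode,
    if (x$range_identifiable) "" else "  [pure nugget; b unidentifiable]"
  ))
  invisible(x)
}

#' @method tidy wolb_variogram_fit
#' @export
tidy.wolb_variogram_fit <- function(x, ...) {
  tibble(
    term = c("C0", "C1", "b"),
    estimate = c(x$C0, x$C1, x$b),
    description = c(
      "nugget variance (not spatially structured)",
      "partial sill (spatially structured variance)",
      "practical range, km"
    )
  )
}

#' @method glance wolb_variogram_fit
#' @export
glance.wolb_variogram_fit <- function(x, ...) {
  tibble(
    sill_total = x$C0 + x$C1,
    sse = x$sse,
    n_bins = nrow(x$empirical),
    weight_mode = x$weight_mode,
    converged = x$converged,
    range_identifiable = x$range_identifiable
  )
}

#' Distance at which the fitted variogram reaches 95% of the total sill
#'
#' For the exponential model the parameter `b` is where the curve
#' reaches \eqn{1 - e^{-3} \approx 95.02\%} of the partial sill above
#' the nugget. When a nugget is present the distance at which
#' \eqn{\gamma(r) = 0.95 (C_0 + C_1)} differs; this function returns
#' that exact solution,
#' \deqn{r^* = -\frac{b}{3} \log\left(\frac{0.05 (C_0 + C_1)}{C_1}\right),}
#' alongside `b`. If 95% of the total sill already lies below the
#' nugget (\eqn{C_1 \le C_0/19}) the level is reached immediately and
#' `range95` is 0.
#'
#' @param model A `wolb_variogram_fit` or any list with `C0`, `C1`, `b`.
#' @return A tibble with `range95` (km) and `b` (km).
#' @export
practical_range <- function(model) {
  m <- as.list(model)
  if (is.null(m$C1) || m$C1 <= 0) {
    abort("practical range undefined: partial sill C1 is zero",
      class = "wolb_undefined_range_error"
    )
  }
  ratio <- 0.05 * (m$C0 + m$C1) / m$C1
  r95 <- if (ratio >= 1) 0 else -(m$b / 3) * log(ratio)
  tibble(range95 = r95, b = m$b)
}
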
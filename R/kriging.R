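# Build the ordinary kriging coefficient matrix [Gamma 1; 1' 0] for a
# site set under an exponential variogram model. Coincident sites make
# the system singular and are a hard error: deduplicate upstream with
# filter_duplicate_locations().
ok_system_matrix <- function(model, sites, d = NULL) {
  n <- nrow(sites)
  if (is.null(d)) d <- distance_matrix(sites)
  if (n > 1) {
    off <- d[upper.tri(d)]
    if (any(off < 1e-9)) {
      abort(
        "coincident site coordinates make the kriging system singular; deduplicate sites first (filter_duplicate_locations)",
        class = "wolb_singular_system_error"
      )
    }
  }
  Gamma <- matrix(exponential_gamma(model, d), n, n)
  diag(Gamma) <- 0
  rbind(cbind(Gamma, 1), c(rep(1, n), 0))
}

# Solve A x = b for the OK system with a ridge fallback on
# near-singularity: 1e-10 added to the Gamma diagonal, with a warning.
ok_solve <- function(A, b) {
  n <- nrow(A) - 1
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol) || anyNA(sol)) {
    warn("kriging system ill-conditioned; applying 1e-10 diagonal ridge")
    A[seq_len(n), seq_len(n)] <- A[seq_len(n), seq_len(n)] + diag(1e-10, n)
    sol <- solve(A, b)
  }
  sol
}

#' Ordinary kriging weights at a target location
#'
#' Solves the ordinary kriging system
#' \deqn{\begin{pmatrix}\Gamma & 1\\ 1^\top & 0\end{pmatrix}
#'   \begin{pmatrix}w\\ \lambda\end{pmatrix} =
#'   \begin{pmatrix}\gamma_0\\ 1\end{pmatrix}}
#' where \eqn{\Gamma_{ik} = \gamma(d_{ik})} for \eqn{i \ne k} with zero
#' diagonal, and \eqn{\gamma_0} holds the modelled semivariances between
#' each site and the target. The constraint row forces the weights to
#' sum to 1 (constant unknown mean, `z ~ 1`).
#'
#' @param model A fitted variogram model (`wolb_variogram_fit` or list
#'   with `C0`, `C1`, `b`).
#' @param sites Data frame of observation sites (`lat`, `lon`).
#' @param target Numeric `c(lat, lon)` of the prediction location.
#' @return A list with `weights` (length n, summing to 1) and
#'   `lagrange` (the Lagrange multiplier).
#' @export
solve_ok_system <- function(model, sites, target) {
  n <- nrow(sites)
  stopifnot(n >= 1)
  A <- ok_system_matrix(model, sites)
  d0 <- haversine_km(as.matrix(sites[, c("lat", "lon")]), matrix(target, ncol = 2))
  gamma0 <- exponential_gamma(model, d0)
  sol <- ok_solve(A, c(gamma0, 1))
  list(weights = sol[seq_len(n)], lagrange = sol[n + 1])
}

#' Ordinary kriging prediction at one location
#'
#' Predicts \eqn{\hat z = \sum_i w_i z_i} with kriging variance
#' \eqn{\sigma^2 = \sum_i w_i \gamma_{0i} + \lambda}. Because the
#' variable is an infection frequency, the prediction is clamped to
#' \eqn{[0, 1]} by default; the raw value is always retained in
#' `z_hat_raw`. The kriging variance depends only on site geometry and
#' the variogram model, not on the observed values.
#'
#' @inheritParams solve_ok_system
#' @param z Observed values at the sites (infection frequencies).
#' @param clamp Clamp predictions to `[0, 1]`? Default TRUE.
#' @return A one-row tibble: `lat`, `lon`, `z_hat`, `krig_var`,
#'   `z_hat_raw`; the weights are attached as attribute `weights`.
#' @export
predict_point <- function(model, sites, z, target, clamp = TRUE) {
  stopifnot(length(z) == nrow(sites))
  sys <- solve_ok_system(model, sites, target)
  d0 <- haversine_km(as.matrix(sites[, c("lat", "lon")]), matrix(target, ncol = 2))
  gamma0 <- exponential_gamma(model, d0)
  raw <- sum(sys$weights * z)
  out <- tibble(
    lat = target[1],
    lon = target[2],
    z_hat = if (clamp) min(1, max(0, raw)) else raw,
    krig_var = sum(sys$weights * gamma0) + sys$lagrange,
    z_hat_raw = raw
  )
  attr(out, "weights") <- sys$weights
  out
}

#' Ordinary kriging over a prediction grid
#'
#' Kriges every grid point from the observation sites. By default all
#' sites enter every prediction (global kriging; appropriate for a few
#' hundred sites) and the coefficient matrix is factorised once. With
#' `neighborhood = k`, only the k nearest sites to each grid point are
#' used and systems are solved per point; per-point failures are
#' recorded as `NA` rows rather than aborting the surface.
#'
#' @inheritParams predict_point
#' @param grid Data frame of prediction points (`lat`, `lon`), e.g. from
#'   [make_grid()].
#' @param neighborhood Optional integer: number of nearest sites per
#'   prediction. `NULL` (default) uses all sites.
#' @return A tibble of class `wolb_surface`: `lat`, `lon`, `z_hat`,
#'   `krig_var`, `z_hat_raw`, with the model and clamp flag as
#'   attributes.
#' @export
predict_grid <- function(model, sites, z, grid, neighborhood = NULL, clamp = TRUE) {
  stopifnot(nrow(grid) >= 1, length(z) == nrow(sites))
  n <- nrow(sites)
  if (!is.null(neighborhood) && neighborhood < n) {
    k <- as.integer(neighborhood)
    d_cross <- cross_distance_matrix(sites, grid)
    rows <- purrr::map(seq_len(nrow(grid)), function(j) {
      idx <- order(d_cross[, j])[seq_len(k)]
      tryCatch(
        predict_point(model, sites[idx, ], z[idx],
          c(grid$lat[j], grid$lon[j]),
          clamp = clamp
        ),
        error = function(e) {
          tibble(
            lat = grid$lat[j], lon = grid$lon[j],
            z_hat = NA_real_, krig_var = NA_real_, z_hat_raw = NA_real_
          )
        }
      )
    })
    out <- purrr::list_rbind(rows)
  } else {
    A <- ok_system_matrix(model, sites)
    d_cross <- cross_distance_matrix(sites, grid)
    Gamma0 <- matrix(exponential_gamma(model, d_cross), n, nrow(grid))
    B <- rbind(Gamma0, 1)
    sol <- tryCatch(solve(A, B), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol)) {
      warn("kriging system ill-conditioned; applying 1e-10 diagonal ridge")
      A[seq_len(n), seq_len(n)] <- A[seq_len(n), seq_len(n)] + diag(1e-10, n)
      sol <- solve(A, B)
    }
    W <- sol[seq_len(n), , drop = FALSE]
    lagrange <- sol[n + 1, ]
    raw <- drop(crossprod(W, z))
    out <- tibble(
      lat = grid$lat,
      lon = grid$lon,
      z_hat = if (clamp) pmin(1, pmax(0, raw)) else raw,
      krig_var = colSums(W * Gamma0) + lagrange,
      z_hat_raw = raw
    )
  }
  attr(out, "model") <- list(C0 = model$C0, C1 = model$C1, b = model$b)
  attr(out, "clamp_applied") <- clamp
  class(out) <- c("wolb_surface", class(out))
  out
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Predicts each site from the remaining n - 1 and summarises the
#' residuals: mean error (bias), RMSE, empirical coverage of the
#' nominal 95% prediction interval \eqn{\pm 1.96\sqrt{\sigma^2}}, and
#' the variance of the standardised residuals
#' \eqn{(z_i - \hat z_i)/\sqrt{\sigma_i^2}}, which is ~1 when the
#' variogram model is well specified.
#'
#' @inheritParams predict_point
#' @return A tibble of class `wolb_loocv` with one row per site:
#'   `id` (if present), `lat`, `lon`, `observed`, `predicted`,
#'   `krig_var`, `residual`, `std_residual`. Summary statistics via
#'   [glance()].
#' @export
loocv <- function(model, sites, z, clamp = FALSE) {
  n <- nrow(sites)
  if (n < 3) abort("LOOCV needs at least 3 sites", class = "wolb_domain_error")
  rows <- purrr::map(seq_len(n), function(i) {
    p <- predict_point(model, sites[-i, ], z[-i],
      c(sites$lat[i], sites$lon[i]),
      clamp = clamp
    )
    tibble(
      lat = sites$lat[i],
      lon = sites$lon[i],
      observed = z[i],
      predicted = p$z_hat,
      krig_var = p$krig_var
    )
  })
  out <- purrr::list_rbind(rows)
  if ("id" %in% names(sites)) out <- dplyr::bind_cols(tibble(id = sites$id), out)
  out <- out |>
    dplyr::mutate(
      residual = .data$observed - .data$predicted,
      std_residual = .data$residual / sqrt(pmax(.data$krig_var, .Machine$double.eps))
    )
  class(out) <- c("wolb_loocv", class(out))
  out
}

#' @method glance wolb_loocv
#' @export
glance.wolb_loocv <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    mean_error = mean(x$residual),
    rmse = sqrt(mean(x$residual^2)),
    coverage95 = mean(abs(x$residual) <= 1.96 * sqrt(pmax(x$krig_var, 0))),
    std_resid_var = stats::var(x$std_residual)
  )
}
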
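# Empirical sample-size pool: the per-population sample sizes of the
# study's native-range table, plus a down-weighted right tail so the law
# has mean ~12 and range 1-68 like the historical dataset.
sample_size_pool <- function() {
  base <- c(12, 12, 12, 12, 12, 12, 9, 10, 12, 2, 12, 12, 11, 5)
  tail <- c(1, 8, 16, 20, 26, 34, 45, 56, 68)
  list(sizes = c(base, tail), prob = c(rep(1, length(base)), rep(0.15, length(tail))))
}

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic population-table generator:
#' site layout, the exponential spatial covariance of the latent
#' infection-frequency surface, the mean frequency, the per-site sample
#' size law, and the link mapping the Gaussian field to `[0, 1]`.
#'
#' Defaults mirror the study conditions: 238 sites over Europe and
#' western Russia, per-site sample sizes with mean ~12 and range 1-68
#' (resampled from the study's empirical sizes plus a right tail), and a
#' latent surface with nugget `C0 = 0.05`, partial sill `C1 = 0.20`,
#' practical range `b = 600` km — synthetic fixture values consistent
#' with a variogram that rises over the first few hundred km and
#' plateaus within ~1000 km.
#'
#' @param n_sites Number of populations to simulate.
#' @param bbox Bounding box `(lat_min, lat_max, lon_min, lon_max)`.
#' @param C0,C1,b Variogram parameters of the latent field (nugget,
#'   partial sill, practical range in km).
#' @param mean_p Mean infection frequency of the latent field.
#' @param sample_size_law `"empirical"` (default law above), a single
#'   integer for fixed N, or a function `(m) -> integer vector`.
#' @param link `"truncate"` (default; clamp the Gaussian field to
#'   `[0, 1]`, matching the mass at 0 and 1 seen in real frequency
#'   tables) or `"logit"` (variance-matched logistic transform).
#' @param site_mode `"uniform"` or `"clustered"` (Thomas-process-like:
#'   uniform parents with Gaussian offspring, mimicking dense regional
#'   sampling).
#' @param seed Integer seed; every simulator is deterministic given the
#'   config.
#' @param year Calendar year stamped on simulated rows.
#' @return A list of class `wolb_sim_config`.
#' @export
sim_config <- function(n_sites = 238,
                       bbox = c(34, 71, -11, 61),
                       C0 = 0.05, C1 = 0.20, b = 600,
                       mean_p = 0.5,
                       sample_size_law = "empirical",
                       link = c("truncate", "logit"),
                       site_mode = c("uniform", "clustered"),
                       seed = 1L,
                       year = 2020L) {
  link <- match.arg(link)
  site_mode <- match.arg(site_mode)
  stopifnot(
    n_sites >= 0, mean_p >= 0, mean_p <= 1,
    C0 >= 0, C1 >= 0, b > 0, length(bbox) == 4
  )
  structure(
    list(
      n_sites = as.integer(n_sites), bbox = as.numeric(bbox),
      model = list(C0 = C0, C1 = C1, b = b),
      mean_p = mean_p, sample_size_law = sample_size_law,
      link = link, site_mode = site_mode,
      seed = as.integer(seed), year = as.integer(year)
    ),
    class = "wolb_sim_config"
  )
}

#' Simulate site locations
#'
#' Uniform points in the bounding box, or a clustered layout (parents
#' uniform, offspring Gaussian around parents with 1.5 degree spread,
#' reflected into the box) mimicking dense regional sampling.
#'
#' @param config A [sim_config()].
#' @return A tibble of `lat`, `lon` with `n_sites` rows.
#' @export
simulate_sites <- function(config) {
  bb <- config$bbox
  n <- config$n_sites
  if (n == 0) return(tibble(lat = numeric(0), lon = numeric(0)))
  withr::with_seed(config$seed, {
    if (config$site_mode == "uniform") {
      lat <- runif(n, bb[1], bb[2])
      lon <- runif(n, bb[3], bb[4])
    } else {
      n_parents <- max(1L, round(n / 10))
      pl <- runif(n_parents, bb[1], bb[2])
      pn <- runif(n_parents, bb[3], bb[4])
      pick <- sample.int(n_parents, n, replace = TRUE)
      reflect <- function(x, lo, hi) {
        span <- hi - lo
        x <- (x - lo) %% (2 * span)
        lo + ifelse(x > span, 2 * span - x, x)
      }
      lat <- reflect(pl[pick] + rnorm(n, sd = 1.5), bb[1], bb[2])
      lon <- reflect(pn[pick] + rnorm(n, sd = 1.5), bb[3], bb[4])
    }
    tibble(lat = lat, lon = lon)
  })
}

#' Simulate a spatially autocorrelated frequency surface at sites
#'
#' Draws one realisation of a Gaussian random field with mean `mean_p`
#' and covariance \eqn{C_0 I + C_1 e^{-3 d / b}} (the covariance dual of
#' the exponential variogram), via Cholesky factorisation of the dense
#' covariance matrix, then maps it to `[0, 1]` through the link:
#' truncation (default), or a logistic transform whose slope is
#' variance-matched at `mean_p` by the delta method.
#'
#' @param sites Site tibble (`lat`, `lon`).
#' @param model List with `C0`, `C1`, `b`.
#' @param mean_p Mean frequency.
#' @param link `"truncate"` or `"logit"`.
#' @param seed Integer seed.
#' @return Numeric vector of per-site latent frequencies in `[0, 1]`.
#' @export
simulate_latent_field <- function(sites, model, mean_p = 0.5,
                                  link = c("truncate", "logit"), seed = 1L) {
  link <- match.arg(link)
  n <- nrow(sites)
  if (n == 0) return(numeric(0))
  sigma_tot <- model$C0 + model$C1
  if (sigma_tot == 0) {
    return(rep(mean_p, n))
  }
  d <- if (n > 1) distance_matrix(sites) else matrix(0, 1, 1)
  Sigma <- model$C1 * exp(-3 * d / model$b)
  diag(Sigma) <- sigma_tot
  L <- NULL
  for (ridge in c(0, 1e-10, 1e-8)) {
    L <- tryCatch(chol(Sigma + diag(ridge, n)), error = function(e) NULL)
    if (!is.null(L)) break
  }
  if (is.null(L)) {
    abort("covariance matrix not positive definite even after ridge",
      class = "wolb_simulation_error"
    )
  }
  withr::with_seed(seed, {
    x <- drop(crossprod(L, rnorm(n)))
  })
  if (link == "truncate") {
    pmin(1, pmax(0, mean_p + x))
  } else {
    slope <- 1 / max(mean_p * (1 - mean_p), 1e-6)
    stats::plogis(stats::qlogis(min(max(mean_p, 1e-6), 1 - 1e-6)) + slope * x)
  }
}

# draw per-site sample sizes from the configured law
draw_sample_sizes <- function(m, law) {
  if (is.function(law)) {
    return(as.integer(law(m)))
  }
  if (is.numeric(law)) {
    return(rep(as.integer(law), m))
  }
  if (identical(law, "empirical")) {
    pool <- sample_size_pool()
    return(sample(pool$sizes, m, replace = TRUE, prob = pool$prob))
  }
  abort("unknown sample_size_law", class = "wolb_config_error")
}

#' Simulate binomial sampling of the latent frequencies
#'
#' Draws per-site sample sizes from the configured law and infected
#' counts `k ~ Binomial(n, latent_p)`.
#'
#' @param latent_p Per-site frequencies in `[0, 1]`.
#' @param sample_size_law See [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with `n` and `k` per site.
#' @export
simulate_counts <- function(latent_p, sample_size_law = "empirical", seed = 1L) {
  stopifnot(all(latent_p >= 0), all(latent_p <= 1))
  m <- length(latent_p)
  withr::with_seed(seed, {
    n <- draw_sample_sizes(m, sample_size_law)
    k <- rbinom(m, n, latent_p)
  })
  tibble(n = as.integer(n), k = as.integer(k))
}

#' Generate a complete synthetic population table
#'
#' Composes [simulate_sites()], [simulate_latent_field()] and
#' [simulate_counts()] (with seeds derived from the config seed) into a
#' population table that passes [validate_population_table()]
#' unchanged, plus the generating truth for parameter-recovery
#' experiments.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (population tibble) and `truth` (tibble
#'   of per-site `latent_p` plus the generating parameters as
#'   attributes).
#' @export
#' @examples
#' sim <- generate_dataset(sim_config(n_sites = 40, seed = 7))
#' sim$table
generate_dataset <- function(config) {
  sites <- simulate_sites(config)
  latent <- simulate_latent_field(
    sites, config$model, config$mean_p, config$link,
    seed = config$seed + 1L
  )
  counts <- simulate_counts(latent, config$sample_size_law, seed = config$seed + 2L)
  tbl <- tibble(
    id = sprintf("S%04d", seq_len(config$n_sites)),
    lat = sites$lat,
    lon = sites$lon,
    year = config$year,
    n = counts$n,
    k = counts$k,
    haplotypes = NA_character_,
    range_label = "native"
  )
  truth <- tibble(id = tbl$id, lat = tbl$lat, lon = tbl$lon, latent_p = latent)
  attr(truth, "model") <- config$model
  attr(truth, "mean_p") <- config$mean_p
  attr(truth, "seed") <- config$seed
  list(table = validate_population_table(tbl), truth = truth)
}
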
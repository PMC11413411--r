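#' Score grid cells as candidate invasion origins
#'
#' Given a kriged infection-frequency surface and the invasive-range
#' sample (`k_inv` infected out of `n_inv`), scores every grid cell by
#' the binomial probability of the invasive observation if the founders
#' had come from a population with that cell's predicted frequency:
#' `compat = dbinom(k_inv, n_inv, p)`. Cells with `compat >= alpha` are
#' flagged as candidate origins. For an entirely uninfected invasive
#' sample (`k_inv = 0`, the motivating case) this is
#' \eqn{(1 - p)^{n_{inv}}}, which excludes regions predicted to be at
#' high or fixed infection frequency and retains uninfected regions.
#'
#' The binomial compatibility score is a quantitative formalisation of
#' the qualitative rule "uninfected regions are candidate origins"; the
#' threshold `alpha` is a configuration choice, not an estimate.
#'
#' @param surface A `wolb_surface` from [predict_grid()] (or any data
#'   frame with `lat`, `lon`, `z_hat`).
#' @param k_inv Number infected in the invasive sample.
#' @param n_inv Number genotyped in the invasive sample.
#' @param alpha Compatibility threshold in (0, 1); default 0.05.
#' @param tail `"point"` (default) scores the exact point mass;
#'   `"two_sided"` scores a two-tailed exact binomial p-value (the sum
#'   of point masses not exceeding the observed one).
#' @return A tibble: `lat`, `lon`, `predicted_p`, `compat`, `candidate`.
#' @export
invasion_compatibility <- function(surface, k_inv, n_inv, alpha = 0.05,
                                   tail = c("point", "two_sided")) {
  tail <- match.arg(tail)
  stopifnot(k_inv >= 0, k_inv <= n_inv, n_inv >= 1, alpha > 0, alpha < 1)
  p <- pmin(1, pmax(0, surface$z_hat))
  compat <- if (tail == "point") {
    dbinom(k_inv, n_inv, p)
  } else {
    vapply(p, function(pp) {
      mass <- dbinom(0:n_inv, n_inv, pp)
      sum(mass[mass <= mass[k_inv + 1] * (1 + 1e-7)])
    }, numeric(1))
  }
  tibble(
    lat = surface$lat,
    lon = surface$lon,
    predicted_p = p,
    compat = compat,
    candidate = compat >= alpha
  )
}

#' Endosymbiont-haplotype concordance
#'
#' Cross-tabulates per-individual infection status against mitochondrial
#' haplotype. Because the CI-causing strain is co-transmitted maternally
#' with haplotype HT2, infected individuals are expected to carry HT2
#' and uninfected individuals HT1; the misassociation rate counts
#' infected/HT1 and uninfected/HT2 individuals (paternal leakage or
#' horizontal transmission in transitional populations).
#'
#' @param individuals Data frame with columns `status` (`"infected"` /
#'   `"uninfected"`) and `haplotype` (`"HT1"` / `"HT2"`).
#' @return A one-row tibble: `n_scored`, `n_infected_HT2`,
#'   `n_infected_HT1`, `n_uninfected_HT1`, `n_uninfected_HT2`,
#'   `misassociation_rate`.
#' @export
#' @examples
#' haplotype_concordance(data.frame(
#'   status = rep("uninfected", 40), haplotype = rep("HT1", 40)
#' ))
haplotype_concordance <- function(individuals) {
  status <- individuals$status
  ht <- individuals$haplotype
  if (!all(status %in% c("infected", "uninfected"))) {
    abort("status labels must be 'infected' or 'uninfected'",
      class = "wolb_validation_error"
    )
  }
  if (!all(ht %in% c("HT1", "HT2"))) {
    abort("haplotype labels must be 'HT1' or 'HT2'", class = "wolb_validation_error")
  }
  n <- length(status)
  n_inf_ht2 <- sum(status == "infected" & ht == "HT2")
  n_inf_ht1 <- sum(status == "infected" & ht == "HT1")
  n_unf_ht1 <- sum(status == "uninfected" & ht == "HT1")
  n_unf_ht2 <- sum(status == "uninfected" & ht == "HT2")
  tibble(
    n_scored = n,
    n_infected_HT2 = n_inf_ht2,
    n_infected_HT1 = n_inf_ht1,
    n_uninfected_HT1 = n_unf_ht1,
    n_uninfected_HT2 = n_unf_ht2,
    misassociation_rate = if (n == 0) NA_real_ else (n_inf_ht1 + n_unf_ht2) / n
  )
}

#' Deterministic spread criterion for a maternally inherited symbiont
#'
#' A strain with relative host fecundity `F` and maternal transmission
#' failure rate `mu` increases deterministically from rarity if and only
#' if its effective fecundity exceeds one: \eqn{F (1 - \mu) > 1}
#' (Fisherian dynamics). Otherwise the dynamics are bistable: a rare
#' infection is lost even if strong cytoplasmic incompatibility would
#' maintain it once common. The boundary \eqn{F(1-\mu) = 1} is
#' classified as bistable (strict inequality).
#'
#' @param F_rel Relative fecundity of infected females, `>= 0`.
#'   Vectorised.
#' @param mu Proportion of uninfected offspring from infected mothers,
#'   in `[0, 1]`. Vectorised.
#' @return A tibble: `F_rel`, `mu`, `effective_fecundity`, `outcome`
#'   (`"spreads_from_rare"` or `"bistable"`).
#' @export
#' @examples
#' ci_spread_criterion(1.1, 0.05) # spreads from rare
#' ci_spread_criterion(1, 0) # boundary: bistable
ci_spread_criterion <- function(F_rel, mu) {
  stopifnot(all(F_rel >= 0), all(mu >= 0), all(mu <= 1))
  eff <- F_rel * (1 - mu)
  tibble(
    F_rel = F_rel,
    mu = mu,
    effective_fecundity = eff,
    outcome = ifelse(eff > 1, "spreads_from_rare", "bistable")
  )
}
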
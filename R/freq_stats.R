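#' Wilson score confidence interval for a binomial proportion
#'
#' Computes the Wilson score interval for `k` successes out of `n`
#' trials. With \eqn{z} the standard-normal \eqn{(1 + conf)/2} quantile
#' and \eqn{\hat p = k/n}, the interval is centred at
#' \eqn{(k + z^2/2)/(n + z^2)} with half-width
#' \eqn{z \sqrt{\hat p (1 - \hat p)/n + z^2/(4 n^2)} / (1 + z^2/n)},
#' clipped to \eqn{[0, 1]}. A Clopper-Pearson ("exact") variant is
#' available through `method`.
#'
#' @param k Number of infected (successes), `0 <= k <= n`. Vectorised.
#' @param n Number genotyped (trials), `n >= 1`. Vectorised.
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return A tibble with columns `ci_low` and `ci_high`.
#' @export
#' @examples
#' wilson_ci(10, 12) # (0.552, 0.953)
#' wilson_ci(0, 40) # upper bound ~0.087
wilson_ci <- function(k, n, conf_level = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(n < 1)) abort("n must be >= 1", class = "wolb_domain_error")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n", class = "wolb_domain_error")
  if (conf_level <= 0 || conf_level >= 1) {
    abort("conf_level must be in (0, 1)", class = "wolb_domain_error")
  }
  if (method == "clopper-pearson") {
    alpha <- 1 - conf_level
    lo <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
    return(tibble(ci_low = lo, ci_high = hi))
  }
  z <- qnorm((1 + conf_level) / 2)
  p_hat <- k / n
  center <- (k + z^2 / 2) / (n + z^2)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tibble(
    # the clip is exact at the boundaries: p_hat = 0 (or 1) forces it
    ci_low = ifelse(k == 0, 0, pmax(0, center - half)),
    ci_high = ifelse(k == n, 1, pmin(1, center + half))
  )
}

#' Estimate per-population infection frequencies
#'
#' Computes, for every population row, the observed infection frequency
#' `p_hat = k/n` with its binomial confidence interval.
#'
#' @param tbl A population table (see [read_population_table()]).
#' @param conf_level Confidence level for the interval; default 0.95.
#' @param method Interval method passed to [wilson_ci()].
#' @return A tibble `id, year, n, k, p_hat, ci_low, ci_high`.
#' @export
#' @examples
#' path <- system.file("extdata", "table1_populations.csv", package = "wolbtrace")
#' read_population_table(path) |> estimate_frequencies()
estimate_frequencies <- function(tbl, conf_level = 0.95,
                                 method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  ci <- wilson_ci(tbl$k, tbl$n, conf_level = conf_level, method = method)
  tibble(
    id = tbl$id,
    year = tbl$year,
    n = tbl$n,
    k = tbl$k,
    p_hat = tbl$k / tbl$n,
    ci_low = ci$ci_low,
    ci_high = ci$ci_high
  )
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional two-sided exact test: with both margins fixed, the P-value
#' sums hypergeometric probabilities of all tables whose probability does
#' not exceed that of the observed table (up to a relative slack of
#' 1e-7). The table is laid out as rows = groups, columns =
#' (infected, uninfected):
#' \preformatted{  a  b
#'   c  d}
#'
#' @param a,b,c,d Nonnegative integer cell counts; at least one positive.
#' @return A tibble with `p_value`, `method`, and the four cell counts.
#' @export
#' @examples
#' fisher_exact_2x2(10, 2, 12, 0) # P = 0.478
#' fisher_exact_2x2(10, 2, 2, 5) # P = 0.045
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be nonnegative integers", class = "wolb_domain_error")
  }
  if (sum(counts) == 0) {
    abort("at least one cell must be positive", class = "wolb_domain_error")
  }
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(m, alternative = "two.sided")$p.value
  tibble(
    p_value = min(p, 1),
    method = "fisher_exact_two_sided",
    a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2]
  )
}

#' Compare infection frequencies of two samples
#'
#' Builds the 2x2 contingency table (infected, uninfected) x (sample 1,
#' sample 2) and applies the two-sided Fisher exact test. Accepts either
#' population rows (columns `n`, `k`) or pooled totals (columns
#' `n_total`, `k_total`); each input must describe exactly one sample.
#' Comparisons are strictly pairwise.
#'
#' @param s1,s2 One-row data frames, or named vectors/lists with elements
#'   `n` and `k`.
#' @return A tibble as returned by [fisher_exact_2x2()].
#' @export
#' @examples
#' compare_populations(c(n = 12, k = 10), c(n = 7, k = 2)) # P = 0.045
compare_populations <- function(s1, s2) {
  nk <- function(s) {
    s <- as.list(s)
    n <- s$n %||% s$n_total
    k <- s$k %||% s$k_total
    if (is.null(n) || is.null(k)) {
      abort("each sample needs n and k (or n_total and k_total)",
        class = "wolb_domain_error"
      )
    }
    c(n = as.integer(n[[1]]), k = as.integer(k[[1]]))
  }
  x1 <- nk(s1)
  x2 <- nk(s2)
  if (x1[["n"]] < 1 || x2[["n"]] < 1) {
    abort("both samples must have n >= 1", class = "wolb_domain_error")
  }
  fisher_exact_2x2(
    x1[["k"]], x1[["n"]] - x1[["k"]],
    x2[["k"]], x2[["n"]] - x2[["k"]]
  )
}

#' Round a proportion for display
#'
#' Half-even rounding to 3 significant figures, mirroring the mixed
#' precision used in published frequency tables (0.0470, 0.833, 1).
#'
#' @param x Numeric vector of proportions.
#' @return Rounded numeric vector.
#' @export
format_proportion <- function(x) {
  signif(x, 3)
}
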
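#' Person/household ratio for a stratum
#'
#' The average number of persons of a given sex-by-age stratum per household
#' in the municipality: `N / D`, where `N` is the stratum population and `D`
#' the municipal household total.  The ratio is returned unrounded; round only
#' for display.
#'
#' @param N stratum population count (non-negative).
#' @param D municipal household total (positive).
#' @return numeric ratio `N / D` (vectorised over `N`).
#' @export
#' @examples
#' round(person_household_ratio(16652, 210093), 4)  # 0.0793
person_household_ratio <- function(N, D) {
  if (any(D <= 0)) stop_("household total D must be positive")
  if (any(N < 0)) stop_("stratum population N must be non-negative")
  N / D
}

#' Households needed to expect a minimum number of individuals in a stratum
#'
#' How many households must be sampled so that the expected number of
#' individuals of a stratum (population `N` out of `D` households) reaches
#' `m_min`.  Computed as `m_min * D / N` with the unrounded person/household
#' ratio, then rounded to the nearest integer (half up).
#'
#' Strata with `N = 0` cannot yield any individuals; they are flagged with
#' `NA` and a warning rather than an infinite requirement.
#'
#' @param N stratum population count.
#' @param D municipal household total.
#' @param m_min minimum expected individuals per stratum (default 30, the
#'   usual normal-approximation threshold).
#' @return integer vector of required households (`NA` where unattainable).
#' @export
#' @examples
#' households_for_minimum(16652, 210093)  # 379
#' households_for_minimum(10905, 210093)  # 578
households_for_minimum <- function(N, D, m_min = 30) {
  if (any(D <= 0)) stop_("household total D must be positive")
  if (m_min <= 0) stop_("m_min must be positive")
  out <- rep(NA_integer_, length(N))
  ok <- N > 0
  if (any(!ok)) {
    warn_("%d stratum(s) with zero population flagged unattainable", sum(!ok))
  }
  out[ok] <- as.integer(round_half_up(m_min * D / N[ok]))
  out
}

#' Base household sample size over a set of strata
#'
#' The base sample `n0` is the maximum over all strata of the per-stratum
#' household requirement: sampling that many households gives every stratum
#' at least its minimum expected count.
#'
#' @param h integer vector of per-stratum household requirements
#'   (from [households_for_minimum()]); `NA` entries (unattainable strata)
#'   are ignored.
#' @return integer `n0`.
#' @export
base_sample_size <- function(h) {
  h <- h[!is.na(h)]
  if (!length(h)) stop_("no attainable strata: cannot compute a sample size")
  as.integer(max(h))
}

#' Inflate a sample size for anticipated non-response
#'
#' Adjusts the base sample `n0` for an anticipated response rate:
#' `n = floor(n0 / response_rate)`.  Truncation (rather than rounding) is the
#' convention used here; with a 90% response rate, 578 households become 642
#' and 620 become 688.
#'
#' @param n0 base household sample size.
#' @param response_rate anticipated response rate in (0, 1]; default 0.90.
#' @return integer inflated sample size `n >= n0`.
#' @export
#' @examples
#' inflate_for_nonresponse(578)  # 642
#' inflate_for_nonresponse(620)  # 688
inflate_for_nonresponse <- function(n0, response_rate = 0.90) {
  if (response_rate <= 0 || response_rate > 1) {
    stop_("response_rate must be in (0, 1]")
  }
  as.integer(floor(n0 / response_rate))
}

#' Expected individuals per stratum for a household sample
#'
#' Expected number of individuals each stratum contributes when `n0`
#' households are sampled: `round(r * n0)` with the unrounded
#' person/household ratio `r = N / D`.
#'
#' @param N stratum population counts.
#' @param D municipal household total.
#' @param n0 household sample size.
#' @return integer vector of expected individuals per stratum.
#' @export
expected_individuals <- function(N, D, n0) {
  if (n0 < 0) stop_("n0 must be non-negative")
  r <- person_household_ratio(N, D)
  as.integer(round_half_up(r * n0))
}

#' Build a full sample-size plan for one municipality
#'
#' Runs the complete planning chain on a stratified reference population:
#' person/household ratios, the households required to expect at least
#' `m_min` individuals in every sex-by-age stratum, the base sample size
#' `n0` (the maximum requirement, attained by the most household-sparse
#' stratum), the non-response-inflated sample `n = floor(n0/response_rate)`,
#' and the expected number of individuals by stratum with sex and grand
#' totals.
#'
#' If rounding a requirement downward leaves that stratum's expectation
#' below `m_min`, a warning identifies it (the plan still reports the
#' conventional arithmetic).
#'
#' @param population data.frame with columns `sex`, `age_group`,
#'   `population` (one municipality; see [reference_census()]).
#' @param households municipal household total `D`.
#' @param m_min minimum expected individuals per stratum (default 30).
#' @param response_rate anticipated response rate (default 0.90).
#' @return An object of class `"sample_plan"`: a list with
#'   `strata` (data.frame: sex, age_group, N, ratio, households_required,
#'   expected_individuals), `D`, `m_min`, `response_rate`, `n0`, `n`,
#'   `limiting_stratum`, `expected_by_sex`, and `expected_total`.
#' @export
#' @examples
#' cen <- reference_census("Picos")
#' plan <- sample_plan(cen$population, cen$households)
#' plan$n0   # 620
#' plan$n    # 688
#' plan$expected_total  # 2134
sample_plan <- function(population, households, m_min = 30,
                        response_rate = 0.90) {
  need <- c("sex", "age_group", "population")
  if (!all(need %in% names(population))) {
    stop_("population must have columns %s", paste(need, collapse = ", "))
  }
  if (!nrow(population)) stop_("empty population table")
  D <- as.numeric(households)
  if (length(D) != 1L || is.na(D) || D <= 0) {
    stop_("households must be a single positive total")
  }

  strata <- data.frame(
    sex = population$sex,
    age_group = population$age_group,
    N = population$population,
    stringsAsFactors = FALSE
  )
  strata$ratio <- person_household_ratio(strata$N, D)
  strata$households_required <- households_for_minimum(strata$N, D, m_min)

  n0 <- base_sample_size(strata$households_required)
  n <- inflate_for_nonresponse(n0, response_rate)
  strata$expected_individuals <- expected_individuals(strata$N, D, n0)

  # exact (unrounded) expectation for the limiting stratum check
  exact_expect <- strata$ratio * n0
  short <- !is.na(strata$households_required) &
    strata$households_required == n0 & exact_expect < m_min
  if (any(short)) {
    warn_(
      "stratum %s %s: expected individuals %.4f falls below the target %d",
      strata$sex[which(short)[1]], as.character(strata$age_group[which(short)[1]]),
      exact_expect[which(short)[1]], m_min
    )
  }

  lim <- which.max(ifelse(is.na(strata$households_required), -Inf,
                          strata$households_required))
  by_sex <- tapply(strata$expected_individuals, strata$sex, sum)

  structure(
    list(
      strata = strata,
      D = D,
      m_min = m_min,
      response_rate = response_rate,
      n0 = n0,
      n = n,
      limiting_stratum = strata[lim, c("sex", "age_group"), drop = FALSE],
      expected_by_sex = by_sex,
      expected_total = sum(strata$expected_individuals)
    ),
    class = "sample_plan"
  )
}

#' @export
print.sample_plan <- function(x, ...) {
  cat("Household sample-size plan\n")
  cat(sprintf("  municipal households (D): %s\n",
              format(x$D, big.mark = ",")))
  cat(sprintf("  minimum individuals per stratum: %d\n", x$m_min))
  cat(sprintf("  base sample n0: %d households (limiting stratum: %s %s)\n",
              x$n0, x$limiting_stratum$sex,
              as.character(x$limiting_stratum$age_group)))
  cat(sprintf("  inflated for %.0f%% response: n = %d households\n",
              100 * x$response_rate, x$n))
  cat(sprintf("  expected individuals: %s (M %s, F %s)\n",
              format(x$expected_total, big.mark = ","),
              format(x$expected_by_sex[["M"]], big.mark = ","),
              format(x$expected_by_sex[["F"]], big.mark = ",")))
  invisible(x)
}

#' Precision profile of a proportion estimate
#'
#' For a sample of `n` individuals and an anticipated proportion `p`, the
#' normal-approximation standard error `se = sqrt(p (1 - p) / n)`, the 95%
#' confidence interval `100 (p +/- z se)` (percent), and the coefficient of
#' variation of the estimate, `Cv = 100 se / p` (percent).  `Cv` below 20%
#' is the usual adequacy criterion for survey estimates.
#'
#' The closed form is the default.  `method = "montecarlo"` estimates the
#' same quantities by binomial resampling (`reps` replicates), which should
#' agree with the closed form within Monte-Carlo error.
#'
#' @param n number of individuals (vectorised; recycled against `p`).
#' @param p anticipated proportion(s) in (0, 1); default grid 0.10 to 0.70.
#' @param z critical value (default 1.96 for 95% confidence).
#' @param method `"analytic"` (closed form) or `"montecarlo"`.
#' @param reps Monte-Carlo replicates (default 10000).
#' @param seed optional RNG seed for the Monte-Carlo mode.
#' @return data.frame of class `"precision_profile"` with columns `n`, `p`,
#'   `se`, `ci_low`, `ci_high` (percent), `cv` (percent).
#' @export
#' @examples
#' precision_profile(46, 0.5)   # cv 14.7, CI 35.5-64.5
#' precision_profile(100, 0.5)  # cv 10.0
precision_profile <- function(n, p = seq(0.10, 0.70, by = 0.10), z = 1.96,
                              method = c("analytic", "montecarlo"),
                              reps = 10000, seed = NULL) {
  method <- match.arg(method)
  if (any(n < 1)) stop_("n must be at least 1")
  if (any(p <= 0 | p >= 1)) stop_("p must be strictly inside (0, 1)")
  grid <- data.frame(n = rep(n, each = length(p)),
                     p = rep(p, times = length(n)))
  if (method == "analytic") {
    se <- sqrt(grid$p * (1 - grid$p) / grid$n)
  } else {
    maybe_seed(seed)
    se <- mapply(function(ni, pi) {
      stats::sd(stats::rbinom(reps, ni, pi) / ni)
    }, grid$n, grid$p)
  }
  out <- data.frame(
    n = grid$n,
    p = grid$p,
    se = se,
    ci_low = 100 * (grid$p - z * se),
    ci_high = 100 * (grid$p + z * se),
    cv = 100 * se / grid$p
  )
  class(out) <- c("precision_profile", "data.frame")
  out
}
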
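#' Assemble a survey dataset from a draw and a person table
#'
#' Joins the interviewed households of a draw to the person records,
#' attaching the design weight and PSU identifier needed by
#' [estimate_proportion()].
#'
#' @param draw a `sample_draw` from [two_stage_draw()].
#' @param persons person table (must carry `household_id`); indicator
#'   columns come along.
#' @param interviewed optional character vector of interviewed household ids
#'   (e.g. from [simulate_fieldwork()]); default all drawn households.
#' @return data.frame of class `"survey_dataset"` with `psu_id`, `weight`
#'   and the person columns; design metadata (`f`, `a`) in attributes.
#' @export
survey_dataset <- function(draw, persons, interviewed = NULL) {
  if (!inherits(draw, "sample_draw")) stop_("draw must be a sample_draw")
  hh <- draw$households
  if (!is.null(interviewed)) {
    hh <- hh[hh$household_id %in% interviewed, , drop = FALSE]
  }
  idx <- match(persons$household_id, hh$household_id)
  keep <- !is.na(idx)
  out <- persons[keep, , drop = FALSE]
  out$psu_id <- hh$psu_id[idx[keep]]
  out$weight <- hh$weight[idx[keep]]
  rownames(out) <- NULL
  attr(out, "design") <- list(f = draw$f, a = draw$a, b = draw$b)
  class(out) <- c("survey_dataset", "data.frame")
  out
}

#' Design-based estimate of a proportion
#'
#' Weighted ratio estimate of a proportion with a Taylor-linearized
#' (ultimate-cluster) variance: the PSUs are treated as independent
#' with-replacement draws from the first stage, absorbing all later stages.
#' With PSU totals `y_i = sum(w y)` and `w_i = sum(w)` over the domain,
#' `p = Y / W` and the linearized PSU residuals are
#' `u_i = (y_i - p w_i) / W`; the variance is
#' `a/(a-1) * sum((u_i - mean(u_i))^2)` over the `a` sampled PSUs.
#' Domain (subpopulation) estimation keeps every PSU in the computation;
#' PSUs without domain members contribute zero residuals.
#'
#' The confidence interval uses the t distribution with `a - 1` degrees of
#' freedom (or the normal with `ci = "z"`), truncated to `[0, 1]`.  The
#' coefficient of variation is `Cv = 100 se / p` and the design effect is
#' `deff = var / (p (1 - p) / n)`, the ratio of the design variance to the
#' variance of a simple random sample of the same `n` respondents.
#'
#' @param data a data.frame with one row per respondent, carrying the PSU
#'   id, weight and indicator columns (e.g. a [survey_dataset()]).
#' @param indicator name of the 0/1 indicator column (`NA`s are dropped).
#' @param domain optional logical vector (length `nrow(data)`) restricting
#'   the estimate to a subpopulation.
#' @param weight,psu column names of the weight and PSU id
#'   (defaults `"weight"`, `"psu_id"`).
#' @param conf_level confidence level (default 0.95).
#' @param ci `"t"` (default) or `"z"` critical values.
#' @return object of class `"svy_estimate"`: list with `p_hat`, `se`,
#'   `ci95` (length-2), `cv` (percent), `deff`, `n` (respondents), `n_psu`
#'   (PSUs with domain members), `a` (PSUs in the design), `indicator`.
#' @export
estimate_proportion <- function(data, indicator, domain = NULL,
                                weight = "weight", psu = "psu_id",
                                conf_level = 0.95, ci = c("t", "z")) {
  ci <- match.arg(ci)
  for (col in c(indicator, weight, psu)) {
    if (!col %in% names(data)) stop_("column '%s' not found", col)
  }
  y <- data[[indicator]]
  w <- data[[weight]]
  if (any(w <= 0, na.rm = TRUE)) stop_("weights must be positive")
  d <- if (is.null(domain)) rep(TRUE, nrow(data)) else domain
  if (length(d) != nrow(data)) stop_("domain must match nrow(data)")
  d[is.na(d)] <- FALSE

  use <- d & !is.na(y)
  if (!sum(use)) stop_("empty domain: no respondents with observed values")
  psu_f <- factor(data[[psu]])  # levels = all PSUs in the dataset
  a <- nlevels(psu_f)

  num_i <- tapply(ifelse(use, w * y, 0), psu_f, sum)
  den_i <- tapply(ifelse(use, w, 0), psu_f, sum)
  num_i[is.na(num_i)] <- 0
  den_i[is.na(den_i)] <- 0

  n_psu <- sum(den_i > 0)
  if (n_psu < 2L) {
    stop_("variance undefined: only %d PSU(s) contain domain members", n_psu)
  }

  W <- sum(den_i)
  p_hat <- sum(num_i) / W
  u_i <- (num_i - p_hat * den_i) / W
  v <- a / (a - 1) * sum((u_i - mean(u_i))^2)
  se <- sqrt(v)

  n <- sum(use)
  alpha <- 1 - conf_level
  crit <- if (ci == "t") stats::qt(1 - alpha / 2, df = a - 1) else
    stats::qnorm(1 - alpha / 2)
  ci95 <- pmin(1, pmax(0, p_hat + c(-1, 1) * crit * se))

  deff <- if (p_hat > 0 && p_hat < 1) v / (p_hat * (1 - p_hat) / n) else NA_real_
  cv <- if (p_hat > 0) 100 * se / p_hat else NA_real_
  if (is.na(deff)) {
    warn_("p_hat is %g: design effect undefined", p_hat)
  }

  structure(
    list(p_hat = p_hat, se = se, ci95 = ci95, cv = cv, deff = deff,
         n = n, n_psu = n_psu, a = a, indicator = indicator,
         conf_level = conf_level),
    class = "svy_estimate"
  )
}

#' @export
print.svy_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: p = %.1f%% (%.0f%%CI %.1f-%.1f), Cv %.1f%%, deff %.2f, n = %d (%d PSUs)\n",
    x$indicator, 100 * x$p_hat, 100 * x$conf_level,
    100 * x$ci95[1], 100 * x$ci95[2], x$cv, x$deff, x$n, x$n_psu))
  invisible(x)
}

#' Design effect of an estimate
#'
#' The ratio of the design-based variance of a proportion to the variance
#' the same estimate would have under simple random sampling (with
#' replacement) of the same number of respondents: values near 1 mean the
#' clustering cost nothing; the common planning approximation is Kish's
#' `1 + (b_bar - 1) rho` for average cluster take `b_bar` and intra-cluster
#' correlation `rho`.
#'
#' @param estimate a `svy_estimate` from [estimate_proportion()].
#' @return numeric `deff`.
#' @export
design_effect <- function(estimate) {
  if (!inherits(estimate, "svy_estimate")) {
    stop_("estimate must be a svy_estimate")
  }
  estimate$deff
}

#' Coefficient of variation of an estimate
#'
#' `Cv = 100 se / p_hat` (percent).  Estimates with `Cv` below 20% are
#' conventionally considered precise enough for reporting.
#'
#' @param estimate a `svy_estimate`.
#' @return numeric `Cv` in percent (`NA` when `p_hat = 0`).
#' @export
cv_of <- function(estimate) {
  if (!inherits(estimate, "svy_estimate")) {
    stop_("estimate must be a svy_estimate")
  }
  if (estimate$p_hat == 0) {
    warn_("p_hat is 0: coefficient of variation undefined")
    return(NA_real_)
  }
  100 * estimate$se / estimate$p_hat
}

#' Tally estimates against precision and design-effect criteria
#'
#' Counts how many of a set of estimates meet the usual adequacy criteria:
#' coefficient of variation below `cv_max` (default 20%), design effect at
#' most `deff_soft` (default 1.5), and design effect below `deff_hard`
#' (default 2).
#'
#' @param estimates a list of `svy_estimate` objects, or a data.frame with
#'   columns `cv` and `deff`.
#' @param cv_max Cv threshold in percent (strictly below passes).
#' @param deff_soft soft deff threshold (at or below passes).
#' @param deff_hard hard deff threshold (strictly below passes).
#' @return list with `n_estimates`, `cv_ok`, `deff_soft_ok`, `deff_hard_ok`
#'   counts and the thresholds used.
#' @export
classify_precision <- function(estimates, cv_max = 20, deff_soft = 1.5,
                               deff_hard = 2) {
  if (is.data.frame(estimates)) {
    cv <- estimates$cv
    deff <- estimates$deff
  } else {
    if (!length(estimates)) stop_("no estimates supplied")
    cv <- vapply(estimates, cv_of, 0)
    deff <- vapply(estimates, design_effect, 0)
  }
  if (!length(cv)) stop_("no estimates supplied")
  list(
    n_estimates = length(cv),
    cv_ok = sum(cv < cv_max, na.rm = TRUE),
    deff_soft_ok = sum(deff <= deff_soft, na.rm = TRUE),
    deff_hard_ok = sum(deff < deff_hard, na.rm = TRUE),
    thresholds = c(cv_max = cv_max, deff_soft = deff_soft,
                   deff_hard = deff_hard)
  )
}
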
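#' Predictive mean matching imputation
#'
#' Fills missing values of `target` by predictive mean matching (PMM): a
#' linear model of `target` on `predictors` is fit to the complete rows,
#' predicted means are computed for every row, and each missing row receives
#' the *observed* value of one of its `k` nearest donors (donors ranked by
#' the distance between predicted means; the donor is drawn uniformly at
#' random among the `k` closest).  Because imputed values are copied from
#' observed ones, they always lie in the observed support — for a 0/1
#' indicator, the completed column remains 0/1.
#'
#' PMM is appropriate for modest missingness; following common survey
#' practice the function refuses to impute when more than 20% of the target
#' is missing (`max_missing`), since the matching model would then dominate
#' the estimates.
#'
#' @param data a data.frame.
#' @param target name of the column to complete.
#' @param predictors character vector of predictor column names (numeric or
#'   factor/character; must be complete).
#' @param k donor-pool size (default 5).
#' @param seed optional RNG seed for the donor draw.
#' @param max_missing maximum allowed missing fraction (default 0.20).
#' @return `data` with the `target` column completed.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(50), y = rbinom(50, 1, 0.4))
#' d$y[1:4] <- NA
#' completed <- pmm_impute(d, "y", "x", seed = 1)
#' sum(is.na(completed$y))  # 0
pmm_impute <- function(data, target, predictors, k = 5, seed = NULL,
                       max_missing = 0.20) {
  for (col in c(target, predictors)) {
    if (!col %in% names(data)) stop_("column '%s' not found", col)
  }
  y <- data[[target]]
  miss <- is.na(y)
  if (!any(miss)) return(data)

  frac <- mean(miss)
  if (frac > max_missing) {
    stop_(paste0(
      "missing fraction %.1f%% of '%s' exceeds the %.0f%% limit for ",
      "predictive mean matching"), 100 * frac, target, 100 * max_missing)
  }
  if (any(vapply(predictors, function(p) anyNA(data[[p]]), TRUE))) {
    stop_("predictors must be complete")
  }
  donors <- which(!miss)
  if (length(donors) < k) {
    stop_("need at least k = %d complete donor rows, have %d",
          k, length(donors))
  }

  fml <- stats::reformulate(predictors, response = target)
  fit <- stats::lm(fml, data = data[donors, , drop = FALSE])
  pred <- stats::predict(fit, newdata = data)

  maybe_seed(seed)
  y_obs <- y[donors]
  pred_obs <- pred[donors]
  for (i in which(miss)) {
    nn <- order(abs(pred_obs - pred[i]))[seq_len(k)]
    y[i] <- y_obs[sample(nn, 1L)]
  }
  data[[target]] <- y
  data
}
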
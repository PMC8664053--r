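#' Fieldwork contact-protocol parameters
#'
#' Parameters of the household contact simulation: on each visit the
#' household is found at home with probability `1 - p_absent_visit`; at the
#' first successful contact the residents refuse with probability
#' `p_refusal` (otherwise they are interviewed); a household never found at
#' home after `max_attempts` visits is a non-response by absence.
#'
#' @param p_refusal probability of refusal at first contact.
#' @param p_absent_visit probability a single visit finds nobody home.
#' @param max_attempts maximum number of visits (default 3, the usual
#'   three-visit protocol with revisits on different days and times).
#' @param seed optional RNG seed.
#' @return object of class `"field_params"`.
#' @export
field_params <- function(p_refusal = 0, p_absent_visit = 0,
                         max_attempts = 3, seed = NULL) {
  if (p_refusal < 0 || p_refusal > 1) stop_("p_refusal must be in [0, 1]")
  if (p_absent_visit < 0 || p_absent_visit > 1) {
    stop_("p_absent_visit must be in [0, 1]")
  }
  if (max_attempts < 1) stop_("max_attempts must be at least 1")
  structure(
    list(p_refusal = p_refusal, p_absent_visit = p_absent_visit,
         max_attempts = as.integer(max_attempts), seed = seed),
    class = "field_params"
  )
}

#' Closed-form outcome probabilities of the contact protocol
#'
#' Under [field_params()], the outcome probabilities are
#' `P(absence) = p_absent_visit^max_attempts`,
#' `P(refusal) = (1 - P(absence)) * p_refusal`, and
#' `P(interviewed) = (1 - P(absence)) * (1 - p_refusal)`.
#'
#' @param params a `field_params` object.
#' @return named numeric vector `c(interviewed, refusal, absence)`.
#' @export
fieldwork_probabilities <- function(params) {
  p_abs <- params$p_absent_visit^params$max_attempts
  c(interviewed = (1 - p_abs) * (1 - params$p_refusal),
    refusal = (1 - p_abs) * params$p_refusal,
    absence = p_abs)
}

#' Simulate fieldwork contact outcomes for a household sample
#'
#' Runs the visit protocol independently for each household: up to
#' `max_attempts` visits, each absent with probability `p_absent_visit`;
#' the first successful contact resolves to `refusal` with probability
#' `p_refusal` and to `interviewed` otherwise; households never contacted
#' are `absence`.
#'
#' @param household_ids character vector of households in the sample.
#' @param params a [field_params()] object.
#' @return data.frame with `household_id`, `outcome`
#'   (`"interviewed"`/`"refusal"`/`"absence"`) and `attempts` (visits used;
#'   equals `max_attempts` for absences).
#' @export
simulate_fieldwork <- function(household_ids, params) {
  if (!inherits(params, "field_params")) stop_("params must be field_params")
  maybe_seed(params$seed)
  n <- length(household_ids)
  # visit at which contact first succeeds; geometric, censored at max_attempts
  contacted_at <- rep(NA_integer_, n)
  pending <- rep(TRUE, n)
  for (v in seq_len(params$max_attempts)) {
    present <- stats::runif(n) >= params$p_absent_visit
    hit <- pending & present
    contacted_at[hit] <- v
    pending <- pending & !present
  }
  outcome <- rep("absence", n)
  reached <- !is.na(contacted_at)
  refuses <- stats::runif(n) < params$p_refusal
  outcome[reached & refuses] <- "refusal"
  outcome[reached & !refuses] <- "interviewed"
  attempts <- ifelse(reached, contacted_at, params$max_attempts)
  data.frame(household_id = household_ids, outcome = outcome,
             attempts = as.integer(attempts), stringsAsFactors = FALSE)
}

#' Household non-response rates
#'
#' From per-household outcomes, computes the non-response counts and rates:
#' with `X` households in the sample, `x_refusal` refusals, `x_absence`
#' absences and `x = x_refusal + x_absence`, the rates are
#' `NRR-Total = 100 x / X`, `NRR-Refusal = 100 x_refusal / X`, and
#' `NRR-Absence = 100 x_absence / X` (percent).  The refusal and absence
#' rates sum to the total rate exactly before rounding.
#'
#' @param outcomes either the data.frame from [simulate_fieldwork()] or a
#'   character vector of outcomes; alternatively supply counts directly via
#'   `X` and `interviewed` (plus optionally `refusal`/`absence`).
#' @param X total households in the sample (overrides `outcomes`).
#' @param interviewed number interviewed (used with `X`).
#' @param refusal,absence optional split of the non-response when supplying
#'   counts (must sum to `X - interviewed`).
#' @return object of class `"nrr_report"`: list with counts `X`, `x`,
#'   `x_refusal`, `x_absence` and rates `nrr_total`, `nrr_refusal`,
#'   `nrr_absence` (percent, unrounded; the print method shows 1 decimal).
#' @export
#' @examples
#' nrr_report(X = 804, interviewed = 497)$nrr_total  # 38.2 (1 dp)
nrr_report <- function(outcomes = NULL, X = NULL, interviewed = NULL,
                       refusal = NULL, absence = NULL) {
  if (!is.null(outcomes)) {
    oc <- if (is.data.frame(outcomes)) outcomes$outcome else outcomes
    bad <- setdiff(unique(oc), c("interviewed", "refusal", "absence"))
    if (length(bad)) stop_("unknown outcome(s): %s", paste(bad, collapse = ", "))
    X <- length(oc)
    x_ref <- sum(oc == "refusal")
    x_abs <- sum(oc == "absence")
  } else {
    if (is.null(X) || is.null(interviewed)) {
      stop_("supply outcomes, or X and interviewed")
    }
    nr <- X - interviewed
    if (nr < 0) stop_("interviewed cannot exceed X")
    if (is.null(refusal) && is.null(absence)) {
      x_ref <- NA_integer_; x_abs <- NA_integer_
    } else {
      x_ref <- if (is.null(refusal)) nr - absence else refusal
      x_abs <- if (is.null(absence)) nr - refusal else absence
      if (x_ref + x_abs != nr) {
        stop_("refusal + absence must equal X - interviewed")
      }
    }
    x <- nr
  }
  if (X == 0) stop_("X must be positive")
  if (!is.null(outcomes)) x <- x_ref + x_abs
  structure(
    list(X = X, x = x, x_refusal = x_ref, x_absence = x_abs,
         nrr_total = 100 * x / X,
         nrr_refusal = if (is.na(x_ref[1])) NA_real_ else 100 * x_ref / X,
         nrr_absence = if (is.na(x_abs[1])) NA_real_ else 100 * x_abs / X),
    class = "nrr_report"
  )
}

#' @export
print.nrr_report <- function(x, ...) {
  cat(sprintf("Household non-response: %d of %d (NRR-Total %.1f%%)\n",
              x$x, x$X, x$nrr_total))
  if (!is.na(x$nrr_refusal)) {
    cat(sprintf("  refusal: %d (%.1f%%), absence: %d (%.1f%%)\n",
                x$x_refusal, x$nrr_refusal, x$x_absence, x$nrr_absence))
  }
  invisible(x)
}
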
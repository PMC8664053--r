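#' Systematic sample of positions from an ordered list
#'
#' Fractional-interval systematic sampling: with `n` units and `k` draws the
#' interval is `n / k` (a real number), the start is uniform on
#' `[0, n/k)`, and the selected positions are
#' `floor(start + (0:(k-1)) * n/k) + 1`.  The fractional interval means `k`
#' need not divide `n` while every unit keeps inclusion probability `k / n`;
#' the `k` selections are always distinct.
#'
#' @param n number of units in the ordered list.
#' @param k number of units to select (`0 <= k <= n`).
#' @param seed optional RNG seed.
#' @return integer vector of `k` distinct 1-based positions, increasing.
#' @export
#' @examples
#' set.seed(1); systematic_positions(10, 5)
systematic_positions <- function(n, k, seed = NULL) {
  if (k < 0) stop_("k must be non-negative")
  if (k > n) stop_("cannot select %d from %d units", k, n)
  if (k == 0) return(integer(0))
  maybe_seed(seed)
  interval <- n / k
  start <- stats::runif(1, 0, interval)
  pos <- as.integer(floor(start + (seq_len(k) - 1) * interval)) + 1L
  pos
}

#' Systematic PPS selection of PSUs
#'
#' Selects `a` PSUs from the code-ordered list with probability proportional
#' to household count: household counts are cumulated in list order, the
#' sampling interval is `I = sum(M) / a`, a uniform start `U` on `[0, I)` is
#' drawn, and the PSUs containing the points `U, U + I, ..., U + (a-1) I`
#' are selected.  Each PSU's expected number of hits is `a M_i / sum(M)`; a
#' PSU larger than the interval is a certainty unit and can be hit more than
#' once (a warning is raised and its inclusion probability capped at 1).
#'
#' @param psus data.frame with `psu_id` and `M` in code order, or a
#'   `psu_frame`.
#' @param a number of PSUs to select.
#' @param seed optional RNG seed.
#' @return data.frame of selection events (one row per hit, `a` rows):
#'   `psu_id`, `M`, `pi` (first-stage inclusion probability, capped at 1),
#'   `hits` (times this PSU was hit in this draw).
#' @export
systematic_pps_select <- function(psus, a, seed = NULL) {
  if (inherits(psus, "psu_frame")) psus <- psus$psus
  if (!all(c("psu_id", "M") %in% names(psus))) {
    stop_("psus must have columns psu_id and M")
  }
  n_psu <- nrow(psus)
  if (a < 1 || a > n_psu) {
    stop_("a must be between 1 and the number of PSUs (%d)", n_psu)
  }
  M <- psus$M
  total <- sum(M)
  interval <- total / a
  if (any(M > interval)) {
    warn_("%d PSU(s) larger than the sampling interval are certainty units",
          sum(M > interval))
  }
  maybe_seed(seed)
  start <- stats::runif(1, 0, interval)
  points <- start + (seq_len(a) - 1) * interval
  idx <- findInterval(points, cumsum(M)) + 1L
  hits <- table(idx)
  sel <- data.frame(
    psu_id = psus$psu_id[idx],
    M = M[idx],
    pi = pmin(1, a * M[idx] / total),
    hits = as.integer(hits[as.character(idx)]),
    stringsAsFactors = FALSE
  )
  attr(sel, "interval") <- interval
  attr(sel, "start") <- start
  sel
}

#' Households to draw in a PSU under a fixed second-stage fraction
#'
#' The design fixes the second-stage fraction at `b / M_i` (planned take
#' over the design-frame size).  Applied to the updated field listing of
#' `M_i'` households, the realised take is `round(b * M_i' / M_i)`: the
#' sample grows or shrinks with the sector, preserving the global sampling
#' fraction (and hence self-weighting) even when the frame has aged.
#'
#' @param b planned households per PSU.
#' @param M_i design-frame household count of the PSU (positive).
#' @param M_i_prime updated household count from the field listing.
#' @return integer number of households to draw (vectorised).
#' @export
#' @examples
#' second_stage_count(10, 100, 120)  # 12
second_stage_count <- function(b, M_i, M_i_prime) {
  if (any(M_i <= 0)) stop_("M_i must be positive")
  if (any(M_i_prime < 0)) stop_("M_i_prime must be non-negative")
  if (any(M_i_prime == 0)) {
    warn_("PSU(s) with an empty field listing draw 0 households")
  }
  as.integer(round_half_up(b * M_i_prime / M_i))
}

#' Execute a two-stage household draw
#'
#' First stage: systematic PPS selection of `a` PSUs.  Second stage:
#' systematic selection of households within each selected PSU, at the fixed
#' fraction `b / M_i` applied to the current listing (see
#' [second_stage_count()]).  When the listing equals the design frame
#' (`M_i' = M_i`), every household's overall inclusion probability is the
#' global fraction `f = a b / sum(M)` and the design is self-weighting with
#' weight `1 / f`.
#'
#' @param psu_frame a `psu_frame` from [build_psus()].
#' @param households household listing with `household_id` and `psu_id`
#'   (e.g. from [assign_households()]), rows in listing order.
#' @param a number of PSUs to select.
#' @param b planned households per selected PSU.
#' @param seed optional RNG seed (one stream for the whole draw).
#' @param M_prime optional named vector of updated listing counts by
#'   `psu_id`; defaults to the design-frame counts (no frame growth).
#' @return object of class `"sample_draw"`: list with
#'   `households` (household_id, psu_id, pi1, f2, p_incl, weight),
#'   `psus` (selection events with realised takes `b_i`),
#'   and design metadata `a`, `b`, `f`, `total_M`.
#' @export
two_stage_draw <- function(psu_frame, households, a, b, seed = NULL,
                           M_prime = NULL) {
  if (!inherits(psu_frame, "psu_frame")) stop_("psu_frame required")
  if (!all(c("household_id", "psu_id") %in% names(households))) {
    stop_("households must have household_id and psu_id")
  }
  if (b < 1) stop_("b must be at least 1")
  maybe_seed(seed)

  sel <- systematic_pps_select(psu_frame, a)
  total_M <- sum(psu_frame$psus$M)
  f <- a * b / total_M

  rows_by_psu <- split(seq_len(nrow(households)), households$psu_id)
  if (is.null(M_prime)) {
    M_prime <- lengths(rows_by_psu)
  }

  sel_rows <- integer(0)
  pi1 <- numeric(0)
  f2 <- numeric(0)
  for (i in seq_len(nrow(sel))) {
    pid <- sel$psu_id[i]
    rows_i <- rows_by_psu[[pid]]
    n_i <- length(rows_i)
    Mp <- if (pid %in% names(M_prime)) M_prime[[pid]] else n_i
    b_i <- second_stage_count(b, sel$M[i], Mp)
    b_i <- min(b_i, n_i)
    sel$M_prime[i] <- Mp
    sel$b_i[i] <- b_i
    if (b_i == 0) next
    pos <- systematic_positions(n_i, b_i)
    sel_rows <- c(sel_rows, rows_i[pos])
    pi1 <- c(pi1, rep(sel$pi[i], b_i))
    f2 <- c(f2, rep(b_i / n_i, b_i))
  }
  out <- data.frame(
    household_id = households$household_id[sel_rows],
    psu_id = households$psu_id[sel_rows],
    pi1 = pi1,
    f2 = f2,
    stringsAsFactors = FALSE
  )
  out$p_incl <- out$pi1 * out$f2
  out$weight <- 1 / out$p_incl

  structure(
    list(households = out, psus = sel, a = a, b = b, f = f,
         total_M = total_M),
    class = "sample_draw"
  )
}

#' @export
print.sample_draw <- function(x, ...) {
  cat(sprintf(
    "Two-stage draw: a = %d PSUs, b = %d planned households/PSU\n",
    x$a, x$b))
  cat(sprintf("  global fraction f = %d*%d/%s = %.6f (weight %.1f)\n",
              x$a, x$b, format(x$total_M, big.mark = ","), x$f, 1 / x$f))
  cat(sprintf("  households drawn: %d\n", nrow(x$households)))
  invisible(x)
}

#' Inclusion probabilities and the global sampling fraction of a draw
#'
#' For a design-frame draw (listing equal to the frame), verifies the
#' self-weighting property: every household's overall inclusion probability
#' equals the global fraction `f = a b / sum(M)`.
#'
#' @param draw a `sample_draw`.
#' @return list with `f` (global fraction), `per_household` (data.frame of
#'   household-level probabilities and weights), and `self_weighting`
#'   (logical: are all realised probabilities equal to `f` up to 1e-9?).
#' @export
inclusion_probabilities <- function(draw) {
  if (!inherits(draw, "sample_draw")) stop_("draw must be a sample_draw")
  ph <- draw$households[, c("household_id", "psu_id", "pi1", "f2",
                            "p_incl", "weight")]
  list(
    f = draw$f,
    per_household = ph,
    self_weighting = all(abs(ph$p_incl - draw$f) < 1e-9)
  )
}
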
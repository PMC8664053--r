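#' Coefficient of variation of PSU sizes
#'
#' Population standard deviation of the PSU household counts divided by
#' their mean.  The design goal is a size CV of at most 10%, so that a
#' PPS draw of homogeneous PSUs is close to equal-probability.
#'
#' @param sizes numeric vector of PSU household counts, or a `psu_frame`.
#' @return the size CV (a fraction, not percent).
#' @export
#' @examples
#' size_cv(c(270, 330))  # 0.10
size_cv <- function(sizes) {
  if (inherits(sizes, "psu_frame")) sizes <- sizes$psus$M
  if (length(sizes) < 2L) stop_("size_cv needs at least 2 PSUs")
  m <- mean(sizes)
  if (m <= 0) stop_("PSU sizes must have positive mean")
  sqrt(mean((sizes - m)^2)) / m
}

# split m households into k consecutive parts of near-equal size
# (largest remainder: the first `m %% k` parts get one extra household)
split_counts <- function(m, k) {
  base <- m %/% k
  extra <- m %% k
  base + as.integer(seq_len(k) <= extra)
}

#' Assemble primary sampling units from census tracts
#'
#' Builds PSUs whose household counts are homogeneous (size CV at most
#' `cv_max`) from an ordered census-tract list.  A PSU may be a single
#' tract, a fraction of a tract, or a grouping of consecutive tracts.
#'
#' The algorithm iterates two moves against the current mean unit size `T`:
#' single-tract units larger than `1.5 T` are split into `ceiling(size/T)`
#' consecutive fractions of near-equal whole-household counts, and units
#' smaller than `0.5 T` are merged with their code-order neighbour.  It
#' stops when the CV constraint holds; if a full pass changes nothing while
#' the constraint still fails, it raises an error carrying the achieved CV
#' and the offending sizes.
#'
#' Every household belongs to exactly one PSU: splits allocate consecutive
#' runs of the tract's household listing (recorded as `hh_from`/`hh_to`),
#' never fractional households.
#'
#' @param tracts a data.frame with columns `tract_id` and `n_households`
#'   (rows in tract-code order), or a `census_frame`.
#' @param cv_max maximum allowed size CV (default 0.10).
#' @return object of class `"psu_frame"`: list with
#'   `psus` (data.frame: psu_id, M) and
#'   `members` (data.frame: psu_id, tract_id, fraction, n_households,
#'   hh_from, hh_to), plus `cv` and `cv_max`.
#' @export
#' @examples
#' tr <- data.frame(tract_id = sprintf("T%02d", 1:5),
#'                  n_households = c(300, 300, 900, 300, 300))
#' pf <- build_psus(tr)
#' pf$psus$M       # all 300
#' size_cv(pf)     # 0
build_psus <- function(tracts, cv_max = 0.10) {
  if (inherits(tracts, "census_frame")) tracts <- tracts$tracts
  need <- c("tract_id", "n_households")
  if (!all(need %in% names(tracts))) {
    stop_("tracts must have columns tract_id and n_households")
  }
  tracts <- tracts[tracts$n_households > 0, , drop = FALSE]
  if (!nrow(tracts)) stop_("no tracts with households")
  tracts <- tracts[order(tracts$tract_id), , drop = FALSE]

  # a unit is a data.frame of member rows (tract_id, n_households, hh_from, hh_to)
  units <- lapply(seq_len(nrow(tracts)), function(i) {
    data.frame(tract_id = tracts$tract_id[i],
               n_households = tracts$n_households[i],
               hh_from = 1L, hh_to = tracts$n_households[i],
               stringsAsFactors = FALSE)
  })

  unit_sizes <- function(u) vapply(u, function(m) sum(m$n_households), 0)

  for (iter in seq_len(1000L)) {
    sizes <- unit_sizes(units)
    if (length(units) < 2L || size_cv(sizes) <= cv_max) break

    target <- mean(sizes)
    changed <- FALSE

    # split oversized single-tract units into consecutive fractions
    out <- list()
    for (u in units) {
      s <- sum(u$n_households)
      if (nrow(u) == 1L && s > 1.5 * target) {
        k <- ceiling(s / target)
        parts <- split_counts(u$n_households, k)
        at <- u$hh_from
        for (p in parts) {
          out[[length(out) + 1L]] <- data.frame(
            tract_id = u$tract_id, n_households = p,
            hh_from = at, hh_to = at + p - 1L, stringsAsFactors = FALSE)
          at <- at + p
        }
        changed <- TRUE
      } else {
        out[[length(out) + 1L]] <- u
      }
    }
    units <- out

    # merge undersized units with their code-order neighbour
    sizes <- unit_sizes(units)
    target <- mean(sizes)
    out <- list()
    i <- 1L
    while (i <= length(units)) {
      u <- units[[i]]
      if (sum(u$n_households) < 0.5 * target && i < length(units)) {
        units[[i + 1L]] <- rbind(u, units[[i + 1L]])
        changed <- TRUE
      } else if (sum(u$n_households) < 0.5 * target && length(out)) {
        out[[length(out)]] <- rbind(out[[length(out)]], u)
        changed <- TRUE
      } else {
        out[[length(out) + 1L]] <- u
      }
      i <- i + 1L
    }
    units <- out

    if (!changed) {
      sizes <- unit_sizes(units)
      stop_(paste0(
        "cannot reach size CV <= %.3f: achieved %.3f with %d units ",
        "(sizes %s); relax cv_max or allow further splitting"),
        cv_max, size_cv(sizes), length(units),
        paste(utils::head(sort(sizes), 10), collapse = ", "))
    }
  }

  psu_id <- sprintf("PSU%04d", seq_along(units))
  members <- do.call(rbind, Map(function(id, u) {
    cbind(psu_id = id, u, stringsAsFactors = FALSE)
  }, psu_id, units))
  rownames(members) <- NULL
  psus <- data.frame(psu_id = psu_id, M = unit_sizes(units),
                     stringsAsFactors = FALSE)

  # conservation check: every household in exactly one PSU
  stopifnot(sum(psus$M) == sum(tracts$n_households))

  structure(
    list(psus = psus, members = members,
         cv = if (nrow(psus) >= 2L) size_cv(psus$M) else NA_real_,
         cv_max = cv_max),
    class = "psu_frame"
  )
}

#' @export
print.psu_frame <- function(x, ...) {
  cat(sprintf("PSU frame: %d PSUs, %s households, size CV %.3f (max %.2f)\n",
              nrow(x$psus), format(sum(x$psus$M), big.mark = ","),
              x$cv, x$cv_max))
  invisible(x)
}

#' Attach PSU membership to a household listing
#'
#' Maps each household to its PSU using the member ranges recorded by
#' [build_psus()]: the `k`-th household of a tract (in listing order)
#' belongs to the member whose `hh_from:hh_to` range contains `k`.
#'
#' @param psu_frame a `psu_frame` from [build_psus()].
#' @param households data.frame with `household_id` and `tract_id`, rows in
#'   listing order within each tract (as produced by [generate_frame()]).
#' @return the `households` data.frame with a `psu_id` column appended.
#' @export
assign_households <- function(psu_frame, households) {
  if (!inherits(psu_frame, "psu_frame")) stop_("psu_frame required")
  need <- c("household_id", "tract_id")
  if (!all(need %in% names(households))) {
    stop_("households must have household_id and tract_id")
  }
  hh <- households
  hh$.pos <- stats::ave(seq_len(nrow(hh)), hh$tract_id, FUN = seq_along)
  m <- psu_frame$members
  hh$psu_id <- NA_character_
  for (i in seq_len(nrow(m))) {
    rows <- hh$tract_id == m$tract_id[i] &
      hh$.pos >= m$hh_from[i] & hh$.pos <= m$hh_to[i]
    hh$psu_id[rows] <- m$psu_id[i]
  }
  if (anyNA(hh$psu_id)) {
    stop_("%d household(s) not covered by the PSU frame", sum(is.na(hh$psu_id)))
  }
  hh$.pos <- NULL
  hh
}
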
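#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up for positive input), as used
#' throughout the planning arithmetic.  Base [round()] rounds half to even,
#' which would disagree with planning tables produced by spreadsheet-style
#' rounding at exact .5 boundaries.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' The seven age groups used for stratification
#'
#' Age bands (years) used to stratify the reference population:
#' under 2, 3-4, 5-9, 10-14, 15-19, 20-59, and 60 or older.
#'
#' @return character vector of the seven age-group labels, in order.
#' @export
#' @examples
#' age_groups()
age_groups <- function() {
  c("0-2", "3-4", "5-9", "10-14", "15-19", "20-59", "60+")
}

# stop() with call. = FALSE and sprintf-style formatting
stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Derive independent per-stage RNG seeds from one master seed, so changing
# one stage's parameters does not perturb another stage's stream.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# set.seed only when a seed was given; NULL leaves the current stream alone
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
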
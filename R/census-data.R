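#' Reference census populations for Teresina and Picos (2010)
#'
#' Loads the 2010 IBGE census reference counts shipped with the package:
#' the urban population of the municipalities of Teresina and Picos (Piaui,
#' Brazil) stratified by sex and the seven age groups of [age_groups()],
#' together with each municipality's private-household total (210,093
#' households in Teresina, 16,944 in Picos).  These tables are the standard
#' input of [sample_plan()].
#'
#' @param municipality optional character; restrict to one municipality
#'   (`"Teresina"` or `"Picos"`).
#' @return A list with components:
#'   \describe{
#'     \item{population}{data.frame with columns `municipality`, `sex`
#'       (`"M"`/`"F"`), `age_group`, `population`.}
#'     \item{households}{named numeric vector of municipal household totals.}
#'   }
#' @export
#' @examples
#' cen <- reference_census()
#' subset(cen$population, municipality == "Picos" & sex == "F")
#' cen$households
reference_census <- function(municipality = NULL) {
  pop <- utils::read.csv(
    system.file("extdata", "stratum_populations.csv", package = "hhsurvey"),
    stringsAsFactors = FALSE
  )
  hh <- utils::read.csv(
    system.file("extdata", "household_totals.csv", package = "hhsurvey"),
    stringsAsFactors = FALSE
  )
  if (!is.null(municipality)) {
    if (!municipality %in% pop$municipality) {
      stop_("unknown municipality '%s'", municipality)
    }
    pop <- pop[pop$municipality == municipality, , drop = FALSE]
    hh <- hh[hh$municipality == municipality, , drop = FALSE]
  }
  households <- stats::setNames(as.numeric(hh$households), hh$municipality)
  pop$age_group <- factor(pop$age_group, levels = age_groups())
  list(population = pop, households = households)
}

#' Read a stratum-population table from CSV
#'
#' Reads and validates a population table in the same shape as the packaged
#' census data: one row per municipality x sex x age-group stratum.
#'
#' @param file path to a CSV file with columns `municipality`, `sex`,
#'   `age_group`, `population`.
#' @return validated data.frame with `age_group` as an ordered factor.
#' @export
read_stratum_populations <- function(file) {
  pop <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("municipality", "sex", "age_group", "population")
  missing_cols <- setdiff(need, names(pop))
  if (length(missing_cols)) {
    stop_("population table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!all(pop$sex %in% c("M", "F"))) {
    stop_("sex must be 'M' or 'F'")
  }
  bad <- setdiff(unique(pop$age_group), age_groups())
  if (length(bad)) {
    stop_("unknown age group(s): %s", paste(bad, collapse = ", "))
  }
  if (any(is.na(pop$population)) || any(pop$population < 0)) {
    stop_("population counts must be non-negative")
  }
  pop$age_group <- factor(pop$age_group, levels = age_groups())
  pop
}
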
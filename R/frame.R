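#' Specification of a binary health indicator for the frame generator
#'
#' Describes one binary indicator to attach to every generated person:
#' its prevalence (overall, or per sex-by-age domain), the within-tract
#' intra-cluster correlation `icc` (the rho that drives design effects in
#' cluster samples), and a completely-at-random missingness rate.
#'
#' @param name indicator name (becomes a column of the person table).
#' @param prevalence either a single probability or a named vector of
#'   probabilities keyed by `"<sex> <age_group>"` (e.g. `"F 20-59"`).
#' @param icc within-tract correlation in `[0, 1)`.
#' @param missing_rate probability a value is missing, in `[0, 1)`.
#' @return object of class `"indicator_spec"`.
#' @export
#' @examples
#' indicator_spec("hypertension", prevalence = 0.3, icc = 0.02)
indicator_spec <- function(name, prevalence, icc = 0, missing_rate = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_("indicator name must be a non-empty string")
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop_("prevalence must be in [0, 1]")
  }
  if (icc < 0 || icc >= 1) stop_("icc must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_("missing_rate must be in [0, 1)")
  }
  structure(
    list(name = name, prevalence = prevalence, icc = icc,
         missing_rate = missing_rate),
    class = "indicator_spec"
  )
}

#' Stratum shares matching the age and sex structure of an urban census
#'
#' Default population shares over the 14 sex-by-age strata, proportional to
#' the packaged Teresina 2010 census counts.  Names are
#' `"<sex> <age_group>"`.
#'
#' @return named numeric vector of 14 shares summing to 1.
#' @export
default_stratum_shares <- function() {
  cen <- reference_census("Teresina")
  pop <- cen$population
  shares <- pop$population / sum(pop$population)
  stats::setNames(shares, paste(pop$sex, as.character(pop$age_group)))
}

#' Configuration of a synthetic census frame
#'
#' Parameters of the synthetic municipality the generator emulates: census
#' tracts of about 300 households / 1,000 inhabitants, a sex-by-age stratum
#' composition, and a set of binary indicators with controllable prevalence
#' and intra-cluster correlation.
#'
#' @param n_tracts number of census tracts (>= 1).
#' @param mean_households_per_tract mean tract size in households
#'   (default 300).
#' @param mean_persons_per_household mean household size (default 10/3, so a
#'   300-household tract holds about 1,000 persons).
#' @param stratum_shares named shares over the 14 sex-by-age strata, summing
#'   to 1; default [default_stratum_shares()].
#' @param indicator_specs list of [indicator_spec()] objects.
#' @param seed RNG seed for the generator.
#' @return object of class `"frame_config"`.
#' @export
frame_config <- function(n_tracts,
                         mean_households_per_tract = 300,
                         mean_persons_per_household = 10 / 3,
                         stratum_shares = default_stratum_shares(),
                         indicator_specs = list(),
                         seed = 1L) {
  if (n_tracts < 1) stop_("n_tracts must be at least 1")
  if (mean_households_per_tract < 1) {
    stop_("mean_households_per_tract must be at least 1")
  }
  if (mean_persons_per_household <= 0) {
    stop_("mean_persons_per_household must be positive")
  }
  if (abs(sum(stratum_shares) - 1) > 1e-9) {
    stop_("stratum_shares must sum to 1 (got %.12f)", sum(stratum_shares))
  }
  if (any(stratum_shares < 0)) stop_("stratum_shares must be non-negative")
  expected <- as.vector(outer(c("M", "F"), age_groups(), paste))
  if (is.null(names(stratum_shares)) ||
      !setequal(names(stratum_shares), expected)) {
    stop_("stratum_shares must be named '<sex> <age_group>' over all 14 strata")
  }
  if (length(indicator_specs) &&
      !all(vapply(indicator_specs, inherits, TRUE, "indicator_spec"))) {
    stop_("indicator_specs must be a list of indicator_spec objects")
  }
  structure(
    list(n_tracts = as.integer(n_tracts),
         mean_households_per_tract = mean_households_per_tract,
         mean_persons_per_household = mean_persons_per_household,
         stratum_shares = stratum_shares[expected],
         indicator_specs = indicator_specs,
         seed = as.integer(seed)),
    class = "frame_config"
  )
}

# Tract-level prevalence with exact within-tract correlation `icc`:
# a common uniform tract quantile mapped through the Beta distribution with
# mean p and intra-class correlation icc (beta-binomial construction).
tract_prevalence <- function(p, icc, tract_quantile) {
  if (icc == 0) return(rep(p, length(tract_quantile)))
  if (p <= 0 || p >= 1) return(rep(p, length(tract_quantile)))
  shape1 <- p * (1 - icc) / icc
  shape2 <- (1 - p) * (1 - icc) / icc
  stats::qbeta(tract_quantile, shape1, shape2)
}

#' Generate a synthetic census frame
#'
#' Builds a municipality-like population: census tracts whose household
#' counts are Poisson around the configured mean (truncated below at 50 so
#' no degenerate mini-tracts arise), households with at least one person and
#' Poisson-distributed extra members, persons assigned to the 14 sex-by-age
#' strata by the configured shares, and binary indicators.
#'
#' Indicators with `icc > 0` are generated with a tract-level random effect:
#' each tract draws one uniform quantile, mapped through the Beta
#' distribution with mean equal to the target prevalence and intra-class
#' correlation equal to `icc` (the beta-binomial construction, which yields
#' the target within-tract correlation exactly).  Per-domain prevalences
#' share the tract quantile, so a high-prevalence tract is high for every
#' domain.  Missingness is applied completely at random.
#'
#' @param config a [frame_config()].
#' @return object of class `"census_frame"`: list with data.frames
#'   `tracts` (tract_id, n_households, n_persons), `households`
#'   (household_id, tract_id, n_persons), `persons` (person_id,
#'   household_id, tract_id, sex, age_group, one column per indicator),
#'   and the `config`.
#' @export
#' @examples
#' cfg <- frame_config(n_tracts = 5, mean_households_per_tract = 60,
#'                     indicator_specs = list(indicator_spec("y", 0.3)),
#'                     seed = 7)
#' fr <- generate_frame(cfg)
#' nrow(fr$tracts)
generate_frame <- function(config) {
  if (!inherits(config, "frame_config")) {
    stop_("config must be a frame_config object")
  }
  maybe_seed(config$seed)

  n_tracts <- config$n_tracts
  mu_hh <- config$mean_households_per_tract
  floor_hh <- min(50, max(1, floor(mu_hh)))  # lower truncation point
  n_households <- stats::rpois(n_tracts, mu_hh)
  for (iter in 1:100) {
    low <- n_households < floor_hh
    if (!any(low)) break
    n_households[low] <- stats::rpois(sum(low), mu_hh)
  }
  n_households <- pmax(n_households, floor_hh)

  tract_id <- sprintf("T%04d", seq_len(n_tracts))
  tracts <- data.frame(tract_id = tract_id, n_households = n_households,
                       stringsAsFactors = FALSE)

  hh_tract <- rep(tract_id, n_households)
  hh_seq <- sequence(n_households)
  household_id <- sprintf("%s_H%04d", hh_tract, hh_seq)
  hh_size <- 1L + stats::rpois(length(household_id),
                               config$mean_persons_per_household - 1)
  households <- data.frame(household_id = household_id, tract_id = hh_tract,
                           n_persons = hh_size, stringsAsFactors = FALSE)

  n_persons <- sum(hh_size)
  strata <- names(config$stratum_shares)
  stratum <- sample(strata, n_persons, replace = TRUE,
                    prob = config$stratum_shares)
  sex <- substr(stratum, 1, 1)
  age_group <- substring(stratum, 3)
  persons <- data.frame(
    person_id = sprintf("P%07d", seq_len(n_persons)),
    household_id = rep(household_id, hh_size),
    tract_id = rep(hh_tract, hh_size),
    sex = sex,
    age_group = age_group,
    stringsAsFactors = FALSE
  )

  tract_index <- match(persons$tract_id, tract_id)
  for (spec in config$indicator_specs) {
    tq <- stats::runif(n_tracts)
    if (length(spec$prevalence) == 1L) {
      p_tract <- tract_prevalence(spec$prevalence, spec$icc, tq)
      p_person <- p_tract[tract_index]
    } else {
      pv <- spec$prevalence
      dom <- paste(persons$sex, persons$age_group)
      if (!all(dom %in% names(pv))) {
        stop_("indicator '%s': prevalence missing for some strata", spec$name)
      }
      p_person <- numeric(n_persons)
      for (d in unique(dom)) {
        rows <- dom == d
        p_tract_d <- tract_prevalence(pv[[d]], spec$icc, tq)
        p_person[rows] <- p_tract_d[tract_index[rows]]
      }
    }
    y <- stats::rbinom(n_persons, 1L, p_person)
    if (spec$missing_rate > 0) {
      y[stats::runif(n_persons) < spec$missing_rate] <- NA_integer_
    }
    persons[[spec$name]] <- y
  }

  tracts$n_persons <- as.integer(
    tapply(households$n_persons, factor(households$tract_id, tract_id), sum)
  )

  structure(
    list(tracts = tracts, households = households, persons = persons,
         config = config),
    class = "census_frame"
  )
}

#' @export
print.census_frame <- function(x, ...) {
  cat(sprintf(
    "Synthetic census frame: %d tracts, %s households, %s persons\n",
    nrow(x$tracts),
    format(nrow(x$households), big.mark = ","),
    format(nrow(x$persons), big.mark = ",")
  ))
  inds <- vapply(x$config$indicator_specs, `[[`, "", "name")
  if (length(inds)) cat("  indicators:", paste(inds, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a frame into a stratum-population table
#'
#' Counts persons by sex and age group and totals the households, producing
#' the planner's input shape (a reference-population table plus a municipal
#' household total).
#'
#' @param frame a `census_frame` from [generate_frame()].
#' @param municipality label for the municipality column (default
#'   `"synthetic"`).
#' @return list with `population` (data.frame: municipality, sex, age_group,
#'   population, with every stratum present, zeros included), `households`
#'   (total household count), and `persons` (total person count).
#' @export
frame_summary <- function(frame, municipality = "synthetic") {
  if (!inherits(frame, "census_frame")) stop_("frame must be a census_frame")
  if (!nrow(frame$persons)) stop_("empty frame")
  tab <- table(
    sex = factor(frame$persons$sex, c("M", "F")),
    age_group = factor(frame$persons$age_group, age_groups())
  )
  pop <- as.data.frame(tab, responseName = "population",
                       stringsAsFactors = FALSE)
  pop <- data.frame(municipality = municipality,
                    sex = pop$sex, age_group = pop$age_group,
                    population = as.integer(pop$population),
                    stringsAsFactors = FALSE)
  list(population = pop,
       households = nrow(frame$households),
       persons = nrow(frame$persons))
}

#' Write a frame to plain-text files
#'
#' Writes `tracts.csv` (with per-stratum person counts), `households.csv`,
#' `persons.csv` and a `manifest.json` recording the generator configuration
#' (including the seed) to a directory.
#'
#' @param frame a `census_frame`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_frame <- function(frame, dir) {
  if (!inherits(frame, "census_frame")) stop_("frame must be a census_frame")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  tab <- table(frame$persons$tract_id,
               paste(frame$persons$sex, frame$persons$age_group))
  tracts <- frame$tracts
  counts <- as.data.frame.matrix(tab)
  counts <- counts[match(tracts$tract_id, rownames(counts)), , drop = FALSE]
  names(counts) <- gsub("[ +-]", "_", paste0("pop_", names(counts)))
  utils::write.csv(cbind(tracts, counts),
                   file.path(dir, "tracts.csv"), row.names = FALSE)
  utils::write.csv(frame$households, file.path(dir, "households.csv"),
                   row.names = FALSE)
  utils::write.csv(frame$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE)

  cfg <- frame$config
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      n_tracts = cfg$n_tracts,
      mean_households_per_tract = cfg$mean_households_per_tract,
      mean_persons_per_household = cfg$mean_persons_per_household,
      stratum_shares = as.list(cfg$stratum_shares),
      indicators = lapply(cfg$indicator_specs, unclass),
      seed = cfg$seed
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
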
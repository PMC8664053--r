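#' Configuration of a replicated survey experiment
#'
#' Bundles everything one end-to-end run needs: the synthetic frame
#' configuration, the design parameters (`a` PSUs, `b` households per PSU),
#' the fieldwork contact parameters, and the number of Monte-Carlo
#' replicates.  One RNG stream per stage is derived from the master seed,
#' so e.g. changing the fieldwork parameters does not perturb the draws.
#'
#' @param frame a [frame_config()].
#' @param a number of PSUs to select per replicate.
#' @param b planned households per selected PSU; default
#'   `round(n_target / a)` if `n_target` is given.
#' @param field a [field_params()] object (default: no non-response).
#' @param replicates number of replicate surveys (default 1).
#' @param seed master seed.
#' @param n_target optional planned household sample (used only to default
#'   `b`).
#' @return object of class `"experiment_config"`.
#' @export
experiment_config <- function(frame, a, b = NULL, field = field_params(),
                              replicates = 1, seed = 1, n_target = NULL) {
  if (!inherits(frame, "frame_config")) stop_("frame must be a frame_config")
  if (!inherits(field, "field_params")) stop_("field must be field_params")
  if (replicates < 1) stop_("replicates must be at least 1")
  if (is.null(b)) {
    if (is.null(n_target)) stop_("supply b or n_target")
    b <- as.integer(round_half_up(n_target / a))
  }
  structure(
    list(frame = frame, a = as.integer(a), b = as.integer(b), field = field,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Run a replicated end-to-end survey experiment
#'
#' Composes every stage of the design on a synthetic municipality:
#' generate the frame, build PSUs, then for each replicate draw a two-stage
#' sample, simulate fieldwork, assemble the respondent dataset and estimate
#' every configured indicator.  The report collects per-replicate
#' non-response rates and estimates, empirical CI coverage of the frame's
#' true prevalences, and the pass counts under the usual precision
#' criteria (Cv < 20%, deff <= 1.5, deff < 2).
#'
#' @param config an [experiment_config()].
#' @return object of class `"experiment_report"`: list with `estimates`
#'   (data.frame, one row per replicate x indicator), `nrr` (per-replicate
#'   non-response), `truth` (frame prevalences), `coverage` (per
#'   indicator), `mean_deff`, `precision` (pass counts), `frame_summary`,
#'   and a `manifest` of every stage's parameters.
#' @export
run_survey_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) {
    stop_("config must be an experiment_config")
  }
  R <- config$replicates
  seeds <- derive_seeds(config$seed, 1L + 2L * R)
  s_frame <- seeds[1L]
  s_draw <- seeds[1L + seq_len(R)]
  s_field <- seeds[1L + R + seq_len(R)]

  frame_cfg <- config$frame
  frame_cfg$seed <- s_frame
  frame <- generate_frame(frame_cfg)
  psus <- tryCatch(build_psus(frame),
                   error = function(e) stop_("psu stage: %s", conditionMessage(e)))
  hh <- assign_households(psus, frame$households)

  specs <- frame_cfg$indicator_specs
  ind_names <- vapply(specs, `[[`, "", "name")
  truth <- vapply(ind_names, function(nm) {
    mean(frame$persons[[nm]], na.rm = TRUE)
  }, 0)

  est_rows <- list()
  nrr_rows <- list()
  for (r in seq_len(R)) {
    draw <- tryCatch(
      two_stage_draw(psus, hh, config$a, config$b, seed = s_draw[r]),
      error = function(e) stop_("draw stage (replicate %d): %s",
                                r, conditionMessage(e)))
    fp <- config$field
    fp$seed <- s_field[r]
    fw <- simulate_fieldwork(draw$households$household_id, fp)
    nrr <- nrr_report(fw)
    nrr_rows[[r]] <- data.frame(
      replicate = r, X = nrr$X, interviewed = nrr$X - nrr$x,
      nrr_total = nrr$nrr_total, nrr_refusal = nrr$nrr_refusal,
      nrr_absence = nrr$nrr_absence)

    interviewed <- fw$household_id[fw$outcome == "interviewed"]
    ds <- survey_dataset(draw, frame$persons, interviewed)
    for (nm in ind_names) {
      est <- tryCatch(estimate_proportion(ds, nm), error = function(e) NULL)
      if (is.null(est)) next
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        replicate = r, indicator = nm, p_hat = est$p_hat, se = est$se,
        ci_low = est$ci95[1], ci_high = est$ci95[2], cv = est$cv,
        deff = est$deff, n = est$n, n_psu = est$n_psu,
        covered = truth[[nm]] >= est$ci95[1] & truth[[nm]] <= est$ci95[2])
    }
  }
  estimates <- if (length(est_rows)) do.call(rbind, est_rows) else
    data.frame()
  nrr <- do.call(rbind, nrr_rows)

  coverage <- if (nrow(estimates)) {
    tapply(estimates$covered, estimates$indicator, mean)
  } else NULL
  mean_deff <- if (nrow(estimates)) {
    tapply(estimates$deff, estimates$indicator, mean, na.rm = TRUE)
  } else NULL
  precision <- if (nrow(estimates)) classify_precision(estimates) else NULL

  structure(
    list(
      estimates = estimates, nrr = nrr, truth = truth,
      coverage = coverage, mean_deff = mean_deff, precision = precision,
      frame_summary = frame_summary(frame),
      psu_cv = psus$cv,
      manifest = list(
        seed = config$seed, replicates = R, a = config$a, b = config$b,
        f = config$a * config$b / sum(psus$psus$M),
        n_tracts = frame_cfg$n_tracts,
        mean_households_per_tract = frame_cfg$mean_households_per_tract,
        mean_persons_per_household = frame_cfg$mean_persons_per_household,
        indicators = lapply(specs, unclass),
        field = unclass(config$field),
        stage_seeds = list(frame = s_frame, draw = s_draw, field = s_field))
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Survey experiment: %d replicate(s), a = %d, b = %d, f = %.5f\n",
              m$replicates, m$a, m$b, m$f))
  cat(sprintf("  mean NRR-Total: %.1f%%\n", mean(x$nrr$nrr_total)))
  if (!is.null(x$coverage)) {
    for (nm in names(x$coverage)) {
      cat(sprintf(
        "  %s: truth %.3f, mean p_hat %.3f, coverage %.3f, mean deff %.2f\n",
        nm, x$truth[[nm]],
        mean(x$estimates$p_hat[x$estimates$indicator == nm]),
        x$coverage[[nm]], x$mean_deff[[nm]]))
    }
  }
  invisible(x)
}

#' Build the full planning table for a reference population
#'
#' Runs the complete planning methodology for one or more municipalities
#' and lays the results out as the familiar planning table: the reference
#' population, person/household ratios, households required per stratum,
#' expected individuals, and the 95% CI / Cv precision simulation at an
#' anticipated proportion.
#'
#' @param population stratum-population data.frame (columns `municipality`,
#'   `sex`, `age_group`, `population`) or the path of such a CSV.
#' @param households named vector of municipal household totals, or the
#'   path of a CSV with columns `municipality`, `households`.
#' @param m_min minimum expected individuals per stratum (default 30).
#' @param response_rate anticipated response rate (default 0.90).
#' @param p anticipated proportion for the precision block (default 0.5,
#'   the most conservative case).
#' @return object of class `"planning_table"`: list with `cells` (one row
#'   per municipality x stratum with every block's value) and `summary`
#'   (per municipality: n0, n, expected individuals by sex and total).
#' @export
#' @examples
#' cen <- reference_census()
#' rep <- planning_table(cen$population, cen$households)
#' rep$summary
planning_table <- function(population, households, m_min = 30,
                             response_rate = 0.90, p = 0.5) {
  if (is.character(population)) {
    population <- read_stratum_populations(population)
  }
  if (is.character(households)) {
    hh <- utils::read.csv(households, stringsAsFactors = FALSE)
    if (!all(c("municipality", "households") %in% names(hh))) {
      stop_("household totals CSV needs municipality and households columns")
    }
    households <- stats::setNames(as.numeric(hh$households), hh$municipality)
  }
  need <- c("municipality", "sex", "age_group", "population")
  if (!all(need %in% names(population))) {
    stop_("population must have columns %s", paste(need, collapse = ", "))
  }
  if (!nrow(population)) stop_("empty population table")

  cells <- list()
  summaries <- list()
  for (city in unique(population$municipality)) {
    if (!city %in% names(households)) {
      stop_("no household total for municipality '%s'", city)
    }
    pop_c <- population[population$municipality == city, , drop = FALSE]
    plan <- sample_plan(pop_c, households[[city]], m_min, response_rate)
    st <- plan$strata
    prof <- precision_profile(st$expected_individuals, p)
    cells[[city]] <- data.frame(
      municipality = city,
      sex = st$sex, age_group = as.character(st$age_group),
      population = st$N,
      ratio = st$ratio,
      households_required = st$households_required,
      expected_individuals = st$expected_individuals,
      ci_low = prof$ci_low, ci_high = prof$ci_high, cv = prof$cv,
      stringsAsFactors = FALSE)
    summaries[[city]] <- data.frame(
      municipality = city, D = plan$D, n0 = plan$n0, n = plan$n,
      expected_M = plan$expected_by_sex[["M"]],
      expected_F = plan$expected_by_sex[["F"]],
      expected_total = plan$expected_total,
      stringsAsFactors = FALSE)
  }
  structure(
    list(cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
         summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
         p = p, m_min = m_min, response_rate = response_rate),
    class = "planning_table"
  )
}

#' @export
print.planning_table <- function(x, ...) {
  cat(sprintf(
    "Planning table (m_min = %d, response rate %.0f%%, precision at p = %.0f%%)\n",
    x$m_min, 100 * x$response_rate, 100 * x$p))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
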
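# Design-based proportion estimation: linearized variance, Cv, deff, PMM.

test_that("degenerate datasets give degenerate estimates", {
  d <- small_survey_fixture()
  d$y <- 1
  expect_warning(est <- estimate_proportion(d, "y"), "undefined")
  expect_equal(est$p_hat, 1)
  expect_equal(est$se, 0)

  # equal PSU-level means: no between-PSU variance
  d2 <- data.frame(psu_id = rep(c("A", "B", "C"), each = 2),
                   weight = 1, y = rep(c(1, 0), 3))
  est2 <- estimate_proportion(d2, "y")
  expect_equal(est2$p_hat, 0.5)
  expect_equal(est2$se, 0)
})

test_that("linearized variance matches the brute-force oracle", {
  d <- small_survey_fixture()
  est <- estimate_proportion(d, "y")
  oc <- oracle_ultimate_cluster(d$y, d$weight, d$psu_id)
  expect_equal(est$p_hat, oc$p, tolerance = 1e-14)
  expect_equal(est$se^2, oc$var, tolerance = 1e-12)
  expect_equal(est$n, 12)
  expect_equal(est$n_psu, 3)
})

test_that("domain estimation keeps all PSUs in the variance", {
  d <- small_survey_fixture()
  est <- estimate_proportion(d, "y", domain = d$sex == "M")
  # oracle on the domain: y and w zeroed outside the domain, all PSUs kept
  y0 <- ifelse(d$sex == "M", d$y, 0)
  w0 <- ifelse(d$sex == "M", d$weight, 0)
  ids <- unique(d$psu_id)
  W <- sum(w0)
  p <- sum(w0 * y0) / W
  z <- vapply(ids, function(id) {
    rows <- d$psu_id == id
    (sum(w0[rows] * y0[rows]) - p * sum(w0[rows])) / W
  }, 0)
  v <- length(ids) / (length(ids) - 1) * sum((z - mean(z))^2)
  expect_equal(est$p_hat, p, tolerance = 1e-14)
  expect_equal(est$se^2, v, tolerance = 1e-12)
  expect_equal(est$n, sum(d$sex == "M"))
})

test_that("estimation errors on unusable designs", {
  d <- small_survey_fixture()
  expect_error(estimate_proportion(d, "y", domain = rep(FALSE, nrow(d))),
               "empty domain")
  expect_error(estimate_proportion(d, "y", domain = d$psu_id == "A"),
               "only 1 PSU")
  d$weight[1] <- -1
  expect_error(estimate_proportion(d, "y"), "positive")
})

test_that("weights are scale invariant for p, se and deff", {
  d <- small_survey_fixture()
  e1 <- estimate_proportion(d, "y")
  d$weight <- d$weight * 7.3
  e2 <- estimate_proportion(d, "y")
  expect_equal(e2$p_hat, e1$p_hat, tolerance = 1e-14)
  expect_equal(e2$se, e1$se, tolerance = 1e-14)
  expect_equal(e2$deff, e1$deff, tolerance = 1e-12)
})

test_that("duplicating every PSU leaves the design effect essentially unchanged", {
  set.seed(61)
  a <- 30
  d <- data.frame(psu_id = rep(sprintf("P%02d", 1:a), each = 8),
                  weight = 1,
                  y = rbinom(8 * a, 1, 0.4))
  e1 <- estimate_proportion(d, "y")
  d2 <- d
  d2$psu_id <- paste0(d$psu_id, "dup")
  both <- rbind(d, d2)
  e2 <- estimate_proportion(both, "y")
  expect_equal(e2$p_hat, e1$p_hat, tolerance = 1e-14)
  # exact invariance holds up to the finite-cluster factor a/(a-1)
  expect_lt(abs(e2$deff - e1$deff) / e1$deff, 1 / (2 * a - 2))
})

test_that("coefficient of variation follows from se and p", {
  d <- small_survey_fixture()
  est <- estimate_proportion(d, "y")
  expect_equal(cv_of(est), 100 * est$se / est$p_hat)
  est$p_hat <- 0.5
  est$se <- 0.0737
  expect_equal(round(cv_of(structure(est, class = "svy_estimate")), 1), 14.7)
  est$se <- est$se / 2
  expect_equal(round(cv_of(structure(est, class = "svy_estimate")), 2), 7.37)
})

test_that("precision classification respects the boundary conventions", {
  fix <- data.frame(cv = c(rep(5, 60), rep(19.9, 11), 25),
                    deff = c(rep(1.0, 55), rep(1.5, 6), 1.9, rep(2.4, 10)))
  counts <- classify_precision(fix)
  expect_equal(counts$n_estimates, 72)
  expect_equal(counts$cv_ok, 71)             # cv strictly below 20
  expect_equal(counts$deff_soft_ok, 61)      # deff <= 1.5
  expect_equal(counts$deff_hard_ok, 62)      # deff < 2 includes the 1.9
  zero <- classify_precision(data.frame(cv = c(0, 0), deff = c(0, 0)))
  expect_equal(zero$cv_ok, 2)
  expect_equal(zero$deff_soft_ok, 2)
})

test_that("deff increases with intra-cluster correlation at fixed take", {
  # single-frame comparison across rho with a common seed
  deffs <- vapply(c(0, 0.05, 0.15), function(rho) {
    d <- build_test_design(
      n_tracts = 60, mean_hh = 200, persons_per_hh = 1,
      specs = list(indicator_spec("y", 0.5, icc = rho)), seed = 7)
    mean(vapply(1:30, function(r) {
      draw <- two_stage_draw(d$pf, d$hh, a = 30, b = 20, seed = 1000 + r)
      ds <- survey_dataset(draw, d$frame$persons)
      estimate_proportion(ds, "y")$deff
    }, 0))
  }, 0)
  expect_true(all(diff(deffs) > 0))
})

test_that("PMM leaves complete data alone and enforces the missingness cap", {
  d <- data.frame(x = rnorm(40), y = rbinom(40, 1, 0.5))
  expect_identical(pmm_impute(d, "y", "x"), d)
  d25 <- d
  d25$y[1:10] <- NA
  expect_error(pmm_impute(d25, "y", "x"), "exceeds the 20% limit")
  d_small <- d[1:6, ]
  d_small$y[1] <- NA
  expect_error(pmm_impute(d_small, "y", "x", k = 10), "donor")
})

test_that("PMM imputes from the observed support and preserves prevalence", {
  set.seed(88)
  n <- 4000
  d <- data.frame(x = rnorm(n))
  p <- plogis(0.5 * d$x - 0.4)
  d$y <- rbinom(n, 1, p)
  p_full <- mean(d$y)
  miss <- sample(n, 0.1 * n)
  d$y[miss] <- NA
  out <- pmm_impute(d, "y", "x", seed = 5)
  expect_false(anyNA(out$y))
  expect_true(all(out$y %in% c(0, 1)))
  expect_identical(out$y[-miss], d$y[-miss])  # observed values untouched
  mc_se <- sqrt(p_full * (1 - p_full) / n)
  expect_lt(abs(mean(out$y) - p_full), 3 * mc_se)
})

test_that("t and z intervals differ as expected", {
  d <- small_survey_fixture()
  et <- estimate_proportion(d, "y", ci = "t")
  ez <- estimate_proportion(d, "y", ci = "z")
  expect_lt(diff(ez$ci95), diff(et$ci95))  # t with 2 df is wider
  expect_true(all(et$ci95 >= 0 & et$ci95 <= 1))
})
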
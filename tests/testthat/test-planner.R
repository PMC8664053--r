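# Sample-size planning: person/household ratios, per-stratum household
# requirements, non-response inflation, expected individuals, precision.

test_that("person/household ratio matches the census planning table", {
  expect_equal(round(person_household_ratio(16652, 210093), 4), 0.0793)
  expect_equal(round(person_household_ratio(248680, 210093), 4), 1.1837)
  expect_equal(person_household_ratio(0, 210093), 0)
  expect_error(person_household_ratio(100, 0), "positive")
})

test_that("per-stratum household requirements match the published planning table", {
  cen <- reference_census()
  # published per-stratum requirements, M 0-2..60+ then F 0-2..60+
  printed <- list(
    Teresina = c(379, 554, 217, 189, 186, 31, 240,
                 392, 578, 225, 192, 175, 25, 164),
    Picos    = c(428, 599, 227, 196, 189, 33, 225,
                 404, 620, 231, 202, 180, 28, 162)
  )
  for (city in names(printed)) {
    pop <- cen$population[cen$population$municipality == city, ]
    h <- households_for_minimum(pop$population, cen$households[[city]])
    expect_equal(h, printed[[city]])
  }
  # N = D means one person of the stratum per household: need exactly m_min
  expect_equal(households_for_minimum(210093, 210093, 30), 30L)
})

test_that("household requirement uses round-to-nearest, not ceiling", {
  # 30 * 210093 / 11373 = 554.19; ceiling would give 555
  expect_equal(households_for_minimum(11373, 210093), 554L)
})

test_that("base sample size is the maximum requirement over strata", {
  cen <- reference_census()
  expected <- c(Teresina = 578L, Picos = 620L)
  for (city in names(expected)) {
    pop <- cen$population[cen$population$municipality == city, ]
    h <- households_for_minimum(pop$population, cen$households[[city]])
    expect_equal(base_sample_size(h), expected[[city]])
  }
  expect_equal(base_sample_size(42L), 42L)
  expect_error(base_sample_size(NA_integer_), "no attainable")
})

test_that("non-response inflation truncates (578 -> 642, 620 -> 688)", {
  expect_equal(inflate_for_nonresponse(578), 642L)
  expect_equal(inflate_for_nonresponse(620), 688L)
  expect_equal(inflate_for_nonresponse(500, response_rate = 1), 500L)
  expect_error(inflate_for_nonresponse(100, response_rate = 0), "response_rate")
})

test_that("expected individuals reproduce the published expected-individual counts and totals", {
  cen <- reference_census()
  printed <- list(
    Teresina = list(n0 = 578,
                    M = c(46, 31, 80, 92, 93, 567, 72),
                    F = c(44, 30, 77, 90, 99, 684, 106),
                    total = 2111),
    Picos = list(n0 = 620,
                 M = c(43, 31, 82, 95, 98, 571, 83),
                 F = c(46, 30, 81, 92, 103, 664, 115),
                 total = 2134)
  )
  for (city in names(printed)) {
    pop <- cen$population[cen$population$municipality == city, ]
    pr <- printed[[city]]
    for (s in c("M", "F")) {
      e <- expected_individuals(pop$population[pop$sex == s],
                                cen$households[[city]], pr$n0)
      expect_equal(e, as.integer(pr[[s]]))
    }
    e_all <- expected_individuals(pop$population, cen$households[[city]],
                                  pr$n0)
    expect_equal(sum(e_all), pr$total)
  }
  expect_equal(expected_individuals(c(100, 200), 1000, 0), c(0L, 0L))
})

test_that("sample_plan assembles the full plan and flags the limiting stratum", {
  cen <- reference_census("Teresina")
  plan <- sample_plan(cen$population, cen$households)
  expect_s3_class(plan, "sample_plan")
  expect_equal(plan$n0, 578L)
  expect_equal(plan$n, 642L)
  expect_equal(plan$expected_total, 2111L)
  expect_equal(plan$limiting_stratum$sex, "F")
  expect_equal(as.character(plan$limiting_stratum$age_group), "3-4")
  expect_error(sample_plan(cen$population[0, ], 1000), "empty")
})

test_that("precision profile matches the published 50%-proportion simulation", {
  # published expected individuals per stratum and the printed Cv / 95% CI
  n_ter <- c(46, 31, 80, 92, 93, 567, 72, 44, 30, 77, 90, 99, 684, 106)
  cv_ter <- c(14.7, 18.0, 11.2, 10.4, 10.4, 4.2, 11.8,
              15.1, 18.26, 11.4, 10.5, 10.1, 3.8, 9.7)
  n_pic <- c(43, 31, 82, 95, 98, 571, 83, 46, 30, 81, 92, 103, 664, 115)
  cv_pic <- c(15.3, 18.0, 11.0, 10.3, 10.1, 4.2, 11.0,
              14.7, 18.3, 11.1, 10.4, 9.8, 3.9, 9.3)
  prof <- precision_profile(c(n_ter, n_pic), 0.5)
  # one-decimal print rounding slack on the published values
  expect_true(all(abs(prof$cv - c(cv_ter, cv_pic)) < 0.06))

  ci_printed <- rbind(
    c(35.5, 64.5), c(32.4, 67.6), c(39.0, 61.0), c(39.8, 60.2),
    c(39.8, 60.2), c(45.8, 54.2), c(38.5, 61.6),
    c(35.2, 64.8), c(32.1, 67.9), c(38.8, 61.2), c(39.7, 60.3),
    c(40.2, 59.8), c(46.3, 53.8), c(40.5, 59.5))
  prof_t <- precision_profile(n_ter, 0.5)
  expect_true(all(abs(prof_t$ci_low - ci_printed[, 1]) < 0.11))
  expect_true(all(abs(prof_t$ci_high - ci_printed[, 2]) < 0.11))
})

test_that("precision at p = 0.5 is exactly 100/sqrt(n)", {
  for (n in c(31, 46, 100, 578, 2111)) {
    expect_equal(precision_profile(n, 0.5)$cv, 100 / sqrt(n))
  }
})

test_that("Monte-Carlo precision mode agrees with the closed form", {
  reps <- 10000
  for (case in list(c(46, 0.5), c(200, 0.3))) {
    n <- case[1]; p <- case[2]
    an <- precision_profile(n, p)
    mc <- precision_profile(n, p, method = "montecarlo", reps = reps,
                            seed = 42)
    # sd of an sd estimate ~ se / sqrt(2 (reps - 1))
    mc_se_cv <- an$cv / sqrt(2 * (reps - 1))
    expect_lt(abs(mc$cv - an$cv), 3 * mc_se_cv * sqrt(2))
  }
})

test_that("planner monotonicity properties hold", {
  D <- 50000
  N <- sort(round(seq(200, 45000, length.out = 25)))
  h <- households_for_minimum(N, D)
  expect_true(all(diff(h) <= 0))  # more people per household, fewer households
  totals <- vapply(c(100, 200, 400, 800), function(n0) {
    sum(expected_individuals(N, D, n0))
  }, 0)
  expect_true(all(diff(totals) >= 0))
})

test_that("precision profile rejects degenerate proportions", {
  expect_error(precision_profile(100, 0), "p must")
  expect_error(precision_profile(100, 1), "p must")
  expect_error(precision_profile(0, 0.5), "n must")
})
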
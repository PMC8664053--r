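# Two-stage systematic PPS sampling and self-weighting.

test_that("systematic positions are distinct, in range, equally spaced", {
  expect_equal(systematic_positions(7, 7, seed = 1), 1:7)
  pos <- systematic_positions(10, 5, seed = 3)
  expect_equal(diff(pos), rep(2L, 4))  # interval n/k = 2 exactly
  expect_true(all(pos >= 1 & pos <= 10))
  # distinctness under fractional intervals
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    k <- sample(seq_len(n), 1)
    p <- systematic_positions(n, k)
    expect_equal(length(unique(p)), k)
    expect_true(all(p >= 1 & p <= n))
  }
  expect_error(systematic_positions(5, 6), "cannot select")
})

test_that("single systematic draw is uniform over the list", {
  set.seed(21)
  n <- 5
  hits <- tabulate(replicate(4000, systematic_positions(n, 1)), n)
  se <- sqrt(4000 * (1 / n) * (1 - 1 / n))
  expect_true(all(abs(hits - 4000 / n) < 3 * se))
})

test_that("PPS selection with a = number of PSUs takes every equal PSU once", {
  psus <- data.frame(psu_id = sprintf("P%02d", 1:8), M = rep(250, 8))
  sel <- systematic_pps_select(psus, a = 8, seed = 2)
  expect_equal(sort(sel$psu_id), psus$psu_id)
  expect_equal(sel$pi, rep(1, 8))
})

test_that("first-stage selection frequencies match pi over 20,000 draws", {
  set.seed(7)
  psus <- data.frame(psu_id = sprintf("P%02d", 1:12),
                     M = as.integer(rpois(12, 300)))
  a <- 4
  reps <- 20000
  pi_i <- a * psus$M / sum(psus$M)
  counts <- integer(nrow(psus))
  for (r in seq_len(reps)) {
    sel <- systematic_pps_select(psus, a)
    idx <- match(unique(sel$psu_id), psus$psu_id)
    counts[idx] <- counts[idx] + 1L
  }
  se <- sqrt(reps * pi_i * (1 - pi_i))
  expect_true(all(abs(counts - reps * pi_i) <= 3 * se))
  # exactly a selection events every draw
  expect_equal(nrow(sel), a)
})

test_that("PSUs larger than the interval are flagged as certainty units", {
  psus <- data.frame(psu_id = c("P1", "P2", "P3"), M = c(1000, 100, 100))
  expect_warning(sel <- systematic_pps_select(psus, a = 2, seed = 1),
                 "certainty")
  expect_true(all(sel$pi <= 1))
  expect_error(systematic_pps_select(psus, a = 5), "between 1 and")
})

test_that("second-stage count scales the planned take with frame growth", {
  expect_equal(second_stage_count(10, 100, 100), 10L)
  expect_equal(second_stage_count(10, 100, 120), 12L)
  expect_warning(k0 <- second_stage_count(10, 100, 0), "empty field listing")
  expect_equal(k0, 0L)
  expect_error(second_stage_count(10, 0, 50), "positive")
})

test_that("a design-frame draw is exactly self-weighting", {
  d <- build_test_design(n_tracts = 15, mean_hh = 250, seed = 8)
  draw <- two_stage_draw(d$pf, d$hh, a = 6, b = 15, seed = 13)
  ip <- inclusion_probabilities(draw)
  expect_true(ip$self_weighting)
  expect_equal(ip$f, 6 * 15 / sum(d$pf$psus$M))
  expect_equal(draw$households$weight, rep(1 / ip$f, nrow(draw$households)))
  # exactly a first-stage selections, b households in each (no growth)
  expect_equal(nrow(draw$psus), 6)
  expect_equal(draw$psus$b_i, rep(15L, 6))
  expect_equal(nrow(draw$households), 90)
})

test_that("doubling every PSU size halves the global fraction", {
  d <- build_test_design(n_tracts = 10, mean_hh = 300, seed = 30)
  f1 <- two_stage_draw(d$pf, d$hh, a = 4, b = 10, seed = 1)$f
  pf2 <- d$pf
  pf2$psus$M <- pf2$psus$M * 2L
  expect_equal(4 * 10 / sum(pf2$psus$M), f1 / 2)
})

test_that("identical seeds reproduce the draw exactly", {
  d <- build_test_design(n_tracts = 12, mean_hh = 300, seed = 9)
  d1 <- two_stage_draw(d$pf, d$hh, a = 5, b = 12, seed = 77)
  d2 <- two_stage_draw(d$pf, d$hh, a = 5, b = 12, seed = 77)
  expect_identical(d1$households, d2$households)
  expect_identical(d1$psus, d2$psus)
})

test_that("frame growth changes realised takes but keeps the fraction fixed", {
  d <- build_test_design(n_tracts = 10, mean_hh = 300, seed = 14)
  grown <- stats::setNames(round(d$pf$psus$M * 1.2), d$pf$psus$psu_id)
  # grow the listing to match: duplicate households into the new listing
  hh <- d$hh
  extra <- do.call(rbind, lapply(d$pf$psus$psu_id, function(p) {
    need <- grown[[p]] - sum(hh$psu_id == p)
    rows <- hh[hh$psu_id == p, ][seq_len(need), ]
    rows$household_id <- paste0(rows$household_id, "_new")
    rows
  }))
  hh2 <- rbind(hh, extra)
  draw <- two_stage_draw(d$pf, hh2, a = 4, b = 10, seed = 5)
  expected_b <- as.integer(round(10 * draw$psus$M_prime / draw$psus$M))
  expect_equal(draw$psus$b_i, expected_b)
  # realised per-household probability in PSU i: pi_i * b_i / M_i'
  # stays within rounding of the global f
  p <- draw$households$p_incl
  expect_true(all(abs(p - draw$f) / draw$f < 0.06))
})
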
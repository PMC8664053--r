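# Independent oracles used to cross-check the package implementation.
# These are written from the defining formulas, deliberately not sharing
# code with the package.

# One-way ANOVA (moment) estimator of the intra-class correlation of y
# within clusters g, for unbalanced cluster sizes.
oracle_anova_icc <- function(y, g) {
  keep <- !is.na(y)
  y <- y[keep]
  g <- factor(g[keep])
  n_i <- as.vector(table(g))
  N <- length(y)
  a <- nlevels(g)
  m_i <- tapply(y, g, mean)
  m <- mean(y)
  ssb <- sum(n_i * (m_i - m)^2)
  ssw <- sum((y - m_i[g])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  k0 <- (N - sum(n_i^2) / N) / (a - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}

# Brute-force, term-by-term evaluation of the ultimate-cluster linearized
# variance of a weighted proportion: p = sum(w y)/sum(w); PSU residuals
# z_j = (Y_j - p W_j)/W; var = a/(a-1) * sum((z_j - mean(z))^2).
oracle_ultimate_cluster <- function(y, w, psu) {
  ids <- unique(psu)
  a <- length(ids)
  Y <- 0
  W <- 0
  for (id in ids) {
    rows <- which(psu == id & !is.na(y))
    for (r in rows) {
      Y <- Y + w[r] * y[r]
      W <- W + w[r]
    }
  }
  p <- Y / W
  z <- numeric(a)
  for (j in seq_along(ids)) {
    rows <- which(psu == ids[j] & !is.na(y))
    Yj <- 0
    Wj <- 0
    for (r in rows) {
      Yj <- Yj + w[r] * y[r]
      Wj <- Wj + w[r]
    }
    z[j] <- (Yj - p * Wj) / W
  }
  zbar <- sum(z) / a
  v <- 0
  for (j in seq_len(a)) v <- v + (z[j] - zbar)^2
  v <- v * a / (a - 1)
  list(p = p, var = v)
}

# Outcome probabilities of the three-visit protocol, by enumeration over
# the visit at which contact first succeeds.
oracle_fieldwork_probs <- function(p_refusal, p_absent, attempts) {
  p_int <- 0
  p_ref <- 0
  for (v in seq_len(attempts)) {
    reach <- p_absent^(v - 1) * (1 - p_absent)
    p_int <- p_int + reach * (1 - p_refusal)
    p_ref <- p_ref + reach * p_refusal
  }
  c(interviewed = p_int, refusal = p_ref,
    absence = 1 - p_int - p_ref)
}

# A tiny fixed three-PSU survey fixture for oracle-equivalence tests.
small_survey_fixture <- function() {
  data.frame(
    psu_id = rep(c("A", "B", "C"), each = 4),
    weight = c(2, 2, 2, 2, 1.5, 1.5, 1.5, 1.5, 3, 3, 3, 3),
    y = c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 1),
    sex = rep(c("M", "F"), 6),
    stringsAsFactors = FALSE
  )
}

# Frame + PSU scaffold used by sampler/estimator tests.
build_test_design <- function(n_tracts = 20, mean_hh = 100,
                              persons_per_hh = 1, specs = list(), seed = 1) {
  cfg <- frame_config(
    n_tracts = n_tracts,
    mean_households_per_tract = mean_hh,
    mean_persons_per_household = persons_per_hh,
    indicator_specs = specs,
    seed = seed
  )
  frame <- generate_frame(cfg)
  pf <- build_psus(frame)
  hh <- assign_households(pf, frame$households)
  list(frame = frame, pf = pf, hh = hh)
}
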
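two_group_ds <- function(counts, levels = c("A", "B")) {
  sch <- covariate_schema(cov_categorical("g", levels))
  tte_dataset(data.frame(g = rep(levels, counts),
                         diagnosis_date = "1990-01-01",
                         survival_days = 100L, vital_status = "dead"), sch)
}

test_that("distribution comparison reports counts, percentages and differences", {
  a <- two_group_ds(c(40, 60))
  same <- compare_covariate_distributions(a, a)
  expect_true(all(same$abs_diff == 0))

  b <- two_group_ds(c(41, 59))
  cmp <- compare_covariate_distributions(a, b)
  g <- cmp[cmp$covariate == "g", ]
  expect_equal(g$abs_diff, c(1, 1))
  expect_equal(g$source_pct, c(40, 60))
  expect_equal(sum(g$source_pct), 100)
  # symmetric in the absolute differences
  rev <- compare_covariate_distributions(b, a)
  expect_equal(rev$abs_diff, cmp$abs_diff)
  # a level absent from one dataset still appears, with zero count
  c3 <- two_group_ds(c(40, 59, 1), levels = c("A", "B", "C"))
  schAB <- attr(a, "schema")
  cmp3 <- compare_covariate_distributions(a, c3, schema = schAB)
  expect_equal(cmp3$source_n[cmp3$level == "C"], 0L)
})

test_that("product-limit estimator matches hand and brute-force computations", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 1 / 3))
  expect_equal(km_estimate(c(4, 9), c(0, 0))$surv, c(1, 1))   # no events
  expect_equal(tail(km_estimate(rep(5, 7), rep(1, 7))$surv, 1), 0)
  expect_error(km_estimate(numeric(0), logical(0)), "empty")

  # brute force on random small instances with ties
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    tt <- sample(1:8, n, replace = TRUE)
    ev <- runif(n) < 0.6
    km <- km_estimate(tt, ev)
    ut <- sort(unique(tt))
    s <- 1; surv_o <- numeric(0)
    for (u in ut) {
      d <- sum(tt == u & ev); r <- sum(tt >= u)
      s <- s * (1 - d / r)
      surv_o <- c(surv_o, s)
    }
    expect_equal(km$surv, surv_o)
  }
})

test_that("restricted mean survival time integrates step and model curves", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 0))
  expect_equal(rmst(km, 3), 1 + 2 / 3 + 1 / 3)
  expect_equal(rmst(km_estimate(c(5, 6), c(0, 0)), 4), 4)     # S == 1
  expect_equal(rmst(toy_fpm(0, 1), 10, no_covariates()), 1 - exp(-10),
               tolerance = 1e-4)
  expect_error(rmst(km, -1), "positive")

  # exact step-area oracle on a random instance
  set.seed(95)
  tt <- round(runif(30, 0.1, 6), 2); ev <- runif(30) < 0.7
  km2 <- km_estimate(tt, ev)
  tau <- 4.5
  grid <- sort(unique(c(0, km2$time[km2$time < tau], tau)))
  oracle <- sum(vapply(seq_len(length(grid) - 1), function(i) {
    s <- if (i == 1) 1 else km2$surv[max(which(km2$time <= grid[i]))]
    s * (grid[i + 1] - grid[i])
  }, numeric(1)))
  expect_equal(rmst(km2, tau), oracle, tolerance = 1e-12)
})

test_that("seed stability reruns generation per seed and is deterministic", {
  src <- small_source()
  ss <- seed_stability(src, seeds = c(3L, 3L, 8L), horizon_years = 8,
                       fits = small_fits())
  expect_equal(ss$rmst_years[1], ss$rmst_years[2])    # same seed, same value
  expect_equal(nrow(ss), 3L)
  expect_true(is.finite(attr(ss, "source_rmst")))
  expect_error(seed_stability(src, seeds = 1L, fits = small_fits()), "2 seeds")
})

test_that("privacy report counts window matches for a matched-profile cohort", {
  fits <- small_fits()
  probes <- make_probe_records(small_source(), 2)
  set.seed(55)
  rep1 <- privacy_match_report(probes[1, ], fits, n_synth = 20000L)
  expect_equal(rep1$pct_alive + rep1$pct_dead, 100)
  expect_true(all(rep1[, grep("^pct", names(rep1))] >= 0 &
                  rep1[, grep("^pct", names(rep1))] <= 100))
  # diagnosis dates are uniform in the probe's year, so the expected match
  # fraction is the window's overlap with the year (31/365 for a mid-year
  # probe, less when the window is clipped at a year boundary)
  pd <- as.Date(probes$diagnosis_date[1])
  yr <- as.integer(format(pd, "%Y"))
  ydays <- seq(as.Date(paste0(yr, "-01-01")), as.Date(paste0(yr, "-12-31")), by = "day")
  p_exp <- mean(abs(as.integer(ydays - pd)) <= 15)
  expect_lt(abs(rep1$pct_date_within_window / 100 - p_exp),
            4 * sqrt(p_exp * (1 - p_exp) / 20000) + 0.002)
  set.seed(55)
  rep2 <- privacy_match_report(probes[1, ], fits, n_synth = 20000L)
  expect_identical(rep1, rep2)
})

test_that("pattern presence across replicates follows the closed-form probability", {
  # marginal model with a known rare level
  sch <- covariate_schema(cov_categorical("g", c("common", "rare")))
  ds <- tte_dataset(data.frame(g = rep(c("common", "rare"), c(990, 10)),
                               diagnosis_date = "1990-01-01",
                               survival_days = 50L, vital_status = "dead"), sch)
  cm <- fit_covariate_sequence(ds)
  set.seed(66)
  frac <- pattern_frequency_audit(data.frame(g = c("rare", "common")), cm,
                                  n_datasets = 200L, n_per_dataset = 100L)
  p <- 0.01
  expected <- 1 - (1 - p)^100                     # ~0.634
  expect_lt(abs(frac[1] - expected), 3 * sqrt(expected * (1 - expected) / 200))
  expect_equal(frac[2], 1)                        # ~always present
})
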
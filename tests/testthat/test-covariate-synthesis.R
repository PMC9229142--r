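test_that("inverse-normal-rank transform maps tie-averaged ranks to normal quantiles", {
  expect_equal(inverse_normal_rank(5), 0)                     # qnorm(0.5)
  expect_equal(inverse_normal_rank(c(5, 1, 9)),
               qnorm(c(3, 1, 5) / 6))                         # (r - 0.5)/3
  x <- c(2, 7, 7, 1, 5)
  z <- inverse_normal_rank(x)
  expect_equal(order(z[c(1, 4, 5)]), order(x[c(1, 4, 5)]))    # order preserving
  expect_equal(z[2], z[3])                                    # ties share a rank
  expect_error(inverse_normal_rank(c(1, NA)), "non-finite")
})

test_that("default modelling order is continuous first, then ascending level count", {
  sch <- covariate_schema(
    cov_categorical("four", c("a", "b", "c", "d")),
    cov_categorical("two", c("x", "y")),
    cov_continuous("age")
  )
  expect_equal(order_covariates(sch), c("age", "two", "four"))

  one <- covariate_schema(cov_continuous("only"))
  expect_equal(order_covariates(one), "only")

  # explicit model_order overrides (the colon schema fixes the published order)
  expect_equal(order_covariates(colon_schema()),
               c("age", "year", "stage", "sex", "subsite"))
  dup <- covariate_schema(cov_categorical("a", "x", model_order = 1L),
                          cov_categorical("b", "y", model_order = 1L))
  expect_error(order_covariates(dup), "duplicate")
})

test_that("a marginal two-level model recovers the logit of the sample proportion", {
  sch <- covariate_schema(cov_categorical("g", c("no", "yes")))
  df <- data.frame(g = rep(c("no", "yes"), c(300, 700)),
                   diagnosis_date = "1990-01-01", survival_days = 100L,
                   vital_status = "dead")
  ds <- tte_dataset(df, sch)
  cm <- fit_covariate_sequence(ds)
  expect_equal(unname(cm$models$g$coefficients[1, "(Intercept)"]),
               log(0.7 / 0.3), tolerance = 1e-3)

  # predicted probabilities sum to one and match the sample split
  P <- survsynth:::multinomial_probs(cm$models$g, df[1, , drop = FALSE])
  expect_equal(sum(P), 1)
  expect_equal(unname(P[1, "yes"]), 0.7, tolerance = 1e-3)
})

test_that("sampling a fitted marginal multinomial reproduces source proportions", {
  sch <- covariate_schema(cov_categorical("g", c("no", "yes")))
  ds <- tte_dataset(data.frame(g = rep(c("no", "yes"), c(300, 700)),
                               diagnosis_date = "1990-01-01",
                               survival_days = 100L, vital_status = "dead"), sch)
  cm <- fit_covariate_sequence(ds)
  n <- 1e6L
  set.seed(31)
  draw <- sample_covariates(cm, n)
  p <- mean(draw$g == "yes")
  expect_lt(abs(p - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  expect_error(sample_covariates(cm, 0), "positive")

  # degenerate single-level covariate: probability one on that level
  sch1 <- covariate_schema(cov_categorical("g", "only"))
  ds1 <- tte_dataset(data.frame(g = "only", diagnosis_date = "1990-01-01",
                                survival_days = 1L, vital_status = "dead")[rep(1, 20), ], sch1)
  cm1 <- fit_covariate_sequence(ds1)
  expect_true(all(sample_covariates(cm1, 50)$g == "only"))
})

test_that("predicted level probabilities sum to one across random profiles", {
  fits <- small_fits()
  cm <- fits$cov_models
  set.seed(77)
  prof <- sample_covariates(cm, 40)
  for (nm in c("year", "stage", "sex", "subsite")) {
    P <- survsynth:::multinomial_probs(cm$models[[nm]], prof)
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
  }
})

test_that("a bimodal continuous covariate is recovered to small KS distance", {
  set.seed(88)
  n <- 9064L
  comp <- runif(n) < 0.35
  x <- ifelse(comp, rnorm(n, 58, 9), rnorm(n, 74, 8))
  sch <- covariate_schema(cov_continuous("x"))
  ds <- tte_dataset(data.frame(x = x, diagnosis_date = "1990-01-01",
                               survival_days = 100L, vital_status = "dead"), sch)
  cm <- fit_covariate_sequence(ds, control = cov_control(round_integers = FALSE))
  draw <- sample_covariates(cm, n, control = cov_control(round_integers = FALSE))
  ks <- suppressWarnings(ks.test(draw$x, x))$statistic
  expect_lt(unname(ks), 0.03)
})

test_that("fit-then-sample recovers a known age-stage dependence", {
  # source with stage probabilities shifted by age (fixture ground truth)
  src <- study_source()
  syn_cov <- {
    set.seed(12)
    sample_covariates(study_fits()$cov_models, nrow(src))
  }
  src_enc <- encode_missing_as_level(src, "stage")
  grp_s <- src_enc$age >= 70
  grp_y <- syn_cov$age >= 70
  for (st in c("Localized", "Distant")) {
    for (g in c(TRUE, FALSE)) {
      ps <- mean(src_enc$stage[grp_s == g] == st)
      py <- mean(syn_cov$stage[grp_y == g] == st)
      expect_lt(abs(ps - py), 3 * sqrt(ps * (1 - ps) / sum(grp_y == g)) + 0.01)
    }
  }
})

test_that("covariate model sets survive a JSON round trip", {
  fits <- small_fits()
  path <- withr::local_tempfile(fileext = ".json")
  write_covariate_models(fits$cov_models, path)
  back <- read_covariate_models(path)
  set.seed(5); a <- sample_covariates(fits$cov_models, 400)
  set.seed(5); b <- sample_covariates(back, 400)
  expect_identical(a, b)
})
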
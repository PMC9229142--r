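test_that("restricted cubic spline basis matches the plus-function definition", {
  k <- c(0, 1, 2)
  b <- rcs_basis(1.5, k)
  expect_equal(unname(b$basis[1, 1]), 1.5)
  expect_equal(unname(b$basis[1, 2]), 0.5^3 - 0.5 * 1.5^3)   # -1.5625
  expect_equal(unname(b$basis[1, 2]), -1.5625)

  # all non-linear columns vanish at and below the first knot
  expect_equal(unname(rcs_basis(0, k)$basis[1, -1]), 0)
  expect_equal(unname(rcs_basis(-3, k)$basis[1, -1]), 0)

  # linear beyond the boundary: second numerical derivative ~ 0
  kn <- c(-1, 0.3, 0.8, 2)
  x0 <- 3; h <- 1e-3
  f <- function(x) rcs_basis(x, kn)$basis
  second <- (f(x0 + h) + f(x0 - h) - 2 * f(x0)) / h^2
  expect_lt(max(abs(second)), 1e-6)
  expect_error(rcs_basis(1, c(2, 1)), "increasing")
})

test_that("basis and first derivative are continuous at every knot", {
  kn <- c(-0.5, 0.2, 1.1, 2.3)
  eps <- 1e-8
  for (k in kn) {
    lo <- rcs_basis(k - eps, kn); hi <- rcs_basis(k + eps, kn)
    expect_lt(max(abs(lo$basis - hi$basis)), 1e-6)
    expect_lt(max(abs(lo$deriv - hi$deriv)), 1e-6)
  }
  # derivative matches a central difference away from knots
  x <- c(-0.2, 0.7, 1.9); h <- 1e-6
  num <- (rcs_basis(x + h, kn)$basis - rcs_basis(x - h, kn)$basis) / (2 * h)
  expect_equal(rcs_basis(x, kn)$deriv, num, tolerance = 1e-5)
})

test_that("winsorizing replaces only the tails, under the declared percentile rule", {
  expect_equal(winsorize(c(3, 1, 2), 0, 100), c(3, 1, 2))
  expect_equal(winsorize(rep(7, 5), 10, 90), rep(7, 5))
  x <- 1:100
  w <- winsorize(x, 2, 98)
  q <- quantile(x, c(0.02, 0.98), type = 7, names = FALSE)
  expect_equal(min(w), q[1])
  expect_equal(max(w), q[2])
  expect_equal(w[x > q[1] & x < q[2]], x[x > q[1] & x < q[2]])
  expect_error(winsorize(numeric(0)), "empty")
  expect_error(winsorize(1:5, 60, 40))
})

test_that("design construction is deterministic and reuses the frozen layout", {
  set.seed(2)
  df <- data.frame(stage = factor(sample(c("L", "R", "D", "M"), 50, TRUE)),
                   age = rnorm(50, 70, 10))
  spec <- fpm_spec(baseline_df = 2L, factors = "stage",
                   continuous = list(age = 3L),
                   interactions = list(c("age", "stage")))
  bd <- build_design(df, spec)
  expect_equal(length(bd$term_cols$stage), 3L)        # 4 levels -> 3 dummies
  expect_equal(length(bd$term_cols$age), 3L)
  expect_equal(length(bd$term_cols$`age:stage`), 9L)  # 3 x 3 products

  # rebuilding on permuted rows gives the same columns, permuted
  perm <- sample(nrow(df))
  bd2 <- build_design(df[perm, ], spec, layout = bd$layout)
  expect_equal(bd2$X, bd$X[perm, ], ignore_attr = TRUE)

  # unseen level is an error
  df2 <- df[1:3, ]; levels(df2$stage) <- c(levels(df2$stage), "X"); df2$stage[1] <- "X"
  expect_error(build_design(df2, spec, layout = bd$layout), "unseen")
})

test_that("log likelihood equals the closed forms of the exponential submodel", {
  D <- rbind(c(1, 0)); Dp <- rbind(c(0, 1))
  # event at t = 1 under H(t) = t: log h(1) - H(1) = -1
  expect_equal(fpm_loglik(c(0, 1), 1, TRUE, cbind(1, log(1)), Dp), -1)
  # censored at t = 2: log S(2) = -2
  expect_equal(fpm_loglik(c(0, 1), 2, FALSE, cbind(1, log(2)), Dp), -2)
  expect_error(fpm_loglik(c(0, 1), 0, TRUE, cbind(1, -Inf), Dp), "positive")
})

test_that("log likelihood equals a brute-force hazard-survival oracle", {
  set.seed(14)
  for (rep in 1:100) {
    n <- 10L
    tt <- rexp(n, 0.5)
    ev <- runif(n) < 0.7
    x <- rnorm(n)
    g0 <- rnorm(1); g1 <- runif(1, 0.2, 3); b <- rnorm(1, 0, 0.5)
    D <- cbind(1, log(tt), x); Dp <- cbind(0, 1, 0)[rep(1, n), ]
    ll <- fpm_loglik(c(g0, g1, b), tt, ev, D, Dp)
    # independent factorization: f = h * S with H = exp(g0 + b x) t^g1
    H <- exp(g0 + b * x) * tt^g1
    h <- exp(g0 + b * x) * g1 * tt^(g1 - 1)
    oracle <- sum(log(h[ev])) - sum(H)
    expect_equal(ll, oracle, tolerance = 1e-10)
  }
})

test_that("df=1 fit is a Weibull maximum-likelihood fit", {
  set.seed(21)
  n <- 4000L
  tt <- rweibull(n, shape = 1.4, scale = 3)
  ev <- tt < 6; tt <- pmin(tt, 6)     # administrative-style censoring
  fit <- fit_fpm(no_covariates(n), fpm_spec(baseline_df = 1L),
                 time = tt, event = ev)
  sr <- survival::survreg(survival::Surv(tt, ev) ~ 1, dist = "weibull")
  shape_hat <- unname(fit$coefficients["lnt.s1"])
  g0_hat <- unname(fit$coefficients["(Intercept)"])
  expect_equal(shape_hat, 1 / sr$scale, tolerance = 1e-4)
  expect_equal(g0_hat, unname(-coef(sr)[1] / sr$scale), tolerance = 1e-4)
  expect_true(fit$convergence$converged)
})

test_that("a df=2 spline fit matches an independent spline-hazard implementation", {
  set.seed(22)
  n <- 1500L
  tt <- rweibull(n, shape = 0.9, scale = 4)
  ev <- tt < 8; tt <- pmin(tt, 8)
  fit <- fit_fpm(no_covariates(n), fpm_spec(baseline_df = 2L),
                 time = tt, event = ev)
  ref <- flexsurv::flexsurvspline(survival::Surv(tt, ev) ~ 1, k = 1,
                                  scale = "hazard")
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
  tg <- c(0.5, 1, 2, 4, 7)
  s_ref <- summary(ref, t = tg, type = "survival", ci = FALSE)[[1]]$est
  expect_equal(predict_survival(fit, no_covariates(1), tg), s_ref,
               tolerance = 1e-3)
})

test_that("fit is invariant to permuting input rows", {
  src <- small_source()
  fits <- small_fits()
  set.seed(30)
  perm <- sample(nrow(src))
  src_p <- tte_dataset(as.data.frame(src)[perm, ], attr(src, "schema"))
  src_p <- encode_missing_as_level(src_p, "stage")
  fit_p <- fit_fpm(src_p, small_fits()$fpm$spec)
  expect_equal(fit_p$loglik, fits$fpm$loglik, tolerance = 1e-6)
})

test_that("predicted survival is a proper, monotone survival function", {
  fit <- small_fits()$fpm
  ds <- encode_missing_as_level(small_source(), "stage")
  set.seed(41)
  tg <- exp(seq(log(0.01), log(11), length.out = 1000))
  for (i in sample(nrow(ds), 5)) {
    prof <- as.data.frame(ds)[i, ]
    s <- predict_survival(fit, prof, tg)
    expect_true(all(s > 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12))
    expect_gt(predict_survival(fit, prof, 1e-8), 0.999999)
  }
})

test_that("hazard agrees with closed forms and with numerical differentiation", {
  expect_equal(predict_hazard(toy_fpm(0, 1), no_covariates(), c(0.3, 1, 5)),
               rep(1, 3))                                   # exponential(1)
  expect_equal(predict_hazard(toy_fpm(0, 2), no_covariates(), c(0.5, 2)),
               c(1, 4))                                     # h(t) = 2t
  fit <- small_fits()$fpm
  prof <- as.data.frame(encode_missing_as_level(small_source(), "stage"))[7, ]
  tg <- seq(0.5, 8, by = 0.5)
  h <- predict_hazard(fit, prof, tg)
  eps <- 1e-5
  num <- -(log(predict_survival(fit, prof, tg + eps)) -
           log(predict_survival(fit, prof, tg - eps))) / (2 * eps)
  expect_equal(h, num, tolerance = 1e-4)
})

test_that("survival model fits survive a JSON round trip", {
  fit <- small_fits()$fpm
  path <- withr::local_tempfile(fileext = ".json")
  write_fpm(fit, path)
  back <- read_fpm(path)
  prof <- as.data.frame(encode_missing_as_level(small_source(), "stage"))[3, ]
  tg <- c(0.2, 1, 3, 9)
  expect_equal(predict_survival(back, prof, tg),
               predict_survival(fit, prof, tg))
  expect_equal(back$baseline_knots, fit$baseline_knots)
})
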
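test_that("the logistic landing curve matches closed-form values", {
  expect_equal(landing_prob_given_wind(logistic_landing(1, 0), c(0, 5, 20)),
               rep(0.5, 3))
  expect_equal(landing_prob_given_wind(logistic_landing(1, 0.8), 0), 0.5)
  expect_equal(landing_prob_given_wind(logistic_landing(1, 0.62), 10),
               1 / (1 + exp(6.2)), tolerance = 1e-12)
  # strictly decreasing iff b > 0
  p <- landing_prob_given_wind(logistic_landing(3, 0.4), seq(0, 15, 0.5))
  expect_true(all(diff(p) < 0))
  expect_error(logistic_landing(0, 1), "positive")
  expect_error(landing_prob_given_wind(logistic_landing(1, 1), -2), ">= 0")
})

test_that("log-normal moment matching inverts exactly", {
  wd <- lognormal_from_moments(10, 0)
  expect_equal(wd$s, 0)
  expect_equal(wd$m, log(10))
  wd2 <- lognormal_from_moments(10, 2)
  expect_equal(wd2$s^2, log(1.04), tolerance = 1e-12)
  expect_equal(wd2$m, log(10) - log(1.04) / 2, tolerance = 1e-12)
  # round trip over a grid
  for (U in c(0.5, 3, 6.1, 13.5)) for (u in c(0, 0.1, 1, 0.5 * U)) {
    w <- lognormal_from_moments(U, u)
    expect_equal(exp(w$m + w$s^2 / 2), U, tolerance = 1e-10)
    expect_equal(sqrt((exp(w$s^2) - 1) * exp(2 * w$m + w$s^2)), u,
                 tolerance = 1e-10)
  }
  expect_error(lognormal_from_moments(0, 1), "> 0")
  expect_error(lognormal_from_moments(5, -1), ">= 0")
})

test_that("sampled winds reproduce the matched moments", {
  wd <- lognormal_from_moments(6.1, 0.2 * 6.1)
  set.seed(3)
  W <- rlnorm(1e5, wd$m, wd$s)
  expect_lt(abs(mean(W) - 6.1), 3 * sd(W) / sqrt(1e5))
  expect_lt(abs(sd(W) - 1.22), 0.03)
})

test_that("the expected landing probability integrates correctly", {
  # flat curve: P = 1/2 whatever the wind distribution
  expect_equal(mean_landing_prob(logistic_landing(1, 0),
                                 lognormal_from_moments(7, 3)), 0.5,
               tolerance = 1e-9)
  # point-mass limit
  m <- logistic_landing(2, 0.5)
  expect_equal(mean_landing_prob(m, lognormal_from_moments(6, 0)),
               landing_prob_given_wind(m, 6))
  expect_lt(abs(mean_landing_prob(m, lognormal_from_moments(6, 1e-6)) -
                  landing_prob_given_wind(m, 6)), 1e-6)
  # agreement with the Monte-Carlo oracle
  set.seed(2)
  for (i in 1:3) {
    a <- runif(1, 0.5, 20); b <- runif(1, 0.1, 1)
    U <- runif(1, 2, 12); u <- runif(1, 0.05, 0.5) * U
    mm <- logistic_landing(a, b); wd <- lognormal_from_moments(U, u)
    mc <- mean_landing_prob_mc(mm, wd, 2e5, seed = i)
    expect_lt(abs(mean_landing_prob(mm, wd) - mc$P), 3 * mc$se)
  }
})

test_that("the Monte-Carlo estimator is exact in degenerate cases", {
  wd <- lognormal_from_moments(8, 2)
  expect_equal(mean_landing_prob_mc(logistic_landing(1, 0), wd, 100, seed = 1)$P,
               0.5)
  m <- logistic_landing(3, 0.7)
  expect_equal(mean_landing_prob_mc(m, lognormal_from_moments(8, 0), 100)$P,
               landing_prob_given_wind(m, 8))
  a <- mean_landing_prob_mc(m, wd, 1000, seed = 5)
  b <- mean_landing_prob_mc(m, wd, 1000, seed = 5)
  expect_identical(a, b)
})

test_that("geometric attempt arithmetic is exact", {
  d <- attempt_distribution(0.5)
  expect_equal(attempt_pmf(d, 2), 0.25)
  expect_equal(attempt_cdf(d, 3), 0.875)
  expect_equal(d$expected_attempts, 2)
  d1 <- attempt_distribution(1)
  expect_equal(attempt_pmf(d1, 1), 1)
  expect_equal(d1$expected_attempts, 1)
  # partial sum + tail is one, and the cdf matches its closed form
  for (P in c(0.05, 0.25, 0.5, 0.9, 1)) {
    dd <- attempt_distribution(P)
    N <- 40
    expect_equal(sum(attempt_pmf(dd, 1:N)) + (1 - P)^N, 1, tolerance = 1e-12)
    expect_equal(attempt_cdf(dd, 1:N), 1 - (1 - P)^(1:N))
  }
  # quantiles bracket their level
  dq <- attempt_distribution(0.3)
  for (q in c(0.1, 0.5, 0.9, 0.99)) {
    nq <- attempt_quantile(dq, q)
    expect_gte(attempt_cdf(dq, nq), q)
    if (nq > 1) expect_lt(attempt_cdf(dq, nq - 1), q)
  }
  expect_error(attempt_distribution(0), "\\(0, 1\\]")
  expect_error(attempt_distribution(1.1), "\\(0, 1\\]")
})

test_that("collapsing the fitted model reproduces its predictions exactly", {
  fit <- shared_fit()
  for (prof in list(guillemot_ln,
                    list(ledge = "small", species = "razorbill", height = "h1"),
                    list(ledge = "large", species = "guillemot", height = "h4"))) {
    ll <- logistic_from_glmm(fit, prof)
    set.seed(4)
    W <- runif(100, 0, 14)
    expect_lt(max(abs(landing_prob_given_wind(ll, W) -
                        predict_success(fit, prof, W))), 1e-12)
  }
  # b is the negated total wind slope for the profile's ledge
  ll_small <- logistic_from_glmm(
    fit, list(ledge = "small", species = "guillemot", height = "h3"))
  expect_equal(ll_small$b,
               -(fit$coefficients[["wind_c"]] +
                   fit$coefficients[["wind_c:ledgesmall"]]),
               tolerance = 1e-10)
  expect_error(logistic_from_glmm(fit, list(ledge = "tiny",
                                            species = "guillemot",
                                            height = "h3")), "unknown ledge")
})

test_that("at-sea curves obey their limiting identities", {
  m <- logistic_landing(5, 0.6)
  # no scaling, no turbulence: the curve is the pointwise logistic
  cv <- landing_curve_at_sea(m, TI = 0, scaling = 1, sea_winds = c(2, 5, 9),
                             n_max = 5)
  expect_equal(cv$P, landing_prob_given_wind(m, c(2, 5, 9)), tolerance = 1e-9)
  # halved winds at the cliff equal the unit-ratio curve at half the sea wind
  c_half <- landing_curve_at_sea(m, TI = 0.2, scaling = 0.5, sea_winds = 10)
  c_unit <- landing_curve_at_sea(m, TI = 0.2, scaling = 1, sea_winds = 5)
  expect_equal(c_half$P, c_unit$P, tolerance = 1e-12)
  # success declines with the at-sea wind; cumulative curves are monotone
  cv2 <- landing_curve_at_sea(m, TI = 0.2, scaling = 0.5, sea_winds = 1:16)
  expect_true(all(diff(cv2$P) < 0))
  cums <- as.matrix(cv2[, grep("^cum_", names(cv2))])
  expect_true(all(apply(cums, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(cums >= 0 & cums <= 1))
  # accepts a scaling_constant object
  sc <- sea_to_cliff_ratio(c(3, 4), c(6, 8))
  expect_equal(landing_curve_at_sea(m, 0.2, sc, 8)$cliff_wind, 4)
})
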
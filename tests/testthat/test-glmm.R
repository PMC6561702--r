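test_that("centring removes the mean and keeps the raw columns", {
  tab <- shared_obs()[1:3, ]
  tab$wind <- c(2, 4, 6)
  cen <- center_predictors(tab)
  expect_equal(cen$table$wind_c, c(-2, 0, 2))
  expect_equal(cen$means[["wind"]], 4)
  expect_equal(cen$table$wind, c(2, 4, 6))
  # an already-centred (all-zero) column is unchanged, with its mean
  # recorded as 0; a constant column also draws a degeneracy warning
  tab$wind <- c(0, 0, 0)
  expect_warning(cen2 <- center_predictors(tab), "no variation")
  expect_equal(cen2$table$wind_c, c(0, 0, 0))
  expect_equal(cen2$means[["wind"]], 0)
  expect_error(center_predictors(shared_obs()[0, ]), "empty")
})

test_that("the mixed model recovers the generating coefficients", {
  fit <- shared_fit()
  truth <- attr(shared_obs(), "truth")$coefficients
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["wind_c"]] - truth[["wind"]]), 0.1)
  expect_lt(abs(fit$coefficients[["ledgesmall"]] - truth[["ledge_small"]]),
            3 * fit$se[["ledgesmall"]] + 0.05)
  expect_lt(abs(fit$coefficients[["speciesrazorbill"]] -
                  truth[["species_razorbill"]]),
            3 * fit$se[["speciesrazorbill"]] + 0.05)
  expect_true(all(fit$se > 0))
  expect_lt(abs(fit$random_intercept_sd - 0.5), 0.2)
  # AIC convention: variance component counts as one parameter
  n_par <- length(fit$coefficients) + 1
  expect_equal(fit$aic, 2 * n_par - 2 * fit$logLik)
})

test_that("shifting wind by a constant changes only the centring mean", {
  obs <- small_obs()
  fit1 <- fit_landing_glmm(obs)
  obs2 <- obs
  obs2$wind <- obs2$wind + 5
  fit2 <- fit_landing_glmm(obs2)
  expect_equal(fit2$centering[["wind"]], fit1$centering[["wind"]] + 5)
  expect_equal(fit2$logLik, fit1$logLik, tolerance = 1e-8)
  # coefficients agree to well below estimation noise (the likelihood is
  # nearly flat along weak terms, so bit-level input changes move them more
  # than the likelihood)
  expect_lt(max(abs(fit2$coefficients - fit1$coefficients) / fit1$se), 0.01)
})

test_that("with no group heterogeneity the fit collapses to plain logistic", {
  cfg <- simulation_config(n_attempts = 3000, random_intercept_sd = 0, seed = 11)
  obs <- generate_observations(cfg)
  fit <- fit_landing_glmm(obs)
  expect_lt(fit$random_intercept_sd, 0.1)
  cen <- center_predictors(obs)
  d <- cen$table
  d$ledge <- factor(d$ledge)
  d$species <- factor(d$species)
  d$height <- factor(d$height, levels = c("h4", "h1", "h2", "h3"))
  g <- glm(success ~ wind_c * ledge + turbulence_c * ledge + species + height,
           binomial, data = d)
  expect_lt(max(abs(fit$coefficients - coef(g)[names(fit$coefficients)])), 0.02)
})

test_that("fitting requires group and factor replication", {
  obs <- shared_obs()[1:50, ]
  obs$day <- "2016-04-28"
  obs$colony <- "colony_01"
  expect_error(fit_landing_glmm(obs), "two \\(day, colony\\) groups")
  obs2 <- shared_obs()[1:200, ]
  obs2$species <- "guillemot"
  expect_error(fit_landing_glmm(obs2), "fewer than 2 observed levels")
})

test_that("predictions respond to wind and reject unknown levels", {
  fit <- shared_fit()
  p <- predict_success(fit, guillemot_ln, wind = 0:12)
  expect_true(all(diff(p) < 0))          # total wind slope is negative
  expect_true(all(p > 0 & p < 1))
  expect_lt(p[9], 0.2)                   # 8 m/s on a long-narrow ledge
  expect_error(predict_success(fit, list(ledge = "vast", species = "guillemot",
                                         height = "h3"), 5),
               "unknown ledge")
  expect_error(predict_success(fit, guillemot_ln, -1), ">= 0")
  # marginal predictions shrink toward 1/2 relative to population-level
  pm <- predict_success(fit, guillemot_ln, wind = c(0, 10), marginal = TRUE)
  pp <- predict_success(fit, guillemot_ln, wind = c(0, 10))
  expect_true(all(abs(pm - 0.5) < abs(pp - 0.5)))
})

test_that("sequential deviance decomposition finds the built-in signal", {
  obs <- generate_observations(simulation_config(n_attempts = 2000, seed = 21))
  an <- anodev_table(obs)
  expect_equal(an$term, c("wind", "ledge", "turbulence", "species", "height",
                          "wind:ledge", "turbulence:ledge"))
  expect_true(all(an$deviance_explained_pct > -1e-8, na.rm = TRUE))
  expect_lt(sum(an$deviance_explained_pct, na.rm = TRUE), 100)
  expect_true(all(an$F_value >= 0, na.rm = TRUE))
})

test_that("with only a wind effect the wind term dominates the deviance", {
  only_wind <- setNames(numeric(13), names(simulation_config()$true_coefficients))
  only_wind["intercept"] <- 1.5
  only_wind["wind"] <- -0.62
  cfg <- simulation_config(n_attempts = 1500, true_coefficients = only_wind,
                           random_intercept_sd = 0.2, seed = 23)
  an <- anodev_table(generate_observations(cfg))
  expect_equal(an$term[which.max(an$deviance_explained_pct)], "wind")
  expect_gt(an$deviance_explained_pct[an$term == "wind"],
            3 * max(an$deviance_explained_pct[an$term != "wind"], na.rm = TRUE))
})

test_that("a pure-noise predictor explains essentially no deviance", {
  zero <- setNames(numeric(13), names(simulation_config()$true_coefficients))
  zero["intercept"] <- 0.5
  cfg <- simulation_config(n_attempts = 1200, true_coefficients = zero,
                           random_intercept_sd = 0.2, seed = 31)
  an <- anodev_table(generate_observations(cfg))
  expect_lt(an$deviance_explained_pct[an$term == "wind"], 1)
  expect_gt(an$p[an$term == "wind"], 0.01)
})

test_that("variance-partition R2 matches the generating variances", {
  fit <- shared_fit()
  r2 <- r2_nakagawa(fit)
  expect_true(r2[["marginal"]] <= r2[["conditional"]])
  expect_true(all(r2 >= 0 & r2 <= 1))
  # analytic value from the generating model
  obs <- shared_obs()
  truth <- attr(obs, "truth")
  b <- truth$coefficients
  wc <- obs$wind - truth$wind_center
  tc <- obs$turbulence - truth$turbulence_center
  ln <- obs$ledge == "long_narrow"; sm <- obs$ledge == "small"
  lp <- b[["intercept"]] + b[["wind"]] * wc + b[["turbulence"]] * tc +
    b[["ledge_long_narrow"]] * ln + b[["ledge_small"]] * sm +
    b[["species_razorbill"]] * (obs$species == "razorbill") +
    b[["height_h1"]] * (obs$height == "h1") +
    b[["height_h2"]] * (obs$height == "h2") +
    b[["height_h3"]] * (obs$height == "h3") +
    b[["wind_x_ledge_long_narrow"]] * wc * ln +
    b[["wind_x_ledge_small"]] * wc * sm +
    b[["turb_x_ledge_long_narrow"]] * tc * ln +
    b[["turb_x_ledge_small"]] * tc * sm
  vf <- var(lp); vr <- truth$random_intercept_sd^2
  expect_lt(abs(r2[["marginal"]] - vf / (vf + vr + pi^2 / 3)), 0.05)
  expect_lt(abs(r2[["conditional"]] - (vf + vr) / (vf + vr + pi^2 / 3)), 0.05)
})

test_that("preference chi-square reproduces hand-computed cases", {
  expect_equal(chi_square_preference(rbind(c(10, 20), c(20, 40)))$statistic, 0)
  hand <- chi_square_preference(rbind(c(10, 0), c(0, 10)))
  expect_equal(hand$statistic, 20)
  expect_equal(hand$df, 1)
  expect_equal(hand$n, 20)
  ref <- suppressWarnings(chisq.test(rbind(c(12, 3, 9), c(4, 8, 20)),
                                     correct = FALSE))
  ours <- chi_square_preference(rbind(c(12, 3, 9), c(4, 8, 20)))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_error(chi_square_preference(rbind(c(1, 0), c(2, 0))), "positive total")
  expect_error(chi_square_preference(rbind(c(1.5, 1), c(1, 1))), "integers")
})

test_that("simulated residuals look uniform for a well-specified model", {
  ru <- residual_uniformity(shared_fit(), n_sim = 200, seed = 8)
  expect_true(all(ru$residuals >= 0 & ru$residuals <= 1))
  expect_gt(ru$p, 0.001)
  ru2 <- residual_uniformity(shared_fit(), n_sim = 200, seed = 8)
  expect_equal(ru$p, ru2$p)
})
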
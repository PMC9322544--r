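test_that("fitted term sets match the three model specifications exactly", {
  d <- simulate_dataset(small_config(4, 5), seed = 61)
  core <- c("(Intercept)", "ep0", "risk0", "targetBeloved", "targetStranger",
            "sex_daM", "same_sex",
            "ep0:targetBeloved", "ep0:targetStranger",
            "risk0:targetBeloved", "risk0:targetStranger")
  f1 <- suppressWarnings(fit_model(d, 1))
  expect_setequal(f1$coefficients$term, core)
  expect_true(all(f1$coefficients$statistic_type == "z"))
  f2 <- suppressWarnings(fit_model(d, 2))
  expect_setequal(f2$coefficients$term,
                  c(core, "choice", "choice:targetBeloved",
                    "choice:targetStranger"))
  expect_true(all(f2$coefficients$statistic_type == "t"))
  f3 <- suppressWarnings(fit_model(d, 3))
  expect_setequal(f3$coefficients$term,
                  c("(Intercept)", "outcome", "risk1", "wtp",
                    "targetBeloved", "targetStranger", "sex_daM", "same_sex",
                    "outcome:targetBeloved", "outcome:targetStranger",
                    "risk1:targetBeloved", "risk1:targetStranger",
                    "wtp:targetBeloved", "wtp:targetStranger"))
  expect_error(fit_model(d, 4), "model")
  expect_equal(f1$n_groups, 9)
  expect_true(f1$converged)
})

test_that("a near-noiseless rating model recovers the generating slope exactly", {
  cfg <- deterministic_config(4, 5)
  cfg$generator$rating$mean[] <- 0
  cfg$generator$rating$mean[["outcome"]] <- 2
  # an exactly zero-variance response is degenerate for a mixed model;
  # epsilon noise keeps the fit well-posed while testing exact recovery
  cfg$generator$noise$rating_sd <- 1e-4
  d <- simulate_dataset(cfg, seed = 62)
  f3 <- suppressWarnings(fit_model(d, 3))
  est <- f3$coefficients
  expect_equal(est$estimate[est$term == "outcome"], 2, tolerance = 1e-3)
  others <- est$estimate[est$term != "outcome"]
  expect_true(all(abs(others) < 1e-3))
})

test_that("the binomial GLMM degenerates to ordinary logistic regression", {
  cfg <- small_config(5, 8)
  cfg$generator$choice$sd[] <- 0  # no subject heterogeneity in choice
  d <- simulate_dataset(cfg, seed = 63)
  f1 <- suppressWarnings(fit_model(d, 1))
  dd <- d
  dd$target <- factor(dd$target, levels = c("Self", "Beloved", "Stranger"))
  ref <- glm(choice ~ (ep0 + risk0) * target + sex_da + same_sex,
             family = binomial(), data = dd)
  expect_lt(as.data.frame(lme4::VarCorr(f1$fit))$sdcor[1], 0.15)
  expect_equal(coef(f1)[names(coef(ref))], coef(ref), tolerance = 0.05)
})

test_that("a single-subject Gaussian mixed model reduces to OLS", {
  cfg <- small_config(0, 1)
  d <- simulate_dataset(cfg, seed = 64)
  f2 <- suppressWarnings(fit_model(d, 2))
  dd <- d; dd$wtp <- dd$bid
  dd$target <- factor(dd$target, levels = c("Self", "Stranger"))
  ref <- lm(wtp ~ (ep0 + risk0 + choice) * target, data = dd)
  est <- coef(ref)[!is.na(coef(ref))]  # lm drops rank-deficient terms as NA
  expect_equal(coef(f2)[names(est)], est, tolerance = 1e-4)
})

test_that("inestimable target contrasts are dropped with a warning", {
  cfg <- small_config(6, 0)  # couples only: no Stranger level
  d <- simulate_dataset(cfg, seed = 65)
  expect_warning(f1 <- fit_model(d, 1), "dropped|constant")
  expect_false("targetStranger" %in% f1$coefficients$term)
  expect_true("targetBeloved" %in% f1$coefficients$term)
})

test_that("missed trials are excluded listwise from the models", {
  cfg <- small_config(4, 5)
  cfg$cohort$miss_prob <- 0.2
  d <- simulate_dataset(cfg, seed = 66)
  f2 <- suppressWarnings(fit_model(d, 2))
  expect_equal(f2$n_obs, sum(d$missed == 0L))
})

test_that("coefficient tables are written in the pipeline CSV dialect", {
  d <- simulate_dataset(small_config(3, 4), seed = 67)
  fits <- lapply(1:2, function(m) suppressWarnings(fit_model(d, m)))
  path <- tempfile(fileext = ".csv")
  tab <- write_coefficient_table(fits, path)
  back <- read.csv(path)
  expect_named(back, c("model", "term", "estimate", "se", "statistic",
                       "statistic_type", "p"))
  expect_setequal(unique(back$model), 1:2)
  expect_equal(nrow(back), nrow(tab))
})

test_that("generating coefficients map onto fitted term names", {
  cfg <- default_run_config()
  for (m in 1:3) {
    truth <- true_fixed_effects(cfg, m)
    d <- simulate_dataset(small_config(3, 3), seed = 68)
    f <- suppressWarnings(fit_model(d, m))
    expect_true(all(f$coefficients$term %in% names(truth)))
  }
})
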
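# deterministic balanced one-way dataset with known group structure
balanced_oneway <- function(g = 8, n = 12, tau = 0.8, sigma = 0.5, seed = 71) {
  set.seed(seed)
  grp <- factor(rep(seq_len(g), each = n))
  a <- rnorm(g, 0, tau)
  data.frame(y = 5 + a[as.integer(grp)] + rnorm(g * n, 0, sigma), group = grp)
}

test_that("REML variance components match the balanced-ANOVA closed form", {
  d <- balanced_oneway()
  fit <- fit_lmm(y ~ 1 + (1 | group), d, REML = TRUE)
  # method-of-moments: sigma2 = MSW, tau2 = (MSB - MSW) / n
  n <- 12
  gm <- tapply(d$y, d$group, mean)
  msb <- n * sum((gm - mean(d$y))^2) / (length(gm) - 1)
  msw <- sum((d$y - gm[as.integer(d$group)])^2) / (nrow(d) - length(gm))
  expect_equal(fit$sigma2, msw, tolerance = 1e-6)
  expect_equal(unname(sum(fit$re_variances)), (msb - msw) / n,
               tolerance = 1e-6)
})

test_that("with zero true group variance the LMM collapses to OLS", {
  set.seed(72)
  d <- data.frame(x = rnorm(120), group = factor(rep(1:6, each = 20)))
  d$y <- 1 + 2 * d$x + rnorm(120, 0, 0.3)   # no group effect
  fit <- fit_lmm(y ~ x + (1 | group), d)
  ols <- lm(y ~ x, d)
  expect_lt(unname(sum(fit$re_variances)), 1e-3)
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(ols)),
               tolerance = 1e-3)
})

test_that("NB GLMM without group variation matches an unmixed NB regression", {
  set.seed(73)
  d <- data.frame(x = rnorm(300), group = factor(rep(1:6, each = 50)))
  d$y <- rnbinom(300, mu = exp(1 + 0.5 * d$x), size = 4)
  fit <- fit_nb_glmm(y ~ x + (1 | group), d)
  ref <- MASS::glm.nb(y ~ x, data = d)
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(ref)),
               tolerance = 1e-3)
  expect_equal(fit$theta, ref$theta, tolerance = 0.05)
})

test_that("on Poisson data the NB fit approaches the Poisson GLMM", {
  set.seed(74)
  d <- data.frame(x = rnorm(240), group = factor(rep(1:6, each = 40)))
  a <- rnorm(6, 0, 0.3)
  d$y <- rpois(240, exp(1 + 0.4 * d$x + a[as.integer(d$group)]))
  nb <- fit_nb_glmm(y ~ x + (1 | group), d)
  po <- fit_poisson_glmm(y ~ x + (1 | group), d)
  expect_gt(nb$theta, 20)   # dispersion -> infinity limit
  se <- nb$coefficients[, 2]
  expect_true(all(abs(nb$coefficients[, 1] - po$coefficients[, 1]) < 2 * se))
})

test_that("input validation catches bad responses and singular designs", {
  d <- data.frame(y = c(1.5, 2, 3, 4), x = 1:4,
                  group = factor(c(1, 1, 2, 2)))
  expect_error(fit_nb_glmm(y ~ x + (1 | group), d), "integer")
  d2 <- data.frame(y = rnorm(40), x = rnorm(40),
                   group = factor(rep(1:4, 10)))
  d2$x2 <- 2 * d2$x
  expect_error(fit_lmm(y ~ x + x2 + (1 | group), d2), "collinear.*x2")
  d3 <- data.frame(smr = c(-1, rep(1, 39)), mass = rep(1, 40),
                   group = factor(rep(1:4, 10)))
  expect_error(fit_lmm(log(smr) ~ log(mass) + (1 | group), d3),
               "row")
})

test_that("the likelihood-ratio test follows the chi-square reference", {
  mk <- function(ll, df) structure(list(logLik = ll, df = df, REML = FALSE),
                                   class = "fit_result")
  same <- likelihood_ratio_test(mk(-100, 4), mk(-100, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  one <- likelihood_ratio_test(mk(-98.08, 5), mk(-100, 4))
  expect_equal(one$df, 1)
  expect_equal(one$p_value, pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(one$p_value, 0.05, tolerance = 1e-3)

  expect_error(likelihood_ratio_test(mk(-105, 5), mk(-100, 4)), "nested")
  expect_error(likelihood_ratio_test(mk(-100, 3), mk(-100, 4)), "nested")
  r <- mk(-100, 4); r$REML <- TRUE
  expect_error(likelihood_ratio_test(mk(-99, 5), r), "REML")
})

test_that("marginal/conditional R2 follows the variance-components formula", {
  mk <- function(fp, re, s2, family = "gaussian", theta = NA, y = NULL)
    structure(list(fixed_predictor = fp, re_variances = re, sigma2 = s2,
                   family = family, theta = theta, response = y),
              class = "fit_result")
  # var(fixed predictor) = 2, var_random = 1, var_resid = 1
  r2 <- nakagawa_r2(mk(c(-1, 1), 1, 1))
  expect_equal(r2$r2_marginal, 0.5)
  expect_equal(r2$r2_conditional, 0.75)

  # no random effects: marginal equals conditional
  r2b <- nakagawa_r2(mk(c(-1, 1), numeric(0), 1))
  expect_equal(r2b$r2_marginal, r2b$r2_conditional)

  expect_error(nakagawa_r2(mk(c(0, 0), numeric(0), 0)), "zero total variance")
})

test_that("R2 of a real fit matches an independent recomputation", {
  sim <- simulate_study(seed = 101, behaviour = FALSE)
  fit <- fit_lmm(log(smr) ~ log(mass) + temp + (1 | group / fish_id),
                 sim$smr_table)
  r2 <- nakagawa_r2(fit)
  # recompute straight from the lme4 object
  obj <- fit$object
  vf <- var(as.numeric(lme4::getME(obj, "X") %*% lme4::fixef(obj)))
  vr <- sum(vapply(lme4::VarCorr(obj), function(m) m[1, 1], numeric(1)))
  ve <- sigma(obj)^2
  expect_equal(r2$r2_marginal, vf / (vf + vr + ve), tolerance = 1e-8)
  expect_equal(r2$r2_conditional, (vf + vr) / (vf + vr + ve), tolerance = 1e-8)
  expect_lte(r2$r2_marginal, r2$r2_conditional)
  expect_true(r2$r2_conditional <= 1 && r2$r2_marginal >= 0)
})

test_that("NB R2 uses the stated observation-level variance approximations", {
  set.seed(75)
  d <- data.frame(x = rnorm(200), group = factor(rep(1:5, each = 40)))
  d$y <- rnbinom(200, mu = exp(1 + 0.6 * d$x), size = 3)
  fit <- fit_nb_glmm(y ~ x + (1 | group), d)
  lam <- mean(d$y)
  nu <- 1 / lam + 1 / fit$theta
  r2_ln <- nakagawa_r2(fit)
  r2_tg <- nakagawa_r2(fit, nb_resid = "trigamma")
  expect_equal(r2_ln$var_residual, log1p(nu))
  expect_equal(r2_tg$var_residual, trigamma(1 / nu))
  expect_lte(r2_ln$r2_marginal, r2_ln$r2_conditional)
})

test_that("backward selection drops null terms, keeps strong ones, honours protection", {
  set.seed(761)
  n <- 240
  d <- data.frame(x_strong = rnorm(n), x_null = rnorm(n),
                  group = factor(rep(1:6, each = 40)))
  d$y <- 1 + 1.5 * d$x_strong + rnorm(n)
  sel <- select_model(y ~ x_strong + x_null + (1 | group), d,
                      family = "gaussian", protect = character(0))
  kept <- attr(terms(lme4::nobars(sel$fit$formula)), "term.labels")
  expect_true("x_strong" %in% kept)
  expect_false("x_null" %in% kept)
  expect_true(all(c("step", "candidate", "p_value", "dropped") %in%
                    names(sel$trace)))

  # mass retained while SMR remains, even though mass is null
  d2 <- data.frame(smr = exp(rnorm(n)), mass = exp(rnorm(n)),
                   group = factor(rep(1:6, each = 40)))
  d2$y <- 2 * log(d2$smr) + rnorm(n, 0, 0.5)
  sel2 <- select_model(y ~ log(mass) + log(smr) + (1 | group), d2,
                       family = "gaussian")
  kept2 <- attr(terms(lme4::nobars(sel2$fit$formula)), "term.labels")
  expect_true(all(c("log(mass)", "log(smr)") %in% kept2))

  # marginality: main effects under a retained interaction are not dropped
  d3 <- data.frame(a = rnorm(n), b = rnorm(n),
                   group = factor(rep(1:6, each = 40)))
  d3$y <- 1 + 2 * d3$a * d3$b + rnorm(n)
  sel3 <- select_model(y ~ a * b + (1 | group), d3, family = "gaussian",
                       protect = character(0))
  kept3 <- attr(terms(lme4::nobars(sel3$fit$formula)), "term.labels")
  expect_true(all(c("a", "b", "a:b") %in% kept3))
})

test_that("fitting is deterministic: identical data gives identical results", {
  sim <- simulate_study(seed = 77, behaviour = FALSE)
  f1 <- fit_lmm(log(smr) ~ log(mass) + temp + (1 | group / fish_id),
                sim$smr_table)
  f2 <- fit_lmm(log(smr) ~ log(mass) + temp + (1 | group / fish_id),
                sim$smr_table)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$logLik, f2$logLik)
})

test_that("battery specs expose the study's model structures", {
  sp <- battery_spec("smr")
  expect_equal(sp$family, "gaussian")
  expect_true(grepl("group/fish_id", deparse(sp$formula[[3]]), fixed = TRUE))
  expect_equal(battery_spec("group_abf")$family, "negative_binomial")
  expect_equal(battery_spec("indiv_abf", indiv_family = "poisson")$family,
               "poisson")
  expect_error(battery_spec("nope"))
})
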
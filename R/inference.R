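# Mixed-effects inference layer: Gaussian LMMs and negative-binomial GLMMs
# with random intercepts (fish nested in group), likelihood-ratio model
# selection, and marginal/conditional R-squared.

# ---- internal helpers -------------------------------------------------------

# model frame over fixed + random grouping variables; errors on non-finite
# values produced e.g. by log() of non-positive data
.check_model_frame <- function(formula, data) {
  mf <- suppressWarnings(stats::model.frame(lme4::subbars(formula),
                                            data = data,
                                            na.action = stats::na.pass))
  num <- vapply(mf, is.numeric, logical(1))
  bad <- which(!stats::complete.cases(mf) |
                 rowSums(!is.finite(as.matrix(mf[, num, drop = FALSE]))) > 0)
  if (length(bad) > 0)
    stop(sprintf(
      "non-finite model values (e.g. log of a non-positive number) in row(s): %s",
      paste(utils::head(bad, 10), collapse = ", ")))
  invisible(mf)
}

.check_fixed_rank <- function(formula, data) {
  X <- stats::model.matrix(lme4::nobars(formula), data = data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("singular fixed-effect design; collinear term(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  invisible(TRUE)
}

# wrap a fitted (g)lmer model into a plain fit_result
.as_fit_result <- function(object, formula, family) {
  co <- stats::coef(summary(object))
  vc <- lme4::VarCorr(object)
  re_var <- vapply(vc, function(m) m[1, 1], numeric(1))
  sigma2 <- if (family == "gaussian") stats::sigma(object)^2 else NA_real_
  theta <- if (family == "negative_binomial")
    lme4::getME(object, "glmer.nb.theta") else NA_real_
  ll <- stats::logLik(object)
  X <- lme4::getME(object, "X")
  eta_fixed <- as.numeric(X %*% lme4::fixef(object))
  structure(
    list(object = object,
         formula = formula,
         family = family,
         coefficients = co,
         re_variances = re_var,
         sigma2 = sigma2,
         theta = theta,
         logLik = as.numeric(ll),
         df = attr(ll, "df"),
         n = stats::nobs(object),
         fixed_predictor = eta_fixed,
         response = lme4::getME(object, "y"),
         REML = lme4::isREML(object)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s mixed model: %s\n", x$family, deparse(x$formula)))
  cat(sprintf("  n = %d, logLik = %.3f (df = %d)%s\n", x$n, x$logLik, x$df,
              if (x$REML) " [REML]" else ""))
  stats::printCoefmat(x$coefficients, ...)
  cat("Random-effect variances:\n")
  print(round(x$re_variances, 5))
  if (!is.na(x$sigma2)) cat(sprintf("Residual variance: %.5f\n", x$sigma2))
  if (!is.na(x$theta)) cat(sprintf("NB dispersion (theta): %.4f\n", x$theta))
  invisible(x)
}

# ---- model fitting ----------------------------------------------------------

#' Fit a Gaussian linear mixed model
#'
#' Random-intercept LMM fitted with [lme4::lmer()]. Maximum likelihood is
#' the default so that fits are comparable in likelihood-ratio tests; REML
#' is available as a switch for final reported fits. Nesting of fish within
#' group is expressed in the usual lme4 syntax, e.g.
#' `log(smr) ~ log(mass) + temp + (1 | group / fish_id)`.
#'
#' @param formula Mixed-model formula (lme4 syntax).
#' @param data Data frame.
#' @param REML Use REML instead of ML (default `FALSE`).
#' @return A `fit_result`: coefficient table, random-effect variances,
#'   residual variance, log-likelihood, fixed-effect linear predictor.
#' @export
fit_lmm <- function(formula, data, REML = FALSE) {
  .check_model_frame(formula, data)
  .check_fixed_rank(formula, data)
  fit <- lme4::lmer(formula, data = data, REML = REML,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  .as_fit_result(fit, formula, "gaussian")
}

#' Fit a negative-binomial generalised linear mixed model
#'
#' Random-intercept GLMM with a negative-binomial response and log link,
#' fitted by Laplace-approximate maximum likelihood via [lme4::glmer.nb()].
#' The NB dispersion (size) parameter theta is estimated; larger theta means
#' closer to Poisson. Used for over-dispersed air-breath counts.
#'
#' @param formula Mixed-model formula (lme4 syntax); response must be
#'   non-negative integer counts.
#' @param data Data frame.
#' @return A `fit_result` (see [fit_lmm()]); `$theta` holds the estimated
#'   dispersion parameter.
#' @export
fit_nb_glmm <- function(formula, data) {
  mf <- .check_model_frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("response must be non-negative integer counts")
  .check_fixed_rank(formula, data)
  fit <- withCallingHandlers(
    lme4::glmer.nb(formula, data = data,
                   control = lme4::glmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w)))
        stop("negative-binomial GLMM failed to converge: ",
             conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  .as_fit_result(fit, formula, "negative_binomial")
}

#' Fit a Poisson generalised linear mixed model
#'
#' Poisson-family alternative for count responses (family switch for the
#' individual air-breathing model when over-dispersion is absent).
#'
#' @inheritParams fit_nb_glmm
#' @return A `fit_result`.
#' @export
fit_poisson_glmm <- function(formula, data) {
  mf <- .check_model_frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("response must be non-negative integer counts")
  .check_fixed_rank(formula, data)
  fit <- lme4::glmer(formula, data = data, family = stats::poisson(),
                     control = lme4::glmerControl(check.conv.singular = "ignore"))
  .as_fit_result(fit, formula, "poisson")
}

# ---- likelihood-ratio testing ----------------------------------------------

#' Likelihood-ratio test between nested mixed-model fits
#'
#' `statistic = 2 (logLik_full - logLik_reduced)`, compared to a chi-squared
#' distribution with df equal to the difference in parameter counts. Both
#' fits must be maximum-likelihood (not REML). Identical models give
#' statistic 0 and p = 1.
#'
#' @param full,reduced `fit_result` objects, `reduced` nested in `full`.
#' @return An object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (isTRUE(full$REML) || isTRUE(reduced$REML))
    stop("LRT requires maximum-likelihood (not REML) fits")
  stat <- 2 * (full$logLik - reduced$logLik)
  df <- full$df - reduced$df
  if (df < 0) stop("`reduced` has more parameters than `full`; models not nested")
  if (stat < -1e-6)
    stop("negative likelihood-ratio statistic: models not nested or not converged")
  stat <- max(stat, 0)
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# ---- marginal / conditional R-squared ---------------------------------------

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-components R-squared for mixed models: the marginal value is the
#' proportion of variance explained by the fixed effects alone,
#' `var_f / (var_f + sum(var_re) + var_resid)`; the conditional value adds
#' the random-effect variances to the numerator. `var_f` is the variance of
#' the fixed-effect linear predictor (on the link scale for GLMMs).
#'
#' For the negative-binomial family with log link the residual
#' (observation-level) variance has no exact closed form; the default is the
#' log-normal approximation `ln(1 + 1/lambda + 1/theta)` with `lambda` the
#' mean observed count, and the trigamma form
#' `trigamma(1 / (1/lambda + 1/theta))` is available as a switch. For the
#' Poisson family the same forms apply with `1/theta = 0`.
#'
#' @param fit A `fit_result`.
#' @param nb_resid `"lognormal"` (default) or `"trigamma"`: observation-level
#'   variance approximation for count families.
#' @return An object of class `r2_result`: list with `r2_marginal`,
#'   `r2_conditional` (both in `[0, 1]`, marginal <= conditional) and the
#'   variance components used.
#' @export
nakagawa_r2 <- function(fit, nb_resid = c("lognormal", "trigamma")) {
  nb_resid <- match.arg(nb_resid)
  var_f <- stats::var(fit$fixed_predictor)
  var_re <- sum(fit$re_variances)
  var_eps <- switch(fit$family,
    gaussian = fit$sigma2,
    negative_binomial = ,
    poisson = {
      lambda <- mean(fit$response)
      inv_theta <- if (fit$family == "poisson") 0 else 1 / fit$theta
      nu <- 1 / lambda + inv_theta
      if (nb_resid == "lognormal") log1p(nu) else trigamma(1 / nu)
    },
    stop("unsupported family: ", fit$family))
  denom <- var_f + var_re + var_eps
  if (denom <= 0) stop("zero total variance; R-squared undefined")
  structure(
    list(r2_marginal = var_f / denom,
         r2_conditional = (var_f + var_re) / denom,
         var_fixed = var_f, var_random = var_re, var_residual = var_eps),
    class = "r2_result"
  )
}

# ---- backward model selection -----------------------------------------------

.refit <- function(formula, data, family) {
  switch(family,
         gaussian = fit_lmm(formula, data),
         negative_binomial = fit_nb_glmm(formula, data),
         poisson = fit_poisson_glmm(formula, data))
}

# fixed-effect terms of a mixed formula
.fixed_terms <- function(formula) {
  attr(stats::terms(lme4::nobars(formula)), "term.labels")
}

# rebuild formula with the given fixed terms plus the original random parts
.rebuild_formula <- function(formula, fixed_terms) {
  bars <- lme4::findbars(formula)
  rhs <- c(if (length(fixed_terms)) fixed_terms else "1",
           vapply(bars, function(b) paste0("(", deparse(b), ")"), character(1)))
  stats::as.formula(paste(deparse(formula[[2]]), "~",
                          paste(rhs, collapse = " + ")),
                    env = environment(formula))
}

#' Backward model selection by likelihood-ratio tests
#'
#' Starting from the full fixed-effect structure, repeatedly drops the
#' single droppable term with the largest LRT p-value above `alpha`
#' (respecting marginality: terms inside retained interactions are never
#' dropped), refits, and stops when every remaining term is significant.
#' All comparisons use ML fits. The `protect` argument encodes substantive
#' retention rules, e.g. mass is retained whenever SMR remains in the model
#' to account for allometric scaling of metabolic rate.
#'
#' @param formula Full mixed-model formula.
#' @param data Data frame.
#' @param family `"gaussian"`, `"negative_binomial"` or `"poisson"`.
#' @param alpha Elimination threshold (default 0.05).
#' @param protect Named character vector: `protect["a"] = "b"` means term
#'   `a` is never dropped while term `b` is in the model. Default protects
#'   `log(mass)` while `log(smr)` remains.
#' @return List with `fit` (final `fit_result`) and `trace` (data frame of
#'   every test: step, dropped candidate, statistic, df, p, decision).
#' @export
select_model <- function(formula, data,
                         family = c("gaussian", "negative_binomial", "poisson"),
                         alpha = 0.05,
                         protect = c("log(mass)" = "log(smr)")) {
  family <- match.arg(family)
  current <- .refit(formula, data, family)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    terms_now <- .fixed_terms(current$formula)
    # marginality: droppable terms are those not contained in a higher term
    droppable <- terms_now[vapply(terms_now, function(tm) {
      others <- setdiff(terms_now, tm)
      f <- strsplit(tm, ":", fixed = TRUE)[[1]]
      !any(vapply(others, function(o)
        all(f %in% strsplit(o, ":", fixed = TRUE)[[1]]), logical(1)))
    }, logical(1))]
    # substantive protection rules
    droppable <- droppable[!vapply(droppable, function(tm) {
      tm %in% names(protect) && protect[[tm]] %in% terms_now
    }, logical(1))]
    if (length(droppable) == 0) break
    tests <- lapply(droppable, function(tm) {
      red_formula <- .rebuild_formula(current$formula, setdiff(terms_now, tm))
      red <- .refit(red_formula, data, family)
      lrt <- likelihood_ratio_test(current, red)
      list(term = tm, fit = red, lrt = lrt)
    })
    pvals <- vapply(tests, function(x) x$lrt$p_value, numeric(1))
    worst <- which.max(pvals)
    for (i in seq_along(tests))
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, candidate = tests[[i]]$term,
        statistic = tests[[i]]$lrt$statistic, df = tests[[i]]$lrt$df,
        p_value = tests[[i]]$lrt$p_value,
        dropped = i == worst && pvals[worst] > alpha,
        stringsAsFactors = FALSE)
    if (pvals[worst] <= alpha) break
    current <- tests[[worst]]$fit
  }
  list(fit = current,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(step = integer(), candidate = character(),
                    statistic = numeric(), df = integer(),
                    p_value = numeric(), dropped = logical()))
}

# ---- the study's model battery ----------------------------------------------

#' Model battery for the air-breathing study design
#'
#' The named model structures fitted to the tidy trial/fish dataset:
#' \describe{
#'   \item{smr}{log SMR ~ log mass + temperature, random intercepts for fish
#'     nested in group (Gaussian).}
#'   \item{group_abf}{group breath total ~ temperature + oxygen level +
#'     activity + cohesion, random intercept for group (negative binomial).}
#'   \item{cd}{coefficient of dispersion ~ temperature + oxygen level +
#'     activity + cohesion, random intercept for group (Gaussian).}
#'   \item{indiv_abf}{individual breath count ~ log mass, log SMR, oxygen
#'     level and temperature with all interactions, random intercepts for
#'     fish nested in group (negative binomial by default).}
#'   \item{activity}{mean speed ~ cohesion + temperature x oxygen level,
#'     random intercept for group (Gaussian).}
#'   \item{cohesion}{cohesion ~ speed + temperature x oxygen level, random
#'     intercept for group (Gaussian).}
#' }
#'
#' @param model One of `"smr"`, `"group_abf"`, `"cd"`, `"indiv_abf"`,
#'   `"activity"`, `"cohesion"`.
#' @param indiv_family Family for the individual-breaths model
#'   (`"negative_binomial"` default, `"poisson"` switch).
#' @return List with `formula`, `family`, and the `protect` rule for
#'   [select_model()].
#' @export
battery_spec <- function(model = c("smr", "group_abf", "cd", "indiv_abf",
                                   "activity", "cohesion"),
                         indiv_family = c("negative_binomial", "poisson")) {
  model <- match.arg(model)
  indiv_family <- match.arg(indiv_family)
  protect <- c("log(mass)" = "log(smr)")
  switch(model,
    smr = list(formula = log(smr) ~ log(mass) + temp + (1 | group / fish_id),
               family = "gaussian", protect = protect),
    group_abf = list(
      formula = abf_group ~ temp + o2 + speed + cohesion + (1 | group),
      family = "negative_binomial", protect = protect),
    cd = list(formula = cd ~ temp + o2 + speed + cohesion + (1 | group),
              family = "gaussian", protect = protect),
    indiv_abf = list(
      formula = abf ~ log(mass) * log(smr) * o2 * temp + (1 | group / fish_id),
      family = indiv_family, protect = protect),
    activity = list(formula = speed ~ cohesion + temp * o2 + (1 | group),
                    family = "gaussian", protect = protect),
    cohesion = list(formula = cohesion ~ speed + temp * o2 + (1 | group),
                    family = "gaussian", protect = protect))
}

#' Fit (and optionally select) one battery model
#'
#' @param model Battery model name, see [battery_spec()].
#' @param data Tidy dataset with the columns the model names (per-fish table
#'   for `smr` / `indiv_abf`, per-trial table otherwise).
#' @param select Run backward LRT elimination (default `TRUE`).
#' @param ... Passed to [battery_spec()].
#' @return List with `fit`, `r2` ([nakagawa_r2()]), and `trace` (empty if
#'   `select = FALSE`).
#' @export
fit_battery_model <- function(model, data, select = TRUE, ...) {
  spec <- battery_spec(model, ...)
  if (select) {
    sel <- select_model(spec$formula, data, family = spec$family,
                        protect = spec$protect)
    fit <- sel$fit; trace <- sel$trace
  } else {
    fit <- .refit(spec$formula, data, spec$family)
    trace <- NULL
  }
  list(fit = fit, r2 = nakagawa_r2(fit), trace = trace)
}

#' Tidy coefficient summary of a fit
#'
#' @param fit A `fit_result`.
#' @return Data frame `term`, `estimate`, `se`, `statistic`, `p_value`
#'   (p-values Wald-normal for GLMMs, absent for Gaussian t-statistics).
#' @export
summary_table <- function(fit) {
  co <- fit$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    statistic = co[, 3], row.names = NULL,
                    stringsAsFactors = FALSE)
  out$p_value <- if ("Pr(>|z|)" %in% colnames(co)) co[, "Pr(>|z|)"] else
    2 * stats::pnorm(abs(out$statistic), lower.tail = FALSE)
  out
}
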
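# the 64-row simulated dataset used throughout this file
glmm_data <- local({
  sim <- small_sim(seed = 42)
  est <- estimate_trials(sim$trials, sim$factors)
  est[est$kept, ]
})

test_that("with the random effect off, the fit matches plain binomial regression", {
  f0 <- fit_olre_binomial_glmm(glmm_data, olre = FALSE)
  g <- glm(cbind(eggs_m2, eggs_total - eggs_m2) ~ mating_order +
             factor(interval_h), data = glmm_data, family = binomial)
  expect_lt(max(abs(f0$coef - coef(g))), 1e-4)
  expect_lt(max(abs(f0$se - sqrt(diag(vcov(g))))), 1e-4)
  expect_equal(f0$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  expect_equal(f0$sigma_olre, 0)
})

test_that("an intercept-only fit with constant proportions recovers the logit of the proportion", {
  d <- data.frame(eggs_m2 = rep(30L, 12), eggs_total = rep(40L, 12))
  f <- fit_olre_binomial_glmm(d, fixed_terms = "1", olre = FALSE)
  expect_equal(unname(f$coef[1]), qlogis(0.75), tolerance = 1e-6)
})

test_that("quadrature log-likelihood is node-stable and exact at sigma zero", {
  X <- model.matrix(~ mating_order + factor(interval_h), glmm_data)
  y <- glmm_data$eggs_m2; n <- glmm_data$eggs_total
  beta <- c(0.1, 0.4, 0.8, 0.5)
  l31 <- olre_loglik(beta, log(0.5), X, y, n, 31)
  l201 <- olre_loglik(beta, log(0.5), X, y, n, 201)
  expect_lt(abs(l31 - l201), 1e-6)
  # sigma = 0 equals the plain binomial log-likelihood exactly
  expect_equal(olre_loglik(beta, -Inf, X, y, n),
               sum(dbinom(y, n, plogis(drop(X %*% beta)), log = TRUE)))
  # degenerate rows and bad node counts rejected
  expect_error(olre_loglik(beta, 0, X, y, rep(0L, length(n))), "positive")
  expect_error(olre_loglik(beta, 0, X, y, n, n_nodes = 10), "odd")
})

test_that("estimates, standard errors and sigma match an independent mixed-model fitter", {
  f <- fit_olre_binomial_glmm(glmm_data)
  d <- glmm_data
  d$obs <- factor(seq_len(nrow(d)))
  g <- lme4::glmer(cbind(eggs_m2, eggs_total - eggs_m2) ~ mating_order +
                     factor(interval_h) + (1 | obs),
                   data = d, family = binomial, nAGQ = 25)
  expect_lt(max(abs(f$coef - lme4::fixef(g))), 1e-3)
  expect_lt(max(abs(f$se - sqrt(diag(as.matrix(vcov(g)))))), 1e-3)
  expect_lt(abs(f$sigma_olre - sqrt(unlist(lme4::VarCorr(g)))), 1e-3)
  expect_true(f$converged)
  # AIC bookkeeping: 2k - 2 loglik with k estimated parameters
  expect_equal(f$aic, 2 * 5 - 2 * f$loglik)
  expect_true(isSymmetric(f$vcov, tol = 1e-8))
  expect_true(all(eigen(f$vcov, only.values = TRUE)$values > -1e-10))
})

test_that("a shared group intercept is recovered via the nested Laplace layer", {
  sim <- small_sim(seed = 13, n = 300, sigma_gen = 0.6, n_generations = 10)
  est <- estimate_trials(sim$trials, sim$factors)
  d <- est[est$kept, ]
  f <- fit_olre_binomial_glmm(d, shared_group = "generation")
  d$obs <- factor(seq_len(nrow(d)))
  g <- lme4::glmer(cbind(eggs_m2, eggs_total - eggs_m2) ~ mating_order +
                     factor(interval_h) + (1 | obs) + (1 | generation),
                   data = d, family = binomial)
  expect_lt(max(abs(f$coef - lme4::fixef(g))), 0.05)
  expect_lt(abs(f$sigma_group -
                  sqrt(unlist(lme4::VarCorr(g))["generation"])), 0.1)
  expect_gt(f$sigma_group, 0.1)
})

test_that("marginal means transform balanced one-factor coefficients directly", {
  set.seed(3)
  d <- data.frame(grp = rep(c("A", "B"), each = 20))
  eta <- 0.2 + 0.6 * (d$grp == "B") + rnorm(40, 0, 0.4)
  d$eggs_total <- rep(50L, 40)
  d$eggs_m2 <- rbinom(40, 50, plogis(eta))
  f <- fit_olre_binomial_glmm(d, fixed_terms = "grp")
  mm <- marginal_means(f, "grp")
  expect_equal(mm$means$estimate_link,
               unname(c(f$coef[1], f$coef[1] + f$coef[2])))
  expect_equal(mm$means$estimate_response,
               plogis(mm$means$estimate_link))
  expect_error(marginal_means(f, "absent"), "not in the model")
})

test_that("marginal means and Tukey contrasts match an independent post hoc oracle", {
  f <- fit_olre_binomial_glmm(glmm_data)
  mm <- marginal_means(f, "interval_h")
  d <- glmm_data
  d$obs <- factor(seq_len(nrow(d)))
  d$interval_h <- factor(d$interval_h)
  g <- lme4::glmer(cbind(eggs_m2, eggs_total - eggs_m2) ~ mating_order +
                     interval_h + (1 | obs), data = d, family = binomial,
                   nAGQ = 25)
  em <- summary(emmeans::emmeans(g, "interval_h"))
  expect_equal(mm$means$estimate_link, em$emmean, tolerance = 1e-3)
  expect_equal(mm$means$se_link, em$SE, tolerance = 1e-3)
  ec <- summary(emmeans::contrast(emmeans::emmeans(g, "interval_h"),
                                  "pairwise", adjust = "tukey"))
  expect_equal(abs(mm$contrasts$estimate), abs(ec$estimate),
               tolerance = 1e-3)
  expect_equal(mm$contrasts$p_adjusted, ec$p.value, tolerance = 2e-3)
})

test_that("Tukey adjustment never reduces a p value and is unity for identical levels", {
  f <- fit_olre_binomial_glmm(glmm_data)
  mm <- marginal_means(f, c("mating_order", "interval_h"))
  expect_true(all(mm$contrasts$p_adjusted >= mm$contrasts$p_raw - 1e-12))
  # two identical levels: beta = 0 by construction
  d <- data.frame(grp = rep(c("A", "B"), each = 30),
                  eggs_m2 = rep(c(20L, 25L, 30L), 20),
                  eggs_total = rep(50L, 60))
  f2 <- fit_olre_binomial_glmm(d, fixed_terms = "grp")
  mm2 <- marginal_means(f2, "grp")
  expect_gt(mm2$contrasts$p_adjusted, 0.95)
})

test_that("model comparison ranks fits by AIC with a two-unit window", {
  f1 <- fit_olre_binomial_glmm(glmm_data)
  f2 <- fit_olre_binomial_glmm(glmm_data, fixed_terms = "mating_order")
  cmp <- compare_aic(full = f1, reduced = f2)
  expect_equal(cmp$dAIC[1], 0)
  expect_true(cmp$competitive[1])
  expect_equal(sort(cmp$model), c("full", "reduced"))
})
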
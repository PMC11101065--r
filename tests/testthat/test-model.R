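test_that("single binary covariate recovers the contingency-table log odds ratio", {
  # counts: exposed 10 events / 5 non-events; unexposed 5 events / 10 non-events
  tab <- data.frame(
    x = c(rep(1, 15), rep(0, 15)),
    label = c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  )
  fit <- nomo_fit(label ~ x, tab)
  expect_equal(unname(coef(fit)["x"]), log(4), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("the fit recovers known generating coefficients on simulated features", {
  cfg <- sim_config(malignant = list(n = 8000L), benign = list(n = 8000L))
  feats <- simulate_feature_table(cfg, seed = 18)
  truth <- ref_beta()
  gen <- nomo_model(truth)
  set.seed(19)
  feats$label <- rbinom(nrow(feats), 1L,
                        predict(gen, feats, type = "response"))
  fit <- nomo_fit(label ~ avg_r + avg_b + entropy, feats)
  for (term in names(truth))
    expect_lt(abs(coef(fit)[term] - truth[term]), 2 * fit$se[term],
              label = paste("recovery of", term))
})

test_that("degenerate fits fail with informative errors", {
  tab <- simulate_feature_table(tiny_config(), seed = 20)
  one <- tab; one$label <- factor("malignant", levels = c("benign", "malignant"))
  expect_error(nomo_fit(label ~ avg_r, one), "single class")
  const <- tab; const$avg_r <- 7
  expect_error(nomo_fit(label ~ avg_r + entropy, const), "constant feature")
  sep <- data.frame(x = c(1:20, 41:60),
                    label = rep(c(0, 1), each = 20))
  expect_error(nomo_fit(label ~ x, sep), "separation")
})

test_that("variable selection screens out noise and keeps informative features", {
  cfg <- sim_config(malignant = list(n = 5000L), benign = list(n = 5000L))
  tab <- simulate_feature_table(cfg, seed = 21)
  set.seed(22)
  tab$noise <- rnorm(nrow(tab))
  sel <- select_variables(tab, c("avg_r", "avg_g", "avg_b", "entropy", "noise"))
  expect_false("noise" %in% sel$selected)
  expect_true(all(c("avg_r", "avg_b", "entropy") %in% sel$selected))
  expect_true(all(c("univariate", "backward") %in% sel$trace$stage) ||
                all(sel$trace$stage == "univariate"))
  # single strongly predictive candidate comes back unchanged
  solo <- select_variables(tab, "entropy")
  expect_identical(solo$selected, "entropy")
  # pure-noise-only candidate set survives as an empty selection, not an error
  expect_warning(none <- select_variables(tab, "noise"), "no candidate")
  expect_length(none$selected, 0L)
})

test_that("Wald table expands beta/SE into chi-square, OR and CI columns", {
  w <- wald_table(c("(Intercept)" = -47.265, avg_r = 0.226, entropy = 2.998),
                  se = c(6.657, 0.032, 0.201))
  r <- w[w$term == "avg_r", ]
  expect_equal(r$or, exp(0.226))
  expect_equal(r$wald_chisq, (0.226 / 0.032)^2)
  expect_equal(r$or_low, exp(0.226 - 1.959964 * 0.032))
  expect_true(is.na(w$or[w$term == "(Intercept)"]))
  # beta = 0: OR 1, CI symmetric about 1 on the log scale
  z <- wald_table(c(x = 0), se = c(0.5))
  expect_equal(z$or, 1)
  expect_equal(log(z$or_low), -log(z$or_high))
})

test_that("predicted probabilities follow the logistic form and coefficient signs", {
  m <- nomo_model(ref_beta(), ref_se())
  at_mal <- data.frame(avg_r = 219.969, avg_b = 220.340, entropy = 5.425)
  expect_equal(predict(m, at_mal), 0.93260, tolerance = 1e-4)
  expect_equal(predict(m, at_mal, type = "link"), 2.62732, tolerance = 1e-4)
  # monotone in each feature per its coefficient sign
  up_H <- at_mal; up_H$entropy <- 6
  expect_gt(predict(m, up_H), predict(m, at_mal))
  up_B <- at_mal; up_B$avg_b <- 230
  expect_lt(predict(m, up_B), predict(m, at_mal))
  up_R <- at_mal; up_R$avg_r <- 225
  expect_gt(predict(m, up_R), predict(m, at_mal))
  # sigmoid endpoints
  flat <- nomo_model(c("(Intercept)" = 0, x = 0))
  expect_equal(predict(flat, data.frame(x = 3)), 0.5)
  deep <- nomo_model(c("(Intercept)" = -20, x = 0))
  expect_lt(predict(deep, data.frame(x = 0)), 1e-8)
  expect_error(predict(m, data.frame(avg_r = 1)), "avg_b")
})

test_that("refitting on self-simulated labels reproduces the coefficients", {
  tab <- simulate_feature_table(sim_config(), seed = 23)
  fit <- nomo_fit(label ~ avg_r + avg_b + entropy, tab)
  sims <- simulate(fit, nsim = 1, seed = 24)
  tab$label2 <- sims$sim_1
  refit <- nomo_fit(label2 ~ avg_r + avg_b + entropy, tab)
  for (term in names(coef(fit)))
    expect_lt(abs(coef(refit)[term] - coef(fit)[term]), 2 * refit$se[term])
})

test_that("model accessors behave like standard fits", {
  tab <- simulate_feature_table(tiny_config(100L, 100L), seed = 25)
  fit <- nomo_fit(label ~ avg_r + entropy, tab)
  expect_identical(names(coef(fit)), c("(Intercept)", "avg_r", "entropy"))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  expect_length(residuals(fit), nrow(tab))
  s <- summary(fit)
  expect_s3_class(s, "summary.nomo_fit")
  expect_identical(s$wald$term, names(coef(fit)))
  expect_output(print(fit), "avg_r")
})
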
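test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(30)
  for (k in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)   # many ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_identical(roc_auc(scores, y)$auc, brute_auc(scores, y))
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  scores <- rnorm(300); y <- rbinom(300, 1, 0.3)
  a <- roc_auc(scores, y)$auc
  expect_identical(roc_auc(plogis(scores), y)$auc, a)
  expect_identical(roc_auc(3 * scores + 17, y)$auc, a)
})

test_that("the ROC curve is a valid monotone path from (0,0) to (1,1)", {
  set.seed(32)
  r <- roc_auc(rnorm(200), rbinom(200, 1, 0.5))
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (k in 1:5) {
    scores <- round(rnorm(150), 1); y <- rbinom(150, 1, 0.4)
    expect_equal(roc_auc(scores, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap AUC intervals are reproducible and sensible", {
  set.seed(34)
  scores <- c(rnorm(250, 1), rnorm(250)); y <- rep(c(1, 0), each = 250)
  a <- bootstrap_auc_ci(scores, y, B = 200, seed = 35)
  b <- bootstrap_auc_ci(scores, y, B = 200, seed = 35)
  expect_identical(a$ci, b$ci)
  expect_lt(a$ci[1], a$auc); expect_gt(a$ci[2], a$auc)
  # perfectly separated large sample: lower bound stays extreme
  sep <- bootstrap_auc_ci(c(rnorm(300, 10), rnorm(300)), rep(c(1, 0), each = 300),
                          B = 100, seed = 36)
  expect_gte(sep$ci[1], 0.99)
  # tiny B still defined
  expect_length(bootstrap_auc_ci(scores, y, B = 2, seed = 37)$ci, 2L)
})

test_that("bootstrap percentile CI brackets the sample AUC across simulations", {
  set.seed(38)
  hits <- 0L
  for (k in 1:200) {
    scores <- c(rnorm(250, 0.7), rnorm(250)); y <- rep(c(1, 0), each = 250)
    r <- bootstrap_auc_ci(scores, y, B = 200, seed = 3000 + k)
    hits <- hits + (r$ci[1] <= r$auc && r$auc <= r$ci[2])
  }
  expect_gte(hits / 200, 0.95)
})

test_that("Hosmer-Lemeshow matches the hand-computed worked table", {
  p <- (1:30) / 31
  y <- c(0,0,0, 0,1,0, 0,0,1, 0,1,0, 1,0,1, 0,1,1, 1,0,1, 1,1,0, 1,1,1, 1,1,1)
  hl <- hosmer_lemeshow(p, y, g = 10)
  expect_equal(hl$statistic, 2.5664757576, tolerance = 1e-8)
  expect_equal(hl$df, 8L)
  expect_equal(hl$p_value, 0.9585589366, tolerance = 1e-8)
  expect_equal(sum(hl$groups$n), 30L)
  # invariant to label-preserving row reordering
  o <- sample(30)
  expect_equal(hosmer_lemeshow(p[o], y[o], g = 10)$statistic, hl$statistic)
})

test_that("Hosmer-Lemeshow is near zero under exact calibration", {
  p <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  y <- unlist(lapply(seq(0.05, 0.95, by = 0.1),
                     function(q) rep(c(1, 0), c(round(20 * q), 20 - round(20 * q)))))
  hl <- hosmer_lemeshow(p, y, g = 10)
  expect_lt(hl$statistic, 1e-10)
  expect_gt(hl$p_value, 0.999)
  expect_error(hosmer_lemeshow(c(0, p[-1]), y), "strictly in")
})

test_that("calibration curves sit on the diagonal for calibrated simulations", {
  set.seed(39)
  n <- 50000
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, p)
  cal <- calibration_curve(p, y, bins = 10)
  expect_equal(nrow(cal), 10L)
  expect_lt(max(abs(cal$obs_frac - cal$mean_pred)), 0.02)
  # constant probabilities collapse to a single informative bin
  cal1 <- calibration_curve(rep(0.4, 50), rbinom(50, 1, 0.4))
  expect_equal(nrow(cal1), 1L)
  # degenerate perfect probabilities give the two corner points
  cal2 <- calibration_curve(rep(c(0.999999, 1e-6), 10), rep(c(1, 0), 10), bins = 2)
  expect_equal(cal2$obs_frac, c(0, 1), tolerance = 1e-5)
})

test_that("decision curves obey the closed-form identities", {
  # perfect predictor: NB equals prevalence at every threshold
  y <- rep(c(1, 0), c(30, 70))
  d <- decision_curve(as.numeric(y), y)
  expect_true(all(abs(d$nb_model - 0.3) < 1e-12))
  expect_true(all(d$nb_none == 0))
  # treat-all crosses zero exactly at the prevalence
  expect_equal(d$nb_all[d$threshold == 0.30], 0, tolerance = 1e-12)
  expect_true(all(d$nb_all[d$threshold < 0.3] > 0))
  expect_true(all(d$nb_all[d$threshold > 0.3] < 0))
  # NB never exceeds prevalence
  set.seed(40)
  p <- runif(200); yy <- rbinom(200, 1, p)
  d2 <- decision_curve(p, yy)
  expect_true(all(d2$nb_model <= mean(yy) + 1e-12))
})

test_that("decision curve matches the hand-computed 10-row example", {
  pr <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  yl <- c(1, 1, 1, 0, 1, 0, 0, 1, 0, 0)
  d <- decision_curve(pr, yl, thresholds = c(0.25, 0.5, 0.75))
  expect_equal(d$nb_model, c(0.3, 0.3, 0.2), tolerance = 1e-12)
  band <- decision_curve(pr, yl, thresholds = c(0.25, 0.5), B = 50, seed = 41)
  expect_true(all(band$nb_low <= band$nb_high))
})

test_that("evaluate_model assembles the full report", {
  tab <- simulate_feature_table(tiny_config(300L, 150L), seed = 42)
  fit <- nomo_fit(label ~ avg_r + avg_b + entropy, tab)
  ev <- evaluate_model(fit, tab, B = 50, seed = 43, dca_B = 20)
  expect_s3_class(ev, "nomo_evaluation")
  expect_true(ev$roc$auc > 0.5)
  expect_length(ev$roc$ci, 2L)
  expect_s3_class(ev$hl, "hl_result")
  expect_equal(sum(ev$calibration$n), nrow(tab))
  expect_true("nb_low" %in% names(ev$dca))
  expect_output(print(ev), "AUC")
})
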
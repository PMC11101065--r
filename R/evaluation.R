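#' ROC curve and Mann-Whitney AUC
#'
#' AUC in its tie-aware Mann-Whitney form: the probability that a random
#' malignant image scores above a random benign one, counting ties as 1/2,
#' computed from mid-ranks. The ROC curve is built by sweeping a threshold
#' over the unique score values; its trapezoidal area is cross-checked against
#' the rank form (they must agree to 1e-12). AUC is invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric risk scores (higher = more malignant).
#' @param labels Event labels: factor `benign`/`malignant`, logical, or 0/1.
#' @return Object of class `roc_result`: `auc`, data.frame `curve` with
#'   columns `fpr`, `tpr` (from (0,0) to (1,1), monotone nondecreasing), and
#'   class counts.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  y <- encode_label(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- as.numeric(sum(y == 1L)); n_neg <- as.numeric(sum(y == 0L))
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present (", n_pos, " malignant, ",
         n_neg, " benign)")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  last <- cumsum(rle(s)$lengths)           # one curve point per unique score
  tp <- c(0, cumsum(yy)[last])
  fp <- c(0, cumsum(1 - yy)[last])
  curve <- data.frame(fpr = fp / n_neg, tpr = tp / n_pos)
  # trapezoid in integer counts (exact in doubles): must equal the rank form
  trap <- sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1))) /
    (2 * n_pos * n_neg)
  stopifnot(abs(trap - auc) < 1e-12)
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d malignant vs %d benign)", x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$ci))
    cat(sprintf(", bootstrap 95%% CI (%.4f, %.4f), B = %d", x$ci[1L], x$ci[2L], x$B))
  cat("\n")
  invisible(x)
}

#' Bootstrap confidence interval for the AUC
#'
#' Case-resampling bootstrap: rows are resampled with replacement B times, the
#' AUC recomputed on each replicate, and the percentile 2.5%/97.5% bounds
#' reported (a normal-approximation interval is available via `type`).
#' Replicates that lose a class are redrawn, up to `100 * B` attempts.
#'
#' @inheritParams roc_auc
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (required: the interval is part of the record).
#' @param conf_level Confidence level (default 0.95).
#' @param type `"percentile"` (default) or `"normal"`.
#' @return `roc_result` with `ci` (lower, upper), `B`, `seed` and the
#'   replicate AUCs in `boot_auc`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 1000L, seed,
                             conf_level = 0.95, type = c("percentile", "normal")) {
  type <- match.arg(type)
  stopifnot(B >= 2L)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  y <- encode_label(labels)
  base <- roc_auc(scores, y)
  set.seed(as.integer(seed))
  n <- length(y)
  boot <- numeric(B)
  attempts <- 0L
  for (b in seq_len(B)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 100L * B)
        stop("bootstrap redraw limit exhausted: replicates keep losing a class")
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    r <- rank(scores[idx], ties.method = "average")
    yi <- y[idx]
    np <- as.numeric(sum(yi == 1L)); nn <- n - np
    boot[b] <- (sum(r[yi == 1L]) - np * (np + 1) / 2) / (np * nn)
  }
  a <- (1 - conf_level) / 2
  ci <- if (type == "percentile") {
    unname(stats::quantile(boot, c(a, 1 - a)))
  } else {
    base$auc + stats::qnorm(c(a, 1 - a)) * stats::sd(boot)
  }
  base$ci <- ci; base$B <- as.integer(B); base$seed <- as.integer(seed)
  base$boot_auc <- boot; base$ci_type <- type
  base
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: observations are split into `g` equal-frequency
#' groups by predicted probability (tied probabilities stay in one group), and
#' `chi^2 = sum_g [(O1 - E1)^2 / E1 + (O0 - E0)^2 / E0]` is referred to a
#' chi-square with `g - 2` degrees of freedom. Groups with a zero expected
#' cell are merged with their neighbour (with a warning).
#'
#' @param probs Predicted probabilities in (0, 1).
#' @param labels Event labels (see [roc_auc()]).
#' @param g Number of groups (default 10).
#' @return Object of class `hl_result`: `statistic`, `df`, `p_value`, and the
#'   per-group table (`n`, `observed`, `expected`, `mean_prob`).
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10L) {
  y <- encode_label(labels)
  stopifnot(length(probs) == length(y), length(y) >= g)
  if (any(probs <= 0 | probs >= 1)) stop("probabilities must lie strictly in (0, 1)")
  br <- unique(stats::quantile(probs, seq(0, 1, length.out = g + 1L)))
  grp <- if (length(br) > 2L)
    cut(probs, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(probs))
  tab <- data.frame(
    n = as.integer(tapply(y, grp, length)),
    observed = as.numeric(tapply(y, grp, sum)),
    expected = as.numeric(tapply(probs, grp, sum)),
    mean_prob = as.numeric(tapply(probs, grp, mean))
  )
  tab <- tab[order(tab$mean_prob), , drop = FALSE]
  # merge any group whose expected events or non-events hit zero
  repeat {
    bad <- which(tab$expected == 0 | (tab$n - tab$expected) == 0)
    if (!length(bad) || nrow(tab) == 1L) break
    i <- bad[1L]
    j <- if (i == 1L) 2L else i - 1L
    warning("merging Hosmer-Lemeshow group with empty expected cell")
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab$mean_prob[j] <- tab$expected[j] / tab$n[j]
    tab <- tab[-i, , drop = FALSE]
  }
  chi2 <- sum((tab$observed - tab$expected)^2 / tab$expected +
                ((tab$n - tab$observed) - (tab$n - tab$expected))^2 /
                (tab$n - tab$expected))
  df <- nrow(tab) - 2L
  structure(list(statistic = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 groups = tab, g = nrow(tab)),
            class = "hl_result")
}

#' @export
print.hl_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi^2 = %.3f, df = %d, p = %.3f (%d groups)\n",
              x$statistic, x$df, x$p_value, x$g))
  invisible(x)
}

#' Calibration curve
#'
#' Equal-frequency binning of predicted probabilities; each bin contributes
#' one point (mean predicted probability, observed event fraction). Points on
#' the diagonal indicate a well-calibrated model.
#'
#' @inheritParams hosmer_lemeshow
#' @param bins Number of equal-frequency bins (default 10).
#' @return data.frame of class `calibration_curve`: `bin`, `n`, `mean_pred`,
#'   `obs_frac`.
#' @export
calibration_curve <- function(probs, labels, bins = 10L) {
  y <- encode_label(labels)
  stopifnot(length(probs) == length(y))
  br <- unique(stats::quantile(probs, seq(0, 1, length.out = bins + 1L)))
  grp <- if (length(br) > 2L)
    cut(probs, breaks = br, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(probs))
  out <- data.frame(
    bin = sort(unique(grp)),
    n = as.integer(tapply(y, grp, length)),
    mean_pred = as.numeric(tapply(probs, grp, mean)),
    obs_frac = as.numeric(tapply(y, grp, mean))
  )
  rownames(out) <- NULL
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' @export
plot.calibration_curve <- function(x, ...) {
  graphics::plot(x$mean_pred, x$obs_frac, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Mean predicted probability",
                 ylab = "Observed malignant fraction",
                 main = "Calibration curve", pch = 19, type = "b", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of treating at threshold probability `p_t`:
#' `NB_model = TP/N - (FP/N) * p_t / (1 - p_t)` where a case is called
#' positive when its predicted probability is at least `p_t`; compared against
#' treat-all (`NB_all = pi - (1 - pi) * p_t / (1 - p_t)`, `pi` the prevalence)
#' and treat-none (identically 0). An optional case-resampling bootstrap adds
#' a percentile 95% band around the model curve.
#'
#' @inheritParams hosmer_lemeshow
#' @param thresholds Threshold grid in (0, 1); default 0.01 to 0.99 by 0.01.
#' @param B Bootstrap replicates for the band (0 = no band).
#' @param seed Integer seed (required when `B > 0`).
#' @return data.frame of class `dca_curve`: `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`, and `nb_low`/`nb_high` when a band was requested; prevalence
#'   in attribute `prevalence`.
#' @export
decision_curve <- function(probs, labels, thresholds = seq(0.01, 0.99, by = 0.01),
                           B = 0L, seed = NULL) {
  y <- encode_label(labels)
  stopifnot(length(probs) == length(y))
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly in (0, 1)")
  n <- length(y); prev <- mean(y)
  nb_model <- function(p, yy, t) {
    pos <- p >= t
    (sum(pos & yy == 1L) - sum(pos & yy == 0L) * t / (1 - t)) / length(yy)
  }
  out <- data.frame(
    threshold = thresholds,
    nb_model = vapply(thresholds, function(t) nb_model(probs, y, t), numeric(1L)),
    nb_all = prev - (1 - prev) * thresholds / (1 - thresholds),
    nb_none = 0
  )
  if (B > 0L) {
    if (is.null(seed)) stop("a seed is required for the bootstrap band")
    set.seed(as.integer(seed))
    reps <- matrix(NA_real_, nrow = B, ncol = length(thresholds))
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      reps[b, ] <- vapply(thresholds,
                          function(t) nb_model(probs[idx], y[idx], t),
                          numeric(1L))
    }
    out$nb_low <- apply(reps, 2L, stats::quantile, probs = 0.025)
    out$nb_high <- apply(reps, 2L, stats::quantile, probs = 0.975)
  }
  attr(out, "prevalence") <- prev
  class(out) <- c("dca_curve", "data.frame")
  out
}

#' @export
plot.dca_curve <- function(x, ...) {
  prev <- attr(x, "prevalence")
  graphics::plot(x$threshold, x$nb_model, type = "l", lwd = 2,
                 ylim = c(min(-0.05, min(x$nb_model)), prev * 1.1),
                 xlab = "Threshold probability",
                 ylab = "Net benefit", main = "Decision curve analysis", ...)
  graphics::lines(x$threshold, x$nb_all, col = "grey40", lty = 2)
  graphics::abline(h = 0, col = "grey70")
  if (!is.null(x$nb_low)) {
    graphics::lines(x$threshold, x$nb_low, lty = 3)
    graphics::lines(x$threshold, x$nb_high, lty = 3)
  }
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 1), lwd = c(2, 1, 1),
                   col = c("black", "grey40", "grey70"), bty = "n")
  invisible(x)
}

#' Full discrimination / calibration / utility report
#'
#' Applies the whole evaluation stack to a fitted classifier on one dataset:
#' ROC with bootstrap AUC CI, Hosmer-Lemeshow test, calibration curve, and
#' decision-curve analysis.
#'
#' @param model A [nomo_fit()] (or [nomo_model()]).
#' @param data Feature table containing the model features and a `label`
#'   column.
#' @param label Response column name.
#' @param B Bootstrap replicates for the AUC CI (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param g Hosmer-Lemeshow group count.
#' @param thresholds DCA threshold grid.
#' @param dca_B Bootstrap replicates for the DCA band (default 0).
#' @return Object of class `nomo_evaluation`: `roc`, `hl`, `calibration`,
#'   `dca`, `n`, `prevalence`.
#' @export
evaluate_model <- function(model, data, label = "label", B = 1000L, seed,
                           g = 10L, thresholds = seq(0.01, 0.99, by = 0.01),
                           dca_B = 0L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  probs <- predict(model, data, type = "response")
  y <- encode_label(data[[label]])
  structure(list(
    roc = bootstrap_auc_ci(probs, y, B = B, seed = seed),
    hl = hosmer_lemeshow(probs, y, g = g),
    calibration = calibration_curve(probs, y, bins = g),
    dca = decision_curve(probs, y, thresholds = thresholds, B = dca_B,
                         seed = if (dca_B > 0L) seed else NULL),
    n = length(y), prevalence = mean(y), seed = as.integer(seed)
  ), class = "nomo_evaluation")
}

#' @export
print.nomo_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation on n = %d (prevalence %.3f)\n", x$n, x$prevalence))
  print(x$roc); print(x$hl)
  invisible(x)
}

#' @export
plot.nomo_evaluation <- function(x, which = c("roc", "calibration", "dca"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    graphics::plot(x$roc$curve$fpr, x$roc$curve$tpr, type = "l", lwd = 2,
                   xlab = "False positive rate", ylab = "True positive rate",
                   main = sprintf("ROC (AUC = %.3f)", x$roc$auc), ...)
    graphics::abline(0, 1, lty = 2, col = "grey50")
  } else if (which == "calibration") {
    plot(x$calibration, ...)
  } else {
    plot(x$dca, ...)
  }
  invisible(x)
}
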
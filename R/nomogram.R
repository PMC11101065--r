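#' Express a logistic model as a points-scale nomogram
#'
#' Maps each model feature to a 0-100 points axis: with `M` the largest
#' coefficient-weighted range `|beta_v| * (hi_v - lo_v)` across features,
#' `points_v(x) = 100 * beta_v * (x - x_ref_v) / M`, where the reference value
#' `x_ref_v` is the low-risk end of the feature's range (the lower end for a
#' positive coefficient, the upper end for a negative one), so every axis
#' starts at 0 and the dominant feature spans exactly 0-100. Total points map
#' back to predicted probability through the linear predictor, so nomogram
#' scoring is algebraically identical to [predict.nomo_fit()].
#'
#' @param model A converged [nomo_fit()].
#' @param ranges Optional 2 x p matrix (rows = min/max, columns named by
#'   feature). Defaults to the ranges observed in the training data.
#' @return Object of class `nomogram_spec`: per-feature `beta`, `ranges`,
#'   `x_ref`, points-per-unit slopes, the scale factor `M`, and the intercept
#'   information needed for the total-points-to-probability map.
#' @examples
#' tab <- simulate_feature_table(sim_config(), seed = 1)
#' fit <- nomo_fit(label ~ avg_r + avg_b + entropy, tab)
#' nom <- build_nomogram(fit)
#' total_points(nom, tab[1:3, ])
#' @export
build_nomogram <- function(model, ranges = NULL) {
  stopifnot(inherits(model, "nomo_fit"))
  if (!isTRUE(model$converged)) stop("model did not converge")
  if (is.null(ranges)) ranges <- model$ranges
  if (is.null(ranges))
    stop("no feature ranges available; supply `ranges` (2 x p matrix)")
  ranges <- as.matrix(ranges)[, model$features, drop = FALSE]
  beta <- model$coefficients[model$features]
  width <- ranges[2L, ] - ranges[1L, ]
  if (any(width == 0))
    warning("zero-width range for ",
            paste(model$features[width == 0], collapse = ", "),
            ": flat 0-point axis")
  M <- max(abs(beta) * width)
  if (M == 0) stop("all features have zero coefficient or zero-width range")
  x_ref <- ifelse(beta >= 0, ranges[1L, ], ranges[2L, ])
  structure(list(
    features = model$features, beta = beta, ranges = ranges, x_ref = x_ref,
    scale = M,
    intercept = unname(model$coefficients["(Intercept)"]),
    ref_offset = sum(beta * x_ref)      # lp = intercept + ref_offset + M/100 * T
  ), class = "nomogram_spec")
}

#' Per-feature nomogram points
#'
#' @param spec A [build_nomogram()] result.
#' @param newdata data.frame with the model features.
#' @return Matrix of points (rows = observations, columns = features), each
#'   column in \[0, 100\] for in-range values.
#' @export
nomogram_points <- function(spec, newdata) {
  stopifnot(inherits(spec, "nomogram_spec"))
  missing <- setdiff(spec$features, names(newdata))
  if (length(missing))
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(newdata[spec$features])
  pts <- sweep(X, 2L, spec$x_ref, `-`)
  pts <- sweep(pts, 2L, spec$beta, `*`) * 100 / spec$scale
  colnames(pts) <- spec$features
  pts
}

#' Total nomogram points
#'
#' @inheritParams nomogram_points
#' @return Numeric vector of total points.
#' @export
total_points <- function(spec, newdata) {
  rowSums(nomogram_points(spec, newdata))
}

#' Map total points to predicted probability
#'
#' Inverts the points scaling back to the linear predictor:
#' `p = plogis(intercept + ref_offset + scale/100 * total)`. Monotone
#' increasing in total points.
#'
#' @param spec A `nomogram_spec`.
#' @param total Numeric vector of total points.
#' @return Probabilities in (0, 1).
#' @export
points_to_prob <- function(spec, total) {
  stats::plogis(spec$intercept + spec$ref_offset + spec$scale / 100 * total)
}

#' Score observations through the nomogram
#'
#' Convenience wrapper: per-feature points, summed, mapped to probability.
#' Pointwise equal to direct logistic scoring.
#'
#' @inheritParams nomogram_points
#' @return Probabilities in (0, 1).
#' @export
score_via_nomogram <- function(spec, newdata) {
  points_to_prob(spec, total_points(spec, newdata))
}

#' @export
print.nomogram_spec <- function(x, ...) {
  cat("Nomogram (points scale 0-100)\n")
  span <- abs(x$beta) * (x$ranges[2L, ] - x$ranges[1L, ]) * 100 / x$scale
  for (i in seq_along(x$features)) {
    cat(sprintf("  %-10s beta %+.4f, range [%.3f, %.3f], max points %.1f\n",
                x$features[i], x$beta[i], x$ranges[1L, i], x$ranges[2L, i],
                span[i]))
  }
  invisible(x)
}

#' Draw the nomogram
#'
#' Base-graphics rendering: one horizontal value axis per feature placed under
#' a shared 0-100 points ruler, then a total-points axis and its predicted
#' probability axis.
#'
#' @param x A `nomogram_spec`.
#' @param n_ticks Ticks per feature axis.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nomogram_spec <- function(x, n_ticks = 6L, ...) {
  p <- length(x$features)
  rows <- p + 3L                                # points ruler + features + total + prob
  graphics::plot(NULL, xlim = c(-0.28, 1), ylim = c(0.5, rows + 0.5),
                 axes = FALSE, xlab = "", ylab = "", main = "Nomogram", ...)
  axis_row <- function(row, label, at, labels) {
    graphics::segments(min(at), row, max(at), row)
    graphics::segments(at, row - 0.08, at, row + 0.08)
    graphics::text(at, row + 0.25, labels, cex = 0.7)
    graphics::text(-0.28, row, label, adj = 0, cex = 0.8)
  }
  axis_row(rows, "Points", seq(0, 1, 0.1), seq(0, 100, 10))
  span <- abs(x$beta) * (x$ranges[2L, ] - x$ranges[1L, ]) / x$scale
  for (i in seq_len(p)) {
    vals <- pretty(x$ranges[, i], n = n_ticks)
    vals <- vals[vals >= x$ranges[1L, i] & vals <= x$ranges[2L, i]]
    pos <- x$beta[i] * (vals - x$x_ref[i]) / x$scale
    axis_row(rows - i, x$features[i], pos, format(vals, digits = 4))
  }
  t_max <- sum(span) * 100
  t_at <- pretty(c(0, t_max), n = 8L)
  axis_row(2L, "Total points", t_at / t_max, t_at)
  probs <- c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99)
  t_for_p <- (stats::qlogis(probs) - x$intercept - x$ref_offset) * 100 / x$scale
  keep <- t_for_p >= 0 & t_for_p <= t_max
  if (any(keep))
    axis_row(1L, "P(malignant)", t_for_p[keep] / t_max, probs[keep])
  invisible(x)
}
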
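#' Per-group summary statistics of a feature table
#'
#' Sample mean and sample SD (n-1 denominator) of each feature within each
#' level of the grouping column, the `mean +/- sd` summaries the univariate
#' comparisons are built from.
#'
#' @param table Feature table data.frame.
#' @param group_key Name of the grouping column (default `"label"`).
#' @param features Feature columns to summarise (default the four image
#'   features present in `table`).
#' @return data.frame with columns `feature`, `group`, `n`, `mean`, `sd`.
#'   `sd` is `NA` for single-row groups.
#' @export
summarize_groups <- function(table, group_key = "label",
                             features = intersect(feature_names(), names(table))) {
  stopifnot(is.data.frame(table), group_key %in% names(table))
  g <- factor(table[[group_key]])
  if (nlevels(g) < 1L) stop("no groups present")
  out <- expand.grid(feature = features, group = levels(g),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$mean <- NA_real_; out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- table[[out$feature[i]]][g == out$group[i]]
    out$n[i] <- length(x)
    out$mean[i] <- mean(x)
    out$sd[i] <- if (length(x) >= 2L) stats::sd(x) else NA_real_
  }
  out
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's equal-variance t computed from group sizes, means and SDs alone:
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))` with pooled variance
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`. The sign follows the argument order: group 1 minus
#' group 2. A Welch (unequal-variance) variant is available via
#' `var_equal = FALSE`.
#'
#' @param n1,m1,s1 Size, mean and SD of the first group.
#' @param n2,m2,s2 Size, mean and SD of the second group.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE).
#' @return List of class `pooled_t` with `statistic`, `df`, `p_value` and a
#'   `sign_convention` string ("group1 - group2").
#' @examples
#' pooled_t_from_summary(509, 226.308, 6.265, 2214, 219.969, 5.137)$statistic
#' @export
pooled_t_from_summary <- function(n1, m1, s1, n2, m2, s2, var_equal = TRUE) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    if (m1 != m2) stop("both SDs are zero with unequal means: t is infinite")
    t <- 0; df <- n1 + n2 - 2
  } else if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  structure(list(statistic = t, df = df,
                 p_value = 2 * stats::pt(-abs(t), df),
                 sign_convention = "group1 - group2",
                 var_equal = var_equal),
            class = "pooled_t")
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("%s two-sample t = %.4f, df = %.1f, p = %.4g (%s)\n",
              if (x$var_equal) "Pooled" else "Welch",
              x$statistic, x$df, x$p_value, x$sign_convention))
  invisible(x)
}

#' Pooled two-sample t-test from raw rows
#'
#' Identical to [pooled_t_from_summary()] but computed from a feature table;
#' the two paths agree to machine precision.
#'
#' @param table Feature table data.frame.
#' @param feature Feature column to test.
#' @param group_key Grouping column (two levels required).
#' @param order Optional character vector of the two group levels; the first
#'   named group is "group 1" in the sign convention. Defaults to factor
#'   level order.
#' @inheritParams pooled_t_from_summary
#' @return A `pooled_t`, with `sign_convention` naming the groups.
#' @export
pooled_t_from_data <- function(table, feature, group_key = "label",
                               order = NULL, var_equal = TRUE) {
  stopifnot(feature %in% names(table), group_key %in% names(table))
  g <- factor(table[[group_key]])
  lev <- if (is.null(order)) levels(g) else order
  if (length(lev) != 2L || !all(lev %in% levels(g)))
    stop("need exactly two groups; observed levels: ",
         paste(levels(g), collapse = ", "))
  x1 <- table[[feature]][g == lev[1L]]
  x2 <- table[[feature]][g == lev[2L]]
  out <- pooled_t_from_summary(length(x1), mean(x1), stats::sd(x1),
                               length(x2), mean(x2), stats::sd(x2),
                               var_equal = var_equal)
  out$sign_convention <- paste(lev[1L], "-", lev[2L])
  out
}

#' Univariate comparison table
#'
#' Runs [pooled_t_from_data()] for every feature, producing the group-summary
#' plus t/p table the cohort comparisons are reported in.
#'
#' @inheritParams pooled_t_from_data
#' @param features Feature columns to compare.
#' @return data.frame: `feature`, per-group `n`/`mean`/`sd`, `t`, `df`, `p`.
#' @export
compare_groups <- function(table, group_key = "label", order = NULL,
                           features = intersect(feature_names(), names(table)),
                           var_equal = TRUE) {
  g <- factor(table[[group_key]])
  lev <- if (is.null(order)) levels(g) else order
  rows <- lapply(features, function(f) {
    tt <- pooled_t_from_data(table, f, group_key, order = lev,
                             var_equal = var_equal)
    x1 <- table[[f]][g == lev[1L]]; x2 <- table[[f]][g == lev[2L]]
    data.frame(feature = f,
               group1 = lev[1L], n1 = length(x1), mean1 = mean(x1),
               sd1 = stats::sd(x1),
               group2 = lev[2L], n2 = length(x2), mean2 = mean(x2),
               sd2 = stats::sd(x2),
               t = tt$statistic, df = tt$df, p = tt$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Random 7:3 train/validation split
#'
#' Simple (non-stratified) random partition. The validation set receives
#' `floor(validation_fraction * N)` rows -- the rule under which a cohort of
#' 2,723 images yields 1,907 training and 816 validation images at the default
#' 0.3 fraction -- and the training set the remainder.
#'
#' @param table Feature table (or any data.frame).
#' @param validation_fraction Fraction held out, in (0, 1). Default 0.3.
#' @param seed Integer seed, required for reproducibility.
#' @return List of class `split_result`: integer row indices `training` and
#'   `validation`, plus `fraction` and `seed`.
#' @examples
#' s <- split_dataset(data.frame(x = 1:10), seed = 1)
#' lengths(s[c("training", "validation")])  # 7 and 3
#' @export
split_dataset <- function(table, validation_fraction = 0.3, seed) {
  n <- nrow(table)
  stopifnot(n >= 2L)
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie strictly between 0 and 1")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  n_val <- floor(validation_fraction * n)
  val <- sort(sample.int(n, n_val))
  structure(list(training = setdiff(seq_len(n), val), validation = val,
                 fraction = validation_fraction, seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Random split (seed %d): %d training / %d validation (%.0f:%.0f)\n",
              x$seed, length(x$training), length(x$validation),
              100 * (1 - x$fraction), 100 * x$fraction))
  invisible(x)
}
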
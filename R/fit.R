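#' Fit the logistic benign/malignant classifier
#'
#' Maximum-likelihood logistic regression of malignancy on image features,
#' fitted by iteratively reweighted least squares with standard errors from the
#' inverse observed Fisher information. Malignant is coded 1 and benign 0, so a
#' positive coefficient means the feature raises the odds of malignancy.
#'
#' With `select = TRUE` the model first screens each candidate in a univariate
#' logistic fit at level `alpha`, then backward-eliminates multivariable Wald
#' p-values `>= alpha`; the elimination trace is kept in the returned object
#' (`$selection`) so the path from candidates to final model is auditable.
#'
#' @param formula Model formula, e.g. `label ~ avg_r + avg_b + entropy`. The
#'   response may be a factor with levels `benign`/`malignant` (second level =
#'   event), a logical, or a 0/1 numeric.
#' @param data Feature table data.frame.
#' @param select Run univariate screen + backward elimination (default FALSE).
#' @param alpha Significance level for selection (default 0.05).
#' @param epsilon,maxit IRLS convergence tolerance on the relative deviance
#'   change and iteration cap.
#' @return Object of class `nomo_fit`: coefficients, standard errors,
#'   coefficient covariance, convergence flag and iteration count, observed
#'   feature ranges, the underlying `glm` fit, and the selection trace if any.
#' @examples
#' tab <- simulate_feature_table(sim_config(), seed = 1)
#' fit <- nomo_fit(label ~ avg_r + avg_b + entropy, tab)
#' coef(fit)
#' @seealso [summary.nomo_fit()] for the Wald/odds-ratio table,
#'   [build_nomogram()] for the points-scale presentation.
#' @export
nomo_fit <- function(formula, data, select = FALSE, alpha = 0.05,
                     epsilon = 1e-10, maxit = 100L) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  mf <- stats::model.frame(formula, data)
  y <- encode_label(stats::model.response(mf))
  features <- attr(stats::terms(mf), "term.labels")
  if (length(unique(y)) < 2L)
    stop("response has a single class; the model is not identifiable")
  const <- features[vapply(features, function(f) stats::var(mf[[f]]) == 0,
                           logical(1L))]
  if (length(const))
    stop("constant feature(s): ", paste(const, collapse = ", "))

  selection <- NULL
  if (select) {
    selection <- select_variables(data, features, label = all.vars(formula)[1L],
                                  alpha = alpha, epsilon = epsilon,
                                  maxit = maxit)
    features <- selection$selected
    if (!length(features)) {
      warning("no candidate survived selection; returning the empty selection")
      return(structure(list(coefficients = numeric(), selection = selection,
                            converged = NA, features = character()),
                       class = "nomo_fit"))
    }
    formula <- stats::reformulate(features, response = all.vars(formula)[1L])
  }

  dat <- data
  dat[[".y"]] <- encode_label(dat[[all.vars(formula)[1L]]])
  fml <- stats::reformulate(features, response = ".y")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  V <- stats::vcov(fit)
  se <- sqrt(diag(V))
  if (!fit$converged)
    stop("IRLS did not converge in ", maxit, " iterations",
         if (sep_warn) " (fitted probabilities of 0/1 suggest perfect separation)")
  if (sep_warn && any(se > 100))
    stop("perfect (or quasi-perfect) separation: standard errors diverge (max SE ",
         signif(max(se), 3), ")")

  structure(list(
    coefficients = stats::coef(fit),
    se = se,
    vcov = V,
    converged = fit$converged,
    iterations = fit$iter,
    features = features,
    ranges = vapply(features, function(f) range(dat[[f]]), numeric(2L)),
    n = nrow(dat),
    n_events = sum(dat$.y),
    glm = fit,
    selection = selection,
    call = match.call()
  ), class = "nomo_fit")
}

encode_label <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) > 2L) stop("response has more than two levels")
    if (all(c("benign", "malignant") %in% levels(y)))
      return(as.integer(y == "malignant"))
    return(as.integer(y) - 1L)
  }
  if (is.character(y)) return(encode_label(factor(y, levels = c("benign", "malignant"))))
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1))) stop("numeric response must be 0/1")
  as.integer(y)
}

#' Construct a logistic scorer from fixed coefficients
#'
#' Builds a `nomo_fit`-shaped object directly from known coefficients (and
#' optionally their standard errors), so an externally reported model -- such
#' as the bundled reference coefficients -- can be used for prediction,
#' nomogram construction and evaluation without refitting.
#'
#' @param beta Named numeric vector including `(Intercept)`.
#' @param se Optional named standard errors (same names).
#' @param ranges Optional 2 x p matrix of feature ranges (rows min/max) used
#'   for nomogram axes.
#' @return A `nomo_fit` with `glm = NULL`.
#' @examples
#' ref <- reference_cohort()$coefficients
#' m <- nomo_model(stats::setNames(ref$beta, ref$term),
#'                 stats::setNames(ref$se, ref$term))
#' predict(m, data.frame(avg_r = 219.969, avg_b = 220.340, entropy = 5.425))
#' @export
nomo_model <- function(beta, se = NULL, ranges = NULL) {
  stopifnot(is.numeric(beta), "(Intercept)" %in% names(beta))
  features <- setdiff(names(beta), "(Intercept)")
  if (!is.null(se)) se <- se[names(beta)]
  structure(list(
    coefficients = beta[c("(Intercept)", features)],
    se = se, vcov = NULL, converged = TRUE, iterations = 0L,
    features = features, ranges = ranges,
    n = NA_integer_, n_events = NA_integer_, glm = NULL, selection = NULL,
    call = match.call()
  ), class = "nomo_fit")
}

#' Univariate screen and backward elimination
#'
#' Stage 1 fits each candidate alone against the label and keeps those with
#' Wald p < `alpha`. Stage 2 fits the survivors jointly and repeatedly drops
#' the feature with the largest multivariable Wald p >= `alpha`, refitting
#' until all remaining p-values clear `alpha`. Every step is recorded.
#'
#' @param table Feature table.
#' @param candidates Candidate feature column names.
#' @param label Response column name (default `"label"`).
#' @param alpha Significance level (default 0.05).
#' @param epsilon,maxit Passed to the logistic fits.
#' @return List of class `variable_selection`: `selected` (character vector,
#'   possibly empty, with a warning) and `trace` (data.frame of `step`,
#'   `stage`, `feature`, `p`, `action`).
#' @export
select_variables <- function(table, candidates, label = "label", alpha = 0.05,
                             epsilon = 1e-10, maxit = 100L) {
  stopifnot(all(candidates %in% names(table)))
  dat <- table
  dat[[".y"]] <- encode_label(dat[[label]])
  wald_p <- function(features) {
    f <- stats::glm(stats::reformulate(features, ".y"), data = dat,
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = epsilon, maxit = maxit))
    z <- stats::coef(f) / sqrt(diag(stats::vcov(f)))
    stats::pchisq(z^2, df = 1L, lower.tail = FALSE)[features]
  }
  trace <- list(); step <- 0L
  keep <- character()
  for (f in candidates) {
    p <- suppressWarnings(wald_p(f))
    step <- step + 1L
    act <- if (p < alpha) "keep" else "drop"
    trace[[step]] <- data.frame(step = step, stage = "univariate", feature = f,
                                p = unname(p), action = act,
                                stringsAsFactors = FALSE)
    if (act == "keep") keep <- c(keep, f)
  }
  while (length(keep) > 1L) {
    p <- suppressWarnings(wald_p(keep))
    if (max(p) < alpha) break
    worst <- names(which.max(p))
    step <- step + 1L
    trace[[step]] <- data.frame(step = step, stage = "backward", feature = worst,
                                p = unname(max(p)), action = "drop",
                                stringsAsFactors = FALSE)
    keep <- setdiff(keep, worst)
  }
  if (length(keep) == 1L) {
    p <- suppressWarnings(wald_p(keep))
    if (p >= alpha) {
      step <- step + 1L
      trace[[step]] <- data.frame(step = step, stage = "backward", feature = keep,
                                  p = unname(p), action = "drop",
                                  stringsAsFactors = FALSE)
      keep <- character()
    }
  }
  if (!length(keep)) warning("no candidate survived selection")
  structure(list(selected = keep, trace = do.call(rbind, trace), alpha = alpha),
            class = "variable_selection")
}

#' @export
print.variable_selection <- function(x, ...) {
  cat("Variable selection (alpha =", x$alpha, ")\n")
  print(x$trace, row.names = FALSE)
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Wald statistics, odds ratios and confidence intervals
#'
#' For each term: Wald chi-square `(beta/SE)^2` with its 1-df upper-tail
#' p-value, odds ratio `exp(beta)`, and 95% CI `exp(beta +/- 1.959964 * SE)`.
#' The default method takes raw coefficient and SE vectors, so a published
#' coefficient table can be expanded without access to the fit.
#'
#' @param object A `nomo_fit`, or a named numeric vector of coefficients.
#' @param se Standard errors (default method only).
#' @param conf_level Confidence level (default 0.95).
#' @param ... Unused.
#' @return data.frame: `term`, `beta`, `se`, `wald_chisq`, `p`, `or`,
#'   `or_low`, `or_high` (odds-ratio columns `NA` for the intercept).
#' @examples
#' wald_table(c(avg_r = 0.226, entropy = 2.998), se = c(0.032, 0.201))
#' @export
wald_table <- function(object, ...) UseMethod("wald_table")

#' @rdname wald_table
#' @export
wald_table.nomo_fit <- function(object, conf_level = 0.95, ...) {
  if (is.null(object$se))
    stop("model has no standard errors (fixed-coefficient scorer)")
  if (!isTRUE(object$converged)) stop("model did not converge")
  wald_table.default(object$coefficients, object$se, conf_level = conf_level)
}

#' @rdname wald_table
#' @export
wald_table.default <- function(object, se, conf_level = 0.95, ...) {
  stopifnot(is.numeric(object), is.numeric(se), length(object) == length(se))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)   # 1.959964 at 95%
  chisq <- (object / se)^2
  out <- data.frame(
    term = if (is.null(names(object))) paste0("x", seq_along(object)) else names(object),
    beta = as.numeric(object), se = as.numeric(se),
    wald_chisq = as.numeric(chisq),
    p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
    or = exp(as.numeric(object)),
    or_low = exp(object - z * se), or_high = exp(object + z * se),
    stringsAsFactors = FALSE
  )
  is_int <- out$term == "(Intercept)"
  out[is_int, c("or", "or_low", "or_high")] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Predicted probability of malignancy
#'
#' `p = 1 / (1 + exp(-(b0 + b'x)))` from the model's coefficients. Increases
#' with features carrying positive coefficients (entropy, mean red) and
#' decreases with negative ones (mean blue) under the reference model's signs.
#'
#' @param object A `nomo_fit`.
#' @param newdata data.frame containing every model feature; defaults to the
#'   training data when the model was fitted here.
#' @param type `"response"` (probability, default) or `"link"` (linear
#'   predictor, log-odds).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.nomo_fit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$glm)) stop("newdata is required for a fixed-coefficient model")
    return(stats::predict(object$glm, type = type))
  }
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("newdata lacks model feature(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(newdata[object$features])
  lp <- drop(object$coefficients["(Intercept)"] +
               X %*% object$coefficients[object$features])
  if (type == "link") lp else stats::plogis(lp)
}

#' @export
coef.nomo_fit <- function(object, ...) object$coefficients

#' @export
vcov.nomo_fit <- function(object, ...) object$vcov

#' @export
residuals.nomo_fit <- function(object, type = "deviance", ...) {
  if (is.null(object$glm)) stop("no residuals for a fixed-coefficient model")
  stats::residuals(object$glm, type = type)
}

#' Simulate labels from a fitted classifier
#'
#' Draws Bernoulli labels at the fitted (or newdata) probabilities -- the
#' parametric-bootstrap step behind the self-consistency checks.
#'
#' @param object A `nomo_fit`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional integer seed.
#' @param newdata Optional covariate data.frame (required for
#'   fixed-coefficient models).
#' @param ... Unused.
#' @return data.frame with `nsim` columns of 0/1 labels.
#' @export
simulate.nomo_fit <- function(object, nsim = 1L, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- if (is.null(newdata)) predict(object, type = "response")
       else predict(object, newdata, type = "response")
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.nomo_fit <- function(x, digits = 4L, ...) {
  cat("Logistic benign/malignant classifier (malignant = 1)\n")
  if (!length(x$coefficients)) {
    cat("  <empty model: no feature survived selection>\n")
    return(invisible(x))
  }
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  if (!is.na(x$n))
    cat(sprintf("  n = %d (%d malignant), IRLS iterations = %d\n",
                x$n, x$n_events, x$iterations))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Summarise a fitted classifier
#'
#' @param object A `nomo_fit`.
#' @param conf_level Confidence level for odds-ratio intervals.
#' @param ... Unused.
#' @return `summary.nomo_fit`: the Wald/odds-ratio table plus fit metadata.
#' @export
summary.nomo_fit <- function(object, conf_level = 0.95, ...) {
  structure(list(wald = wald_table(object, conf_level = conf_level),
                 n = object$n, n_events = object$n_events,
                 converged = object$converged, iterations = object$iterations,
                 selection = object$selection, call = object$call),
            class = "summary.nomo_fit")
}

#' @export
print.summary.nomo_fit <- function(x, digits = 4L, ...) {
  cat("Logistic benign/malignant classifier\n")
  if (!is.na(x$n))
    cat(sprintf("n = %d (%d malignant), converged in %d IRLS iterations\n\n",
                x$n, x$n_events, x$iterations))
  w <- x$wald
  w[] <- lapply(w, function(col) if (is.numeric(col)) signif(col, digits) else col)
  print(w, row.names = FALSE)
  if (!is.null(x$selection)) {
    cat("\n"); print(x$selection)
  }
  invisible(x)
}

#' @export
plot.nomo_fit <- function(x, ...) {
  plot(build_nomogram(x), ...)
}
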
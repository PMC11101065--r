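#' Reference cohort statistics and coefficients
#'
#' Per-class summary statistics (n, mean, SD) of the four image features in a
#' reference cohort of 2,723 H&E breast-pathology images (2,214 infiltrating
#' ductal carcinoma, 509 benign adenosis/fibroadenoma), together with the
#' per-class summaries of its 1,907-image training subset and the three-variable
#' logistic coefficients fitted on that subset. These numbers parameterise the
#' package's default simulation scenario (see [sim_config()]) and let the cohort
#' statistics and the Wald/odds-ratio table be recomputed from summary cells
#' alone.
#'
#' Features are `avg_r`, `avg_g`, `avg_b` (mean channel intensity, 0-255) and
#' `entropy` (grayscale histogram Shannon entropy, bits).
#'
#' @return A list with elements:
#' \describe{
#'   \item{cohort}{data.frame of full-cohort per-class summaries: columns
#'     `feature`, `group`, `n`, `mean`, `sd`.}
#'   \item{training}{same shape for the training subset.}
#'   \item{coefficients}{data.frame with `term`, `beta`, `se` for the reference
#'     logistic model (`(Intercept)`, `avg_r`, `avg_b`, `entropy`).}
#'   \item{n_total, n_training, n_validation}{cohort sizes.}
#' }
#' @examples
#' ref <- reference_cohort()
#' subset(ref$cohort, feature == "entropy")
#' @export
reference_cohort <- function() {
  feat <- c("avg_r", "avg_g", "avg_b", "entropy")
  cohort <- data.frame(
    feature = rep(feat, each = 2L),
    group   = rep(c("malignant", "benign"), 4L),
    n       = rep(c(2214L, 509L), 4L),
    mean    = c(219.969, 226.308, 202.0238, 219.060,
                220.340, 228.996, 5.425, 4.146),
    sd      = c(5.137, 6.265, 13.060, 17.180,
                8.827, 7.237, 0.573, 0.984),
    stringsAsFactors = FALSE
  )
  training <- data.frame(
    feature = rep(feat, each = 2L),
    group   = rep(c("malignant", "benign"), 4L),
    n       = rep(c(1541L, 366L), 4L),
    mean    = c(219.908, 226.730, 201.866, 220.272,
                220.278, 229.530, 5.430, 4.084),
    sd      = c(5.226, 5.965, 13.183, 16.253,
                8.825, 6.650, 0.579, 0.958),
    stringsAsFactors = FALSE
  )
  coefficients <- data.frame(
    term = c("(Intercept)", "avg_r", "avg_b", "entropy"),
    beta = c(-47.265, 0.226, -0.073, 2.998),
    se   = c(6.657, 0.032, 0.018, 0.201),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, training = training, coefficients = coefficients,
       n_total = 2723L, n_training = 1907L, n_validation = 816L)
}
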
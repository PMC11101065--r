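#' Simulation configuration for class-conditional image features
#'
#' Defines the generative model behind the synthetic cohort: per class
#' (benign / malignant) a mean vector and SD vector over the four features
#' (`avg_r`, `avg_g`, `avg_b` in intensity units 0-255; `entropy` in bits), an
#' optional 4x4 correlation matrix (identity by default -- only the marginals of
#' the reference cohort are known), the number of images per class, and the
#' rendering geometry used when realising feature rows as actual pixels.
#'
#' Defaults are the reference cohort's class-conditional means and SDs
#' (see [reference_cohort()]) at the reference class sizes (2,214 malignant /
#' 509 benign). The gray-level window `window` (W) is the number of distinct
#' latent gray levels a rendered image may use; entropy targets must satisfy
#' `H < log2(W)`. W = 64 keeps channel offsets clip-free for channel means near
#' 220-229.
#'
#' @param malignant,benign Named lists with numeric vectors `mean` and `sd` of
#'   length 4 (names `avg_r`, `avg_g`, `avg_b`, `entropy`), optional `cor`
#'   (4x4 correlation matrix, default identity) and integer `n`.
#' @param width,height Rendered image size in pixels.
#' @param window Gray-level window width W, integer in \[2, 256\].
#' @param seed Optional integer seed recorded in the config; operations also
#'   accept an explicit seed argument.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$malignant$mean
#' @export
sim_config <- function(malignant = NULL, benign = NULL,
                       width = 128L, height = 128L, window = 64L,
                       seed = NULL) {
  ref <- reference_cohort()
  take <- function(group) {
    rows <- ref$cohort[ref$cohort$group == group, ]
    list(mean = stats::setNames(rows$mean, rows$feature),
         sd   = stats::setNames(rows$sd, rows$feature),
         cor  = diag(4L),
         n    = rows$n[1L])
  }
  fill <- function(user, group) {
    out <- take(group)
    if (!is.null(user)) {
      for (f in intersect(names(user), c("mean", "sd", "cor", "n"))) {
        out[[f]] <- user[[f]]
      }
    }
    out$mean <- as.numeric(out$mean)
    out$sd <- as.numeric(out$sd)
    names(out$mean) <- names(out$sd) <- feature_names()
    out$n <- as.integer(out$n)
    out
  }
  cfg <- structure(
    list(malignant = fill(malignant, "malignant"),
         benign = fill(benign, "benign"),
         width = as.integer(width), height = as.integer(height),
         window = as.integer(window), seed = seed),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

feature_names <- function() c("avg_r", "avg_g", "avg_b", "entropy")

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$window < 2L || cfg$window > 256L)
    stop("gray-level window must lie in [2, 256], got ", cfg$window)
  if (cfg$width < 1L || cfg$height < 1L)
    stop("image dimensions must be positive")
  for (cls in c("malignant", "benign")) {
    p <- cfg[[cls]]
    if (length(p$mean) != 4L || length(p$sd) != 4L)
      stop("class '", cls, "': mean and sd must have length 4")
    if (any(p$sd < 0))
      stop("class '", cls, "': SDs must be non-negative")
    if (p$n < 1L)
      stop("class '", cls, "': n per class must be >= 1")
    cm <- p$cor
    if (!is.matrix(cm) || !identical(dim(cm), c(4L, 4L)))
      stop("class '", cls, "': correlation matrix must be 4x4")
    if (max(abs(cm - t(cm))) > 1e-8 || max(abs(diag(cm) - 1)) > 1e-8)
      stop("class '", cls, "': correlation matrix must be symmetric with unit diagonal")
    ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("class '", cls, "': correlation matrix is not positive semi-definite ",
           "(smallest eigenvalue ", signif(min(ev), 3), ")")
    if (any(p$mean[1:3] < 0 | p$mean[1:3] > 255))
      stop("class '", cls, "': channel means must lie in [0, 255]")
    if (p$mean[4L] >= log2(cfg$window))
      stop("class '", cls, "': target entropy ", p$mean[4L],
           " must be below log2(window) = ", signif(log2(cfg$window), 4))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic H&E feature simulation config\n")
  for (cls in c("malignant", "benign")) {
    p <- x[[cls]]
    cat(sprintf("  %-9s n = %d\n", cls, p$n))
    cat(sprintf("    mean: %s\n", paste(sprintf("%s=%.3f", names(p$mean), p$mean),
                                        collapse = ", ")))
    cat(sprintf("    sd:   %s\n", paste(sprintf("%s=%.3f", names(p$sd), p$sd),
                                        collapse = ", ")))
  }
  cat(sprintf("  render: %dx%d px, gray window W = %d\n", x$width, x$height, x$window))
  invisible(x)
}
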
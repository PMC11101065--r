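# Shared fixtures and independent brute-force oracles.

tiny_config <- function(n_mal = 25L, n_ben = 25L, width = 32L, height = 32L) {
  sim_config(malignant = list(n = n_mal), benign = list(n = n_ben),
             width = width, height = height)
}

random_rgb <- function(height, width, seed) {
  set.seed(seed)
  array(sample(0:255, height * width * 3L, replace = TRUE),
        dim = c(height, width, 3L))
}

# naive per-pixel double-loop accumulation
brute_channel_means <- function(px) {
  tot <- c(0, 0, 0); n <- 0L
  for (i in seq_len(dim(px)[1L])) for (j in seq_len(dim(px)[2L])) {
    tot <- tot + px[i, j, ]; n <- n + 1L
  }
  stats::setNames(tot / n, c("avg_r", "avg_g", "avg_b"))
}

# entropy from an explicitly tabulated histogram
brute_entropy <- function(gray) {
  tab <- table(as.vector(gray))
  p <- as.numeric(tab) / length(gray)
  -sum(p * log2(p))
}

# exhaustive pair counting over all positive x negative pairs
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

ref_beta <- function() {
  cf <- reference_cohort()$coefficients
  stats::setNames(cf$beta, cf$term)
}

ref_se <- function() {
  cf <- reference_cohort()$coefficients
  stats::setNames(cf$se, cf$term)
}
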
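test_that("simulated feature tables match their configured distribution", {
  cfg <- sim_config(malignant = list(n = 10000L), benign = list(n = 10000L))
  tab <- simulate_feature_table(cfg, seed = 11)
  expect_equal(nrow(tab), 20000L)
  # each sample mean within 4 SD/sqrt(n) of its configured mean
  for (cls in c("malignant", "benign")) {
    p <- cfg[[cls]]
    rows <- tab[tab$label == cls, ]
    for (f in c("avg_r", "avg_g", "avg_b", "entropy")) {
      expect_lt(abs(mean(rows[[f]]) - p$mean[f]), 4 * p$sd[f] / sqrt(p$n),
                label = paste(cls, f, "sample mean"))
    }
  }
  # channel features clipped to [0,255], entropy to [0,8]
  expect_true(all(tab$avg_r >= 0 & tab$avg_r <= 255))
  expect_true(all(tab$entropy >= 0 & tab$entropy <= 8))
})

test_that("simulation is deterministic given config and seed", {
  cfg <- tiny_config()
  expect_identical(simulate_feature_table(cfg, seed = 3),
                   simulate_feature_table(cfg, seed = 3))
  expect_false(identical(simulate_feature_table(cfg, seed = 3),
                         simulate_feature_table(cfg, seed = 4)))
})

test_that("zero SDs produce the class means exactly", {
  cfg <- sim_config(malignant = list(sd = rep(0, 4), n = 5L),
                    benign = list(sd = rep(0, 4), n = 5L))
  tab <- simulate_feature_table(cfg, seed = 1)
  mal <- tab[tab$label == "malignant", ]
  for (f in c("avg_r", "avg_g", "avg_b", "entropy"))
    expect_true(all(mal[[f]] == cfg$malignant$mean[f]))
})

test_that("identity correlation yields near-zero pairwise sample correlations", {
  cfg <- sim_config(malignant = list(n = 50000L), benign = list(n = 50000L))
  tab <- simulate_feature_table(cfg, seed = 5)
  for (cls in c("malignant", "benign")) {
    cm <- cor(tab[tab$label == cls, c("avg_r", "avg_g", "avg_b", "entropy")])
    expect_lt(max(abs(cm[upper.tri(cm)])), 0.02)
  }
})

test_that("a requested correlation structure is realised", {
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.6
  cfg <- sim_config(malignant = list(n = 50000L, cor = R),
                    benign = list(n = 100L))
  tab <- simulate_feature_table(cfg, seed = 6)
  mal <- tab[tab$label == "malignant", ]
  expect_lt(abs(cor(mal$avg_r, mal$avg_g) - 0.6), 0.02)
})

test_that("invalid configurations are rejected with diagnostics", {
  bad <- diag(4); bad[1, 2] <- bad[2, 1] <- 1.5   # not PSD
  expect_error(sim_config(malignant = list(cor = bad)),
               "malignant.*not positive semi-definite")
  expect_error(sim_config(benign = list(sd = c(-1, 1, 1, 0.5))), "benign")
  expect_error(sim_config(malignant = list(n = 0L)), "n per class")
  expect_error(sim_config(window = 300), "window")
  # requested entropy must stay below log2(window)
  expect_error(sim_config(malignant = list(mean = c(220, 202, 220, 6.5)),
                          window = 64), "log2")
})

test_that("rendered images hit targeted features within contract tolerances", {
  target <- c(avg_r = 220, avg_g = 202, avg_b = 220, entropy = 5.425)
  img <- render_image(target, width = 512, height = 512, window = 64, seed = 2)
  expect_false(img$clipped)
  cm <- channel_means(img)
  expect_lt(max(abs(cm - target[1:3])), 1.0)
  expect_lt(abs(gray_entropy(to_grayscale(img)) - target["entropy"]), 0.1)
})

test_that("zero-entropy target renders a constant image", {
  img <- render_image(c(avg_r = 100, avg_g = 150, avg_b = 200, entropy = 0),
                      width = 16, height = 16, seed = 1)
  expect_identical(gray_entropy(to_grayscale(img)), 0)
  expect_true(all(img$pixels[, , 1] == img$pixels[1, 1, 1]))
})

test_that("luma of a rendered image is the latent level plus a constant", {
  # luma weights sum to 1, so the gray histogram is a shift of the latent one
  # and extracted entropy equals the latent entropy whenever nothing clips
  set.seed(91)
  for (k in 1:20) {
    target <- c(avg_r = runif(1, 180, 235), avg_g = runif(1, 180, 235),
                avg_b = runif(1, 180, 235), entropy = runif(1, 1, 5.8))
    img <- render_image(target, width = 64, height = 64, window = 64,
                        seed = 1000 + k)
    expect_false(img$clipped)
    gray <- to_grayscale(img)
    # reconstruct the latent level from the red plane (a pure shift of it)
    latent <- img$pixels[, , 1] - min(img$pixels[, , 1])
    expect_equal(gray_entropy(gray), brute_entropy(latent), tolerance = 1e-12)
    expect_lt(abs(gray_entropy(gray) - target["entropy"]), 0.1)
  }
})

test_that("infeasible targets set the clipping flag instead of failing", {
  expect_warning(
    img <- render_image(c(avg_r = 254, avg_g = 254, avg_b = 254, entropy = 5.9),
                        width = 64, height = 64, window = 64, seed = 1),
    "clipped")
  expect_true(img$clipped)
  expect_gt(img$clip_fraction, 0.01)
})

test_that("generate_dataset writes one image per row plus a reproducible manifest", {
  cfg <- tiny_config(n_mal = 5L, n_ben = 5L, width = 16L, height = 16L)
  d1 <- withr::local_tempdir()
  man <- generate_dataset(cfg, d1, seed = 7)
  expect_equal(nrow(man), 10L)
  expect_equal(sum(man$label == "malignant"), 5L)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(d1, "manifest.csv")))

  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(cfg, d2, seed = 7)
  a <- read.csv(file.path(d1, "manifest.csv"))
  b <- read.csv(file.path(d2, "manifest.csv"))
  expect_identical(a[c("image_id", "label")], b[c("image_id", "label")])
  # and the images themselves are byte-identical
  expect_identical(readBin(man$path[1], "raw", 1e6),
                   readBin(man2$path[1], "raw", 1e6))
})

test_that("generate_dataset rejects unwritable paths", {
  expect_error(generate_dataset(tiny_config(), "/proc/nope/never"), "/proc/nope")
})
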
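#' Assemble a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: the data source (a simulation
#' config or an image manifest), the split fraction, the selection level, the
#' bootstrap sizes and the Hosmer-Lemeshow group count, plus the run seed from
#' which every stage seed is derived (simulation: seed, split: seed + 1,
#' training bootstrap: seed + 2, validation bootstrap: seed + 3, DCA band:
#' seed + 4), so each stage is individually reproducible.
#'
#' @param simulation A [sim_config()], or NULL when `manifest` is given.
#' @param manifest Path to a manifest CSV (or a manifest data.frame) of images
#'   to extract features from; overrides `simulation`.
#' @param seed Run-level integer seed.
#' @param render Simulate by rendering actual images and re-extracting their
#'   features (TRUE), or draw the feature table directly (FALSE, default --
#'   equivalent up to render tolerances and far faster at cohort scale).
#' @param validation_fraction Held-out fraction (default 0.3).
#' @param alpha Selection significance level (default 0.05).
#' @param candidates Candidate features for selection.
#' @param bootstrap_B AUC bootstrap replicates (default 1000).
#' @param hl_groups Hosmer-Lemeshow groups (default 10).
#' @param dca_B DCA band replicates (default 0).
#' @param thresholds DCA threshold grid.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulation = sim_config(), manifest = NULL, seed = 1L,
                       render = FALSE, validation_fraction = 0.3, alpha = 0.05,
                       candidates = feature_names(), bootstrap_B = 1000L,
                       hl_groups = 10L, dca_B = 0L,
                       thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(simulation = simulation, manifest = manifest,
                 seed = as.integer(seed), render = isTRUE(render),
                 validation_fraction = validation_fraction, alpha = alpha,
                 candidates = candidates, bootstrap_B = as.integer(bootstrap_B),
                 hl_groups = as.integer(hl_groups), dca_B = as.integer(dca_B),
                 thresholds = thresholds),
            class = "run_config")
}

#' Read a run configuration from a YAML/JSON file
#'
#' Flat key-value dialect: class blocks `benign:` / `malignant:` with keys
#' `mean_r`, `mean_g`, `mean_b`, `mean_h`, `sd_r`, `sd_g`, `sd_b`, `sd_h`,
#' `n`; top-level `seed`, `width`, `height`, `window`; plus the pipeline keys
#' `manifest`, `render`, `validation_fraction`, `alpha`, `bootstrap_B`,
#' `hl_groups`, `dca_B`. Missing keys fall back to the defaults of
#' [sim_config()] / [run_config()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  # identity bool handlers keep the class-block key `n` from being read as a
  # YAML 1.1 boolean
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = function(x) if (tolower(x) == "y") x else TRUE,
    "bool#no" = function(x) if (tolower(x) == "n") x else FALSE))
  class_block <- function(b) {
    if (is.null(b)) return(NULL)
    out <- list()
    mk <- c(mean_r = "avg_r", mean_g = "avg_g", mean_b = "avg_b", mean_h = "entropy")
    sk <- c(sd_r = "avg_r", sd_g = "avg_g", sd_b = "avg_b", sd_h = "entropy")
    if (any(names(mk) %in% names(b))) {
      m <- sim_config()$benign$mean
      for (k in names(mk)) if (!is.null(b[[k]])) m[mk[k]] <- b[[k]]
      out$mean <- m
    }
    if (any(names(sk) %in% names(b))) {
      s <- sim_config()$benign$sd
      for (k in names(sk)) if (!is.null(b[[k]])) s[sk[k]] <- b[[k]]
      out$sd <- s
    }
    if (!is.null(b$n)) out$n <- b$n
    out
  }
  grab <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  sim <- sim_config(
    malignant = class_block(raw$malignant), benign = class_block(raw$benign),
    width = grab("width", 128L), height = grab("height", 128L),
    window = grab("window", 64L), seed = raw$seed
  )
  run_config(simulation = sim, manifest = raw$manifest,
             seed = grab("seed", 1L), render = grab("render", FALSE),
             validation_fraction = grab("validation_fraction", 0.3),
             alpha = grab("alpha", 0.05),
             bootstrap_B = grab("bootstrap_B", 1000L),
             hl_groups = grab("hl_groups", 10L), dca_B = grab("dca_B", 0L))
}

#' Run the end-to-end analysis
#'
#' Acquire data (simulate, or extract from a manifest), compare the benign and
#' malignant groups, split 7:3, compare training against validation and the
#' classes within training, select variables and fit the logistic model on the
#' training partition, build the nomogram, and evaluate on both partitions.
#' Deterministic given the run seed.
#'
#' @param config A [run_config()] (or a path readable by [read_run_config()]).
#' @param output_dir Optional directory; when given, writes `report.json`,
#'   `model.json`, `tables/*.csv` and `figures/*.png` there.
#' @param quiet Suppress progress messages (default TRUE).
#' @return List of class `run_report`: config echo, stage row counts, the
#'   three comparison tables, the selection trace, the Wald table, the
#'   nomogram spec, and training/validation `nomo_evaluation`s.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed

  feats <- stage("data", {
    if (!is.null(config$manifest)) {
      say("extracting features from manifest")
      tab <- extract_features(config$manifest)
      fails <- attr(tab, "failures")
      if (nrow(fails)) say(nrow(fails), " rows failed extraction")
      tab
    } else if (config$render) {
      say("rendering synthetic images")
      dir <- if (is.null(output_dir)) tempfile("pathnomo_imgs")
             else file.path(output_dir, "images")
      man <- generate_dataset(config$simulation, dir, seed = seed)
      extract_features(man)
    } else {
      say("simulating feature table")
      simulate_feature_table(config$simulation, seed = seed)
    }
  })

  group_cmp <- stage("cohort comparison",
    compare_groups(feats, order = c("benign", "malignant")))

  split <- stage("split",
    split_dataset(feats, config$validation_fraction, seed = seed + 1L))
  train <- feats[split$training, ]
  valid <- feats[split$validation, ]
  part <- feats["image_id"]
  part$partition <- "training"
  part$partition[split$validation] <- "validation"

  split_tab <- feats
  split_tab$partition <- part$partition
  partition_cmp <- stage("partition comparison",
    compare_groups(split_tab, group_key = "partition",
                   order = c("validation", "training")))
  training_cmp <- stage("training comparison",
    compare_groups(train, order = c("malignant", "benign")))

  fit <- stage("fit", nomo_fit(stats::reformulate(config$candidates, "label"),
                               train, select = TRUE, alpha = config$alpha))
  if (!length(fit$features)) stop("pipeline stage 'fit' failed: empty model")
  nomogram <- stage("nomogram", build_nomogram(fit))
  eval_train <- stage("evaluation (training)",
    evaluate_model(fit, train, B = config$bootstrap_B, seed = seed + 2L,
                   g = config$hl_groups, thresholds = config$thresholds,
                   dca_B = config$dca_B))
  eval_valid <- stage("evaluation (validation)",
    evaluate_model(fit, valid, B = config$bootstrap_B, seed = seed + 3L,
                   g = config$hl_groups, thresholds = config$thresholds,
                   dca_B = config$dca_B))

  report <- structure(list(
    config = config,
    counts = list(total = nrow(feats), training = nrow(train),
                  validation = nrow(valid),
                  malignant = sum(feats$label == "malignant"),
                  benign = sum(feats$label == "benign")),
    group_comparison = group_cmp,
    partition_comparison = partition_cmp,
    training_comparison = training_cmp,
    split = split,
    model = fit,
    wald = wald_table(fit),
    nomogram = nomogram,
    evaluation = list(training = eval_train, validation = eval_valid),
    version = as.character(utils::packageVersion("pathnomo")),
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "run_report")

  if (!is.null(output_dir)) write_run_report(report, output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pathnomo run report\n")
  cat(sprintf("  data: %d images (%d malignant / %d benign)\n",
              x$counts$total, x$counts$malignant, x$counts$benign))
  cat(sprintf("  split: %d training / %d validation (seed %d)\n",
              x$counts$training, x$counts$validation, x$split$seed))
  cat("  model features:", paste(x$model$features, collapse = ", "), "\n")
  cat(sprintf("  training   AUC %.3f (%.3f, %.3f); HL p %.3f\n",
              x$evaluation$training$roc$auc, x$evaluation$training$roc$ci[1],
              x$evaluation$training$roc$ci[2], x$evaluation$training$hl$p_value))
  cat(sprintf("  validation AUC %.3f (%.3f, %.3f); HL p %.3f\n",
              x$evaluation$validation$roc$auc, x$evaluation$validation$roc$ci[1],
              x$evaluation$validation$roc$ci[2], x$evaluation$validation$hl$p_value))
  invisible(x)
}

#' Serialise a run report to disk
#'
#' Writes `report.json` (all numbers), `model.json` (coefficients, SEs,
#' covariance, label encoding, training metadata), the comparison and Wald
#' tables plus split manifest under `tables/`, and ROC / calibration / DCA
#' figures under `figures/`.
#'
#' @param report A `run_report`.
#' @param output_dir Target directory (created if needed).
#' @param figures Also render PNG figures (default TRUE).
#' @return `output_dir`, invisibly.
#' @export
write_run_report <- function(report, output_dir, figures = TRUE) {
  dir.create(file.path(output_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  ev_json <- function(ev) list(
    auc = ev$roc$auc, auc_ci = ev$roc$ci, bootstrap_B = ev$roc$B,
    hl_chi2 = ev$hl$statistic, hl_df = ev$hl$df, hl_p = ev$hl$p_value,
    calibration = as.data.frame(ev$calibration),
    dca = as.data.frame(ev$dca),
    n = ev$n, prevalence = ev$prevalence, seed = ev$seed)
  json <- list(
    version = report$version, timestamp = report$timestamp,
    seed = report$config$seed,
    counts = report$counts,
    group_comparison = report$group_comparison,
    partition_comparison = report$partition_comparison,
    training_comparison = report$training_comparison,
    wald = report$wald,
    selection = if (!is.null(report$model$selection))
      report$model$selection$trace,
    evaluation = list(training = ev_json(report$evaluation$training),
                      validation = ev_json(report$evaluation$validation))
  )
  jsonlite::write_json(json, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  m <- report$model
  jsonlite::write_json(list(
    features = m$features, coefficients = as.list(m$coefficients),
    se = as.list(m$se), covariance = m$vcov,
    label_encoding = list(malignant = 1L, benign = 0L),
    n = m$n, n_events = m$n_events, seed = report$config$seed
  ), file.path(output_dir, "model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wt <- function(df, name)
    utils::write.csv(df, file.path(output_dir, "tables", name), row.names = FALSE)
  wt(report$group_comparison, "group_comparison.csv")
  wt(report$partition_comparison, "partition_comparison.csv")
  wt(report$training_comparison, "training_comparison.csv")
  wt(report$wald, "wald.csv")
  split_manifest <- data.frame(
    row = seq_len(report$counts$total),
    partition = ifelse(seq_len(report$counts$total) %in% report$split$validation,
                       "validation", "training"))
  wt(split_manifest, "split.csv")
  if (figures) {
    dir.create(file.path(output_dir, "figures"), showWarnings = FALSE)
    fig <- function(name, expr) {
      grDevices::png(file.path(output_dir, "figures", name),
                     width = 900, height = 700, res = 120)
      on.exit(grDevices::dev.off(), add = TRUE)
      force(expr)
    }
    fig("nomogram.png", plot(report$nomogram))
    fig("roc_training.png", plot(report$evaluation$training, "roc"))
    fig("roc_validation.png", plot(report$evaluation$validation, "roc"))
    fig("calibration.png", plot(report$evaluation$validation, "calibration"))
    fig("dca.png", plot(report$evaluation$validation, "dca"))
  }
  invisible(output_dir)
}

#' Command-line interface
#'
#' Subcommand dispatcher used by the `inst/cli/pathnomo` Rscript:
#' `simulate --config cfg.yaml --out dir` (render images + manifest),
#' `extract --manifest m.csv --out feats.csv`,
#' `stats --features feats.csv --out dir`,
#' `fit --features feats.csv --out dir`,
#' `evaluate --features feats.csv --model model.json --out dir`,
#' `run --config cfg.yaml --out dir`.
#' Common flags: `--seed <int>`, `--verbose`.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit code: 0 on success, 1 on usage errors or failures
#'   (with a message on stderr).
#' @export
pathnomo_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pathnomo <simulate|extract|stats|fit|evaluate|run> [options]",
    "  simulate --config cfg.yaml --out dir [--seed N]",
    "  extract  --manifest manifest.csv --out features.csv",
    "  stats    --features features.csv --out dir [--seed N]",
    "  fit      --features features.csv --out dir [--seed N]",
    "  evaluate --features features.csv --model model.json --out dir [--seed N]",
    "  run      [--config cfg.yaml] --out dir [--seed N]",
    sep = "\n")
  opt <- list(verbose = FALSE)
  if (!length(argv)) { message(usage); return(1L) }
  cmd <- argv[1L]; argv <- argv[-1L]
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--") || i == length(argv)) {
      message("unknown or valueless flag: ", a, "\n", usage); return(1L)
    }
    opt[[substring(a, 3L)]] <- argv[i + 1L]
    i <- i + 2L
  }
  need <- function(k) {
    if (is.null(opt[[k]])) stop("missing required flag --", k, call. = FALSE)
    opt[[k]]
  }
  seed <- as.integer(if (is.null(opt$seed)) 1L else opt$seed)
  res <- tryCatch({
    switch(cmd,
      simulate = {
        cfg <- read_run_config(need("config"))
        generate_dataset(cfg$simulation, need("out"), seed = seed)
        message("wrote images + manifest to ", opt$out)
      },
      extract = {
        tab <- extract_features(need("manifest"))
        utils::write.csv(tab, need("out"), row.names = FALSE)
        fails <- attr(tab, "failures")
        if (nrow(fails)) message(nrow(fails), " rows failed; first: ",
                                 fails$error[1L])
        message("wrote ", nrow(tab), " feature rows to ", opt$out)
      },
      stats = {
        tab <- read_feature_csv(need("features"))
        dir.create(need("out"), recursive = TRUE, showWarnings = FALSE)
        cmp <- compare_groups(tab, order = c("benign", "malignant"))
        utils::write.csv(cmp, file.path(opt$out, "group_comparison.csv"),
                         row.names = FALSE)
        message("wrote group comparison to ", opt$out)
      },
      fit = {
        tab <- read_feature_csv(need("features"))
        fit <- nomo_fit(stats::reformulate(
          intersect(feature_names(), names(tab)), "label"), tab, select = TRUE)
        dir.create(need("out"), recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(wald_table(fit), file.path(opt$out, "wald.csv"),
                         row.names = FALSE)
        jsonlite::write_json(list(features = fit$features,
                                  coefficients = as.list(fit$coefficients),
                                  se = as.list(fit$se)),
                             file.path(opt$out, "model.json"),
                             auto_unbox = TRUE, digits = NA)
        message("wrote model + Wald table to ", opt$out)
      },
      evaluate = {
        tab <- read_feature_csv(need("features"))
        mj <- jsonlite::read_json(need("model"), simplifyVector = TRUE)
        model <- nomo_model(unlist(mj$coefficients))
        ev <- evaluate_model(model, tab, seed = seed)
        dir.create(need("out"), recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(list(auc = ev$roc$auc, auc_ci = ev$roc$ci,
                                  hl_chi2 = ev$hl$statistic, hl_p = ev$hl$p_value),
                             file.path(opt$out, "evaluation.json"),
                             auto_unbox = TRUE, digits = NA)
        message(sprintf("AUC %.3f (%.3f, %.3f); wrote %s", ev$roc$auc,
                        ev$roc$ci[1], ev$roc$ci[2], opt$out))
      },
      run = {
        cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
               else run_config(seed = seed)
        cfg$seed <- seed
        run_pipeline(cfg, output_dir = need("out"), quiet = !opt$verbose)
        message("wrote run report to ", opt$out)
      },
      stop("unknown subcommand '", cmd, "'", call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e), "\n", usage)
    1L
  })
  res
}

read_feature_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("label" %in% names(tab))
    tab$label <- factor(tab$label, levels = c("benign", "malignant"))
  tab
}
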
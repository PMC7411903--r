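# End-to-end experiment drivers: simulate phantoms, segment, extract
# features, train/evaluate the fuzzy SVM. Each driver validates its config
# up front and echoes the exact config (with seeds) into the output
# directory so every run is reproducible.

#' Default pipeline configuration
#'
#' @param ... overrides of the default fields.
#' @return validated config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    method = "ipfcm",          # otsu | fcm | ifcm | pfcm | ipfcm
    k = 3,
    p = 2,
    W = 1,
    sugeno_lambda = 2,
    tol = 1e-5,
    max_iter = 100,
    size = 128,
    n_benign = 20,
    n_malignant = 20,
    contrast = 0.35,
    texture_sd = 0.05,
    noise_levels = numeric(0),  # e.g. c(5, 7, 9) for a sweep
    noise_kind = "salt_pepper",
    C = 10,
    sigma = 1,
    weighting = TRUE,
    train_fraction = 0.7,
    seed = 1
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg config list.
#' @export
validate_config <- function(cfg) {
  methods <- c("otsu", "fcm", "ifcm", "pfcm", "ipfcm")
  if (!cfg$method %in% methods) {
    stop("unknown method '", cfg$method, "'; choose one of: ",
         paste(methods, collapse = ", "))
  }
  stopifnot(cfg$k >= 2, cfg$p > 1, cfg$W > 0, cfg$sugeno_lambda >= 0,
            cfg$size >= 64, cfg$n_benign >= 1, cfg$n_malignant >= 1,
            cfg$C > 0, cfg$sigma > 0,
            cfg$train_fraction > 0, cfg$train_fraction < 1)
  if (length(cfg$noise_levels) > 0 &&
      any(cfg$noise_levels <= 0 | cfg$noise_levels >= 100)) {
    stop("noise levels must lie in (0, 100)")
  }
  cfg
}

#' Load a JSON config, applying defaults for missing fields
#'
#' @param path JSON file.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, cfg)
}

echo_config <- function(cfg, out_dir) {
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a phantom dataset to disk
#'
#' Writes one PGM per phantom plus `manifest.csv` (id, class, seed, noise
#' level) and the config.
#'
#' @param cfg config from [default_config()].
#' @param out_dir output directory (created if missing).
#' @return manifest data.frame, invisibly.
#' @export
cmd_simulate <- function(cfg = default_config(), out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phantoms <- make_labeled_dataset(cfg$n_benign, cfg$n_malignant,
                                   seed = cfg$seed, size = cfg$size,
                                   contrast = cfg$contrast,
                                   texture_sd = cfg$texture_sd)
  manifest <- data.frame(
    id = sprintf("phantom_%03d", seq_along(phantoms)),
    class = vapply(phantoms, `[[`, character(1), "class"),
    seed = vapply(phantoms, `[[`, integer(1), "seed"),
    noise_level = 0
  )
  for (i in seq_along(phantoms)) {
    write_pgm(phantoms[[i]]$image, file.path(out_dir,
                                             paste0(manifest$id[i], ".pgm")))
    write_pgm(phantoms[[i]]$truth_labels / 2,
              file.path(out_dir, paste0(manifest$id[i], "_truth.pgm")))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  echo_config(cfg, out_dir)
  invisible(manifest)
}

#' Segment phantoms and tabulate accuracy by method and noise level
#'
#' Runs the configured method (or several) over a phantom list and an
#' optional noise sweep, and returns per-image accuracies plus a
#' methods-by-levels mean-accuracy table (the noise-robustness layout).
#'
#' @param cfg config; `cfg$noise_levels` drives the sweep (empty = clean
#'   only).
#' @param phantoms list of `phantom` objects; defaults to a fresh dataset
#'   from the config.
#' @param methods methods to run (default just `cfg$method`).
#' @param out_dir optional directory for the CSV outputs.
#' @return list(per_image, summary).
#' @export
cmd_segment <- function(cfg = default_config(), phantoms = NULL,
                        methods = cfg$method, out_dir = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(phantoms)) {
    phantoms <- make_labeled_dataset(cfg$n_benign, cfg$n_malignant,
                                     seed = cfg$seed, size = cfg$size,
                                     contrast = cfg$contrast,
                                     texture_sd = cfg$texture_sd)
  }
  suites <- list(level_0 = phantoms)
  if (length(cfg$noise_levels) > 0) {
    suites <- c(suites, noise_sweep_suite(phantoms, cfg$noise_levels,
                                          seed = cfg$seed + 1L,
                                          kind = cfg$noise_kind))
  }
  rows <- list()
  for (lvl in names(suites)) {
    level <- as.numeric(sub("level_", "", lvl))
    for (m in methods) {
      for (i in seq_along(suites[[lvl]])) {
        ph <- suites[[lvl]][[i]]
        seg <- segment_method_from_cfg(ph$image, m, cfg,
                                       seed = ph$seed, truth = ph$truth_labels)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, noise_level = level, id = i, accuracy = seg$accuracy)
      }
    }
  }
  per_image <- do.call(rbind, rows)
  summary <- stats::aggregate(accuracy ~ method + noise_level, per_image, mean)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_image, file.path(out_dir, "accuracy_per_image.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "accuracy_summary.csv"),
                     row.names = FALSE)
    echo_config(cfg, out_dir)
  }
  list(per_image = per_image, summary = summary)
}

segment_method_from_cfg <- function(image, method, cfg, seed, truth = NULL) {
  if (method == "otsu") {
    segment_image(image, "otsu", truth = truth)
  } else {
    args <- list(image = image, method = method, k = cfg$k, seed = seed,
                 truth = truth, p = cfg$p, tol = cfg$tol,
                 max_iter = cfg$max_iter)
    if (method %in% c("pfcm", "ipfcm")) args$W <- cfg$W
    if (method %in% c("ifcm", "ipfcm")) args$sugeno_lambda <- cfg$sugeno_lambda
    do.call(segment_image, args)
  }
}

#' Segment a dataset and extract the feature table
#'
#' @param cfg config.
#' @param phantoms phantom list (default: fresh dataset from config).
#' @param out_dir optional directory for `features.csv`.
#' @return feature data.frame (16 feature columns + id + class).
#' @export
cmd_features <- function(cfg = default_config(), phantoms = NULL,
                         out_dir = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(phantoms)) {
    phantoms <- make_labeled_dataset(cfg$n_benign, cfg$n_malignant,
                                     seed = cfg$seed, size = cfg$size,
                                     contrast = cfg$contrast,
                                     texture_sd = cfg$texture_sd)
  }
  images <- list(); masks <- list(); ids <- character(0); cls <- character(0)
  for (i in seq_along(phantoms)) {
    ph <- phantoms[[i]]
    seg <- segment_method_from_cfg(ph$image, cfg$method, cfg, seed = ph$seed)
    mask <- tryCatch(roi_mask_from_labels(seg$label_map, seg$roi_cluster),
                     error = function(e) {
                       warning("phantom ", i, " skipped: ",
                               conditionMessage(e))
                       NULL
                     })
    if (is.null(mask)) next
    images[[length(images) + 1L]] <- ph$image
    masks[[length(masks) + 1L]] <- mask
    ids <- c(ids, sprintf("phantom_%03d", i))
    cls <- c(cls, ph$class)
  }
  tab <- feature_table(images, masks, ids = ids, classes = cls)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_csv(tab, file.path(out_dir, "features.csv"))
    echo_config(cfg, out_dir)
  }
  tab
}

# Seeded stratified train/test split on a class factor.
stratified_split <- function(classes, train_fraction, seed) {
  idx <- with_seed(seed, {
    unlist(lapply(unique(classes), function(cl) {
      pool <- which(classes == cl)
      sample(pool, round(length(pool) * train_fraction))
    }))
  })
  list(train = sort(idx), test = sort(setdiff(seq_along(classes), idx)))
}

#' Train the fuzzy SVM on a feature table and evaluate on a held-out split
#'
#' @param tab feature table from [cmd_features()] (needs a `class` column).
#' @param cfg config (C, sigma, weighting, train_fraction).
#' @param split_seed seed of the stratified split (default `cfg$seed`).
#' @return list: metrics (six confusion metrics + auc), counts, split,
#'   model fit.
#' @export
cmd_evaluate <- function(tab, cfg = default_config(),
                         split_seed = cfg$seed) {
  cfg <- validate_config(cfg)
  stopifnot("class" %in% names(tab))
  z <- ifelse(tab$class == "malignant", 1, -1)
  X <- as.matrix(tab[, feature_names])
  split <- stratified_split(tab$class, cfg$train_fraction, split_seed)
  if (length(unique(z[split$train])) < 2L) {
    stop("training split lost a class; adjust train_fraction")
  }
  fit <- fit_predict(X[split$train, , drop = FALSE], z[split$train],
                     X[split$test, , drop = FALSE],
                     C = cfg$C, sigma = cfg$sigma, weighting = cfg$weighting)
  counts <- confusion_counts(z[split$test], fit$predictions)
  metrics <- binary_metrics(counts)
  metrics$auc <- roc_auc(fit$decision_values, z[split$test])$auc
  list(metrics = metrics, counts = counts, split = split, fit = fit)
}

#' Full pipeline: simulate, segment, extract, classify, evaluate
#'
#' Runs the four pipeline stages on a fresh phantom dataset and writes a
#' JSON metrics report. Any stage failure aborts with a stage-tagged
#' message.
#'
#' @param cfg config from [default_config()].
#' @param out_dir optional output directory for report + config.
#' @param split_seeds one or more split seeds; metrics are reported per seed
#'   plus their mean.
#' @return list: per_split (list of metric lists), mean (averaged metrics),
#'   features (the feature table).
#' @export
cmd_pipeline <- function(cfg = default_config(), out_dir = NULL,
                         split_seeds = cfg$seed) {
  cfg <- validate_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  phantoms <- stage("simulate",
    make_labeled_dataset(cfg$n_benign, cfg$n_malignant, seed = cfg$seed,
                         size = cfg$size, contrast = cfg$contrast,
                         texture_sd = cfg$texture_sd))
  if (length(cfg$noise_levels) == 1) {
    phantoms <- stage("noise",
      noise_sweep_suite(phantoms, cfg$noise_levels, seed = cfg$seed + 1L,
                        kind = cfg$noise_kind)[[1]])
  }
  tab <- stage("features", cmd_features(cfg, phantoms))
  per_split <- lapply(split_seeds, function(s) {
    stage("classify", cmd_evaluate(tab, cfg, split_seed = s))$metrics
  })
  names(per_split) <- paste0("split_", split_seeds)
  metric_names <- names(per_split[[1]])
  mean_metrics <- lapply(metric_names, function(mn) {
    mean(vapply(per_split, function(m) as.numeric(m[[mn]]), numeric(1)))
  })
  names(mean_metrics) <- metric_names
  report <- list(config = cfg, per_split = per_split, mean = mean_metrics)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         digits = NA, auto_unbox = TRUE, na = "null",
                         pretty = TRUE)
    echo_config(cfg, out_dir)
  }
  list(per_split = per_split, mean = mean_metrics, features = tab,
       config = cfg)
}
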
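#' Pipeline configuration
#'
#' Bundles every tunable parameter of the two-stage experiment. Stage
#' seeds are derived from the single global `seed` by fixed offsets, so
#' stages can be re-run in isolation and the whole run is reproducible.
#'
#' @param max_blank Maximum tolerated blank ratio (tiles above it are
#'   discarded).
#' @param white_threshold Near-white intensity threshold for blankness.
#' @param clahe A [clahe_params()] object, or `NULL` to skip enhancement.
#' @param features A [feature_config()].
#' @param train_fraction Train share of the 80:20-style split.
#' @param order `"standard"` splits first and applies SMOTE to the
#'   training set only; `"paper_literal"` oversamples the full table
#'   before splitting, so synthetic rows can land in the test set.
#' @param smote_k SMOTE neighbour count.
#' @param learner_specs Hyperparameters, see [default_learner_specs()].
#' @param cv_folds Folds for the accuracy-based ensemble weights.
#' @param threshold Decision threshold for probabilities.
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(max_blank = 0.30, white_threshold = 220,
                            clahe = clahe_params(),
                            features = feature_config(),
                            train_fraction = 0.8,
                            order = c("standard", "paper_literal"),
                            smote_k = 5,
                            learner_specs = default_learner_specs(),
                            cv_folds = 5, threshold = 0.5, seed = 42) {
  order <- match.arg(order)
  structure(list(max_blank = max_blank, white_threshold = white_threshold,
                 clahe = clahe, features = features,
                 train_fraction = train_fraction, order = order,
                 smote_k = smote_k, learner_specs = learner_specs,
                 cv_folds = cv_folds, threshold = threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  config$seed + switch(stage, split = 101L, smote = 202L,
                       train = 303L, weights = 404L)
}

#' Generate the default synthetic fixture
#'
#' The reference dataset every end-to-end test runs on: 25 positive
#' (coarse-texture) and 102 negative (fine-texture) tiles of 512x512
#' pixels at seed 42, mirroring the imbalance shape of the relapse
#' cohort at desk scale. Deterministic for a given seed.
#'
#' @param seed Integer seed (default 42).
#' @param dir If non-`NULL`, tiles and `manifest.csv` are written there.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A dataset list (`tiles`, `manifest`), see [generate_dataset()].
#' @export
make_fixture <- function(seed = 42, dir = NULL, ...) {
  ds <- generate_dataset(synthetic_spec(seed = seed, ...))
  if (!is.null(dir)) ds$manifest <- write_dataset(ds, dir)
  ds
}

#' Run the full two-stage classification pipeline
#'
#' Executes, in order: blank-ratio filtering, CLAHE enhancement, texture
#' feature extraction, stratified train/test split, SMOTE rebalancing of
#' the training set, training of the six base learners, accuracy-weighted
#' averaging, soft voting and hard voting, and held-out evaluation
#' (confusion-matrix metrics plus ROC/AUC) of all nine systems. The same
#' configuration and seed reproduce identical results.
#'
#' @param dataset A dataset list (`tiles` + `manifest`) as produced by
#'   [generate_dataset()] / [make_fixture()] / [read_dataset()].
#' @param config A [pipeline_config()].
#' @param output_dir If non-`NULL`, artifacts (features, split manifest,
#'   predictions, metrics JSON, ROC points, rejection log, resolved
#'   config) are written there.
#' @return A `wmcm_run` object: `metrics` (9-row tibble), `roc` (long
#'   tibble of ROC points), `weights`, `panel`, `predictions`, `features`,
#'   `split`, `rejection_log`, `config`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  tiles <- dataset$tiles
  if (length(unique(dataset$manifest$label)) < 2) {
    stop("pipeline requires both classes in the input manifest", call. = FALSE)
  }

  filt <- filter_tiles(tiles, max_blank = config$max_blank,
                       white_threshold = config$white_threshold)
  if (length(filt$kept) == 0) stop("all tiles rejected as blank", call. = FALSE)
  tiles <- filt$kept
  if (!is.null(config$clahe)) {
    tiles <- lapply(tiles, clahe, params = config$clahe)
  }

  features <- extract_features_dataset(tiles, config$features)
  if (length(unique(features$label)) < 2) {
    stop("single class left after filtering; cannot train", call. = FALSE)
  }

  if (config$order == "paper_literal") {
    features <- smote(features, k = config$smote_k,
                      seed = stage_seed(config, "smote"))
    parts <- stratified_split(features, config$train_fraction,
                              seed = stage_seed(config, "split"))
    train <- parts$train
  } else {
    parts <- stratified_split(features, config$train_fraction,
                              seed = stage_seed(config, "split"))
    train <- smote(parts$train, k = config$smote_k,
                   seed = stage_seed(config, "smote"))
  }
  test <- parts$test

  model <- train_base_learners(train, seed = stage_seed(config, "train"),
                               specs = config$learner_specs)
  weights <- derive_weights(model, train, seed = stage_seed(config, "weights"),
                            folds = config$cv_folds)
  panel <- predict_panel(model, test)

  systems <- c(stats::setNames(as.list(names(model$fits)), names(model$fits)),
               list(weighted_averaging = "weighted_averaging",
                    soft_voting = "soft_voting", hard_voting = "hard_voting"))
  scores <- c(
    lapply(stats::setNames(names(model$fits), names(model$fits)),
           function(nm) panel[[paste0("p_", nm)]]),
    list(
      weighted_averaging = weighted_average(panel, weights,
                                            config$threshold)$score,
      soft_voting = soft_vote(panel, config$threshold)$score,
      hard_voting = hard_vote(panel)$score
    )
  )
  y <- test$label
  metrics <- purrr::imap_dfr(scores, function(s, nm) {
    lbl <- as.integer(s >= config$threshold)
    cm <- confusion(y, lbl)
    ra <- roc_auc(s, y)
    dplyr::bind_cols(
      tibble::tibble(system = nm,
                     stage = ifelse(nm %in% names(model$fits),
                                    "base", "ensemble")),
      compute_metrics(cm),
      tibble::tibble(auc = ra$auc)
    )
  })
  roc_pts <- purrr::imap_dfr(scores, function(s, nm) {
    dplyr::mutate(roc_auc(s, y)$roc, system = nm, .before = 1)
  })
  predictions <- dplyr::bind_cols(
    tibble::tibble(tile_id = test$tile_id, label = y), panel,
    tibble::tibble(
      score_wavg = scores$weighted_averaging,
      score_soft = scores$soft_voting,
      votes = scores$hard_voting,
      label_wavg = as.integer(scores$weighted_averaging >= config$threshold),
      label_soft = as.integer(scores$soft_voting >= config$threshold),
      label_hard = as.integer(scores$hard_voting >= 0.5)
    )
  )

  run <- structure(
    list(metrics = metrics, roc = roc_pts, weights = weights, panel = panel,
         predictions = predictions, features = features,
         split = list(train = train, test = test),
         rejection_log = filt$log, config = config),
    class = "wmcm_run"
  )
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(run$rejection_log, file.path(dir, "rejection_log.csv"),
                   row.names = FALSE)
  split_tbl <- dplyr::bind_rows(
    dplyr::mutate(run$split$train, split = "train"),
    dplyr::mutate(run$split$test, split = "test")
  )
  utils::write.csv(split_tbl, file.path(dir, "split.csv"), row.names = FALSE)
  utils::write.csv(run$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(run$roc, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = run$metrics,
         weights = as.list(stats::setNames(as.numeric(run$weights),
                                           names(run$weights)))),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  cfg <- run$config
  cfg$clahe <- unclass(cfg$clahe)
  cfg$features <- unclass(cfg$features)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.wmcm_run <- function(x, ...) {
  cat("<wmcm_run>\n")
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  cat(sprintf("  %d systems evaluated on %d held-out tiles\n",
              nrow(x$metrics), nrow(x$predictions)))
  cat(sprintf("  best: %s (accuracy %.2f%%, AUC %.3f)\n",
              best$system, best$accuracy, best$auc))
  invisible(x)
}
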
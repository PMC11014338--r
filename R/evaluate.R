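#' Repeated random-split evaluation
#'
#' Repeats the 70/30 random split `n_repeats` times; each repeat
#' re-assigns the split *and* re-initializes weights (fresh seed per
#' repeat), trains one model per feature and evaluates test-split R²,
#' MAE and RMSE. Training failures in a repeat are recorded, not fatal.
#'
#' @param dataset Labeled dataset.
#' @param features Feature names to evaluate.
#' @param n_repeats Number of repeats (default 10).
#' @param test_frac Test fraction (default 0.3).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param structures Named list (by feature) of [structure_spec()]s, or a
#'   single spec used for all.
#' @param config A [train_config()] (its `seed` is overridden per repeat).
#' @return List with `runs` (long data.frame of per-repeat metric rows)
#'   and `summary` (per-feature mean and n-1 SD of test R²).
#' @export
repeated_split_eval <- function(dataset, features, n_repeats = 10,
                                test_frac = 0.3, seed = 0L,
                                structures = structure_spec(7),
                                config = train_config()) {
  runs <- list()
  for (r in seq_len(n_repeats)) {
    ds <- assign_split(dataset, test_frac = test_frac, seed = seed + r)
    for (f in features) {
      spec <- if (inherits(structures, "structure_spec")) structures else
        structures[[f]]
      cfg <- config; cfg$seed <- as.integer(seed + 1000L * r)
      row <- tryCatch({
        model <- train_localizer(ds, f, spec, cfg)
        te <- dataset_matrix(ds, f, "test")
        pred <- predict(model, te$X)
        cbind(metric_report(f, "test", te$y, pred$coord,
                            dataset$sampling_rate),
              repeat_id = r, error = NA_character_)
      }, error = function(e)
        data.frame(feature = f, split = "test", r2 = NA, mae_samples = NA,
                   mae_ms = NA, rmse_samples = NA, rmse_ms = NA, n = NA,
                   repeat_id = r, error = conditionMessage(e)))
      runs[[length(runs) + 1]] <- row
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(features, function(f) {
    v <- runs$r2[runs$feature == f & !is.na(runs$r2)]
    s <- if (length(v) >= 2) summarize_runs(v) else
      list(mean = NA_real_, sample_sd = NA_real_)
    data.frame(feature = f, mean_r2 = s$mean, sd_r2 = s$sample_sd,
               n_runs = length(v))
  }))
  list(runs = runs, summary = summary)
}

#' k-fold cross-validation
#'
#' Seed-deterministic disjoint folds (sizes differing by at most one);
#' each fold serves once as the test set. Per-feature fold R² values are
#' summarized with [summarize_runs()] (n-1 SD).
#'
#' @param dataset Labeled dataset.
#' @param features Feature names.
#' @param k Number of folds (default 5); requires `n >= k`.
#' @param seed Fold-assignment seed.
#' @param structures Per-feature named list of specs or a single spec.
#' @param config A [train_config()].
#' @return List with `fold_assignment`, `folds` (long data.frame of
#'   per-fold rows) and `summary` (per-feature mean/SD of fold R²).
#' @export
kfold_cv <- function(dataset, features, k = 5, seed = 0L,
                     structures = structure_spec(7),
                     config = train_config()) {
  n <- length(dataset$segments)
  if (n < k) stop("n = ", n, " < k = ", k)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = n))
  rows <- list()
  for (fold in seq_len(k)) {
    ds <- dataset
    ds$split <- ifelse(fold_of == fold, "test", "train")
    for (f in features) {
      spec <- if (inherits(structures, "structure_spec")) structures else
        structures[[f]]
      cfg <- config; cfg$seed <- as.integer(seed + 1000L * fold)
      row <- tryCatch({
        model <- train_localizer(ds, f, spec, cfg)
        te <- dataset_matrix(ds, f, "test")
        pred <- predict(model, te$X)
        cbind(metric_report(f, paste0("fold", fold), te$y, pred$coord,
                            dataset$sampling_rate), error = NA_character_)
      }, error = function(e)
        data.frame(feature = f, split = paste0("fold", fold), r2 = NA,
                   mae_samples = NA, mae_ms = NA, rmse_samples = NA,
                   rmse_ms = NA, n = NA, error = conditionMessage(e)))
      rows[[length(rows) + 1]] <- row
    }
  }
  folds <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(features, function(f) {
    v <- folds$r2[folds$feature == f & !is.na(folds$r2)]
    s <- if (length(v) >= 2) summarize_runs(v) else
      list(mean = NA_real_, sample_sd = NA_real_)
    data.frame(feature = f, mean_r2 = s$mean, sd_r2 = s$sample_sd,
               n_folds = length(v))
  }))
  list(fold_assignment = fold_of, folds = folds, summary = summary)
}
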
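#' End-to-end run configuration
#'
#' Bundles every stage's parameters. One master seed deterministically
#' derives all module seeds (phantom cohort, split shuffle, augmentation
#' noise, weight initialization, training order), so a full run is
#' reproducible bit for bit from `seed` alone.
#'
#' @param n_patients phantom cohort size.
#' @param per_patient_slices bladder-bearing slices per patient (scalar or
#'   vector, see [generate_cohort()]).
#' @param phantom base [phantom_config()].
#' @param rule [threshold_rule()] for label generation.
#' @param aug [augmentation_config()] applied to the training side only.
#' @param train_fraction patient-level split fraction in (0, 1);
#'   default 0.8 (the conventional 80/20 split).
#' @param margin context slices around foreground runs (see
#'   [extract_bladder_slices()]).
#' @param model [model_spec()]; its input size must equal the phantom's
#'   in-plane CT shape.
#' @param train [train_spec()].
#' @param seed master seed.
#' @return A `suvseg_run_config`.
#' @export
run_config <- function(n_patients = 4L, per_patient_slices = 4L,
                       phantom = phantom_config(),
                       rule = threshold_rule(),
                       aug = default_aug_config(),
                       train_fraction = 0.8, margin = 0L,
                       model = model_spec("fcn8s",
                                          input_size = phantom$ct_shape[2:3],
                                          width_scale = 0.125),
                       train = train_spec(iterations = 100L),
                       seed = 1L) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop_suvseg("train_fraction must lie strictly between 0 and 1",
                class = "suvseg_config_error")
  }
  if (!all(model$input_size == phantom$ct_shape[2:3])) {
    stop_suvseg("model input size must match the phantom in-plane shape",
                class = "suvseg_config_error")
  }
  structure(list(n_patients = as.integer(n_patients),
                 per_patient_slices = per_patient_slices,
                 phantom = phantom, rule = rule, aug = aug,
                 train_fraction = train_fraction, margin = as.integer(margin),
                 model = model, train = train, seed = as.integer(seed)),
            class = "suvseg_run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_suvseg(sprintf("pipeline stage '%s' failed: %s", stage,
                        conditionMessage(e)), class = "suvseg_pipeline_error")
  })
}

#' Run the full pipeline: phantom -> labels -> split -> augment -> train ->
#' evaluate
#'
#' Augmentation is applied to the training side only; the test side is
#' never augmented. Writes (when `out_dir` is given) the train/test slice
#' manifests, the trained model (`model.rds`) and a machine-readable JSON
#' run report with per-stage counts, derived seeds and mean metrics.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (must be empty or absent unless
#'   `overwrite = TRUE`).
#' @param overwrite allow writing into an existing nonempty directory.
#' @return The run report, invisibly a list:
#'   counts per stage, derived seeds, loss trace, metric means and the
#'   evaluated per-slice table.
#' @export
run_pipeline <- function(config, out_dir = NULL, overwrite = FALSE) {
  stopifnot(inherits(config, "suvseg_run_config"))
  if (!is.null(out_dir) && dir.exists(out_dir) &&
      length(dir(out_dir)) > 0L && !overwrite) {
    stop_suvseg("output directory exists and is not empty: ", out_dir,
                class = "suvseg_io_error")
  }
  seeds <- list(cohort = derive_seed(config$seed, "cohort"),
                split = derive_seed(config$seed, "split"),
                augment = derive_seed(config$seed, "augment"),
                init = derive_seed(config$seed, "init"),
                train = derive_seed(config$seed, "train"))

  cohort <- run_stage("phantom", generate_cohort(
    config$n_patients, config$per_patient_slices,
    base_config = config$phantom, seed = seeds$cohort))

  pairs <- run_stage("labels", {
    unlist(lapply(cohort, function(cs) {
      make_labels(cs$pet, cs$ct, config$rule, margin = config$margin)
    }), recursive = FALSE)
  })

  sp <- run_stage("split", split_by_patient(pairs, config$train_fraction,
                                            seed = seeds$split))

  aug_cfg <- config$aug
  aug_cfg$rng_seed <- seeds$augment
  train_pairs <- run_stage("augment", augment_dataset(sp$train, aug_cfg))

  model <- run_stage("model", build_model(config$model, seed = seeds$init))
  tr_spec <- config$train
  tr_spec$seed <- seeds$train
  fit <- run_stage("train", train_model(model, train_pairs, tr_spec))

  report_metrics <- run_stage("evaluate", {
    ev_pairs <- lapply(sp$test, function(p) {
      list(pred = predict_mask(fit$model, p$image), gt = p$mask)
    })
    evaluate_cohort(ev_pairs)
  })

  report <- list(
    counts = list(n_patients = config$n_patients,
                  n_label_slices = length(pairs),
                  n_train_slices = length(sp$train),
                  n_test_slices = length(sp$test),
                  n_augmented = length(train_pairs),
                  magnification = length(train_pairs) / length(sp$train)),
    seeds = c(master = config$seed, seeds),
    config = list(family = config$model$family,
                  input_size = config$model$input_size,
                  width_scale = config$model$width_scale,
                  threshold_fraction = config$rule$fraction,
                  train_fraction = config$train_fraction,
                  iterations = tr_spec$iterations,
                  learning_rate = tr_spec$learning_rate),
    loss_trace = fit$loss_trace,
    metrics_mean = as.list(report_metrics$means),
    metrics_excluded = as.list(report_metrics$n_excluded))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_slice_dataset(train_pairs, file.path(out_dir, "train"),
                         overwrite = overwrite)
    export_slice_dataset(sp$test, file.path(out_dir, "test"),
                         overwrite = overwrite)
    saveRDS(fit$model, file.path(out_dir, "model.rds"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report$per_slice <- report_metrics$per_pair
  invisible(report)
}
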
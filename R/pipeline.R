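# Pipeline orchestration: a single structured configuration drives
# chainable, independently runnable steps (simulate, preprocess,
# features, encode, train, evaluate, report). Every step logs a manifest
# (seed, config hash, package version) so each artifact is re-derivable
# from raw input + config + seed alone.

#' Default pipeline configuration
#'
#' Nested sections mirror the pipeline stages; every default equals the
#' package's fixed design values. Unknown keys are rejected by
#' [validate_pipeline_config()].
#'
#' @param overrides Named nested list of overrides, e.g.
#'   `list(train = list(max_epochs = 5))`.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    simulate = list(n_per_class = 20, seed = 1L, duration_min = 22,
                    variability_factor = 0.5, accel_factor = 0.25,
                    decel_factor = 3),
    preprocess = list(max_interp_s = 15, segment_len = 2400,
                      quality_cap = 0.10),
    features = list(apen_m = 2, apen_r_factor = 0.2),
    encode = list(encoders = default_encoders(), size = 64),
    train = list(model = "combined", fusion = "softmax", lr = 1e-4,
                 decay = 1e-4 / 200, max_epochs = 100, batch_size = 32,
                 patience = 2, val_fraction = 0.1, train_fraction = 0.8,
                 seed = 1L),
    evaluate = list(repetitions = 30, alpha = 0.01))
  cfg <- .merge_config(cfg, overrides)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", nm)
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks section and key names against the schema of
#' [pipeline_config()] and basic value sanity; stops with the list of
#' violations otherwise.
#'
#' @param cfg A nested configuration list.
#' @return The validated config, invisibly.
#' @export
validate_pipeline_config <- function(cfg) {
  schema <- list(
    simulate = c("n_per_class", "seed", "duration_min", "variability_factor",
                 "accel_factor", "decel_factor"),
    preprocess = c("max_interp_s", "segment_len", "quality_cap"),
    features = c("apen_m", "apen_r_factor"),
    encode = c("encoders", "size"),
    train = c("model", "fusion", "lr", "decay", "max_epochs", "batch_size",
              "patience", "val_fraction", "train_fraction", "seed"),
    evaluate = c("repetitions", "alpha"))
  bad <- character(0)
  for (sec in names(cfg)) {
    if (!sec %in% names(schema)) { bad <- c(bad, sec); next }
    extra <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(extra)) bad <- c(bad, paste0(sec, "$", extra))
  }
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!cfg$train$model %in% c("mlp", "cnn", "combined"))
    stop("train$model must be one of mlp, cnn, combined")
  if (!all(cfg$encode$encoders %in% encoder_names()))
    stop("unknown encoder name(s) in encode$encoders")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

.write_manifest <- function(dir, step, cfg, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- list(step = step,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
            seed = seed,
            config_hash = .config_hash(cfg),
            package_version = as.character(utils::packageVersion("fhrfusion")))
  jsonlite::write_json(m, file.path(dir, paste0("manifest_", step, ".json")),
                       auto_unbox = TRUE, null = "null")
}

.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # small rolling hash; stable across sessions
  v <- utf8ToInt(s)
  sprintf("%08x", Reduce(function(h, c) (h * 31 + c) %% 2147483647,
                         as.numeric(v), accumulate = FALSE))
}

#' Run one pipeline step
#'
#' Dispatches to the step implementations; paths name the input/output
#' artifacts each step consumes and produces.
#'
#' @param name One of `"simulate"`, `"preprocess"`, `"features"`,
#'   `"encode"`, `"train"`, `"evaluate"`, `"report"`.
#' @param cfg A [pipeline_config()].
#' @param paths Named list of paths; the steps use `records_dir`,
#'   `segments_dir`, `features_file`, `stacks_file`, `model_dir`,
#'   `eval_dir`, `report_file` as applicable.
#' @return Step-dependent value, invisibly.
#' @export
run_pipeline_step <- function(name, cfg = pipeline_config(), paths = list()) {
  name <- match.arg(name, c("simulate", "preprocess", "features", "encode",
                            "train", "evaluate", "report"))
  switch(name,
    simulate = pipe_simulate(cfg, paths$records_dir),
    preprocess = pipe_preprocess(cfg, paths$records_dir, paths$segments_dir),
    features = pipe_features(cfg, paths$segments_dir, paths$features_file),
    encode = pipe_encode(cfg, paths$segments_dir, paths$stacks_file),
    train = pipe_train(cfg, paths$features_file, paths$stacks_file,
                       paths$model_dir),
    evaluate = pipe_evaluate(cfg, paths$model_dir, paths$eval_dir),
    report = pipe_report(paths$eval_dir, paths$report_file))
}

#' @rdname run_pipeline_step
#' @param records_dir Output directory for simulated records.
#' @export
pipe_simulate <- function(cfg, records_dir) {
  sc <- cfg$simulate
  healthy <- synth_config(duration_min = sc$duration_min)
  patho <- pathological_config(healthy,
                               variability_factor = sc$variability_factor,
                               accel_factor = sc$accel_factor,
                               decel_factor = sc$decel_factor)
  ds <- generate_dataset(sc$n_per_class, healthy, patho, seed = sc$seed)
  for (r in ds$records) write_ctg_record(r, records_dir)
  .write_manifest(records_dir, "simulate", cfg, seed = sc$seed)
  message(sprintf("simulate: wrote %d records to %s",
                  length(ds$records), records_dir))
  invisible(length(ds$records))
}

.list_records <- function(dir) {
  f <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  f[!grepl("_events\\.csv$", f)]
}

#' @rdname run_pipeline_step
#' @param segments_dir Directory for clean segment files.
#' @export
pipe_preprocess <- function(cfg, records_dir, segments_dir) {
  files <- .list_records(records_dir)
  if (length(files) == 0) stop("no record CSV files found in ", records_dir)
  pc <- cfg$preprocess
  n_seg <- 0L
  for (f in files) {
    rec <- read_ctg_record(f)
    segs <- tryCatch(
      preprocess_record(rec, max_interp_s = pc$max_interp_s,
                        segment_len = pc$segment_len,
                        quality_cap = pc$quality_cap),
      error = function(e) list())
    for (s in segs) { write_segment(s, segments_dir); n_seg <- n_seg + 1L }
  }
  .write_manifest(segments_dir, "preprocess", cfg)
  message(sprintf("preprocess: %d records -> %d segments", length(files), n_seg))
  invisible(n_seg)
}

#' @rdname run_pipeline_step
#' @param features_file Output CSV path for the feature table.
#' @export
pipe_features <- function(cfg, segments_dir, features_file) {
  files <- sort(list.files(segments_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no segment files found in ", segments_dir)
  segs <- lapply(files, read_segment)
  tab <- feature_table(segs, apen_m = cfg$features$apen_m,
                       apen_r_factor = cfg$features$apen_r_factor)
  dir.create(dirname(features_file), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tab, features_file, row.names = FALSE)
  .write_manifest(dirname(features_file), "features", cfg)
  message(sprintf("features: %d segments -> %s", nrow(tab), features_file))
  invisible(tab)
}

#' @rdname run_pipeline_step
#' @param stacks_file Output path (`.rds`) for the image-stack container.
#' @export
pipe_encode <- function(cfg, segments_dir, stacks_file) {
  files <- sort(list.files(segments_dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no segment files found in ", segments_dir)
  segs <- lapply(files, read_segment)
  enc <- cfg$encode$encoders
  size <- cfg$encode$size
  arr <- array(0, c(size, size, length(enc), length(segs)))
  ids <- character(length(segs))
  labels <- integer(length(segs))
  for (i in seq_along(segs)) {
    arr[, , , i] <- encode_stack(segs[[i]], enc, size = size)
    ids[i] <- sprintf("%s_seg%06d", segs[[i]]$record_id,
                      segs[[i]]$start_offset)
    labels[i] <- segs[[i]]$label
  }
  dir.create(dirname(stacks_file), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(ids = ids, labels = labels, encoders = enc, images = arr),
          stacks_file)
  .write_manifest(dirname(stacks_file), "encode", cfg)
  message(sprintf("encode: %d stacks (%s) -> %s", length(segs),
                  paste(enc, collapse = "+"), stacks_file))
  invisible(stacks_file)
}

# Align features and stacks on segment id; returns model inputs.
.load_inputs <- function(cfg, features_file, stacks_file) {
  need_tab <- cfg$train$model %in% c("mlp", "combined")
  need_img <- cfg$train$model %in% c("cnn", "combined")
  feats <- stacks <- NULL
  if (need_tab || !is.null(features_file)) {
    feats <- utils::read.csv(features_file)
    feats$seg_id <- sprintf("%s_seg%06d", feats$record_id, feats$start_offset)
  }
  if (need_img) {
    stacks <- readRDS(stacks_file)
    if (!is.null(feats)) {
      common <- intersect(feats$seg_id, stacks$ids)
      feats <- feats[match(common, feats$seg_id), ]
      sel <- match(common, stacks$ids)
      stacks$images <- stacks$images[, , , sel, drop = FALSE]
      stacks$labels <- stacks$labels[sel]
      stacks$ids <- stacks$ids[sel]
    }
  }
  labels <- if (!is.null(feats)) feats$label else stacks$labels
  list(features_raw = if (!is.null(feats))
         as.matrix(feats[, feature_names()]) else NULL,
       images = if (!is.null(stacks)) stacks$images else NULL,
       labels = as.integer(labels))
}

#' @rdname run_pipeline_step
#' @param model_dir Output directory for the trained model and history.
#' @export
pipe_train <- function(cfg, features_file, stacks_file, model_dir) {
  tc <- cfg$train
  inp <- .load_inputs(cfg, features_file, stacks_file)
  n <- length(inp$labels)
  set.seed(tc$seed)
  test_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    cand <- which(inp$labels == cl)
    test_idx <- c(test_idx, sample(cand, round(length(cand) * (1 - tc$train_fraction))))
  }
  tr_idx <- setdiff(seq_len(n), test_idx)

  scaler <- NULL
  x_tr <- x_te <- list()
  if (!is.null(inp$features_raw)) {
    scaler <- fit_feature_scaler(inp$features_raw[tr_idx, , drop = FALSE])
    x_tr$features <- apply_feature_scaler(scaler, inp$features_raw[tr_idx, , drop = FALSE])
    x_te$features <- apply_feature_scaler(scaler, inp$features_raw[test_idx, , drop = FALSE])
  }
  if (!is.null(inp$images)) {
    x_tr$images <- inp$images[, , , tr_idx, drop = FALSE]
    x_te$images <- inp$images[, , , test_idx, drop = FALSE]
  }
  n_ch <- if (!is.null(inp$images)) dim(inp$images)[3] else length(cfg$encode$encoders)
  spec <- switch(tc$model,
                 mlp = mlp_spec(),
                 cnn = cnn_spec(n_channels = n_ch),
                 combined = combined_spec(n_channels = n_ch,
                                          fusion = tc$fusion))
  tcfg <- training_config(lr = tc$lr, decay = tc$decay,
                          max_epochs = tc$max_epochs,
                          batch_size = tc$batch_size, patience = tc$patience,
                          val_fraction = tc$val_fraction, seed = tc$seed)
  xin_tr <- if (tc$model == "mlp") x_tr$features
            else if (tc$model == "cnn") x_tr$images else x_tr
  model <- build_model(spec, seed = tc$seed)
  model <- train_model(model, xin_tr, inp$labels[tr_idx], tcfg)

  dir.create(model_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(model = model, scaler = scaler, test_idx = test_idx,
               x_te = x_te, y_te = inp$labels[test_idx], cfg = cfg),
          file.path(model_dir, "model.rds"))
  utils::write.csv(model$history, file.path(model_dir, "history.csv"),
                   row.names = FALSE)
  .write_manifest(model_dir, "train", cfg, seed = tc$seed)
  message(sprintf("train: %s model, %d train / %d test, stopped at epoch %d",
                  tc$model, length(tr_idx), length(test_idx),
                  max(model$history$epoch)))
  invisible(file.path(model_dir, "model.rds"))
}

#' @rdname run_pipeline_step
#' @param eval_dir Output directory for evaluation artifacts.
#' @export
pipe_evaluate <- function(cfg, model_dir, eval_dir) {
  st <- readRDS(file.path(model_dir, "model.rds"))
  tc <- st$cfg$train
  xin <- if (tc$model == "mlp") st$x_te$features
         else if (tc$model == "cnn") st$x_te$images else st$x_te
  p <- predict_proba(st$model, xin)
  cmr <- confusion_matrix(st$y_te, as.integer(p[, 2] > p[, 1]))
  rep <- classification_metrics(cmr, scores = p[, 2], truth = st$y_te)
  dir.create(eval_dir, showWarnings = FALSE, recursive = TRUE)
  keys <- c("ACC", "TPR", "TNR", "PPV", "NPV", "FPR", "FNR", "FDR", "AUC")
  df <- data.frame(model = tc$model, n_test = length(st$y_te),
                   TP = cmr$TP, FN = cmr$FN, FP = cmr$FP, TN = cmr$TN)
  for (k in keys) df[[k]] <- rep[[k]]
  utils::write.csv(df, file.path(eval_dir, "metrics.csv"), row.names = FALSE)
  .write_manifest(eval_dir, "evaluate", cfg)
  message(sprintf("evaluate: accuracy %.3f on %d test segments",
                  rep$ACC, length(st$y_te)))
  invisible(df)
}

#' @rdname run_pipeline_step
#' @param report_file Output text file for the summary table.
#' @export
pipe_report <- function(eval_dir, report_file) {
  df <- utils::read.csv(file.path(eval_dir, "metrics.csv"))
  lines <- c("Confusion matrix (positive = pathological)",
             sprintf("  %-10s TP=%d FN=%d FP=%d TN=%d", df$model,
                     df$TP, df$FN, df$FP, df$TN),
             "",
             "Performance metrics",
             paste0("  ", paste(c("model", "ACC", "TPR", "TNR", "PPV", "NPV",
                                  "FPR", "FNR", "FDR", "AUC"),
                                collapse = "\t")),
             sprintf("  %s\t%s", df$model,
                     paste(sprintf("%.2f", as.numeric(
                       df[1, c("ACC", "TPR", "TNR", "PPV", "NPV",
                               "FPR", "FNR", "FDR", "AUC")])),
                       collapse = "\t")))
  dir.create(dirname(report_file), showWarnings = FALSE, recursive = TRUE)
  writeLines(lines, report_file)
  message("report: wrote ", report_file)
  invisible(report_file)
}
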
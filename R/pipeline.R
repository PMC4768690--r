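#' Pipeline run configuration
#'
#' Collects every tunable parameter of the STFT-DA pipeline with its
#' standard default, validating each against the module preconditions.
#'
#' @param threshold Binarization threshold in (0, 1).
#' @param min_area Minimum object area in pixels.
#' @param ordering Contour sample ordering, `"traversal"` or
#'   `"angle_sorted"`.
#' @param resample_n Resampled contour length.
#' @param window Window kind, one of [window_kinds()].
#' @param window_length Window length in samples.
#' @param overlap Overlapping samples between segments.
#' @param shape_param Optional window shape parameter.
#' @param nfft DFT length (`NULL` = automatic).
#' @param zscore_ddof 1 for sample or 0 for population standard deviation in
#'   the feature z-scores.
#' @param feature_set `"combined"` (default, 32 features), `"abs_only"` or
#'   `"ang_only"` (16 features each).
#' @param prior Discriminant priors, `"uniform"` or `"empirical"`.
#' @param ridge Ridge factor for an ill-conditioned pooled covariance.
#' @param seed Integer seed recorded with outputs.
#' @return A named list of class `"stftda_config"`.
#' @export
stftda_config <- function(threshold = 0.1, min_area = 50000,
                          ordering = "traversal", resample_n = 1000,
                          window = "gaussian", window_length = 100,
                          overlap = 40, shape_param = NULL, nfft = NULL,
                          zscore_ddof = 1, feature_set = "combined",
                          prior = "uniform", ridge = 0, seed = 1) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  if (min_area < 1) stop("min_area must be >= 1", call. = FALSE)
  ordering <- match.arg(ordering, c("traversal", "angle_sorted"))
  if (resample_n < 4) stop("resample_n must be >= 4", call. = FALSE)
  if (!(window %in% window_kinds())) {
    stop("unknown window kind: ", window, call. = FALSE)
  }
  if (overlap < 0 || overlap >= window_length) {
    stop("overlap must satisfy 0 <= overlap < window_length", call. = FALSE)
  }
  if (window_length > resample_n) {
    stop("window_length must not exceed resample_n", call. = FALSE)
  }
  if (!zscore_ddof %in% c(0, 1)) {
    stop("zscore_ddof must be 0 or 1", call. = FALSE)
  }
  feature_set <- match.arg(feature_set,
                           c("combined", "abs_only", "ang_only"))
  prior <- match.arg(prior, c("uniform", "empirical"))
  structure(
    list(threshold = threshold, min_area = min_area, ordering = ordering,
         resample_n = resample_n, window = window,
         window_length = window_length, overlap = overlap,
         shape_param = shape_param, nfft = nfft, zscore_ddof = zscore_ddof,
         feature_set = feature_set, prior = prior, ridge = ridge,
         seed = as.integer(seed)),
    class = "stftda_config"
  )
}

#' @export
print.stftda_config <- function(x, ...) {
  cat("STFT-DA pipeline configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-14s %s\n", k,
                if (is.null(v)) "auto" else paste(v, collapse = " ")))
  }
  invisible(x)
}

# select feature columns for the configured feature set
select_features <- function(feats, feature_set) {
  switch(feature_set,
         combined = feats$combined,
         abs_only = {
           v <- feats$max_abs
           names(v) <- sprintf("MAX_ABS_%02d", seq_along(v))
           v
         },
         ang_only = {
           v <- feats$max_ang
           names(v) <- sprintf("MAX_ANG_%02d", seq_along(v))
           v
         })
}

#' Feature vector of a single image
#'
#' Runs the full contour + spectral pipeline on one intensity matrix.
#'
#' @param img Numeric intensity matrix in `[0, 1]`.
#' @param config Pipeline configuration, see [stftda_config()].
#' @return Named numeric feature vector (length 32 for the combined set,
#'   16 otherwise).
#' @export
image_features <- function(img, config = stftda_config()) {
  sig <- image_to_signal(img, threshold = config$threshold,
                         min_area = config$min_area,
                         ordering = config$ordering)
  feats <- signal_to_features(
    sig, resample_n = config$resample_n, window = config$window,
    length = config$window_length, overlap = config$overlap,
    nfft = config$nfft, shape_param = config$shape_param,
    ddof = config$zscore_ddof
  )
  select_features(feats, config$feature_set)
}

#' Feature table of a set of in-memory images
#'
#' @param images Named list of intensity matrices.
#' @param config Pipeline configuration.
#' @param on_error `"stop"` or `"skip"` (skipped images are reported via
#'   the `"failures"` attribute).
#' @return Data frame with columns `image_id, f01, f02, ...`.
#' @export
features_from_images <- function(images, config = stftda_config(),
                                 on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("img_%03d", seq_along(images))
  rows <- list()
  failures <- list()
  for (i in seq_along(images)) {
    fv <- tryCatch(image_features(images[[i]], config), error = identity)
    if (inherits(fv, "error")) {
      if (on_error == "stop") {
        stop("feature extraction failed for '", ids[i], "': ",
             conditionMessage(fv), call. = FALSE)
      }
      failures[[ids[i]]] <- conditionMessage(fv)
      next
    }
    row <- as.data.frame(as.list(fv))
    names(row) <- sprintf("f%02d", seq_along(fv))
    rows[[ids[i]]] <- cbind(data.frame(image_id = ids[i],
                                       stringsAsFactors = FALSE), row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Extract features from image files
#'
#' Command-level operation: reads every image, extracts its feature vector
#' and returns (optionally writes) the feature table. Per-image failures are
#' recorded and reported; the call fails only if every image fails.
#'
#' @param paths Character vector of image paths, or a single directory
#'   (scanned for PNG/TIFF/JPEG files).
#' @param config Pipeline configuration.
#' @param labels Optional vector of class labels (recycled against `paths`
#'   after directory expansion is not supported: supply one per file).
#' @param out_csv Optional output CSV path.
#' @return Data frame `image_id[, label], f01...`; failures in the
#'   `"failures"` attribute.
#' @export
cmd_extract <- function(paths, config = stftda_config(), labels = NULL,
                        out_csv = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
  }
  if (length(paths) == 0L) {
    stop("no readable images supplied", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(paths)) {
    stop("labels must match the number of image files", call. = FALSE)
  }
  ids <- tools::file_path_sans_ext(basename(paths))
  rows <- list()
  failures <- list()
  for (i in seq_along(paths)) {
    fv <- tryCatch(image_features(read_gray_image(paths[i]), config),
                   error = identity)
    if (inherits(fv, "error")) {
      failures[[ids[i]]] <- conditionMessage(fv)
      message("extract: skipping '", ids[i], "': ", conditionMessage(fv))
      next
    }
    row <- as.data.frame(as.list(fv))
    names(row) <- sprintf("f%02d", seq_along(fv))
    meta <- data.frame(image_id = ids[i], stringsAsFactors = FALSE)
    if (!is.null(labels)) meta$label <- labels[i]
    rows[[ids[i]]] <- cbind(meta, row)
  }
  if (length(rows) == 0L) {
    stop("feature extraction failed for every image", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
  }
  out
}

feature_columns <- function(df) {
  grep("^f[0-9]+$", names(df), value = TRUE)
}

#' Train a model from a feature table
#'
#' @param features Feature data frame (from [cmd_extract()] or a CSV read
#'   with the same schema) with a `label` column and `f..` feature columns.
#' @param config Pipeline configuration (priors, ridge; echoed into the
#'   model file).
#' @param out_json Optional path to save the model as JSON.
#' @return A fitted `"stftda"` model.
#' @export
cmd_train <- function(features, config = stftda_config(), out_json = NULL) {
  if (is.character(features)) features <- utils::read.csv(features)
  fcols <- feature_columns(features)
  if (length(fcols) == 0L || !"label" %in% names(features)) {
    stop("feature table must have a 'label' column and f01.. columns",
         call. = FALSE)
  }
  model <- stftda.default(as.matrix(features[, fcols]), features$label,
                          prior = config$prior, ridge = config$ridge)
  if (!is.null(out_json)) write_stftda(model, out_json, config = config)
  model
}

#' Predict labels for a feature table
#'
#' @param model A fitted `"stftda"` model or a path to a model JSON.
#' @param features Feature data frame or CSV path.
#' @param out_csv Optional output CSV (`image_id, predicted` + scores).
#' @return Data frame of predictions with per-class discriminant scores.
#' @export
cmd_predict <- function(model, features, out_csv = NULL) {
  if (is.character(model)) model <- read_stftda(model)
  if (is.character(features)) features <- utils::read.csv(features)
  fcols <- feature_columns(features)
  pr <- predict(model, as.matrix(features[, fcols]), type = "both")
  out <- data.frame(
    image_id = if ("image_id" %in% names(features)) features$image_id
               else seq_len(nrow(features)),
    predicted = as.character(pr$class),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(pr$scores))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Evaluate a model on a labelled feature table
#'
#' @param model A fitted `"stftda"` model or model JSON path.
#' @param features Labelled feature data frame or CSV path (needs a `label`
#'   column).
#' @param out_csv Optional path for the confusion matrix CSV.
#' @return List with `confusion`, `accuracy`, `accuracy_pct` and
#'   `per_class` accuracies.
#' @export
cmd_evaluate <- function(model, features, out_csv = NULL) {
  if (is.character(model)) model <- read_stftda(model)
  if (is.character(features)) features <- utils::read.csv(features)
  if (!"label" %in% names(features)) {
    stop("feature table must have a 'label' column", call. = FALSE)
  }
  fcols <- feature_columns(features)
  ev <- evaluate(model, as.matrix(features[, fcols]), features$label)
  ev$per_class <- class_accuracy(ev$confusion)
  if (!is.null(out_csv)) {
    utils::write.csv(as.data.frame(unclass(ev$confusion)), out_csv)
  }
  ev
}

#' Window-function and feature-set ablation sweeps
#'
#' Re-runs feature extraction and classification for every window kind (or
#' every feature set) on a fixed train/test split of resampled contour
#' signals, reporting the overall test accuracy per condition — the
#' classical ablation used to select the Gaussian window and the combined
#' 32-feature descriptor.
#'
#' @param train_signals,test_signals Lists of resampled numeric signals
#'   (each of length `config$resample_n`).
#' @param train_labels,test_labels Matching class labels.
#' @param what `"windows"` (16 rows) or `"feature_sets"` (3 rows).
#' @param config Base pipeline configuration.
#' @param windows Optional subset of window kinds to sweep.
#' @return Data frame with columns `condition` and `accuracy_pct`.
#' @export
cmd_sweep <- function(train_signals, train_labels, test_signals, test_labels,
                      what = c("windows", "feature_sets"),
                      config = stftda_config(), windows = window_kinds()) {
  what <- match.arg(what)
  sig_feats <- function(sig, cfg) {
    feats <- signal_to_features(
      sig, resample_n = cfg$resample_n, window = cfg$window,
      length = cfg$window_length, overlap = cfg$overlap, nfft = cfg$nfft,
      shape_param = cfg$shape_param, ddof = cfg$zscore_ddof
    )
    select_features(feats, cfg$feature_set)
  }
  run_one <- function(cfg) {
    xtr <- t(vapply(train_signals, sig_feats, numeric(feat_len(cfg)), cfg))
    xte <- t(vapply(test_signals, sig_feats, numeric(feat_len(cfg)), cfg))
    model <- stftda.default(xtr, train_labels, prior = cfg$prior,
                            ridge = cfg$ridge)
    evaluate(model, xte, test_labels)$accuracy_pct
  }
  feat_len <- function(cfg) {
    S <- (cfg$resample_n - cfg$overlap) %/% (cfg$window_length - cfg$overlap)
    if (cfg$feature_set == "combined") 2L * S else S
  }
  if (what == "windows") {
    conds <- windows
    acc <- vapply(conds, function(wk) {
      cfg <- config
      cfg$window <- wk
      cfg$shape_param <- NULL  # each window's standard shape default
      run_one(cfg)
    }, numeric(1))
  } else {
    conds <- c("abs_only", "ang_only", "combined")
    acc <- vapply(conds, function(fs) {
      cfg <- config
      cfg$feature_set <- fs
      run_one(cfg)
    }, numeric(1))
  }
  data.frame(condition = conds, accuracy_pct = as.numeric(acc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Resampled contour signals of a set of images
#'
#' Helper for [cmd_sweep()]: runs the contour stage once per image so that
#' repeated window sweeps do not repeat the (comparatively expensive)
#' segmentation.
#'
#' @param images Named list of intensity matrices.
#' @param config Pipeline configuration.
#' @return Named list of numeric signals of length `config$resample_n`.
#' @export
signals_from_images <- function(images, config = stftda_config()) {
  lapply(images, function(img) {
    resample_fft(
      image_to_signal(img, threshold = config$threshold,
                      min_area = config$min_area,
                      ordering = config$ordering),
      config$resample_n
    )
  })
}

#' Published reference confusion matrices
#'
#' Confusion matrices reported by the original STFT-DA study (Gaussian
#' window, 100-sample segments with 40-sample overlap, combined 32-feature
#' descriptor) for three fish families and their combination, shipped as
#' plain-text data. They serve as worked examples for the accuracy
#' arithmetic; reproducing them requires the study's otolith photographs,
#' which are not distributed with this package.
#'
#' @param dataset One of `"engraulidae"`, `"sciaenidae"`, `"ariidae"`,
#'   `"all_families"`.
#' @return A `"confusion_matrix"` object.
#' @export
reference_confusion <- function(dataset = c("engraulidae", "sciaenidae",
                                            "ariidae", "all_families")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0("confusion_", dataset, ".csv"),
                      package = "stftda", mustWork = TRUE)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  structure(m, dimnames = list(target = rownames(df),
                               predicted = colnames(df)),
            class = c("confusion_matrix", "matrix"))
}
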
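#' Random Forest configuration
#'
#' @param n_trees Number of trees in the ensemble.
#' @param max_features Number of features drawn at random as split
#'   candidates at each node (at most 16).
#' @param max_depth Maximum tree depth; 0 means unlimited.
#' @param min_samples_leaf Minimum samples per leaf.
#' @param seed Integer seed making training deterministic.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100, max_features = 4, max_depth = 0,
                          min_samples_leaf = 1, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (max_features < 1 || max_features > 16)
    stop("max_features must be in [1, 16]")
  structure(
    list(n_trees = as.integer(n_trees), max_features = as.integer(max_features),
         max_depth = as.integer(max_depth),
         min_samples_leaf = as.integer(min_samples_leaf),
         seed = as.integer(seed)),
    class = "forest_config"
  )
}

strip_second_index <- function(features) {
  features[, setdiff(names(features), "second_index"), drop = FALSE]
}

#' Fit the Random Forest motion classifier
#'
#' An ensemble of CART-style decision trees, each grown on a bootstrap
#' sample of the seconds with a random subset of features considered at
#' every split; per-second class probabilities are the average of the
#' trees' leaf class frequencies. Fitting is delegated to
#' \pkg{ranger}; the returned model records the feature ordering (and
#' validates it at prediction time) plus the out-of-bag probabilities
#' used for training ROC analysis.
#'
#' @param features Data frame of per-second features (a `second_index`
#'   column, if present, is dropped).
#' @param labels Integer 0/1 motion truth labels, one per row.
#' @param cfg A [forest_config].
#' @return An object of class `motion_model`.
#' @export
fit_forest <- function(features, labels, cfg = forest_config()) {
  x <- strip_second_index(as.data.frame(features))
  if (nrow(x) != length(labels))
    stop("features and labels differ in length")
  if (length(unique(labels)) < 2)
    stop("single-class training data: cannot fit a binary classifier")
  y <- factor(labels, levels = c(0, 1))
  rf <- ranger::ranger(
    x = x, y = y,
    num.trees = cfg$n_trees,
    mtry = min(cfg$max_features, ncol(x)),
    max.depth = cfg$max_depth,
    min.node.size = cfg$min_samples_leaf,
    probability = TRUE,
    seed = cfg$seed,
    num.threads = 1
  )
  structure(
    list(rf = rf, feature_names = names(x), cfg = cfg,
         oob_probs = rf$predictions[, "1"]),
    class = "motion_model"
  )
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf("<motion_model: %d trees, mtry %d, %d features>\n",
              x$cfg$n_trees, x$cfg$max_features, length(x$feature_names)))
  invisible(x)
}

#' Predict the per-second motion probability signal
#'
#' The probability for each second is the mean over trees of the tree's
#' motion-class probability.
#'
#' @param model A `motion_model` from [fit_forest()].
#' @param features Data frame with exactly the training feature columns.
#' @param threshold Optional operating threshold stored in the signal.
#' @return An object of class `probability_signal`: list with `probs`
#'   (values in `[0, 1]`) and `threshold`.
#' @export
predict_proba <- function(model, features, threshold = NULL) {
  x <- strip_second_index(as.data.frame(features))
  if (!identical(names(x), model$feature_names)) {
    missing <- setdiff(model$feature_names, names(x))
    extra <- setdiff(names(x), model$feature_names)
    stop("feature columns do not match training: ",
         if (length(missing)) paste0("missing [", paste(missing, collapse = ", "), "] "),
         if (length(extra)) paste0("unexpected [", paste(extra, collapse = ", "), "] "),
         "expected order: ", paste(model$feature_names, collapse = ", "))
  }
  p <- predict(model$rf, data = x, num.threads = 1)$predictions[, "1"]
  structure(list(probs = as.numeric(p), threshold = threshold),
            class = "probability_signal")
}

#' Per-tree motion probabilities
#'
#' Matrix of each individual tree's motion-class probability per second;
#' row means reproduce [predict_proba()].
#'
#' @param model A `motion_model`.
#' @param features Data frame with the training feature columns.
#' @return Numeric matrix, seconds by trees.
#' @export
predict_proba_per_tree <- function(model, features) {
  x <- strip_second_index(as.data.frame(features))
  p <- predict(model$rf, data = x, num.threads = 1, predict.all = TRUE)$predictions
  cls <- dimnames(p)[[2]]
  if (is.null(cls)) cls <- colnames(model$rf$predictions)
  p[, which(cls == "1"), , drop = TRUE]
}

#' Threshold a probability signal into motion labels
#'
#' Motion is flagged iff the probability is strictly greater than the
#' threshold; ties at the threshold are classified as no-motion.
#'
#' @param signal A `probability_signal` or numeric probability vector.
#' @param threshold Operating threshold in `[0, 1]`; defaults to the
#'   threshold stored in the signal.
#' @return Integer vector of 0/1 predicted labels.
#' @export
classify_motion <- function(signal, threshold = NULL) {
  p <- if (inherits(signal, "probability_signal")) signal$probs else signal
  if (is.null(threshold) && inherits(signal, "probability_signal"))
    threshold <- signal$threshold
  if (is.null(threshold)) stop("no threshold supplied or stored")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  as.integer(p > threshold)
}

MODEL_FORMAT_VERSION <- 1L

#' Persist / restore a trained motion model
#'
#' The file embeds the forest, the feature ordering, every configuration
#' used to produce the training features, and training provenance;
#' [predict_proba()] refuses to run when feature names mismatch.
#'
#' @param model A `motion_model`.
#' @param path Output path.
#' @param denoise_cfg,feature_cfg Configurations recorded for provenance.
#' @return `path`, invisibly (write); the restored model (read).
#' @export
write_motion_model <- function(model, path, denoise_cfg = NULL,
                               feature_cfg = NULL) {
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = model,
               denoise_cfg = denoise_cfg, feature_cfg = feature_cfg,
               created = as.character(Sys.time()),
               r_version = R.version.string),
          path)
  invisible(path)
}

#' @rdname write_motion_model
#' @export
read_motion_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION))
    stop("unsupported model file version: ", obj$format_version)
  obj
}
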
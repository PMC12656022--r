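# RBF-SVM detector: standardization, grid-searched training, persistence.

C_GRID <- c(0.01, 0.1, 1, 10, 100)
GAMMA_GRID <- c(0.001, 0.01, 0.1, 1)
MODEL_FORMAT_VERSION <- 1L

fit_standardizer <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- 1   # zero-variance features pass through
  list(center = center, scale = scale)
}

apply_standardizer <- function(std, x) {
  sweep(sweep(as.matrix(x), 2L, std$center, "-"), 2L, std$scale, "/")
}

# F1 with FoG (1) as the positive class; no predicted or true positives -> 0.
f1_score <- function(truth, pred) {
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds, so every fold's class mix is within one window
# of the global prevalence.
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Train the FoG detector with a hyperparameter grid search
#'
#' Fits an RBF-kernel SVM over the full 5 x 4 grid of regularization
#' parameter C in \{0.01, 0.1, 1, 10, 100\} and kernel coefficient gamma in
#' \{0.001, 0.01, 0.1, 1\}. Each grid point is scored by stratified k-fold
#' cross-validation (k = 5) using the mean F1 score across folds, FoG as
#' the positive class; ties break toward smaller C, then smaller gamma.
#' The winning point is retrained on the whole training set. Features are
#' z-scored with a standardizer fitted on the training matrix (never on
#' test data) and stored in the model.
#'
#' @param features M x p numeric matrix, columns in [feature_names()] order.
#' @param labels binary vector of length M (1 = FoG).
#' @param k cross-validation folds (default 5).
#' @param seed integer seed controlling fold assignment; with a fixed seed
#'   training is fully reproducible.
#' @param class_weights optional inverse-prevalence class weighting
#'   (default off, mirroring stratification-only handling of imbalance).
#' @return A `fog_detector` with elements `standardizer`, `svm`,
#'   `chosen_c`, `chosen_gamma`, `cv_f1`, `feature_order`, `grid`.
#' @export
grid_search_train <- function(features, labels, k = 5L, seed = 1L,
                              class_weights = FALSE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  m <- nrow(features)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; need both FoG and normal")
  if (m < k) stop("need at least k = ", k, " rows, got ", m)
  std <- fit_standardizer(features)
  z <- apply_standardizer(std, features)
  folds <- stratified_folds(labels, k, seed)
  cw <- if (class_weights) {
    w <- m / (2 * table(factor(labels, levels = c(0L, 1L))))
    stats::setNames(as.numeric(w), c("0", "1"))
  } else NULL
  best <- list(f1 = -Inf, c = NA_real_, gamma = NA_real_)
  for (cc in C_GRID) for (gg in GAMMA_GRID) {
    f1s <- vapply(seq_len(k), function(fold) {
      tr <- folds != fold
      if (length(unique(labels[tr])) < 2L) return(0)
      fit <- e1071::svm(z[tr, , drop = FALSE],
                        factor(labels[tr], levels = c(0L, 1L)),
                        kernel = "radial", cost = cc, gamma = gg,
                        scale = FALSE, class.weights = cw)
      pred <- as.integer(as.character(
        stats::predict(fit, z[!tr, , drop = FALSE])))
      f1_score(labels[!tr], pred)
    }, numeric(1))
    f1 <- mean(f1s)
    if (f1 > best$f1 + 1e-12) best <- list(f1 = f1, c = cc, gamma = gg)
  }
  final <- e1071::svm(z, factor(labels, levels = c(0L, 1L)),
                      kernel = "radial", cost = best$c, gamma = best$gamma,
                      scale = FALSE, class.weights = cw)
  structure(
    list(standardizer = std, svm = final, chosen_c = best$c,
         chosen_gamma = best$gamma, cv_f1 = best$f1,
         feature_order = colnames(features),
         grid = list(c = C_GRID, gamma = GAMMA_GRID),
         seed = seed, version = MODEL_FORMAT_VERSION),
    class = "fog_detector")
}

#' @export
print.fog_detector <- function(x, ...) {
  cat("<fog_detector> RBF-SVM, C = ", x$chosen_c, ", gamma = ",
      x$chosen_gamma, ", cv F1 = ", round(x$cv_f1, 3), ", ",
      length(x$feature_order), " features, ", nrow(x$svm$SV),
      " support vectors\n", sep = "")
  invisible(x)
}

#' Classify feature rows with a trained detector
#'
#' @param object a `fog_detector`.
#' @param features matrix (or named vector for one window) whose columns
#'   match the model's stored feature order.
#' @param ... unused.
#' @return list with `label` (1 = FoG iff `score > 0`) and `score` (signed
#'   decision value, positive toward FoG).
#' @export
predict.fog_detector <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, 1L,
                                                 dimnames = list(NULL, names(features)))
  features <- as.matrix(features)
  if (ncol(features) != length(object$feature_order))
    stop("expected ", length(object$feature_order), " features, got ",
         ncol(features))
  if (!is.null(colnames(features))) {
    mism <- which(colnames(features) != object$feature_order)
    if (length(mism))
      stop("feature order mismatch at column ", mism[1L], ": expected '",
           object$feature_order[mism[1L]], "', got '",
           colnames(features)[mism[1L]], "'")
  }
  z <- apply_standardizer(object$standardizer, features)
  pr <- stats::predict(object$svm, z, decision.values = TRUE)
  # libsvm orients decision values toward whichever class it saw first in
  # the training data (the column name records the pair, e.g. "0/1"):
  # orient so positive scores always mean FoG.
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  score <- if (identical(first, "1")) as.numeric(dv) else -as.numeric(dv)
  list(label = as.integer(score > 0), score = score)
}

#' Persist / restore a detector
#'
#' `save_model()` writes a self-contained archive (`path`) plus a JSON
#' metadata sidecar (`path`.json) recording the format version, feature
#' order, hyperparameter grids, seed, chosen point and CV F1 — enough to
#' audit a model without loading it. `load_model()` refuses archives whose
#' version or feature order disagrees with the sidecar, preventing
#' train/serve feature skew.
#'
#' @param model a `fog_detector`.
#' @param path archive path; the sidecar is written next to it.
#' @return `save_model()`: `path` invisibly. `load_model()`: the restored
#'   `fog_detector`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fog_detector"))
  meta <- list(format_version = model$version,
               feature_order = model$feature_order,
               grid = model$grid, seed = model$seed,
               chosen_c = model$chosen_c, chosen_gamma = model$chosen_gamma,
               cv_f1 = model$cv_f1)
  saveRDS(model, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "fog_detector")) stop("not a fog_detector archive")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(as.integer(meta$format_version),
                   as.integer(model$version)))
      stop("model format version mismatch: archive ", model$version,
           ", sidecar ", meta$format_version)
    if (!identical(as.character(meta$feature_order), model$feature_order))
      stop("feature order in sidecar disagrees with archive; refusing to ",
           "load a model with possible feature skew")
  }
  model
}
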
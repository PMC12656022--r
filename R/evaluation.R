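# Window-level evaluation: confusion metrics, LOPO and repeated stratified
# split regimes, permutation feature importance.

#' Window-level classification metrics from confusion counts
#'
#' Sensitivity = tp/(tp+fn) (fraction of true FoG windows detected),
#' specificity = tn/(tn+fp), precision = tp/(tp+fp), F1 = harmonic mean of
#' precision and sensitivity, accuracy, and window-level prevalence
#' (tp+fn)/total. Ratios with a zero denominator are reported as 0 and the
#' metric name is listed in `undefined`.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts; total must be positive.
#' @return list with `metrics` (named numeric), the counts, and
#'   `undefined` (character vector of flagged metric names).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero")
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f1 <- if (prec + sens == 0) { undefined <- c(undefined, "f1"); 0 }
        else 2 * prec * sens / (prec + sens)
  list(metrics = c(sensitivity = sens, specificity = spec,
                   precision = prec, f1 = f1,
                   accuracy = (tp + tn) / total,
                   prevalence = (tp + fn) / total),
       counts = counts, undefined = undefined)
}

METRIC_NAMES <- c("sensitivity", "specificity", "precision", "f1",
                  "accuracy", "prevalence")

report_row <- function(subject, cm, flagged = FALSE) {
  data.frame(subject_id = subject, t(cm$metrics),
             tp = cm$counts[["tp"]], fp = cm$counts[["fp"]],
             tn = cm$counts[["tn"]], fn = cm$counts[["fn"]],
             flagged = flagged || length(cm$undefined) > 0,
             row.names = NULL)
}

new_eval_report <- function(rows, regime) {
  agg <- list(mean = colMeans(rows[METRIC_NAMES]),
              sd = apply(rows[METRIC_NAMES], 2L, stats::sd))
  structure(list(rows = rows, aggregate = agg, regime = regime),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> regime: ", x$regime, ", ", nrow(x$rows),
      " subject row(s)\n", sep = "")
  print(cbind(x$rows["subject_id"],
              round(x$rows[METRIC_NAMES], 3)), row.names = FALSE)
  cat("mean +/- sd:\n")
  print(round(rbind(mean = x$aggregate$mean, sd = x$aggregate$sd), 3))
  invisible(x)
}

batch_xy <- function(batch, include_discarded) {
  list(x = batch_features(batch, include_discarded),
       y = as.integer(batch$labels))
}

#' Leave-one-patient-out evaluation
#'
#' Trains one grid-searched detector per held-out subject on the pooled
#' windows of all other subjects, then scores the held-out subject's
#' windows: the patient-independent regime. Subjects whose held-out data
#' lack one of the two classes get a flagged row.
#'
#' @param batches list of per-subject `window_batch` objects (>= 2).
#' @param seed integer seed (fold assignment inside each grid search).
#' @param include_discarded use the 17-feature set instead of the default
#'   14.
#' @param k inner cross-validation folds for the grid search (default 5).
#' @return An `eval_report` (regime `"lopo"`) with one row per subject plus
#'   mean/sd aggregates, and a `models` attribute holding the per-fold
#'   detectors.
#' @export
lopo_evaluate <- function(batches, seed = 1L, include_discarded = FALSE,
                          k = 5L) {
  if (length(batches) < 2L)
    stop("LOPO needs at least 2 subjects, got ", length(batches))
  data <- lapply(batches, batch_xy, include_discarded = include_discarded)
  rows <- list(); models <- list()
  for (i in seq_along(batches)) {
    train_x <- do.call(rbind, lapply(data[-i], `[[`, "x"))
    train_y <- unlist(lapply(data[-i], `[[`, "y"))
    model <- grid_search_train(train_x, train_y, k = k, seed = seed)
    pred <- predict(model, data[[i]]$x)
    y <- data[[i]]$y
    cm <- confusion_metrics(tp = sum(y == 1L & pred$label == 1L),
                            fp = sum(y == 0L & pred$label == 1L),
                            tn = sum(y == 0L & pred$label == 0L),
                            fn = sum(y == 1L & pred$label == 0L))
    rows[[i]] <- report_row(batches[[i]]$subject_id, cm,
                            flagged = length(unique(y)) < 2L)
    models[[batches[[i]]$subject_id]] <- model
  }
  rep <- new_eval_report(do.call(rbind, rows), "lopo")
  attr(rep, "models") <- models
  rep
}

#' Patient-specific repeated stratified split evaluation
#'
#' Realizes the 75 % / 25 % stratified train/test regime as a repeated
#' stratified 4-fold partition: within each repeat every fold serves once
#' as the 25 % test split (so class proportions in every split are within
#' one window of the subject's overall prevalence), a grid-searched
#' detector is trained on the remaining 75 %, and the repeat's pooled
#' confusion counts are scored. Metrics are averaged across repeats.
#'
#' @param batch a single subject's `window_batch` containing both classes
#'   and at least 4 FoG windows.
#' @param train_frac training fraction; must correspond to an integer fold
#'   count (default 0.75 -> 4 folds).
#' @param repeats number of repeated partitions (default 5).
#' @param seed integer seed; the r-th repeat uses `seed + r - 1`.
#' @param include_discarded 17-feature set instead of 14.
#' @param k inner grid-search folds (default 5).
#' @return An `eval_report` (regime `"kfold"`) with one row carrying the
#'   repeat-averaged metrics and summed confusion counts.
#' @export
kfold_evaluate <- function(batch, train_frac = 0.75, repeats = 5L,
                           seed = 1L, include_discarded = FALSE, k = 5L) {
  nfolds <- 1 / (1 - train_frac)
  if (abs(nfolds - round(nfolds)) > 1e-9)
    stop("train_frac must give an integer fold count; 0.75 -> 4 folds")
  nfolds <- as.integer(round(nfolds))
  d <- batch_xy(batch, include_discarded)
  if (length(unique(d$y)) < 2L)
    stop("subject ", batch$subject_id, " has a single class")
  if (sum(d$y == 1L) < nfolds)
    stop("subject ", batch$subject_id, " has ", sum(d$y == 1L),
         " FoG windows; at least ", nfolds, " are required to stratify")
  per_repeat <- matrix(0, repeats, length(METRIC_NAMES),
                       dimnames = list(NULL, METRIC_NAMES))
  counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(d$y, nfolds, seed + r - 1L)
    # leakage guard: fold ids partition every window exactly once
    stopifnot(length(folds) == length(d$y),
              all(folds %in% seq_len(nfolds)))
    rc <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    for (fold in seq_len(nfolds)) {
      te <- folds == fold
      model <- grid_search_train(d$x[!te, , drop = FALSE], d$y[!te],
                                 k = k, seed = seed + r - 1L)
      pred <- predict(model, d$x[te, , drop = FALSE])
      y <- d$y[te]
      rc <- rc + c(tp = sum(y == 1L & pred$label == 1L),
                   fp = sum(y == 0L & pred$label == 1L),
                   tn = sum(y == 0L & pred$label == 0L),
                   fn = sum(y == 1L & pred$label == 0L))
    }
    per_repeat[r, ] <- confusion_metrics(rc[["tp"]], rc[["fp"]],
                                         rc[["tn"]], rc[["fn"]])$metrics
    counts <- counts + rc
  }
  cm <- list(metrics = colMeans(per_repeat), counts = counts,
             undefined = character(0))
  new_eval_report(report_row(batch$subject_id, cm), "kfold")
}

#' Permutation feature importance on held-out windows
#'
#' Trains one grid-searched detector on a stratified 75 % split of the
#' subject's windows, then measures, for each feature, the drop in
#' held-out F1 when that feature's column is shuffled (averaged over
#' `repeats` shuffles). Drops are clipped at zero and normalized so the
#' largest equals 1. Run on the 17-feature set by default so the retained
#' and discarded features can be compared on one map.
#'
#' @param batch a single subject's `window_batch`.
#' @param repeats shuffles per feature (default 5).
#' @param seed integer seed for the split and the shuffles.
#' @param include_discarded default `TRUE` (17 features).
#' @param k inner grid-search folds (default 5).
#' @param features optional precomputed feature matrix (one row per window
#'   of `batch`, named columns) used instead of extracting from the batch.
#' @return named numeric vector of normalized importances in \[0, 1\].
#' @export
feature_importance <- function(batch, repeats = 5L, seed = 1L,
                               include_discarded = TRUE, k = 5L,
                               features = NULL) {
  d <- if (is.null(features)) batch_xy(batch, include_discarded)
       else list(x = as.matrix(features), y = as.integer(batch$labels))
  set.seed(seed)
  folds <- stratified_folds(d$y, 4L, seed)
  te <- folds == 1L
  if (length(unique(d$y[te])) < 2L)
    stop("held-out windows have a single class; cannot score importance")
  model <- grid_search_train(d$x[!te, , drop = FALSE], d$y[!te],
                             k = k, seed = seed)
  x_te <- d$x[te, , drop = FALSE]
  y_te <- d$y[te]
  base <- f1_score(y_te, predict(model, x_te)$label)
  drops <- vapply(seq_len(ncol(x_te)), function(j) {
    f1s <- vapply(seq_len(repeats), function(r) {
      xp <- x_te
      xp[, j] <- sample(xp[, j])
      f1_score(y_te, predict(model, xp)$label)
    }, numeric(1))
    base - mean(f1s)
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (max(drops) > 0) drops <- drops / max(drops)
  stats::setNames(drops, colnames(x_te))
}

#' Cohort feature-importance map
#'
#' @param batches list of per-subject `window_batch` objects.
#' @param ... passed to [feature_importance()].
#' @return matrix, one row per subject, one column per feature, values in
#'   \[0, 1\] with each row's maximum equal to 1.
#' @export
cohort_importance <- function(batches, ...) {
  rows <- lapply(batches, feature_importance, ...)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(batches, `[[`, character(1), "subject_id")
  m
}

#' Mean gait speed of a walk test
#'
#' Convenience for the clinical walk-test arithmetic: distance divided by
#' elapsed time (e.g. a 10 m path covered in 1 min 51 s gives 0.090 m/s).
#'
#' @param distance_m path length in meters.
#' @param duration_s elapsed time in seconds.
#' @return speed in m/s.
#' @export
mean_gait_speed <- function(distance_m, duration_s) {
  if (duration_s <= 0) stop("duration must be positive")
  distance_m / duration_s
}

#' Plot per-subject metrics as grouped bars
#'
#' @param report an `eval_report` (or a list of them to place regimes side
#'   by side).
#' @param metrics which metrics to draw.
#' @return invisibly, the matrix plotted.
#' @export
plot_eval_report <- function(report,
                             metrics = c("sensitivity", "specificity",
                                         "f1")) {
  reports <- if (inherits(report, "eval_report")) list(report) else report
  m <- do.call(rbind, lapply(reports, function(r)
    stats::setNames(r$aggregate$mean[metrics],
                    paste(r$regime, metrics, sep = "."))))
  vals <- t(sapply(reports, function(r) r$aggregate$mean[metrics]))
  rownames(vals) <- vapply(reports, `[[`, character(1), "regime")
  graphics::barplot(vals, beside = TRUE, ylim = c(0, 1),
                    legend.text = rownames(vals),
                    ylab = "score", main = "Window-level FoG metrics")
  invisible(vals)
}

#' Plot a feature-importance heat map
#'
#' @param imp matrix from [cohort_importance()] (subjects x features).
#' @return invisibly, `imp`.
#' @export
plot_importance <- function(imp) {
  graphics::image(seq_len(ncol(imp)), seq_len(nrow(imp)), t(imp),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Normalized permutation importance")
  graphics::axis(1, seq_len(ncol(imp)), colnames(imp), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(imp)), rownames(imp), las = 1,
                 cex.axis = 0.7)
  invisible(imp)
}

#' Persist an evaluation report
#'
#' Writes per-subject rows as CSV and a JSON summary (regime, aggregates).
#'
#' @param report an `eval_report`.
#' @param csv_path,json_path destinations (either may be `NULL` to skip).
#' @return invisibly, `report`.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- cbind(regime = report$regime, report$rows)
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(list(regime = report$regime,
                              mean = as.list(report$aggregate$mean),
                              sd = as.list(report$aggregate$sd)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
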
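# Confusion metrics, LOPO / repeated stratified split regimes, importance.

test_that("confusion metrics follow their definitions", {
  r <- confusion_metrics(tp = 3, fp = 0, tn = 5, fn = 1)
  expect_equal(r$metrics[["sensitivity"]], 0.75)
  expect_equal(r$metrics[["specificity"]], 1)
  expect_equal(r$metrics[["precision"]], 1)
  expect_equal(r$metrics[["prevalence"]], 4 / 9)
  expect_length(r$undefined, 0L)
  # degenerate: no positives at all
  d <- confusion_metrics(0, 0, 10, 0)
  expect_equal(d$metrics[["sensitivity"]], 0)
  expect_equal(d$metrics[["specificity"]], 1)
  expect_true("sensitivity" %in% d$undefined)
  expect_error(confusion_metrics(-1, 0, 1, 0), "nonnegative")
  # F1 equals the harmonic-mean oracle on random tables
  set.seed(12)
  for (i in 1:1000) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (sum(cts) == 0) next
    r <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    p <- r$metrics[["precision"]]; s <- r$metrics[["sensitivity"]]
    f1 <- if (p + s == 0) 0 else 2 * p * s / (p + s)
    expect_equal(r$metrics[["f1"]], f1)
    expect_true(all(r$metrics >= 0 & r$metrics <= 1))
  }
})

test_that("stratified folds partition windows with balanced classes", {
  y <- c(rep(0L, 80), rep(1L, 20))
  folds <- fogcue:::stratified_folds(y, 4L, seed = 3)
  # set-algebra oracle: folds are disjoint and exhaustive
  expect_setequal(unlist(lapply(1:4, function(f) which(folds == f))),
                  seq_along(y))
  for (f in 1:4) {
    expect_equal(sum(folds == f & y == 0L), 20L)
    expect_equal(sum(folds == f & y == 1L), 5L)
  }
})

test_that("repeated stratified split evaluation is deterministic and sane", {
  b <- fixture_batch()
  r1 <- kfold_evaluate(b, repeats = 2, seed = 5, k = 3)
  r2 <- kfold_evaluate(b, repeats = 2, seed = 5, k = 3)
  expect_equal(r1$rows, r2$rows)
  expect_equal(r1$regime, "kfold")
  expect_true(all(r1$rows[fogcue:::METRIC_NAMES] >= 0 &
                    r1$rows[fogcue:::METRIC_NAMES] <= 1))
  # confusion counts cover every window exactly once per repeat
  expect_equal(sum(r1$rows[c("tp", "fp", "tn", "fn")]),
               2 * length(b$labels))
  expect_gt(r1$rows$sensitivity, 0.8)   # strongly separable simulation
  expect_error(kfold_evaluate(b, train_frac = 0.7), "integer fold")
})

test_that("kfold refuses subjects without enough FoG windows", {
  b <- fixture_batch()
  few <- b
  keep <- c(which(few$labels == 0L), which(few$labels == 1L)[1:2])
  few$windows <- few$windows[keep, ]; few$labels <- few$labels[keep]
  few$start_index <- few$start_index[keep]
  expect_error(kfold_evaluate(few), "at least 4")
})

test_that("LOPO trains one model per held-out subject, no leakage", {
  cohort <- memo("eval_cohort", function()
    lapply(simulate_cohort(3, sim_spec(duration_s = 90, fog_episodes = 2,
                                       fog_dur_range = c(4, 10)),
                           seed = 21), make_batch))
  rep <- lopo_evaluate(cohort, seed = 1, k = 3)
  expect_equal(nrow(rep$rows), 3L)
  expect_length(attr(rep, "models"), 3L)
  # every subject's windows scored exactly once across the report
  expect_equal(sum(rep$rows[c("tp", "fp", "tn", "fn")]),
               sum(vapply(cohort, function(b) length(b$labels),
                          integer(1))))
  # aggregates are the mean/sd of the rows (recomputation oracle)
  expect_equal(rep$aggregate$mean[["f1"]], mean(rep$rows$f1))
  expect_equal(rep$aggregate$sd[["f1"]], sd(rep$rows$f1))
  expect_error(lopo_evaluate(cohort[1]), "at least 2")
})

test_that("two identical subjects get identical LOPO rows", {
  b <- fixture_batch()
  b2 <- b; b2$subject_id <- "twin"
  rep <- lopo_evaluate(list(b, b2), seed = 1, k = 3)
  expect_equal(rep$rows[1, fogcue:::METRIC_NAMES],
               rep$rows[2, fogcue:::METRIC_NAMES],
               ignore_attr = TRUE)
})

test_that("permutation importance finds the informative feature", {
  # constructed experiment: only the first column separates the classes
  set.seed(44)
  n <- 160L
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, c("fi", "a", "b", "c", "d")))
  x[, 1] <- x[, 1] + 3 * y
  batch <- structure(list(windows = matrix(0, n, 4), labels = y,
                          start_index = seq_len(n), subject_id = "syn",
                          window_s = 4, step_s = 0.5, fs_hz = 64),
                     class = "window_batch")
  imp <- feature_importance(batch, repeats = 10, seed = 2, k = 3,
                            features = x)
  expect_equal(unname(imp["fi"]), 1)          # the max by construction
  expect_lt(max(imp[c("a", "b", "c", "d")]), 0.1)  # pure-noise features
  # a duplicated informative column shares the signal
  x2 <- cbind(x, fi2 = x[, 1])
  imp2 <- feature_importance(batch, repeats = 20, seed = 2, k = 3,
                             features = x2)
  expect_lt(abs(imp2[["fi2"]] - imp2[["fi"]]), 0.25)
  expect_true(all(imp2 >= 0 & imp2 <= 1))
})

test_that("gait-speed arithmetic matches the walk-test worked example", {
  expect_equal(mean_gait_speed(10, 60 + 51), 0.0901, tolerance = 1e-3)
  expect_error(mean_gait_speed(10, 0), "positive")
})

test_that("patient-specific training is at least as sensitive as LOPO", {
  # FoG signatures differ between patients, which is what makes the
  # patient-specific regime win: here the probe subject trembles in an
  # atypical band straddling the 3 Hz locomotion edge, so its Freezing
  # Index is depressed relative to the typical subjects a cross-patient
  # model is trained on. Seeded statistical test over 10 cohort draws,
  # not per-run.
  diffs <- memo("regime_diffs", function() vapply(1:10, function(i) {
    mk <- function(band, seed)
      make_batch(simulate_subject(
        sim_spec(duration_s = 90, fog_episodes = 2,
                 fog_dur_range = c(4, 10), fog_band = band,
                 noise_std = 0.05, seed = seed)))
    batches <- list(mk(c(2.3, 4.3), 300 + i),    # atypical freezer
                    mk(c(5, 8), 400 + i), mk(c(4.5, 7.5), 500 + i))
    lopo <- lopo_evaluate(batches, seed = i, k = 3)
    kf <- kfold_evaluate(batches[[1]], repeats = 2, seed = i, k = 3)
    kf$rows$sensitivity[1] - lopo$rows$sensitivity[1]
  }, numeric(1)))
  expect_gte(mean(diffs), 0)
})
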
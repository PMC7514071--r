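#' Effect-size table: Impact versus Cohen's d
#'
#' Computes the Impact effect size and both Cohen's d pooling variants for a
#' list of two-group samples. Degenerate Cohen's d cases (zero pooled SD)
#' are reported as `NA` and flagged, never coerced to a number.
#'
#' @param samples Named list of `labeled_sample` objects.
#' @param config An [impact_config()].
#' @return Data frame with one row per sample: `subset`, `impact`,
#'   `gated_zero`, `ct_diff`, `morph_diff`, `gmd_pooled`, `d_rms`,
#'   `d_n_weighted`, `d_undefined`.
#' @export
effect_size_table <- function(samples, config = impact_config()) {
  nm <- names(samples)
  if (is.null(nm)) nm <- sprintf("%03d", seq_along(samples))
  rows <- lapply(seq_along(samples), function(i) {
    s <- as_two_groups(samples[[i]])
    r <- impact(samples[[i]], config = config)
    d1 <- suppressWarnings(cohens_d(s$x1, s$x2, "rms"))
    d2 <- suppressWarnings(cohens_d(s$x1, s$x2, "n_weighted"))
    data.frame(subset = nm[i], impact = r$impact,
               gated_zero = r$gated_zero, ct_diff = r$ct_diff,
               morph_diff = r$morph_diff, gmd_pooled = r$gmd_pooled,
               d_rms = d1, d_n_weighted = d2,
               d_undefined = is.na(d1) || is.na(d2))
  })
  do.call(rbind, rows)
}

# Class-proportional subsample of a labeled_sample: round(frac * n_g) rows
# from each group.
.subsample_proportional <- function(sample, frac) {
  g <- sample$group
  idx <- unlist(lapply(unique(g), function(lev) {
    pool <- which(g == lev)
    sample(pool, max(1L, round(frac * length(pool))))
  }))
  sample[idx, , drop = FALSE]
}

#' Subsampling robustness of Impact and Cohen's d
#'
#' Monte-Carlo study of estimator stability: for each fraction, `n_runs`
#' class-proportional random subsamples are drawn and both effect sizes
#' recomputed; the mean, SD and coefficient of variation (CV% = 100 SD /
#' |mean|) across runs are reported. At fraction 1 every run uses the
#' complete data, so SD and CV are exactly 0.
#'
#' @param sample A `labeled_sample`.
#' @param fractions Vector of subsample fractions in (0, 1].
#' @param n_runs Subsamples per fraction (default 10).
#' @param config An [impact_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `fraction`, `statistic` (`"impact"` or
#'   `"cohens_d"`), `mean`, `sd`, `cv`, `n1`, `n2`, `flagged` (TRUE when a
#'   subsample had fewer than 2 observations in a group or an undefined
#'   Cohen's d).
#' @export
robustness_subsampling <- function(sample, fractions = seq(1, 0.1, by = -0.1),
                                   n_runs = 10L, config = impact_config(),
                                   seed = 1L) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  s0 <- as_two_groups(sample)
  with_seed(seed, {
    out <- lapply(fractions, function(f) {
      imp <- num_d <- numeric(n_runs)
      flagged <- FALSE
      n1 <- n2 <- NA_integer_
      for (r in seq_len(n_runs)) {
        sub <- if (f == 1) sample else .subsample_proportional(sample, f)
        ss <- as_two_groups(sub)
        n1 <- length(ss$x1)
        n2 <- length(ss$x2)
        if (n1 < 2L || n2 < 2L) flagged <- TRUE
        imp[r] <- impact(sub, config = config)$impact
        d <- suppressWarnings(cohens_d(ss$x1, ss$x2, "rms"))
        if (is.na(d)) flagged <- TRUE
        num_d[r] <- d
      }
      summarize <- function(v, name) {
        m <- mean(v)
        s <- if (f == 1) 0 else stats::sd(v)
        data.frame(fraction = f, statistic = name, mean = m, sd = s,
                   cv = if (is.na(m) || m == 0) NA_real_ else 100 * s / abs(m),
                   n1 = n1, n2 = n2, flagged = flagged)
      }
      rbind(summarize(imp, "impact"), summarize(num_d, "cohens_d"))
    })
    do.call(rbind, out)
  })
}

# Confusion-matrix metrics with group "2" as the positive class.
.classification_metrics <- function(truth, prob_pos, threshold = 0.5) {
  pred <- ifelse(prob_pos >= threshold, 2L, 1L)
  tp <- sum(pred == 2L & truth == 2L)
  tn <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 2L & truth == 1L)
  fn <- sum(pred == 1L & truth == 2L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  f1 <- if (is.na(ppv) || ppv + sens == 0) NA_real_ else
    2 * ppv * sens / (ppv + sens)
  acc <- (tp + tn) / length(truth)
  auc <- as.numeric(pROC::auc(
    pROC::roc(response = truth, predictor = prob_pos,
              levels = c(1L, 2L), direction = "<", quiet = TRUE)))
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    f1 = f1, accuracy = acc, auc = auc)
}

#' Tree and random-forest classification of the 20-variable benchmark
#'
#' Monte-Carlo cross-validation (non-overlapping stratified train/test
#' splits, default 2/3 training) of two classifiers on the
#' [make_dataset4()] matrix: a single Gini-impurity decision tree
#' ([rpart::rpart()]) and a random forest of 500 trees with `sqrt(d)`
#' features per split ([randomForest::randomForest()]). With
#' `feature_set = "reduced"` the mean-shifted variables (location block,
#' var0011-var0015) are removed, so group separation must come from
#' distribution shape alone. With `permute_control = TRUE` every feature of
#' the training split is independently permuted (test data untouched), the
#' negative control whose accuracy should fall to chance.
#'
#' @param dataset Output of [make_dataset4()].
#' @param feature_set `"full"` (all variables) or `"reduced"` (location
#'   block removed).
#' @param n_cv Number of Monte-Carlo cross-validation runs (default 100).
#' @param train_frac Training fraction (default 2/3).
#' @param permute_control Permute training features independently (default
#'   FALSE).
#' @param seed Integer seed.
#' @param ntree Trees in the forest (default 500).
#' @return List with `summary` (data frame: `classifier`, `metric`,
#'   `median`, `min`, `max`, percentages), `runs` (per-run metrics) and
#'   `metadata`.
#' @export
classification_experiment <- function(dataset,
                                      feature_set = c("full", "reduced"),
                                      n_cv = 100L, train_frac = 2 / 3,
                                      permute_control = FALSE, seed = 1L,
                                      ntree = 500L) {
  feature_set <- match.arg(feature_set)
  x <- dataset$data
  if (feature_set == "reduced") {
    x <- x[, -dataset$blocks$location, drop = FALSE]
  }
  y <- factor(dataset$group, levels = 1:2)
  mtry <- max(1L, floor(sqrt(ncol(x))))
  idx_by_class <- split(seq_along(y), y)
  runs <- with_seed(seed, {
    lapply(seq_len(n_cv), function(run) {
      train_idx <- sort(unlist(lapply(idx_by_class, function(pool) {
        sample(pool, round(train_frac * length(pool)))
      })))
      test_idx <- setdiff(seq_along(y), train_idx)
      xtr <- x[train_idx, , drop = FALSE]
      ytr <- y[train_idx]
      if (permute_control) {
        xtr[] <- lapply(xtr, sample) # each feature shuffled independently
      }
      xte <- x[test_idx, , drop = FALSE]
      yte <- as.integer(y[test_idx])

      tree <- rpart::rpart(class ~ ., data = cbind(xtr, class = ytr),
                           method = "class")
      p_tree <- stats::predict(tree, xte)[, "2"]
      rf <- randomForest::randomForest(x = xtr, y = ytr, ntree = ntree,
                                       mtry = mtry)
      p_rf <- stats::predict(rf, xte, type = "prob")[, "2"]

      rbind(
        data.frame(run = run, classifier = "tree",
                   t(.classification_metrics(yte, p_tree))),
        data.frame(run = run, classifier = "forest",
                   t(.classification_metrics(yte, p_rf)))
      )
    })
  })
  runs <- do.call(rbind, runs)
  metric_cols <- setdiff(names(runs), c("run", "classifier"))
  summary <- do.call(rbind, lapply(split(runs, runs$classifier), function(d) {
    do.call(rbind, lapply(metric_cols, function(m) {
      v <- 100 * d[[m]]
      data.frame(classifier = d$classifier[1], metric = m,
                 median = stats::median(v, na.rm = TRUE),
                 min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
    }))
  }))
  rownames(summary) <- NULL
  list(summary = summary, runs = runs,
       metadata = list(feature_set = feature_set, n_cv = n_cv,
                       train_frac = train_frac,
                       permute_control = permute_control, seed = seed,
                       ntree = ntree, mtry = mtry, d = ncol(x)))
}

#' Write an experiment report as TSV and JSON
#'
#' The tabular part (`summary` for list reports, the data frame itself
#' otherwise) is written to `<basename>.tsv`; the full report to
#' `<basename>.json`.
#'
#' @param report Data frame or list report from the experiment functions.
#' @param basename Output path without extension.
#' @return The two paths, invisibly.
#' @export
write_experiment_report <- function(report, basename) {
  tab <- if (is.data.frame(report)) report else report$summary
  tsv <- paste0(basename, ".tsv")
  json <- paste0(basename, ".json")
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = tsv, json = json))
}
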
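#' Confusion counts for a binary task
#'
#' @param truth,estimate Class labels (same level universe).
#' @param positive The positive class.
#' @return One-row tibble: `positive_class`, `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, estimate, positive) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  tibble::tibble(positive_class = positive,
                 TP = sum(truth == positive & estimate == positive),
                 FP = sum(truth != positive & estimate == positive),
                 TN = sum(truth != positive & estimate != positive),
                 FN = sum(truth == positive & estimate != positive))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' accuracy = (TP + TN) / total; sensitivity = TP / (TP + FN) (true positive
#' rate); specificity = TN / (TN + FP) (true negative rate). A zero
#' denominator yields `NA` with a warning.
#'
#' @param counts A one-row tibble as from [confusion_counts()] (or any list
#'   with TP, FP, TN, FN).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, FP, TN, FN) < 0)) abort("Negative confusion counts.")
    total <- TP + FP + TN + FN
    if (total == 0) abort("No evaluated cases.")
    ratio <- function(num, den, what) {
      if (den == 0) { warn(paste0(what, " undefined (zero denominator).")); NA_real_ }
      else num / den
    }
    tibble::tibble(accuracy = (TP + TN) / total,
                   sensitivity = ratio(TP, TP + FN, "sensitivity"),
                   specificity = ratio(TN, TN + FP, "specificity"))
  })
}

#' Pipeline configuration for nested cross-validation
#'
#' Bundles every tunable of the end-to-end pipeline. The defaults are sized
#' for synthetic desk-scale cohorts; clinical-scale selection would raise
#' the GA population toward its [ga_config()] default of 500.
#'
#' @param ga A [ga_config()] for per-group feature selection.
#' @param rcga An [rcga_config()] for kernel-weight estimation.
#' @param kernel_kinds Named kernel assignment per group (any permutation of
#'   the three kinds is valid; the default is the published assignment).
#' @param C0 Soft-margin constant.
#' @param n_folds Outer folds (reduced, with a message, when a class has
#'   fewer studies).
#' @param selection `"ga"`, `"ttest"` (screening baseline) or `"none"`.
#' @param estimate_weights Estimate beta by the real-coded GA? `FALSE` keeps
#'   uniform weights.
#' @param normalization `"fold"` (z-scoring fitted on each training fold
#'   only; leakage-free default) or `"global"` (single whole-cohort fit, the
#'   fidelity mode).
#' @param stratified Stratify the outer folds by class?
#' @param vote_rule `"vote"` (accumulated kernel votes) or `"margin"`.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(ga = ga_config(population_size = 30L,
                                           max_generations = 10L),
                            rcga = rcga_config(population_size = 10L,
                                               max_generations = 6L,
                                               cv_folds = 3L),
                            kernel_kinds = c(M = "linear", S = "polynomial2",
                                             A = "gaussian"),
                            C0 = 1, n_folds = 10L,
                            selection = c("ga", "ttest", "none"),
                            estimate_weights = TRUE,
                            normalization = c("fold", "global"),
                            stratified = TRUE,
                            vote_rule = c("vote", "margin"),
                            seed = 1L) {
  structure(list(ga = ga, rcga = rcga, kernel_kinds = kernel_kinds, C0 = C0,
                 n_folds = as.integer(n_folds),
                 selection = match.arg(selection),
                 estimate_weights = estimate_weights,
                 normalization = match.arg(normalization),
                 stratified = stratified, vote_rule = match.arg(vote_rule),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Select masks for all three groups on training data (internal).
select_masks <- function(features, config, base_seed) {
  labels <- features$labels
  groups <- c("M", "S", "A")
  masks <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    if (config$selection == "none") { masks[g] <- list(NULL); next }
    if (ncol(features[[g]]) < 2L) { masks[g] <- list(NULL); next }
    if (config$selection == "ga") {
      cfg <- config$ga
      cfg$rng_seed <- (base_seed + 101L * gi) %% .Machine$integer.max
      masks[[g]] <- run_feature_selection(features[[g]], labels, cfg, g)$bits
    } else {
      cfg <- config$ga
      cfg$rng_seed <- (base_seed + 101L * gi) %% .Machine$integer.max
      masks[[g]] <- ttest_baseline_selection(features[[g]], labels, cfg)$bits
    }
  }
  masks
}

#' Nested cross-validation of the full pipeline
#'
#' The evaluation protocol: studies are partitioned into near-equal folds;
#' for each fold, z-scoring, feature selection, kernel-weight estimation and
#' classifier training all see only the other folds' studies, and the
#' held-out studies are predicted exactly once. Pooled predictions give the
#' overall accuracy (and sensitivity/specificity for binary cohorts).
#'
#' @param features A raw [feature_groups()] with labels.
#' @param config A [pipeline_config()].
#' @param positive For binary cohorts, the positive class of the
#'   sensitivity/specificity report (default: first non-"NC" class).
#' @return An object of class `nested_cv`: `predictions` (tibble with
#'   `study_id`, `fold`, `truth`, `.pred`, vote columns), `metrics` (pooled),
#'   `fold_details` (per-fold masks sizes, beta, accuracy), `folds`,
#'   `config`.
#' @export
run_nested_cv <- function(features, config = pipeline_config(), positive = NULL) {
  labels <- features$labels
  if (is.null(labels) || nlevels(labels) < 2L)
    abort("Nested CV requires labels with >= 2 classes.")
  n <- nrow(features$M)
  k <- min(config$n_folds, min(table(labels)))
  if (k < config$n_folds)
    message("Reducing folds to ", k, " (smallest class size).")
  folds <- make_cv_folds(labels, k, seed = config$seed,
                         stratified = config$stratified)
  specs0 <- default_kernel_specs(kinds = config$kernel_kinds)
  preds <- vector("list", k)
  fold_details <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    z <- if (config$normalization == "fold")
      zscore_features(features, fit_rows = tr)
    else zscore_features(features)
    fg_tr <- fg_rows(z, tr); fg_te <- fg_rows(z, te)
    base_seed <- (config$seed + 7919L * f) %% .Machine$integer.max
    masks <- select_masks(fg_tr, config, base_seed)
    specs <- specs0
    beta <- c(M = 1, S = 1, A = 1)
    if (config$estimate_weights) {
      rc <- config$rcga
      rc$rng_seed <- (base_seed + 13L) %% .Machine$integer.max
      w <- estimate_kernel_weights(fg_tr, masks, specs, rc, C0 = config$C0)
      beta <- w$beta
      for (g in names(specs)) specs[[g]]$weight <- beta[[g]]
    }
    model <- mkl_train(fg_tr, masks, specs, C0 = config$C0)
    pr <- suppressWarnings(predict(model, fg_te, rule = config$vote_rule))
    pr$fold <- f
    pr$truth <- factor(as.character(labels[te]), levels = levels(labels))
    preds[[f]] <- pr
    fold_details[[f]] <- tibble::tibble(
      fold = f,
      n_train = length(tr), n_test = length(te),
      n_sel_M = if (is.null(masks$M)) ncol(features$M) else sum(masks$M),
      n_sel_S = if (is.null(masks$S)) ncol(features$S) else sum(masks$S),
      n_sel_A = if (is.null(masks$A)) ncol(features$A) else sum(masks$A),
      beta_M = beta[["M"]], beta_S = beta[["S"]], beta_A = beta[["A"]],
      fold_accuracy = mean(as.character(pr$.pred) == as.character(pr$truth)))
  }
  predictions <- dplyr::bind_rows(preds)
  acc <- mean(as.character(predictions$.pred) ==
                as.character(predictions$truth))
  metrics <- tibble::tibble(metric = "accuracy", value = acc)
  if (nlevels(labels) == 2L) {
    if (is.null(positive)) {
      pos_cand <- setdiff(levels(labels), "NC")
      positive <- if (length(pos_cand)) pos_cand[1] else levels(labels)[1]
    }
    cm <- classification_metrics(confusion_counts(predictions$truth,
                                                  predictions$.pred, positive))
    metrics <- tibble::tibble(metric = c("accuracy", "sensitivity", "specificity"),
                              value = c(cm$accuracy, cm$sensitivity,
                                        cm$specificity))
  }
  structure(list(predictions = predictions, metrics = metrics,
                 fold_details = dplyr::bind_rows(fold_details),
                 folds = folds, positive = positive, config = config),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat("<nested_cv> ", max(x$predictions$fold), " folds, ",
      nrow(x$predictions), " studies\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.nested_cv <- function(x, ...) x$fold_details

#' @export
glance.nested_cv <- function(x, ...) {
  tidyr::pivot_wider(x$metrics, names_from = "metric", values_from = "value") |>
    dplyr::mutate(n_studies = nrow(x$predictions),
                  n_folds = max(x$predictions$fold))
}

#' Plot nested-CV results
#'
#' @param object A `nested_cv`.
#' @param ... Unused.
#' @return A ggplot confusion-matrix tile plot of the pooled predictions.
#' @export
autoplot.nested_cv <- function(object, ...) {
  df <- dplyr::count(object$predictions, .data$truth, .data$.pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$.pred,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white") +
    ggplot2::scale_fill_gradient(low = "grey70", high = "firebrick") +
    ggplot2::labs(x = "clinical label", y = "predicted",
                  title = "Pooled nested-CV confusion") +
    ggplot2::theme_minimal()
}

#' Pairwise two-class experiments
#'
#' Runs the nested-CV protocol restricted to each class pair (AD vs NC,
#' FTD vs NC, AD vs FTD for the standard three-class cohort) and reports
#' accuracy, sensitivity and specificity per pair, with the disease class
#' (the non-NC class, else the first) as positive.
#'
#' @param features A raw [feature_groups()] with >= 2 classes.
#' @param config A [pipeline_config()].
#' @return An object of class `pairwise_experiments`: `report` (tibble:
#'   `pair`, `positive`, `metric`, `value`) and `runs` (named list of
#'   `nested_cv` objects).
#' @export
pairwise_experiments <- function(features, config = pipeline_config()) {
  lev <- levels(features$labels)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  runs <- list()
  report <- list()
  for (pr in pairs) {
    rows <- which(features$labels %in% pr)
    sub <- fg_rows(features, rows)
    run <- run_nested_cv(sub, config)
    nm <- paste(pr, collapse = ".vs.")
    runs[[nm]] <- run
    report[[nm]] <- dplyr::mutate(run$metrics, pair = nm,
                                  positive = run$positive, .before = 1)
  }
  structure(list(report = dplyr::bind_rows(report), runs = runs),
            class = "pairwise_experiments")
}

#' @export
print.pairwise_experiments <- function(x, ...) {
  print(tidyr::pivot_wider(x$report, names_from = "metric",
                           values_from = "value"))
  invisible(x)
}

#' Fraction of features rejecting mean equality between two classes
#'
#' Per feature column, a two-sample t-test of equal class means
#' (Welch by default; the pooled-variance Student variant via
#' `var_equal = TRUE`), reported as the fraction of columns with p < alpha,
#' per group and overall. No multiple-testing correction is applied by
#' default (`bonferroni = TRUE` divides alpha by the group's column count).
#' Columns constant within both classes carry no evidence and are counted
#' as non-rejecting, with a warning.
#'
#' @param features A [feature_groups()] with labels.
#' @param class_pair Character vector of the two classes to compare
#'   (`NULL` = the two classes present; an error if more).
#' @param alpha Significance level in `[0, 1)`.
#' @param var_equal Pooled-variance Student test instead of Welch?
#' @param bonferroni Apply a Bonferroni-corrected alpha per group?
#' @return Tibble: `group` (M, S, A, overall), `n_features`, `n_reject`,
#'   `fraction`.
#' @export
ttest_rejection_rate <- function(features, class_pair = NULL, alpha = 0.05,
                                 var_equal = FALSE, bonferroni = FALSE) {
  labels <- features$labels
  if (is.null(class_pair)) {
    class_pair <- levels(droplevels(labels))
    if (length(class_pair) != 2L)
      abort("Specify `class_pair` when more than two classes are present.")
  }
  if (alpha < 0 || alpha >= 1) abort("`alpha` must lie in [0, 1).")
  i1 <- which(labels == class_pair[1]); i2 <- which(labels == class_pair[2])
  if (!length(i1) || !length(i2))
    abort("Both classes of `class_pair` must be present.")
  rows <- purrr::map_dfr(c("M", "S", "A"), function(g) {
    x <- features[[g]]
    a <- if (bonferroni) alpha / ncol(x) else alpha
    n_const <- 0L
    rej <- vapply(seq_len(ncol(x)), function(j) {
      x1 <- x[i1, j]; x2 <- x[i2, j]
      if (var(x1) == 0 && var(x2) == 0) { n_const <<- n_const + 1L; return(FALSE) }
      if (a == 0) return(FALSE)
      t.test(x1, x2, var.equal = var_equal)$p.value < a
    }, logical(1))
    if (n_const > 0L)
      warn(paste0("Group ", g, ": ", n_const,
                  " zero-variance column(s) counted as non-rejecting."))
    tibble::tibble(group = g, n_features = ncol(x), n_reject = sum(rej))
  })
  out <- dplyr::bind_rows(rows,
                          tibble::tibble(group = "overall",
                                         n_features = sum(rows$n_features),
                                         n_reject = sum(rows$n_reject)))
  dplyr::mutate(out, fraction = .data$n_reject / .data$n_features)
}

#' t-test screening baseline for feature selection
#'
#' Ranks features by the magnitude of the two-sample t statistic (for more
#' than two classes, the maximum over class pairs), then performs a greedy
#' forward search down the ranking, keeping a feature whenever it strictly
#' improves the seeded cross-validated linear-SVM accuracy. The output mask
#' is interchangeable with [run_feature_selection()] masks, enabling a
#' head-to-head comparison of screening versus wrapper selection. Being
#' univariate, the ranking is blind to features that are informative only
#' jointly.
#'
#' @param x Numeric matrix (studies x features) of one feature group.
#' @param labels Class labels.
#' @param config A [ga_config()] (only `cv_folds`, `svm_C0` and `rng_seed`
#'   are used).
#' @return An object of class `ttest_selection`: `bits`, `selected`,
#'   `fitness`, `ranking` (tibble: feature, statistic, rank).
#' @export
ttest_baseline_selection <- function(x, labels, config = ga_config()) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) abort("At least 2 classes are required.")
  with_seed(config$rng_seed, {
    pairs <- utils::combn(levels(labels), 2, simplify = FALSE)
    stat <- vapply(seq_len(ncol(x)), function(j) {
      max(vapply(pairs, function(pr) {
        x1 <- x[labels == pr[1], j]; x2 <- x[labels == pr[2], j]
        if (var(x1) == 0 && var(x2) == 0) return(0)
        abs(t.test(x1, x2)$statistic)
      }, numeric(1)))
    }, numeric(1))
    rank_order <- order(stat, decreasing = TRUE)
    k <- min(config$cv_folds, min(table(labels)))
    folds <- lapply(seq_len(config$cv_repeats), function(i)
      make_cv_folds(labels, k))          # same fitness structure as the GA
    acc_of <- function(b) mean(vapply(folds, function(f)
      ga_fitness(b, x, labels, f, config$svm_C0), numeric(1)))
    bits <- integer(ncol(x))
    best_acc <- 0
    for (j in rank_order) {
      cand <- bits; cand[j] <- 1L
      acc <- acc_of(cand)
      if (acc > best_acc) { bits <- cand; best_acc <- acc }
      else break                      # forward search stops when accuracy stalls
    }
    if (all(bits == 0L)) { bits[rank_order[1]] <- 1L
      best_acc <- acc_of(bits) }
    structure(list(bits = bits, selected = which(bits != 0),
                   fitness = best_acc,
                   ranking = tibble::tibble(
                     feature = colnames(x) %||% as.character(seq_len(ncol(x))),
                     statistic = stat,
                     rank = match(seq_len(ncol(x)), rank_order))),
              class = "ttest_selection")
  })
}

#' @export
print.ttest_selection <- function(x, ...) {
  cat("<ttest_selection> ", length(x$selected), "/", length(x$bits),
      " features, CV accuracy ", formatC(x$fitness, digits = 4, format = "f"),
      "\n", sep = "")
  invisible(x)
}
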
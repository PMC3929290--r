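test_that("metrics follow their defining ratios and degenerate rules", {
  m <- classification_metrics(list(TP = 9, FN = 1, TN = 10, FP = 0))
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 1.00)
  expect_equal(m$accuracy, 0.95)
  perfect <- classification_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_true(all(unlist(perfect) == 1))
  blind <- classification_metrics(list(TP = 0, FN = 7, TN = 3, FP = 0))
  expect_equal(blind$sensitivity, 0)
  expect_warning(nd <- classification_metrics(list(TP = 0, FN = 0, TN = 4, FP = 1)),
                 "undefined")
  expect_true(is.na(nd$sensitivity))
  expect_error(classification_metrics(list(TP = -1, FN = 0, TN = 1, FP = 0)),
               "Negative")
  cc <- confusion_counts(c("AD", "AD", "NC"), c("AD", "NC", "NC"), "AD")
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 0, TN = 1, FN = 1))
})

test_that("fold assignment is a near-equal partition, stratified when asked", {
  labels <- rep(c("AD", "FTD", "NC"), times = c(17, 19, 23))
  f <- make_cv_folds(labels, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_lte(diff(range(table(f))), 1)
  for (cl in unique(labels)) {
    per_fold <- table(factor(f[labels == cl], levels = 1:10))
    expect_lte(diff(range(per_fold)), 1)   # class balanced across folds
  }
  f2 <- make_cv_folds(labels, 10, seed = 3, stratified = FALSE)
  expect_lte(diff(range(table(f2))), 1)
  expect_identical(make_cv_folds(labels, 10, seed = 3), f)
})

test_that("nested CV tests each study once and stays at chance under a label shuffle", {
  spec <- cohort_spec(n_per_class = c(AD = 10, FTD = 10, NC = 10),
                      hypometabolism_depth = 0.45, seed = 8)
  fg <- simulate_feature_table(spec)$features
  cfg <- pipeline_config(selection = "none", estimate_weights = FALSE,
                         n_folds = 5, seed = 2)
  run <- run_nested_cv(fg, cfg)
  expect_setequal(run$predictions$study_id, fg$study_id)
  expect_equal(nrow(run$predictions), 30)
  expect_gte(run$metrics$value[run$metrics$metric == "accuracy"], 0.9)
  # shuffled labels: pooled accuracy inside a generous chance band
  set.seed(77)
  fg_null <- fg
  fg_null$labels <- sample(fg$labels)
  run0 <- run_nested_cv(fg_null, cfg)
  band <- qbinom(c(0.005, 0.995), 30, 1 / 3) / 30
  acc0 <- run0$metrics$value[run0$metrics$metric == "accuracy"]
  expect_gte(acc0, band[1])
  expect_lte(acc0, band[2])
})

test_that("held-out studies never influence the trained fold model", {
  spec <- cohort_spec(n_per_class = c(AD = 8, NC = 8),
                      hypometabolism_depth = 0.3, seed = 18)
  fg <- simulate_feature_table(spec)$features
  cfg <- pipeline_config(selection = "none", estimate_weights = FALSE,
                         n_folds = 4, seed = 9)
  folds <- make_cv_folds(fg$labels, 4, seed = cfg$seed, stratified = TRUE)
  tr <- which(folds != 1)
  # model trained inside run_nested_cv for fold 1 == model trained after
  # deleting the test rows entirely
  z_all <- zscore_features(fg, fit_rows = tr)
  m_a <- mkl_train(neuromkl:::fg_rows(z_all, tr))
  fg_del <- neuromkl:::fg_rows(fg, tr)
  m_b <- mkl_train(zscore_features(fg_del))
  expect_equal(m_a$blocks, m_b$blocks, tolerance = 1e-12)
  for (k in seq_along(m_a$tasks)) {
    expect_equal(m_a$tasks[[k]]$alpha, m_b$tasks[[k]]$alpha, tolerance = 1e-8)
    expect_equal(m_a$tasks[[k]]$b, m_b$tasks[[k]]$b, tolerance = 1e-6)
  }
})

test_that("pairwise experiments report three metrics for every class pair", {
  spec <- cohort_spec(n_per_class = c(AD = 8, FTD = 8, NC = 8),
                      hypometabolism_depth = 0.5, seed = 28)
  fg <- simulate_feature_table(spec)$features
  cfg <- pipeline_config(selection = "none", estimate_weights = FALSE,
                         n_folds = 4, seed = 5)
  pw <- pairwise_experiments(fg, cfg)
  expect_equal(nrow(pw$report), 9)         # 3 pairs x 3 metrics
  expect_setequal(unique(pw$report$pair),
                  c("AD.vs.FTD", "AD.vs.NC", "FTD.vs.NC"))
  expect_true(all(pw$report$value >= 0 & pw$report$value <= 1, na.rm = TRUE))
  # disease class is the positive class against NC
  expect_equal(unique(pw$report$positive[pw$report$pair == "AD.vs.NC"]), "AD")
  # accuracy decomposes into the class-weighted sensitivity/specificity
  for (nm in names(pw$runs)) {
    run <- pw$runs[[nm]]
    wide <- tidyr::pivot_wider(run$metrics, names_from = "metric",
                               values_from = "value")
    npos <- sum(run$predictions$truth == run$positive)
    nneg <- sum(run$predictions$truth != run$positive)
    expect_equal(wide$accuracy,
                 (wide$sensitivity * npos + wide$specificity * nneg) /
                   (npos + nneg),
                 tolerance = 1e-12)
  }
})

test_that("t-test rejection fraction is calibrated at null and saturated at huge effect", {
  set.seed(91)
  # planted 5-sd shift in every column -> rejection fraction ~ 1
  n <- 30
  mk_fg <- function(shift) {
    M <- matrix(rnorm(n * 10), n); S <- matrix(abs(rnorm(n * 10)) + 1, n)
    A <- matrix(rnorm(n * 5), n)
    M[1:(n / 2), ] <- M[1:(n / 2), ] + shift
    S[1:(n / 2), ] <- S[1:(n / 2), ] + shift
    A[1:(n / 2), ] <- A[1:(n / 2), ] + shift
    feature_groups(M, S, A, paste0("s", 1:n), rep(c("AD", "NC"), each = n / 2))
  }
  r_big <- ttest_rejection_rate(mk_fg(5), c("AD", "NC"))
  expect_gte(r_big$fraction[r_big$group == "overall"], 0.99)
  r0 <- ttest_rejection_rate(mk_fg(0), c("AD", "NC"), alpha = 0)
  expect_equal(r0$fraction[r0$group == "overall"], 0)
  # zero-variance columns count as non-rejecting
  fg <- mk_fg(0); fg$M[, 1] <- 3
  expect_warning(rz <- ttest_rejection_rate(fg, c("AD", "NC")), "zero-variance")
  expect_error(ttest_rejection_rate(mk_fg(0), c("AD", "NC"), alpha = 1.2),
               "alpha")
})

test_that("t-test screening finds a lone marginal signal but misses a joint one", {
  d <- simulate_planted_features(n = 30, p = 10, informative = 4, effect = 3,
                                 seed = 51)
  cfg <- ga_config(population_size = 10, rng_seed = 6)
  sel <- ttest_baseline_selection(d$x, d$labels, cfg)
  expect_equal(sel$ranking$rank[4], 1)      # informative column ranked first
  expect_true(4 %in% sel$selected)
  # interface contract: t-test masks drive the MKL exactly like GA masks
  z <- small_zscored_cohort(n = 6)
  selM <- ttest_baseline_selection(z$M, z$labels, cfg)
  m <- mkl_train(z, masks = list(M = selM$bits))
  expect_s3_class(m, "mkl_model")
  # suppressor pair: univariate screening cannot reach the accuracy that
  # the jointly informative pair supports
  di <- simulate_interacting_features(n = 30, p_noise = 6, effect = 4,
                                      shared_sd = 10, seed = 52)
  selI <- ttest_baseline_selection(di$x, di$labels, cfg)
  joint <- integer(ncol(di$x)); joint[1:2] <- 1L
  folds <- make_cv_folds(di$labels, 10, seed = 1)
  expect_lt(mask_fitness(selI$bits, di$x, di$labels, folds),
            mask_fitness(joint, di$x, di$labels, folds))
})
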
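# Single-group blocks helper: same matrix as group M, empty-ish S/A not
# allowed, so single-group tests use specs restricted to M.
single_group_specs <- function(kind = "linear", weight = 1, sigma = NULL)
  list(M = kernel_spec("M", kind, sigma = sigma, weight = weight))

test_that("two-point problem recovers the closed-form dual solution", {
  blocks <- list(M = matrix(c(1, -1), 2, 1))
  fit <- mkl_train_binary(blocks, c(1, -1), single_group_specs(), C0 = 100)
  expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_lte(fit$kkt[["equality"]], 1e-6)
  # decision boundary at the midpoint: f(0) = 0
  f0 <- sum(fit$alpha * c(1, -1) * c(1, -1) * 0) - fit$b
  expect_equal(f0, 0, tolerance = 1e-6)
})

test_that("dual feasibility and separable consistency on random blobs", {
  set.seed(12)
  for (r in 1:5) {
    n <- 16
    x <- rbind(matrix(rnorm(n * 2, 3), n / 2), matrix(rnorm(n * 2, -3), n / 2))
    t <- rep(c(1, -1), each = n / 2)
    blocks <- list(M = x)
    fit <- mkl_train_binary(blocks, t, single_group_specs(), C0 = 10)
    expect_true(all(fit$alpha >= -1e-9 & fit$alpha <= 10 + 1e-9))
    expect_lte(fit$kkt[["equality"]], 1e-6)
    expect_lte(fit$kkt[["box"]], 1e-6)
    K <- tcrossprod(x)
    f <- as.numeric(K %*% (fit$alpha * t)) - fit$b
    expect_true(all(sign(f) == t))
  }
})

test_that("duplicating the training set leaves the decision function unchanged", {
  set.seed(14)
  x <- rbind(matrix(rnorm(10, 2), 5, 2), matrix(rnorm(10, -2), 5, 2))
  t <- rep(c(1, -1), each = 5)
  xt <- matrix(rnorm(12), 6, 2)
  sp <- single_group_specs()
  f1 <- mkl_train_binary(list(M = x), t, sp, C0 = 5)
  f2 <- mkl_train_binary(list(M = rbind(x, x)), c(t, t), sp, C0 = 5)
  K1 <- neuromkl:::kernel_matrix(sp$M, x, xt)
  K2 <- neuromkl:::kernel_matrix(sp$M, rbind(x, x), xt)
  d1 <- as.numeric(crossprod(K1, f1$alpha * t)) - f1$b
  d2 <- as.numeric(crossprod(K2, f2$alpha * c(t, t))) - f2$b
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("single-kernel training matches the reference SVM dual optimum", {
  skip_if_not_installed("e1071")
  set.seed(15)
  n <- 20
  x <- rbind(matrix(rnorm(n, 1.2), n / 2), matrix(rnorm(n, -1.2), n / 2))
  t <- rep(c(1, -1), each = n / 2)
  C0 <- 1
  mine <- mkl_train_binary(list(M = x), t, single_group_specs(), C0 = C0)
  ref <- e1071::svm(x, factor(t, levels = c(1, -1)), kernel = "linear",
                    cost = C0, scale = FALSE, tolerance = 1e-8)
  # same dual objective value at both solutions
  K <- tcrossprod(x)
  dual_obj <- function(a) sum(a) - 0.5 * sum((a * t) %o% (a * t) * K)
  a_ref <- rep(0, n)
  a_ref[ref$index] <- abs(ref$coefs)
  expect_equal(dual_obj(mine$alpha), dual_obj(a_ref), tolerance = 1e-6)
  # the (unique) primal weight vector agrees up to solver tolerance; the
  # bias is compared separately since both solvers reconstruct it from
  # (possibly different) support-vector subsets
  w_mine <- crossprod(x, mine$alpha * t)
  w_ref <- crossprod(x, a_ref * t)
  expect_equal(as.numeric(w_mine), as.numeric(w_ref), tolerance = 1e-4)
  expect_equal(mine$b, -ref$rho, tolerance = 0.2)
  f_mine <- as.numeric(K %*% (mine$alpha * t)) - mine$b
  f_ref <- as.numeric(K %*% (a_ref * t)) - (-ref$rho)
  expect_true(all(sign(f_mine) == sign(f_ref)))
})

test_that("multi-class training satisfies per-task dual constraints", {
  z <- small_zscored_cohort(n = 6)
  m <- mkl_train(z, specs = default_kernel_specs())
  expect_length(m$tasks, 3)
  for (task in m$tasks) {
    expect_lte(task$kkt[["equality"]], 1e-6)
    expect_true(all(task$alpha >= 0 & task$alpha <= m$C0 + 1e-9))
  }
  td <- tidy(m)
  expect_equal(nrow(td), 3)
  expect_true(all(td$n_support >= 1))
  expect_error(mkl_train(simulate_feature_table(
    cohort_spec(n_per_class = c(AD = 3, NC = 3), seed = 1))$features),
    "z-scored")
})

test_that("vote prediction follows accumulated kernel similarity", {
  z <- small_zscored_cohort(n = 6, depth = 0.5)
  m <- mkl_train(z)
  pr <- suppressWarnings(predict(m, z))
  # training data on a well-separated cohort is classified correctly
  expect_gte(mean(as.character(pr$.pred) == as.character(z$labels)), 0.9)
  expect_true(all(c("vote_AD", "vote_FTD", "vote_NC") %in% names(pr)))
  expect_error(predict(m, simulate_feature_table(
    cohort_spec(n_per_class = c(AD = 3, FTD = 3, NC = 3), seed = 2))$features),
    "z-scored")
})

test_that("scaling all kernel weights leaves predicted labels unchanged", {
  z <- small_zscored_cohort(n = 5, depth = 0.3)
  sp1 <- default_kernel_specs(weights = c(M = 0.7, S = 1.3, A = 2))
  sp2 <- default_kernel_specs(weights = 17 * c(M = 0.7, S = 1.3, A = 2))
  # fix the bandwidth so both machines see the same geometry
  sig <- median_heuristic_sigma(z$A)
  sp1$A$sigma <- sp2$A$sigma <- sig
  p1 <- suppressWarnings(predict(mkl_train(z, specs = sp1), z))
  p2 <- suppressWarnings(predict(mkl_train(z, specs = sp2), z))
  expect_equal(as.character(p1$.pred), as.character(p2$.pred))
})

test_that("accumulated-vote and one-vs-one margin rules agree on separable data", {
  spec <- cohort_spec(n_per_class = c(AD = 12, FTD = 12, NC = 12),
                      hypometabolism_depth = 0.5, seed = 31)
  z <- zscore_features(simulate_feature_table(spec)$features)
  m <- mkl_train(z)
  test_spec <- spec; test_spec$seed <- 99
  zt <- zscore_features(simulate_feature_table(test_spec)$features)
  pv <- suppressWarnings(predict(m, zt, rule = "vote"))
  pm <- suppressWarnings(predict(m, zt, rule = "margin"))
  expect_gte(mean(as.character(pv$.pred) == as.character(pm$.pred)), 0.95)
})

test_that("kernel-weight search is deterministic and beats uniform weights on its folds", {
  # mild reduction: accuracy below ceiling, so the weight search has signal
  spec <- cohort_spec(n_per_class = c(AD = 12, NC = 12),
                      hypometabolism_depth = 0.05, asymmetry_delta = 0,
                      seed = 41)
  z <- zscore_features(simulate_feature_table(spec)$features)
  cfg <- rcga_config(population_size = 8, max_generations = 4, cv_folds = 3,
                     rng_seed = 5)
  w1 <- estimate_kernel_weights(z, config = cfg)
  w2 <- estimate_kernel_weights(z, config = cfg)
  expect_identical(w1$beta, w2$beta)
  expect_true(all(w1$beta > 0 & w1$beta <= cfg$beta_max))
  # CV accuracy at the returned beta >= at uniform beta, on the same folds
  # (kernel geometry — bandwidth and trace scale — resolved once on the
  # full cohort, exactly as inside the estimator)
  eval_beta <- function(beta) {
    sp <- neuromkl:::resolve_specs(default_kernel_specs(weights = beta),
                                   neuromkl:::masked_blocks(z, list()))
    correct <- 0
    for (f in sort(unique(w1$folds))) {
      tr <- which(w1$folds != f); te <- which(w1$folds == f)
      mm <- mkl_train(neuromkl:::fg_rows(z, tr), specs = sp)
      pr <- suppressWarnings(predict(mm, neuromkl:::fg_rows(z, te)))
      correct <- correct + sum(as.character(pr$.pred) ==
                                 as.character(z$labels[te]))
    }
    correct / length(w1$folds)
  }
  expect_gte(w1$fitness, eval_beta(c(M = 1, S = 1, A = 1)) - 1e-9)
  expect_equal(w1$fitness, eval_beta(w1$beta), tolerance = 1e-9)
})

test_that("model JSON round trip reproduces predictions exactly", {
  z <- small_zscored_cohort(n = 5)
  m <- mkl_train(z)
  p <- withr::local_tempfile(fileext = ".json")
  write_mkl_model(m, p)
  m2 <- read_mkl_model(p)
  pr1 <- suppressWarnings(predict(m, z))
  pr2 <- suppressWarnings(predict(m2, z))
  expect_equal(pr1$.pred, pr2$.pred)
  expect_equal(pr1$vote_AD, pr2$vote_AD, tolerance = 1e-12)
})
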
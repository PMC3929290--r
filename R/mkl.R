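#' Train one binary soft-margin multi-kernel SVM (dual QP)
#'
#' Solves the box-constrained dual of the soft-margin SVM,
#' maximize `sum(alpha) - 1/2 sum_ij alpha_i alpha_j t_i t_j K(i, j)`
#' subject to `0 <= alpha_i <= C0` and `sum(alpha_i t_i) = 0`, with `K` the
#' beta-weighted combined Gram over the feature groups. The QP is solved by
#' an interior-point method ([kernlab::ipop()]); if the solver reports a
#' non-positive-definite system the Gram diagonal is jittered (starting at
#' 1e-10) and the solve retried. The bias is recovered from the margin
#' support vectors (`0 < alpha_i < C0`); if none exist it falls back to the
#' midpoint of the decision-value bounds, with a warning.
#'
#' @param blocks Named list of numeric matrices (cases x features), one per
#'   group in `specs`.
#' @param t Labels in `{-1, +1}` (both present).
#' @param specs Named list of [kernel_spec()] with resolved `sigma`.
#' @param C0 Soft-margin constant (> 0).
#' @param tol Interior-point significant-digit target (passed as
#'   `sigf`-compatible precision; KKT equality residual is checked against
#'   1e-6).
#' @return List: `alpha` (length n, clipped to the box), `b` (bias),
#'   `support` (indices with alpha > 0), `kkt` (named residuals:
#'   `equality` = |sum alpha t|, `box` = max box violation before clipping),
#'   `objective` (dual objective at the solution).
#' @export
mkl_train_binary <- function(blocks, t, specs, C0 = 1, tol = 1e-8) {
  t <- as.numeric(t)
  if (!all(t %in% c(-1, 1)) || length(unique(t)) < 2L)
    abort("`t` must contain both -1 and +1.")
  n <- length(t)
  G <- combined_gram(specs, blocks)
  H <- (t %o% t) * G
  jitter <- 0
  sol <- NULL
  for (attempt in 1:6) {
    sol <- tryCatch(
      kernlab::ipop(c = rep(-1, n), H = H + diag(jitter, n),
                    A = matrix(t, 1), b = 0, r = 0,
                    l = rep(0, n), u = rep(C0, n),
                    sigf = 9, maxiter = 400),
      error = function(e) e)
    if (!inherits(sol, "error") &&
        kernlab::how(sol) %in% c("converged", "primal and dual feasible"))
      break
    jitter <- if (jitter == 0) 1e-10 else jitter * 100
  }
  if (inherits(sol, "error"))
    abort(paste0("Dual QP solve failed: ", conditionMessage(sol)))
  alpha_raw <- as.numeric(kernlab::primal(sol))
  box_viol <- max(0, max(-alpha_raw), max(alpha_raw - C0))
  alpha <- pmin(pmax(alpha_raw, 0), C0)
  alpha[alpha < 1e-8 * C0] <- 0
  f0 <- as.numeric(G %*% (alpha * t))          # decision values without bias
  margin <- which(alpha > 1e-6 * C0 & alpha < (1 - 1e-6) * C0)
  if (length(margin)) {
    b <- mean(f0[margin] - t[margin])
  } else {
    warn("No margin support vectors; bias set from decision-value bounds.")
    up <- f0[t == 1]; dn <- f0[t == -1]
    b <- (max(dn) + min(up)) / 2
  }
  obj <- sum(alpha) - 0.5 * sum((alpha * t) * f0)
  list(alpha = alpha, b = b, support = which(alpha > 0),
       kkt = c(equality = abs(sum(alpha * t)), box = box_viol),
       objective = obj)
}

# Masked, per-group blocks from a z-scored feature_groups (internal).
masked_blocks <- function(features, masks, groups = c("M", "S", "A")) {
  out <- lapply(setNames(groups, groups), function(g) {
    x <- features[[g]]
    bits <- masks[[g]]
    if (is.null(bits)) x else x[, which(bits != 0), drop = FALSE]
  })
  out
}

#' Train the multi-kernel SVM classifier
#'
#' Fits one-vs-one binary multi-kernel SVMs over all class pairs, sharing a
#' single kernel assignment and weight vector beta across tasks. Gaussian
#' bandwidths left unset are resolved by [median_heuristic_sigma()] on the
#' group's masked training block.
#'
#' @param features A z-scored [feature_groups()] with labels (>= 2 classes).
#' @param masks Named list of binary masks per group (`NULL` entries keep
#'   all columns), e.g. from [run_feature_selection()] `$bits`.
#' @param specs Named list of [kernel_spec()]; see [default_kernel_specs()].
#' @param C0 Soft-margin constant.
#' @return An object of class `mkl_model`.
#' @export
mkl_train <- function(features, masks = list(), specs = default_kernel_specs(),
                      C0 = 1) {
  if (features$normalization != "zscored")
    abort("`features` must be z-scored before training (see zscore_features()).")
  labels <- features$labels
  if (is.null(labels) || nlevels(labels) < 2L)
    abort("Training requires labels with >= 2 classes.")
  blocks <- masked_blocks(features, masks)
  specs <- resolve_specs(specs, blocks)
  lev <- levels(labels)
  tasks <- list()
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    if (b <= a) next
    idx <- which(labels %in% lev[c(a, b)])
    t <- ifelse(labels[idx] == lev[a], 1, -1)
    fit <- mkl_train_binary(lapply(blocks, function(x) x[idx, , drop = FALSE]),
                            t, specs, C0 = C0)
    tasks[[paste0(lev[a], ".vs.", lev[b])]] <-
      list(positive = lev[a], negative = lev[b], index = idx, t = t,
           alpha = fit$alpha, b = fit$b, kkt = fit$kkt,
           objective = fit$objective)
  }
  structure(list(specs = specs, masks = masks, blocks = blocks,
                 labels = labels, classes = lev, tasks = tasks, C0 = C0,
                 norm_params = features$norm_params,
                 study_id = features$study_id),
            class = "mkl_model")
}

#' @export
print.mkl_model <- function(x, ...) {
  cat("<mkl_model> ", length(x$classes), " classes (",
      paste(x$classes, collapse = ", "), "), ", length(x$tasks),
      " one-vs-one task(s), C0 = ", x$C0, "\n", sep = "")
  for (g in names(x$specs))
    cat("  ", g, ": ", x$specs[[g]]$kind, ", beta = ",
        signif(x$specs[[g]]$weight, 4),
        if (!is.null(x$specs[[g]]$sigma))
          paste0(", sigma = ", signif(x$specs[[g]]$sigma, 4)) else "",
        "\n", sep = "")
  invisible(x)
}

#' Predict classes by accumulated kernel votes
#'
#' The default rule accrues, for each test case j and every training case i
#' with a positive support coefficient, the vote
#' `alpha_i * sum_C beta_C K_C(X_i, X_j)` to training case i's own class,
#' summed across the one-vs-one tasks; the predicted label is the class with
#' the maximum accumulated vote. `rule = "margin"` instead casts one vote
#' per task to the sign-winning class of the biased decision function
#' (standard one-vs-one voting); the concordance of the two rules is a
#' useful diagnostic. Ties are broken by class order with a warning.
#'
#' @param object An [mkl_train()] model.
#' @param newdata A z-scored [feature_groups()] (normalize test studies with
#'   the training norm_params via [apply_norm_params()] or the nested-CV
#'   driver; raw input is an error).
#' @param rule `"vote"` (accumulated kernel votes) or `"margin"`.
#' @param ... Unused.
#' @return A tibble: `study_id`, `.pred`, one `vote_<class>` column per
#'   class.
#' @export
predict.mkl_model <- function(object, newdata, rule = c("vote", "margin"), ...) {
  rule <- match.arg(rule)
  if (newdata$normalization != "zscored")
    abort("`newdata` must be z-scored with the model's norm_params.")
  test_blocks <- masked_blocks(newdata, object$masks)
  n_test <- nrow(newdata$M)
  votes <- matrix(0, n_test, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (task in object$tasks) {
    Ktt <- combined_gram(object$specs,
                         lapply(object$blocks, function(x)
                           x[task$index, , drop = FALSE]),
                         test_blocks)              # n_train_task x n_test
    if (rule == "vote") {
      w <- task$alpha * Ktt                         # alpha_i * K(i, j)
      pos <- task$t == 1
      votes[, task$positive] <- votes[, task$positive] + colSums(w[pos, , drop = FALSE])
      votes[, task$negative] <- votes[, task$negative] + colSums(w[!pos, , drop = FALSE])
    } else {
      f <- as.numeric(crossprod(Ktt, task$alpha * task$t)) - task$b
      votes[, task$positive] <- votes[, task$positive] + (f >= 0)
      votes[, task$negative] <- votes[, task$negative] + (f < 0)
    }
  }
  pred_idx <- apply(votes, 1, which.max)
  n_tied <- sum(apply(votes, 1, function(v) sum(v == max(v)) > 1L))
  if (n_tied > 0L)
    warn(paste0(n_tied, " tie(s) in accumulated votes; broken by class order."))
  tibble::tibble(study_id = newdata$study_id,
                 .pred = factor(object$classes[pred_idx],
                                levels = object$classes)) |>
    dplyr::bind_cols(tibble::as_tibble(votes, .name_repair = ~ paste0("vote_", .x)))
}

#' @export
tidy.mkl_model <- function(x, ...) {
  purrr::imap_dfr(x$tasks, function(tk, nm)
    tibble::tibble(task = nm, positive = tk$positive,
                   negative = tk$negative, n_cases = length(tk$index),
                   n_support = sum(tk$alpha > 0), bias = tk$b,
                   kkt_equality = tk$kkt[["equality"]],
                   objective = tk$objective))
}

#' @export
glance.mkl_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_tasks = length(x$tasks),
                 C0 = x$C0,
                 kernels = paste(vapply(x$specs, function(s)
                   paste0(s$group, ":", s$kind), character(1)), collapse = ","),
                 beta = paste(signif(vapply(x$specs, function(s) s$weight,
                                            numeric(1)), 4), collapse = ","))
}

#' Plot kernel weights of a trained model
#'
#' @param object An `mkl_model`.
#' @param ... Unused.
#' @return A ggplot bar chart of the normalized kernel weights per group.
#' @export
autoplot.mkl_model <- function(object, ...) {
  b <- vapply(object$specs, function(s) s$weight, numeric(1))
  df <- tibble::tibble(group = names(b), beta = b, share = b / sum(b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "feature group", y = "normalized kernel weight",
                  title = "Multi-kernel weights") +
    ggplot2::theme_minimal()
}

#' Real-coded GA configuration for kernel-weight estimation
#'
#' @param population_size Individuals (real beta vectors).
#' @param max_generations Generations.
#' @param beta_min,beta_max Box constraints on each kernel weight (> 0).
#' @param cv_folds Folds of the fitness cross-validation.
#' @param p_m0,alpha_pm,T_pm Adaptive per-gene mutation schedule (same rule
#'   as the binary GA: kept on improvement, multiplied by `alpha_pm`
#'   otherwise, reset to `p_m0` at `T_pm`).
#' @param mutation_sd Sd of the Gaussian gene perturbation, as a fraction of
#'   the box width.
#' @param crossover_probability Probability of blend (arithmetic) crossover.
#' @param elitism_count Elites carried over unchanged.
#' @param rng_seed Integer seed; `NULL` = current RNG state.
#' @return An object of class `rcga_config`.
#' @export
rcga_config <- function(population_size = 50L, max_generations = 30L,
                        beta_min = 1e-3, beta_max = 10, cv_folds = 10L,
                        p_m0 = 0.1, alpha_pm = 1.5, T_pm = 0.8,
                        mutation_sd = 0.1, crossover_probability = 0.8,
                        elitism_count = 1L, rng_seed = NULL) {
  if (beta_min <= 0 || beta_max <= beta_min)
    abort("Need 0 < beta_min < beta_max.")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 beta_min = beta_min, beta_max = beta_max,
                 cv_folds = as.integer(cv_folds), p_m0 = p_m0,
                 alpha_pm = alpha_pm, T_pm = T_pm, mutation_sd = mutation_sd,
                 crossover_probability = crossover_probability,
                 elitism_count = as.integer(elitism_count),
                 rng_seed = rng_seed),
            class = "rcga_config")
}

#' Estimate kernel weights by a real-coded genetic algorithm
#'
#' Searches the box `[beta_min, beta_max]^3` for the weight vector
#' `[beta_M, beta_S, beta_A]` maximizing the seeded k-fold cross-validated
#' accuracy of the multi-kernel classifier, using blend (arithmetic)
#' crossover, Gaussian gene mutation under the same adaptive schedule as the
#' binary GA, and elitist inheritance. The fold partition is drawn once per
#' run, so fitness is deterministic within the run.
#'
#' @param features A z-scored [feature_groups()] with labels.
#' @param masks Named list of per-group masks (as in [mkl_train()]).
#' @param specs Kernel assignment; Gaussian sigmas are resolved once on the
#'   full masked blocks and held fixed during the search.
#' @param config An [rcga_config()].
#' @param C0 Soft-margin constant.
#' @return An object of class `mkl_weights`: `beta` (named vector),
#'   `fitness` (CV accuracy at `beta`), `trace` (per-generation tibble),
#'   `folds`, `config`.
#' @export
estimate_kernel_weights <- function(features, masks = list(),
                                    specs = default_kernel_specs(),
                                    config = rcga_config(), C0 = 1) {
  labels <- features$labels
  if (is.null(labels) || nlevels(labels) < 2L)
    abort("Weight estimation requires labels with >= 2 classes.")
  blocks <- masked_blocks(features, masks)
  specs <- resolve_specs(specs, blocks)
  with_seed(config$rng_seed, {
    k <- min(config$cv_folds, min(table(labels)))
    folds <- make_cv_folds(labels, k)
    fit_beta <- function(beta) {
      sp <- specs
      for (i in seq_along(sp)) sp[[i]]$weight <- beta[i]
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- which(folds != f); te <- which(folds == f)
        m <- mkl_train(fg_rows(features, tr), masks, sp, C0 = C0)
        pr <- suppressWarnings(predict(m, fg_rows(features, te)))
        correct <- correct + sum(as.character(pr$.pred) ==
                                   as.character(labels[te]))
      }
      correct / length(labels)
    }
    d <- length(specs)
    pop <- lapply(seq_len(config$population_size), function(i)
      runif(d, config$beta_min, config$beta_max))
    p_m <- config$p_m0
    best_beta <- NULL; best_fit <- -Inf; prev_best <- -Inf
    trace <- vector("list", config$max_generations + 1L)
    all_fits <- numeric(0)
    for (gen in 0:config$max_generations) {
      fitness <- vapply(pop, fit_beta, numeric(1))
      all_fits <- c(all_fits, fitness)
      if (max(fitness) > best_fit) {
        best_fit <- max(fitness); best_beta <- pop[[which.max(fitness)]]
      }
      trace[[gen + 1L]] <- tibble::tibble(generation = gen,
                                          pop_best = max(fitness),
                                          pop_mean = mean(fitness),
                                          best_so_far = best_fit, p_m = p_m)
      if (gen == config$max_generations) break
      if (gen > 0L)
        p_m <- update_mutation_probability(p_m, max(fitness) > prev_best, config)
      prev_best <- max(fitness)
      elite_idx <- order(fitness, decreasing = TRUE)[seq_len(config$elitism_count)]
      nxt <- pop[elite_idx]
      while (length(nxt) < config$population_size) {
        par <- roulette_select(fitness, 2L)
        p1 <- pop[[par[1]]]; p2 <- pop[[par[2]]]
        if (runif(1) < config$crossover_probability) {
          u <- runif(d)
          c1 <- u * p1 + (1 - u) * p2
          c2 <- u * p2 + (1 - u) * p1
        } else { c1 <- p1; c2 <- p2 }
        for (child in list(c1, c2)) {
          mut <- runif(d) < p_m
          child[mut] <- child[mut] +
            rnorm(sum(mut), 0, config$mutation_sd *
                    (config$beta_max - config$beta_min))
          child <- pmin(pmax(child, config$beta_min), config$beta_max)
          if (length(nxt) < config$population_size)
            nxt[[length(nxt) + 1L]] <- child
        }
      }
      pop <- nxt
    }
    if (length(unique(all_fits)) == 1L) {
      warn("Degenerate search: all candidate weights tie; returning uniform beta.")
      best_beta <- rep(1, d)
    }
    names(best_beta) <- names(specs)
    structure(list(beta = best_beta, fitness = best_fit,
                   trace = dplyr::bind_rows(trace), folds = folds,
                   config = config),
              class = "mkl_weights")
  })
}

#' @export
print.mkl_weights <- function(x, ...) {
  cat("<mkl_weights> beta = [", paste(signif(x$beta, 4), collapse = ", "),
      "], CV accuracy ", formatC(x$fitness, digits = 4, format = "f"),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mkl_weights <- function(x, ...) x$trace

#' @export
glance.mkl_weights <- function(x, ...) {
  tibble::tibble(beta_M = x$beta[["M"]], beta_S = x$beta[["S"]],
                 beta_A = x$beta[["A"]], fitness = x$fitness,
                 generations = max(x$trace$generation))
}
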
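#' Genetic-algorithm configuration for wrapper feature selection
#'
#' Defaults are the clinical-scale configuration (population 500, 10-fold
#' cross-validated fitness, stagnation window of 4 generations), with
#' standard GA practice for the remaining knobs. All of them are exposed so
#' the sensitivity of any choice can be probed; the synthetic desk-scale
#' studies use much smaller populations.
#'
#' @param population_size Number of binary individuals (>= 2).
#' @param max_generations Generations to evolve.
#' @param p_m0 Initial per-bit mutation probability.
#' @param alpha_pm Multiplicative increase of the mutation probability when
#'   the best fitness fails to improve (> 1).
#' @param T_pm Threshold at which the mutation probability is reset to
#'   `p_m0` (prevents degeneration to random search).
#' @param stagnation_window Generations of unchanged best fitness after
#'   which every individual tied at the best fitness is replaced by a
#'   mutated offspring.
#' @param elitism_count Individuals copied unchanged into the next
#'   generation.
#' @param crossover_probability Probability that a selected parent pair is
#'   recombined by one-point crossover.
#' @param cv_folds Folds of the fitness cross-validation (reduced to the
#'   smallest class size when needed).
#' @param cv_repeats Number of independently seeded fold partitions the
#'   fitness is averaged over (all drawn once per run and held fixed).
#'   A single partition lets masks that exploit one partition's test-fold
#'   luck tie with genuinely better masks; averaging over a second
#'   partition removes most of that selection overfitting at twice the
#'   cost.
#' @param svm_C0 Soft-margin constant of the linear-SVM fitness classifier.
#' @param rng_seed Integer seed fixing the entire evolutionary trajectory
#'   (fold partition included); `NULL` = current RNG state.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 500L, max_generations = 50L,
                      p_m0 = 0.01, alpha_pm = 1.5, T_pm = 0.2,
                      stagnation_window = 4L, elitism_count = 1L,
                      crossover_probability = 0.8, cv_folds = 10L,
                      cv_repeats = 2L, svm_C0 = 1, rng_seed = NULL) {
  if (!(p_m0 > 0 && p_m0 <= T_pm && T_pm <= 1))
    abort("Need 0 < p_m0 <= T_pm <= 1.")
  if (alpha_pm <= 1) abort("`alpha_pm` must exceed 1.")
  if (population_size < 2L) abort("`population_size` must be >= 2.")
  if (svm_C0 <= 0) abort("`svm_C0` must be positive.")
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 p_m0 = p_m0, alpha_pm = alpha_pm, T_pm = T_pm,
                 stagnation_window = as.integer(stagnation_window),
                 elitism_count = as.integer(elitism_count),
                 crossover_probability = crossover_probability,
                 cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(max(1L, cv_repeats)),
                 svm_C0 = svm_C0, rng_seed = rng_seed),
            class = "ga_config")
}

#' Cross-validation fold assignment
#'
#' Partitions studies into `n_folds` folds of near-equal size (difference at
#' most 1). Stratified assignment (the default) balances every class across
#' folds; plain random assignment reproduces simple random equal-size
#' subsamples.
#'
#' @param labels Class labels, one per study.
#' @param n_folds Number of folds.
#' @param seed Integer seed; `NULL` = current RNG state.
#' @param stratified Balance classes across folds?
#' @return Integer vector of fold ids (1..n_folds), one per study.
#' @export
make_cv_folds <- function(labels, n_folds = 10L, seed = NULL, stratified = TRUE) {
  labels <- factor(labels)
  n <- length(labels)
  n_folds <- min(n_folds, n)
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      start <- 0L
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        folds[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
        start <- start + length(idx)
      }
    } else {
      folds[sample(n)] <- ((seq_len(n) - 1L) %% n_folds) + 1L
    }
    folds
  })
}

# Cross-validated linear-SVM accuracy of a masked feature block; the GA
# fitness. A mask with no set bit has fitness 0 by convention.
ga_fitness <- function(bits, x, labels, folds, C0 = 1) {
  cols <- which(bits != 0)
  if (length(cols) == 0L) return(0)
  .cv_linear_svm_accuracy(x, as.integer(factor(labels)), as.integer(folds),
                          as.integer(cols), C0)
}

#' Cross-validated fitness of a feature mask
#'
#' The wrapper-selection objective: mean k-fold cross-validated accuracy of
#' a linear soft-margin SVM trained on the masked columns (one-vs-one with
#' majority vote beyond two classes). An all-zero mask has fitness 0 by
#' convention, with a warning.
#'
#' @param bits Binary inclusion vector over the columns of `x`.
#' @param x Numeric feature matrix (studies x features).
#' @param labels Class labels.
#' @param folds Fold assignment as from [make_cv_folds()], or a list of
#'   such assignments (fitness averaged across them); `NULL` draws a
#'   stratified partition using `cv_folds` and `seed`.
#' @param C0 Soft-margin constant.
#' @param cv_folds Fold count used when `folds` is `NULL`.
#' @param seed Seed for the drawn partition when `folds` is `NULL`.
#' @return Accuracy in `[0, 1]`.
#' @export
mask_fitness <- function(bits, x, labels, folds = NULL, C0 = 1,
                         cv_folds = 10L, seed = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (length(bits) != ncol(x))
    abort("`bits` length must equal ncol(x).")
  if (all(bits == 0)) {
    warn("All-zero mask; fitness 0 by convention.")
    return(0)
  }
  if (is.null(folds))
    folds <- make_cv_folds(labels, min(cv_folds, min(table(labels))), seed)
  if (!is.list(folds)) folds <- list(folds)
  mean(vapply(folds, function(f)
    ga_fitness(as.integer(bits != 0), x, labels, f, C0), numeric(1)))
}

#' Roulette-wheel parent selection
#'
#' Selects individual i with probability `fitness[i] / sum(fitness)`. When
#' all fitness values are zero the draw is uniform (with a warning).
#'
#' @param fitness Non-negative fitness values.
#' @param n Number of draws.
#' @return Integer indices of the selected individuals.
#' @export
roulette_select <- function(fitness, n = 1L) {
  if (any(fitness < 0)) abort("Fitness values must be non-negative.")
  if (all(fitness == 0)) {
    warn("All-zero fitness; selecting uniformly.")
    return(sample.int(length(fitness), n, replace = TRUE))
  }
  sample.int(length(fitness), n, replace = TRUE, prob = fitness)
}

#' One-point crossover of two binary masks
#'
#' A single cut point drawn uniformly from 1..(length - 1); each offspring
#' takes one parent's prefix and the other's suffix.
#'
#' @param a,b Equal-length binary vectors.
#' @param cut Optional fixed cut point (for testing); `NULL` = random.
#' @return List of two offspring vectors.
#' @export
one_point_crossover <- function(a, b, cut = NULL) {
  L <- length(a)
  if (length(b) != L) abort("Parents must have equal length.")
  if (L < 2L) return(list(a, b))
  k <- if (is.null(cut)) sample.int(L - 1L, 1L) else as.integer(cut)
  list(c(a[1:k], b[(k + 1L):L]), c(b[1:k], a[(k + 1L):L]))
}

#' Random bit-flip mutation
#'
#' Each bit flips independently with probability `p_m`. An all-zero result
#' is repaired by setting one uniformly random bit, so the mask stays
#' submittable to the fitness function.
#'
#' @param bits Binary vector.
#' @param p_m Per-bit flip probability in `[0, 1]`.
#' @return Mutated binary vector.
#' @export
mutate_mask <- function(bits, p_m) {
  flip <- runif(length(bits)) < p_m
  out <- ifelse(flip, 1L - bits, bits)
  if (all(out == 0L)) out[sample.int(length(out), 1L)] <- 1L
  out
}

#' Adaptive mutation-probability schedule
#'
#' The mutation probability is kept when the best fitness improved over the
#' previous generation and multiplied by `alpha_pm` otherwise; when the
#' updated value reaches the threshold `T_pm` it is reset to the initial
#' `p_m0`, so the search never degenerates into random sampling.
#'
#' @param p_m Current mutation probability.
#' @param improved Did the best fitness strictly improve this generation?
#' @param config A [ga_config()].
#' @return The next mutation probability.
#' @export
update_mutation_probability <- function(p_m, improved, config) {
  if (improved) return(p_m)
  p_new <- config$alpha_pm * p_m
  if (p_new >= config$T_pm) config$p_m0 else p_new
}

#' Gene modification of the incumbent best mask
#'
#' Scores every set bit by its marginal contribution to the fitness
#' (fitness of the mask minus fitness with that bit cleared, on the same
#' fold partition) and emits the masks obtained by clearing the 1, 2 and 3
#' lowest-contribution bits — never clearing below one set bit. Lower
#' dimensionality is favored by the fitness classifier, so these targeted
#' deletions accelerate pruning of uninformative features.
#'
#' @param bits Binary mask (the incumbent best individual).
#' @param x Feature matrix of the group under selection.
#' @param labels Class labels.
#' @param config A [ga_config()].
#' @param folds Optional fixed fold assignment (or list of assignments,
#'   averaged); `NULL` = draw one.
#' @return List of up to 3 masks, each a strict sub-mask of `bits`.
#' @export
gene_modification <- function(bits, x, labels, config = ga_config(), folds = NULL) {
  set_idx <- which(bits != 0)
  k <- length(set_idx)
  if (k <= 1L) return(list())
  if (is.null(folds))
    folds <- make_cv_folds(labels, min(config$cv_folds, min(table(labels))))
  if (!is.list(folds)) folds <- list(folds)
  fit_avg <- function(b) mean(vapply(folds, function(f)
    ga_fitness(b, x, labels, f, config$svm_C0), numeric(1)))
  base_fit <- fit_avg(bits)
  contrib <- vapply(set_idx, function(j) {
    b <- bits; b[j] <- 0L
    base_fit - fit_avg(b)
  }, numeric(1))
  drop_order <- set_idx[order(contrib)]
  lapply(seq_len(min(3L, k - 1L)), function(d) {
    b <- bits; b[drop_order[seq_len(d)]] <- 0L; b
  })
}

#' Binary-GA wrapper feature selection
#'
#' Evolves a population of binary masks over one feature group, maximizing
#' the mean cross-validated accuracy of a linear soft-margin SVM on the
#' masked columns. Operators: elitist inheritance, roulette-wheel selection,
#' one-point crossover, random mutation under the adaptive schedule of
#' [update_mutation_probability()], gene modification of the incumbent
#' best, and a stagnation kick that replaces every individual tied at the
#' best fitness by a mutated offspring once the best fitness has been
#' unchanged for more than `stagnation_window` generations.
#'
#' The `cv_repeats` fold partitions of the fitness are drawn once per run
#' from the seeded RNG and then held fixed (fitness = mean accuracy across
#' them), so the fitness landscape is deterministic within a run and the
#' adaptive schedule's generation-to-generation comparison is meaningful.
#'
#' @param x Numeric matrix (studies x features) of one feature group.
#' @param labels Class labels (>= 2 classes).
#' @param config A [ga_config()].
#' @param group_id Optional group tag (`"M"`, `"S"` or `"A"`) carried into
#'   the result.
#' @return An object of class `ga_selection`: `bits` (the best mask found),
#'   `selected` (its column indices), `fitness` (its cross-validated
#'   accuracy), `trace` (per-generation tibble: population best/mean,
#'   running best, mutation probability), `folds` (list of the fixed fold
#'   partitions), `config`, `group_id`, `n_evaluations` (distinct fitness
#'   evaluations).
#' @export
run_feature_selection <- function(x, labels, config = ga_config(),
                                  group_id = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) abort("At least 2 classes are required.")
  if (ncol(x) < 2L) abort("At least 2 feature columns are required.")
  p <- ncol(x)
  with_seed(config$rng_seed, {
    k_folds <- min(config$cv_folds, min(table(labels)))
    folds <- lapply(seq_len(config$cv_repeats), function(i)
      make_cv_folds(labels, k_folds))
    cache <- new.env(parent = emptyenv())
    n_eval <- 0L
    fit1 <- function(bits) {
      key <- paste(which(bits != 0), collapse = ",")
      if (is.null(cache[[key]])) {
        cache[[key]] <- mean(vapply(folds, function(f)
          ga_fitness(bits, x, labels, f, config$svm_C0), numeric(1)))
        n_eval <<- n_eval + 1L
      }
      cache[[key]]
    }
    pop <- lapply(seq_len(config$population_size), function(i) {
      b <- as.integer(runif(p) < 0.5)
      if (all(b == 0L)) b[sample.int(p, 1L)] <- 1L
      b
    })
    p_m <- config$p_m0
    best_bits <- NULL; best_fit <- -Inf
    prev_pop_best <- -Inf
    stagnation <- 0L
    trace <- vector("list", config$max_generations + 1L)
    for (gen in 0:config$max_generations) {
      fitness <- vapply(pop, fit1, numeric(1))
      pop_best <- max(fitness)
      if (pop_best > best_fit) {
        best_fit <- pop_best
        best_bits <- pop[[which.max(fitness)]]
      }
      trace[[gen + 1L]] <- tibble::tibble(
        generation = gen, pop_best = pop_best, pop_mean = mean(fitness),
        best_so_far = best_fit, p_m = p_m)
      if (gen == config$max_generations) break
      improved <- pop_best > prev_pop_best
      if (gen > 0L) {
        stagnation <- if (improved) 0L else stagnation + 1L
        p_m <- update_mutation_probability(p_m, improved, config)
      }
      prev_pop_best <- pop_best
      # stagnation kick: diversify everything tied at the current best
      if (stagnation > config$stagnation_window) {
        tied <- which(fitness == pop_best)
        for (i in tied) pop[[i]] <- mutate_mask(pop[[i]], max(p_m, config$p_m0))
        fitness[tied] <- vapply(pop[tied], fit1, numeric(1))
        stagnation <- 0L
      }
      elite_idx <- order(fitness, decreasing = TRUE)[seq_len(min(config$elitism_count,
                                                                 length(pop)))]
      nxt <- pop[elite_idx]
      while (length(nxt) < config$population_size) {
        par <- roulette_select(fitness, 2L)
        off <- if (runif(1) < config$crossover_probability)
          one_point_crossover(pop[[par[1]]], pop[[par[2]]])
        else list(pop[[par[1]]], pop[[par[2]]])
        for (o in off) {
          if (length(nxt) < config$population_size)
            nxt[[length(nxt) + 1L]] <- mutate_mask(o, p_m)
        }
      }
      # gene modification of the incumbent best; offspring replace the worst
      mods <- gene_modification(best_bits, x, labels, config, folds)
      if (length(mods)) {
        nfit <- vapply(nxt, fit1, numeric(1))
        worst <- order(nfit)[seq_along(mods)]
        for (m in seq_along(mods)) nxt[[worst[m]]] <- mods[[m]]
      }
      pop <- nxt
    }
    structure(list(bits = best_bits, selected = which(best_bits != 0),
                   fitness = best_fit, trace = dplyr::bind_rows(trace),
                   folds = folds, config = config, group_id = group_id,
                   n_evaluations = n_eval),
              class = "ga_selection")
  })
}

#' @export
print.ga_selection <- function(x, ...) {
  cat("<ga_selection> group ", x$group_id %||% "?", ": ", length(x$selected),
      "/", length(x$bits), " features, CV accuracy ",
      formatC(x$fitness, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ga_selection <- function(x, ...) x$trace

#' @export
glance.ga_selection <- function(x, ...) {
  tibble::tibble(group = x$group_id %||% NA_character_,
                 n_selected = length(x$selected), n_features = length(x$bits),
                 fitness = x$fitness, n_evaluations = x$n_evaluations,
                 generations = max(x$trace$generation))
}

#' Plot a selection run's fitness trace
#'
#' @param object A `ga_selection`.
#' @param ... Unused.
#' @return A ggplot: population best/mean and running-best fitness by
#'   generation, with the mutation-probability schedule beneath.
#' @export
autoplot.ga_selection <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("pop_best", "pop_mean", "best_so_far"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "CV accuracy (fitness)",
                  color = NULL,
                  title = paste0("GA feature selection",
                                 if (!is.null(object$group_id))
                                   paste0(" (group ", object$group_id, ")"))) +
    ggplot2::theme_minimal()
}

#' Serialize / deserialize a selection mask as JSON
#'
#' @param selection A `ga_selection` (or any object with `bits`).
#' @param path JSON file path.
#' @return The selection (write) / a list with `bits`, `group_id`,
#'   `fitness` (read).
#' @export
write_mask_json <- function(selection, path) {
  jsonlite::write_json(list(group = selection$group_id, bits = selection$bits,
                            fitness = selection$fitness,
                            selected = selection$selected),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(selection)
}

#' @rdname write_mask_json
#' @export
read_mask_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(bits = as.integer(raw$bits), group_id = raw$group,
       fitness = raw$fitness, selected = which(raw$bits != 0))
}
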
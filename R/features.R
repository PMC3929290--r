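#' Parametric image
#'
#' A spatially normalized parametric PET volume (voxels in metabolic-rate
#' units, e.g. umol glucose / 100 g / min) with its study id and, optionally,
#' a class label. Voxels must all be finite: parametric maps are expected to
#' be dense after spatial normalization, so NaN/Inf is rejected at load time.
#'
#' @param voxels 3D numeric array.
#' @param study_id Character scalar.
#' @param label Optional class label (e.g. `"AD"`, `"FTD"`, `"NC"`).
#' @return An object of class `parametric_image`.
#' @export
parametric_image <- function(voxels, study_id, label = NA_character_) {
  if (length(dim(voxels)) != 3L) abort("`voxels` must be a 3D array.")
  if (!all(is.finite(voxels)))
    abort(paste0("Non-finite voxel values in study '", study_id, "'."))
  structure(list(voxels = voxels, study_id = as.character(study_id),
                 label = as.character(label)),
            class = "parametric_image")
}

#' Read a parametric image from NIfTI
#'
#' @param path NIfTI file (.nii / .nii.gz).
#' @param study_id Study identifier; defaults to the file name stem.
#' @param label Optional class label.
#' @return A [parametric_image()].
#' @export
read_parametric_image <- function(path, study_id = NULL, label = NA_character_) {
  if (is.null(study_id))
    study_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  parametric_image(as.array(RNifti::readNifti(path)), study_id, label)
}

check_shapes <- function(image, atlas) {
  if (!identical(dim(image$voxels), dim(atlas$label_volume)))
    abort(paste0("Image '", image$study_id, "' has shape ",
                 paste(dim(image$voxels), collapse = "x"),
                 " but the atlas label volume is ",
                 paste(dim(atlas$label_volume), collapse = "x"), "."))
}

#' Per-VOI mean and standard deviation of voxel values
#'
#' For each VOI in the atlas, the mean and the standard deviation of the
#' voxels whose label equals that VOI's id. Background (label 0) never
#' contributes. A single-voxel VOI has sd 0 under either convention.
#'
#' @param image A [parametric_image()].
#' @param atlas A [parcellation_atlas()] with the same volume shape.
#' @param sd_type `"population"` (divide by n, the default: the voxels of a
#'   region are the complete population of that region) or `"sample"`
#'   (divide by n - 1).
#' @return A tibble with one row per VOI: `voi_id`, `name`, `hemisphere`,
#'   `pair_id`, `n_voxels`, `mean`, `sd`, ordered by `voi_id`.
#' @export
extract_voi_stats <- function(image, atlas, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  check_shapes(image, atlas)
  lab <- as.vector(atlas$label_volume)
  val <- as.vector(image$voxels)
  keep <- lab != 0L
  lab <- lab[keep]; val <- val[keep]
  ids <- sort(atlas$voi_table$voi_id)
  f <- factor(lab, levels = ids)
  n <- as.integer(table(f))
  empty <- ids[n == 0L]
  if (length(empty))
    abort(paste0("VOI(s) with zero voxels in study '", image$study_id, "': ",
                 paste(empty, collapse = ", "), "."))
  sums <- as.numeric(rowsum(val, f))
  mu <- sums / n
  ss <- as.numeric(rowsum(val * val, f))
  var_pop <- pmax(ss / n - mu^2, 0)
  sdv <- if (sd_type == "population") sqrt(var_pop)
         else sqrt(ifelse(n > 1L, var_pop * n / (n - 1L), 0))
  vt <- dplyr::arrange(atlas$voi_table, .data$voi_id)
  tibble::tibble(voi_id = ids, name = vt$name, hemisphere = vt$hemisphere,
                 pair_id = vt$pair_id, n_voxels = n, mean = mu, sd = sdv)
}

#' Left-minus-right asymmetry of paired VOI means
#'
#' One value per declared left-right pair: mean(left VOI) - mean(right VOI).
#' A negative value therefore flags left-sided hypometabolism.
#'
#' @param voi_means Either the tibble returned by [extract_voi_stats()] or a
#'   numeric vector of per-VOI means named by `voi_id`.
#' @param atlas A [parcellation_atlas()] declaring at least one pair.
#' @return A tibble with columns `pair_id`, `name`, `left_voi`, `right_voi`,
#'   `asymmetry`, ordered by `pair_id`.
#' @export
extract_asymmetry <- function(voi_means, atlas) {
  if (is.data.frame(voi_means))
    voi_means <- setNames(voi_means$mean, voi_means$voi_id)
  pairs <- atlas$pairs
  if (nrow(pairs) == 0L) abort("The atlas declares no left-right pairs.")
  miss <- setdiff(c(pairs$left_voi, pairs$right_voi), as.integer(names(voi_means)))
  if (length(miss))
    abort(paste0("Pair references VOI(s) with no mean value: ",
                 paste(miss, collapse = ", "), "."))
  tibble::tibble(
    pair_id = pairs$pair_id, name = pairs$name,
    left_voi = pairs$left_voi, right_voi = pairs$right_voi,
    asymmetry = unname(voi_means[as.character(pairs$left_voi)] -
                       voi_means[as.character(pairs$right_voi)]))
}

#' Feature groups
#'
#' Container for the three per-study feature blocks: `M` (per-VOI means),
#' `S` (per-VOI standard deviations) and `A` (left-minus-right differences of
#' paired VOI means), plus study ids and class labels.
#'
#' @param M,S Numeric matrices, studies x VOIs, identical column layout.
#' @param A Numeric matrix, studies x pairs.
#' @param study_id Character vector of unique study ids (one per row).
#' @param labels Class labels (factor or character), one per row, or `NULL`.
#' @param normalization `"raw"` or `"zscored"`.
#' @param norm_params Per-group list of per-column `(mean, sd)` used for
#'   z-scoring, or `NULL` while raw.
#' @return An object of class `feature_groups`.
#' @export
feature_groups <- function(M, S, A, study_id, labels = NULL,
                           normalization = "raw", norm_params = NULL) {
  M <- as.matrix(M); S <- as.matrix(S); A <- as.matrix(A)
  n <- nrow(M)
  if (nrow(S) != n || nrow(A) != n)
    abort("M, S and A must have the same number of rows (studies).")
  if (ncol(M) != ncol(S))
    abort("M and S must have the same number of columns (VOIs).")
  study_id <- as.character(study_id)
  if (length(study_id) != n) abort("One study_id per row is required.")
  if (anyDuplicated(study_id))
    abort(paste0("Duplicate study_id: ",
                 paste(unique(study_id[duplicated(study_id)]), collapse = ", "), "."))
  if (!is.null(labels)) {
    labels <- factor(labels)
    if (length(labels) != n) abort("One label per row is required.")
  }
  if (normalization == "raw" && any(S < 0))
    abort("Raw S features (standard deviations) must be non-negative.")
  rownames(M) <- rownames(S) <- rownames(A) <- study_id
  structure(list(M = M, S = S, A = A, study_id = study_id, labels = labels,
                 normalization = normalization, norm_params = norm_params),
            class = "feature_groups")
}

#' @export
print.feature_groups <- function(x, ...) {
  cat("<feature_groups> ", nrow(x$M), " studies; M/S: ", ncol(x$M),
      " VOIs, A: ", ncol(x$A), " pairs (", x$normalization, ")\n", sep = "")
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Build the three feature groups for a cohort of studies
#'
#' Runs [extract_voi_stats()] and [extract_asymmetry()] on every study and
#' stacks the results: row i of each block is study i.
#'
#' @param images List of [parametric_image()] objects (>= 2, unique ids).
#' @param atlas A [parcellation_atlas()].
#' @inheritParams extract_voi_stats
#' @return A raw [feature_groups()] object; labels are taken from the images.
#' @export
build_feature_groups <- function(images, atlas, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(images) < 2L) abort("At least 2 studies are required.")
  ids <- vapply(images, function(im) im$study_id, character(1))
  if (anyDuplicated(ids))
    abort(paste0("Duplicate study_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "), "."))
  stats <- lapply(images, extract_voi_stats, atlas = atlas, sd_type = sd_type)
  M <- do.call(rbind, lapply(stats, function(s) s$mean))
  S <- do.call(rbind, lapply(stats, function(s) s$sd))
  A <- do.call(rbind, lapply(stats, function(s)
    extract_asymmetry(s, atlas)$asymmetry))
  colnames(M) <- colnames(S) <- paste0("voi_", sort(atlas$voi_table$voi_id))
  colnames(A) <- paste0("pair_", atlas$pairs$pair_id)
  labels <- vapply(images, function(im) im$label, character(1))
  if (all(is.na(labels))) labels <- NULL
  feature_groups(M, S, A, ids, labels)
}

#' Z-score feature columns with leakage control
#'
#' Standardizes every column of every block to zero mean and unit standard
#' deviation, with the centering/scaling statistics computed on `fit_rows`
#' only and then applied to all rows. With the default `fit_rows = NULL` all
#' rows are used (the global, single-cohort normalization); inside
#' cross-validation pass the training rows so held-out studies are
#' transformed with training-fold statistics only.
#'
#' Columns that are constant over the fit rows carry no information; they
#' pass through as all zeros with a warning.
#'
#' @param features A raw [feature_groups()] object.
#' @param fit_rows Integer or logical row index of the rows used to fit the
#'   normalization, or `NULL` for all rows.
#' @param sd_type `"sample"` (divide by n - 1, the default: the cohort is a
#'   sample) or `"population"`.
#' @return A z-scored [feature_groups()] with `norm_params` recorded.
#' @export
zscore_features <- function(features, fit_rows = NULL,
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (features$normalization != "raw")
    abort("`features` is already normalized.")
  n <- nrow(features$M)
  fit_rows <- if (is.null(fit_rows)) seq_len(n) else {
    fr <- if (is.logical(fit_rows)) which(fit_rows) else as.integer(fit_rows)
    if (length(fr) == 0L) abort("`fit_rows` must be nonempty.")
    fr
  }
  np <- list()
  blocks <- list()
  for (g in c("M", "S", "A")) {
    x <- features[[g]]
    xf <- x[fit_rows, , drop = FALSE]
    mu <- colMeans(xf)
    sdv <- apply(xf, 2, sd)                       # sample convention
    if (sd_type == "population")
      sdv <- sdv * sqrt((nrow(xf) - 1) / nrow(xf))
    const <- !is.finite(sdv) | sdv == 0
    if (any(const)) {
      warn(paste0("Group ", g, ": ", sum(const),
                  " constant column(s) over the fit rows; passed through as zeros."))
      sdv[const] <- 1
    }
    z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
    z[, const] <- 0
    blocks[[g]] <- z
    np[[g]] <- tibble::tibble(feature = colnames(x) %||% as.character(seq_along(mu)),
                              mean = unname(mu), sd = unname(sdv),
                              constant = unname(const))
  }
  feature_groups(blocks$M, blocks$S, blocks$A, features$study_id,
                 features$labels, normalization = "zscored", norm_params = np)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy a feature_groups object into a long tibble
#'
#' @param x A [feature_groups()] object.
#' @param ... Unused.
#' @return Tibble with columns `study_id`, `label`, `group`, `feature`, `value`.
#' @export
tidy.feature_groups <- function(x, ...) {
  purrr::map_dfr(c("M", "S", "A"), function(g) {
    m <- x[[g]]
    tibble::tibble(
      study_id = rep(x$study_id, times = ncol(m)),
      label = if (is.null(x$labels)) NA_character_
              else rep(as.character(x$labels), times = ncol(m)),
      group = g,
      feature = rep(colnames(m) %||% as.character(seq_len(ncol(m))),
                    each = nrow(m)),
      value = as.vector(m))
  })
}

#' @export
glance.feature_groups <- function(x, ...) {
  tibble::tibble(n_studies = nrow(x$M), n_vois = ncol(x$M),
                 n_pairs = ncol(x$A), n_features = 2L * ncol(x$M) + ncol(x$A),
                 n_classes = if (is.null(x$labels)) NA_integer_
                             else nlevels(x$labels),
                 normalization = x$normalization)
}

#' Write / read feature groups as wide CSV
#'
#' One wide table: `study_id`, `label`, then `m_*`, `s_*`, `a_*` columns.
#'
#' @param features A [feature_groups()] object.
#' @param path CSV path.
#' @return `features` (write) / a [feature_groups()] (read).
#' @export
write_feature_csv <- function(features, path) {
  wide <- data.frame(study_id = features$study_id,
                     label = if (is.null(features$labels)) NA_character_
                             else as.character(features$labels),
                     stringsAsFactors = FALSE)
  for (g in c("M", "S", "A")) {
    m <- features[[g]]
    colnames(m) <- paste0(tolower(g), "_", colnames(m) %||% seq_len(ncol(m)))
    wide <- cbind(wide, m)
  }
  write.csv(wide, path, row.names = FALSE)
  invisible(features)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_"), names(wide), value = TRUE)
    m <- as.matrix(wide[cols]); colnames(m) <- sub(paste0("^", prefix, "_"), "", cols)
    m
  }
  labels <- if (all(is.na(wide$label))) NULL else wide$label
  feature_groups(pick("m"), pick("s"), pick("a"), wide$study_id, labels)
}

# Subset rows of a feature_groups object (internal).
fg_rows <- function(features, rows) {
  feature_groups(features$M[rows, , drop = FALSE],
                 features$S[rows, , drop = FALSE],
                 features$A[rows, , drop = FALSE],
                 features$study_id[rows],
                 if (is.null(features$labels)) NULL else
                   droplevels(features$labels[rows]),
                 normalization = features$normalization,
                 norm_params = features$norm_params)
}

# Apply stored norm_params (from a fit cohort) to a raw feature_groups.
apply_norm_params <- function(features, norm_params) {
  blocks <- lapply(c("M", "S", "A"), function(g) {
    np <- norm_params[[g]]
    z <- sweep(sweep(features[[g]], 2, np$mean, "-"), 2, np$sd, "/")
    z[, np$constant] <- 0
    z
  })
  feature_groups(blocks[[1]], blocks[[2]], blocks[[3]], features$study_id,
                 features$labels, normalization = "zscored",
                 norm_params = norm_params)
}
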
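#' Synthetic cohort specification
#'
#' Parameters of the phantom generator: a toy block parcellation with
#' mirrored left-right VOI pairs, and three classes of studies with
#' class-specific regional hypometabolism. The defaults emulate the clinical
#' picture at desk scale: an AD-like class with symmetric hypometabolism in
#' posterior VOIs, an FTD-like class with hypometabolism in anterior VOIs
#' plus a left-sided asymmetry, and a normal-control class at baseline.
#'
#' Units follow parametric CMRGlc maps (umol glucose / 100 g / min): gray
#' matter baseline around 30, within-region spatial variation around 10% of
#' baseline, a moderate 25% metabolic reduction in affected regions, and a
#' global per-subject offset capturing between-subject variation of whole
#' brain metabolism (which cancels exactly in asymmetry features).
#'
#' @param n_per_class Named integer vector `c(AD=, FTD=, NC=)` of studies per
#'   class (each >= 1).
#' @param n_voi_pairs Number of mirrored left-right VOI pairs (>= 1).
#' @param n_midline_vois Number of unpaired midline VOIs (>= 0).
#' @param voi_block Side length, in voxels, of each cubic VOI block.
#' @param atlas_shape Optional 3D dimensions for the label volume; must be at
#'   least the tiling minimum (an error states the minimum otherwise).
#'   `NULL` = exactly the tiling minimum.
#' @param baseline_mean Baseline regional mean metabolic rate.
#' @param within_voi_sd Spatial (voxel-to-voxel) sd within a VOI.
#' @param hypometabolism_depth Fractional reduction of the baseline mean in
#'   affected VOIs, in `[0, 1)`.
#' @param affected_vois Named list of VOI-id vectors per class; `NULL` picks
#'   the defaults: FTD-like = both hemispheres of the anterior half of the
#'   pairs, AD-like = both hemispheres of the posterior half, NC = none.
#' @param asymmetry_delta Additional absolute reduction applied to the left
#'   VOI of each FTD-affected pair (injected lateralization).
#' @param measurement_noise_sd Independent voxel noise sd.
#' @param between_subject_sd Sd of the per-study global offset added to all
#'   voxels.
#' @param sd_scale Named per-class multiplier of `within_voi_sd`
#'   (class-specific spatial heterogeneity; makes the S group informative).
#' @param seed Integer seed; `NULL` = use the current RNG state.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_per_class = c(AD = 30L, FTD = 30L, NC = 30L),
                        n_voi_pairs = 6L, n_midline_vois = 2L, voi_block = 4L,
                        atlas_shape = NULL,
                        baseline_mean = 30, within_voi_sd = 3,
                        hypometabolism_depth = 0.25, affected_vois = NULL,
                        asymmetry_delta = 3, measurement_noise_sd = 1,
                        between_subject_sd = 1.5,
                        sd_scale = c(AD = 1, FTD = 1, NC = 1),
                        seed = NULL) {
  classes <- c("AD", "FTD", "NC")
  if (is.null(names(n_per_class))) names(n_per_class) <- classes[seq_along(n_per_class)]
  n_per_class <- n_per_class[intersect(classes, names(n_per_class))]
  if (any(n_per_class < 1L)) abort("Each class needs n >= 1 studies.")
  if (hypometabolism_depth < 0 || hypometabolism_depth >= 1)
    abort("`hypometabolism_depth` must lie in [0, 1).")
  if (n_voi_pairs < 1L) abort("`n_voi_pairs` must be >= 1.")
  if (is.null(names(sd_scale))) names(sd_scale) <- classes[seq_along(sd_scale)]
  spec <- structure(list(
    n_per_class = setNames(as.integer(n_per_class), names(n_per_class)),
    n_voi_pairs = as.integer(n_voi_pairs),
    n_midline_vois = as.integer(n_midline_vois), voi_block = as.integer(voi_block),
    atlas_shape = atlas_shape, baseline_mean = baseline_mean,
    within_voi_sd = within_voi_sd, hypometabolism_depth = hypometabolism_depth,
    affected_vois = affected_vois, asymmetry_delta = asymmetry_delta,
    measurement_noise_sd = measurement_noise_sd,
    between_subject_sd = between_subject_sd, sd_scale = sd_scale, seed = seed),
    class = "cohort_spec")
  spec$affected_vois <- default_affected_vois(spec)
  spec
}

# FTD affects the anterior half of the pairs (low y slots), AD the posterior
# half; both hemispheres of each affected pair. VOI ids follow make_toy_atlas:
# pair p -> left 2p-1, right 2p.
default_affected_vois <- function(spec) {
  if (!is.null(spec$affected_vois)) {
    bad <- setdiff(unlist(spec$affected_vois),
                   seq_len(2L * spec$n_voi_pairs + spec$n_midline_vois))
    if (length(bad))
      abort(paste0("affected_vois outside the atlas registry: ",
                   paste(bad, collapse = ", "), "."))
    return(spec$affected_vois)
  }
  P <- spec$n_voi_pairs
  ant <- seq_len(ceiling(P / 2))
  post <- setdiff(seq_len(P), ant)
  if (length(post) == 0L) post <- P  # single-pair atlas: both classes share it
  list(AD = sort(c(2L * post - 1L, 2L * post)),
       FTD = sort(c(2L * ant - 1L, 2L * ant)),
       NC = integer())
}

#' Build a toy block parcellation atlas
#'
#' Cubic VOI blocks tiled on a y-z grid, with each pair's left block mirrored
#' across the mid-sagittal (x) plane onto its right homologue; midline VOIs
#' straddle the plane symmetrically. Pair p gets left VOI id 2p-1 and right
#' id 2p; midline ids follow. Slot order along y is read as
#' anterior -> posterior.
#'
#' @param spec A [cohort_spec()] (only the atlas fields are used).
#' @return A [parcellation_atlas()].
#' @export
make_toy_atlas <- function(spec) {
  b <- spec$voi_block; P <- spec$n_voi_pairs; Mn <- spec$n_midline_vois
  nslot <- P + Mn
  gy <- ceiling(sqrt(nslot)); gz <- ceiling(nslot / gy)
  h <- b + 1L                                   # half-width incl. margin
  need <- c(2L * h, gy * (b + 1L) + 1L, gz * (b + 1L) + 1L)
  shape <- spec$atlas_shape
  if (is.null(shape)) shape <- need
  if (any(shape < need))
    abort(paste0("atlas_shape too small; minimum is ",
                 paste(need, collapse = " x "), "."))
  lab <- array(0L, shape)
  mb <- ceiling(b / 2)
  slot_range <- function(g) ((g - 1L) * (b + 1L) + 2L):((g - 1L) * (b + 1L) + 1L + b)
  rows <- list()
  for (s in seq_len(nslot)) {
    iy <- slot_range((s - 1L) %% gy + 1L)
    iz <- slot_range((s - 1L) %/% gy + 1L)
    if (s <= P) {
      lid <- 2L * s - 1L; rid <- 2L * s
      lab[1:b, iy, iz] <- lid
      lab[(shape[1] - b + 1L):shape[1], iy, iz] <- rid
      rows[[length(rows) + 1L]] <- tibble::tibble(
        voi_id = c(lid, rid), name = paste0("pair", s, c("_L", "_R")),
        hemisphere = c("left", "right"), pair_id = c(s, s))
    } else {
      mid <- 2L * P + (s - P)
      lab[(h - mb + 1L):(h + mb), iy, iz] <- mid
      rows[[length(rows) + 1L]] <- tibble::tibble(
        voi_id = mid, name = paste0("midline", s - P),
        hemisphere = "midline", pair_id = NA_integer_)
    }
  }
  parcellation_atlas(lab, dplyr::bind_rows(rows))
}

# Per-class, per-VOI mean metabolic rate implied by a spec.
class_mean_table <- function(spec, atlas) {
  ids <- sort(atlas$voi_table$voi_id)
  purrr::map_dfr(names(spec$n_per_class), function(cl) {
    aff <- spec$affected_vois[[cl]] %||% integer()
    mu <- rep(spec$baseline_mean, length(ids))
    mu[ids %in% aff] <- spec$baseline_mean * (1 - spec$hypometabolism_depth)
    if (cl == "FTD" && spec$asymmetry_delta != 0) {
      left_aff <- intersect(aff, atlas$pairs$left_voi)
      mu[ids %in% left_aff] <- mu[ids %in% left_aff] - spec$asymmetry_delta
    }
    tibble::tibble(class = cl, voi_id = ids, mu = mu,
                   voxel_sd = sqrt((spec$within_voi_sd *
                                      (spec$sd_scale[[cl]] %||% 1))^2 +
                                   spec$measurement_noise_sd^2))
  })
}

#' Simulate a phantom cohort of parametric volumes
#'
#' Draws, for every study, voxel values in VOI v from
#' `Normal(mu_cv + g_i, within_voi_sd * sd_scale)` plus independent
#' measurement noise, where `mu_cv` is the class-conditional regional mean
#' (baseline, reduced by `hypometabolism_depth` in affected VOIs, with
#' `asymmetry_delta` further subtracted on the left hemisphere of
#' FTD-affected pairs) and `g_i ~ Normal(0, between_subject_sd)` is the
#' study's global offset. Background voxels are 0.
#'
#' @param spec A [cohort_spec()].
#' @param atlas Optional [parcellation_atlas()]; `NULL` = [make_toy_atlas()].
#' @return A list with elements `images` (list of [parametric_image()]),
#'   `atlas`, and `manifest` (ground truth: the spec, the per-class regional
#'   mean table, affected sets, per-study global offsets, seed).
#' @export
simulate_cohort <- function(spec, atlas = NULL) {
  if (is.null(atlas)) atlas <- make_toy_atlas(spec)
  with_seed(spec$seed, {
    mu_tab <- class_mean_table(spec, atlas)
    ids <- sort(atlas$voi_table$voi_id)
    vox_idx <- lapply(ids, function(v) which(atlas$label_volume == v))
    labels <- rep(names(spec$n_per_class), spec$n_per_class)
    study_id <- sprintf("study_%03d", seq_along(labels))
    offsets <- rnorm(length(labels), 0, spec$between_subject_sd)
    images <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      vol <- array(0, dim(atlas$label_volume))
      mt <- mu_tab[mu_tab$class == labels[i], ]
      for (k in seq_along(ids)) {
        nv <- length(vox_idx[[k]])
        vol[vox_idx[[k]]] <- rnorm(nv, mt$mu[k] + offsets[i],
                                   spec$within_voi_sd * (spec$sd_scale[[labels[i]]] %||% 1)) +
          rnorm(nv, 0, spec$measurement_noise_sd)
      }
      images[[i]] <- parametric_image(vol, study_id[i], labels[i])
    }
    manifest <- list(spec = spec, class_means = mu_tab,
                     affected_vois = spec$affected_vois,
                     studies = tibble::tibble(study_id = study_id, label = labels,
                                              global_offset = offsets),
                     seed = spec$seed)
    list(images = images, atlas = atlas, manifest = manifest)
  })
}

#' Simulate a feature table directly (volume-free fast path)
#'
#' Draws the M/S/A feature blocks straight from the sampling distributions
#' implied by [simulate_cohort()] — per-VOI sample means are normal with
#' variance `voxel_sd^2 / n_voxels`, per-VOI sds follow the scaled-chi
#' sampling law, and asymmetries are differences of the drawn paired means —
#' bypassing voxel simulation (one to two orders of magnitude faster; used
#' for selection/kernel-weight stress tests).
#'
#' @inheritParams simulate_cohort
#' @return A list with `features` (raw [feature_groups()]), `atlas`, `manifest`.
#' @export
simulate_feature_table <- function(spec, atlas = NULL) {
  if (is.null(atlas)) atlas <- make_toy_atlas(spec)
  with_seed(spec$seed, {
    mu_tab <- class_mean_table(spec, atlas)
    ids <- sort(atlas$voi_table$voi_id)
    nvox <- vapply(ids, function(v) sum(atlas$label_volume == v), integer(1))
    labels <- rep(names(spec$n_per_class), spec$n_per_class)
    study_id <- sprintf("study_%03d", seq_along(labels))
    n <- length(labels)
    offsets <- rnorm(n, 0, spec$between_subject_sd)
    M <- S <- matrix(0, n, length(ids))
    for (i in seq_len(n)) {
      mt <- mu_tab[mu_tab$class == labels[i], ]
      M[i, ] <- rnorm(length(ids), mt$mu + offsets[i], mt$voxel_sd / sqrt(nvox))
      # population-sd convention: sum of squares about the sample mean / n
      S[i, ] <- mt$voxel_sd * sqrt(stats::rchisq(length(ids), nvox - 1L) / nvox)
    }
    colnames(M) <- colnames(S) <- paste0("voi_", ids)
    li <- match(atlas$pairs$left_voi, ids); ri <- match(atlas$pairs$right_voi, ids)
    A <- M[, li, drop = FALSE] - M[, ri, drop = FALSE]
    colnames(A) <- paste0("pair_", atlas$pairs$pair_id)
    feats <- feature_groups(M, S, A, study_id, labels)
    manifest <- list(spec = spec, class_means = mu_tab,
                     affected_vois = spec$affected_vois,
                     studies = tibble::tibble(study_id = study_id, label = labels,
                                              global_offset = offsets),
                     seed = spec$seed)
    list(features = feats, atlas = atlas, manifest = manifest)
  })
}

#' Planted-column feature cohort
#'
#' A two-class (or multi-class) feature matrix of standard-normal noise with
#' a chosen set of informative columns whose class means are separated by
#' `effect` within-class standard deviations — the ground-truth benchmark
#' for feature-selection recovery.
#'
#' @param n Studies per class.
#' @param p Total number of columns.
#' @param informative Integer indices of the informative columns.
#' @param effect Class-mean separation of the informative columns, in units
#'   of the within-class sd (which is 1).
#' @param n_classes 2 or 3 (class c mean = (c-1) * effect on informative cols).
#' @param seed Integer seed.
#' @return List with `x` (matrix), `labels` (factor), `informative`.
#' @export
simulate_planted_features <- function(n = 30, p = 20, informative = 1:3,
                                      effect = 3, n_classes = 2, seed = NULL) {
  with_seed(seed, {
    N <- n * n_classes
    x <- matrix(rnorm(N * p), N, p)
    labels <- factor(rep(paste0("C", seq_len(n_classes)), each = n))
    for (c in seq_len(n_classes))
      x[as.integer(labels) == c, informative] <-
        x[as.integer(labels) == c, informative] + (c - 1) * effect
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, labels = labels, informative = informative)
  })
}

#' Interacting-pair (suppressor) feature cohort
#'
#' The canonical suppressor construction: `x1 = d + u` carries the class
#' signal `d ~ Normal(+-effect/2, 1)` buried under a shared nuisance
#' component `u ~ Normal(0, shared_sd)`, and `x2 = u` is that nuisance alone
#' — by itself completely uninformative (its marginal class difference is
#' exactly zero), yet subtracting it from `x1` uncovers the full signal:
#' `x1 - x2 = d` separates the classes by `effect` sd units. Univariate
#' t-ranking puts `x2` at the bottom and sees `x1` only weakly; a wrapper
#' that evaluates features jointly can recover the pair. Remaining columns
#' are pure noise.
#'
#' @param n Studies per class (2 classes).
#' @param p_noise Number of additional pure-noise columns.
#' @param effect Class separation of the hidden signal `x1 - x2`, sd units.
#' @param shared_sd Sd of the shared nuisance component.
#' @param seed Integer seed.
#' @return List with `x`, `labels`, `informative` (= 1:2).
#' @export
simulate_interacting_features <- function(n = 30, p_noise = 8, effect = 4,
                                          shared_sd = 8, seed = NULL) {
  with_seed(seed, {
    N <- 2L * n
    labels <- factor(rep(c("C1", "C2"), each = n))
    sgn <- ifelse(labels == "C1", -1, 1)
    u <- rnorm(N, 0, shared_sd)          # shared nuisance
    d <- rnorm(N, sgn * effect / 2, 1)   # hidden class signal
    x <- cbind(d + u, u, matrix(rnorm(N * p_noise), N, p_noise))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    list(x = x, labels = labels, informative = 1:2)
  })
}
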
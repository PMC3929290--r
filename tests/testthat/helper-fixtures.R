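# Shared fixtures and independent brute-force oracles.

# Tiny two-pair / one-midline atlas used across tests.
tiny_atlas <- function(voi_block = 2L, n_voi_pairs = 2L, n_midline = 1L) {
  make_toy_atlas(cohort_spec(n_per_class = c(AD = 2L, FTD = 2L, NC = 2L),
                             n_voi_pairs = n_voi_pairs,
                             n_midline_vois = n_midline,
                             voi_block = voi_block, seed = 1))
}

# Brute-force per-VOI statistics: explicit voxel-list gather per label.
brute_voi_stats <- function(voxels, label_volume, sd_type = "population") {
  ids <- sort(setdiff(unique(as.vector(label_volume)), 0L))
  do.call(rbind, lapply(ids, function(id) {
    v <- voxels[label_volume == id]
    m <- sum(v) / length(v)
    ss <- sum((v - m)^2)
    s <- if (sd_type == "population") sqrt(ss / length(v))
         else if (length(v) > 1) sqrt(ss / (length(v) - 1)) else 0
    data.frame(voi_id = id, mean = m, sd = s)
  }))
}

# Random labeled volume: every VOI id guaranteed at least one voxel.
random_labeled_volume <- function(dims, n_vois) {
  lab <- array(sample(0:n_vois, prod(dims), replace = TRUE), dims)
  for (id in seq_len(n_vois)) {
    if (!any(lab == id)) lab[sample(prod(dims), 1)] <- id
  }
  lab
}

# Atlas over an arbitrary label volume: odd ids left, even right, paired.
paired_atlas_from_labels <- function(lab, n_vois) {
  stopifnot(n_vois %% 2 == 0)
  p <- n_vois / 2
  parcellation_atlas(lab, data.frame(
    voi_id = seq_len(n_vois),
    name = paste0("v", seq_len(n_vois)),
    hemisphere = rep(c("left", "right"), p),
    pair_id = rep(seq_len(p), each = 2)))
}

# Small z-scored three-class feature cohort for classifier tests.
small_zscored_cohort <- function(n = 8, depth = 0.4, seed = 7) {
  spec <- cohort_spec(n_per_class = c(AD = n, FTD = n, NC = n),
                      hypometabolism_depth = depth, seed = seed)
  zscore_features(simulate_feature_table(spec)$features)
}
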
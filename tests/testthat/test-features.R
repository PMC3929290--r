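test_that("per-VOI statistics match direct arithmetic on constant and small regions", {
  lab <- array(0L, c(4, 2, 1))
  lab[1:2, , 1] <- 1L; lab[3:4, , 1] <- 2L
  vt <- data.frame(voi_id = 1:2, name = c("a_L", "a_R"),
                   hemisphere = c("left", "right"), pair_id = c(1L, 1L))
  atl <- parcellation_atlas(lab, vt)
  vox <- array(0, c(4, 2, 1))
  vox[1:2, , 1] <- 5                      # constant region
  vox[3:4, , 1] <- c(1, 2, 3, 4)
  im <- parametric_image(vox, "s1")
  st <- extract_voi_stats(im, atl)
  expect_equal(st$mean, c(5, 2.5))
  expect_equal(st$sd[1], 0)
  # population sd of {1,2,3,4}
  expect_equal(st$sd[2], sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  st_s <- extract_voi_stats(im, atl, sd_type = "sample")
  expect_equal(st_s$sd[2], sd(c(1, 2, 3, 4)))
})

test_that("interleaved VOIs reproduce the brute-force voxel gather", {
  set.seed(42)
  lab <- array(rep(c(1L, 2L), 8), c(4, 2, 2))   # interleaved labels
  atl <- paired_atlas_from_labels(lab, 2)
  vox <- array(rnorm(16, 10, 2), dim(lab))
  st <- extract_voi_stats(parametric_image(vox, "s1"), atl)
  oracle <- brute_voi_stats(vox, lab)
  expect_equal(st$mean, oracle$mean, tolerance = 1e-12)
  expect_equal(st$sd, oracle$sd, tolerance = 1e-12)
})

test_that("stats extraction rejects shape mismatch, empty VOIs, non-finite voxels", {
  atl <- tiny_atlas()
  expect_error(extract_voi_stats(parametric_image(array(0, c(2, 2, 2)), "s"),
                                 atl), "shape")
  lab <- atl$label_volume
  lab[lab == 2L] <- 0L                      # VOI 2 left with zero voxels
  atl2 <- parcellation_atlas(lab, atl$voi_table)
  vox <- array(1, dim(lab))
  expect_error(extract_voi_stats(parametric_image(vox, "s"), atl2), "VOI")
  bad <- vox; bad[1] <- NaN
  expect_error(parametric_image(bad, "s"), "Non-finite")
})

test_that("asymmetry is left minus right, ordered by pair, and fatal on missing VOIs", {
  atl <- tiny_atlas()
  means <- setNames(rep(3, nrow(atl$voi_table)), atl$voi_table$voi_id)
  expect_equal(extract_asymmetry(means, atl)$asymmetry,
               rep(0, nrow(atl$pairs)))
  means[as.character(atl$pairs$left_voi[1])] <- 2
  means[as.character(atl$pairs$right_voi[1])] <- 5
  asym <- extract_asymmetry(means, atl)
  expect_equal(asym$asymmetry[1], -3)
  expect_equal(asym$pair_id, sort(asym$pair_id))
  expect_error(extract_asymmetry(means[-1], atl), "no mean value")
})

test_that("asymmetry negates exactly when left/right roles are swapped", {
  set.seed(3)
  lab <- random_labeled_volume(c(5, 4, 3), 4)
  atl <- paired_atlas_from_labels(lab, 4)
  vt_sw <- atl$voi_table
  vt_sw$hemisphere <- ifelse(vt_sw$hemisphere == "left", "right", "left")
  atl_sw <- parcellation_atlas(lab, vt_sw)
  vox <- array(rnorm(prod(dim(lab)), 8), dim(lab))
  st <- extract_voi_stats(parametric_image(vox, "s"), atl)
  expect_equal(extract_asymmetry(st, atl)$asymmetry,
               -extract_asymmetry(st, atl_sw)$asymmetry)
})

test_that("feature blocks have the contract shapes and per-study rows", {
  atl <- tiny_atlas()                       # 5 VOIs (2 pairs + 1 midline)
  set.seed(9)
  imgs <- lapply(1:3, function(i)
    parametric_image(array(rnorm(prod(dim(atl$label_volume)), 20, 2),
                           dim(atl$label_volume)), paste0("s", i), "NC"))
  fg <- build_feature_groups(imgs, atl)
  expect_equal(dim(fg$M), c(3, 5))
  expect_equal(dim(fg$S), c(3, 5))
  expect_equal(dim(fg$A), c(3, 2))
  # each row reproduces a single-study extraction
  st2 <- extract_voi_stats(imgs[[2]], atl)
  expect_equal(unname(fg$M[2, ]), st2$mean)
  expect_equal(unname(fg$S[2, ]), st2$sd)
  # permuting studies permutes rows identically in all blocks
  fg_perm <- build_feature_groups(imgs[c(3, 1, 2)], atl)
  expect_equal(fg_perm$M, fg$M[c(3, 1, 2), ])
  expect_equal(fg_perm$A, fg$A[c(3, 1, 2), ])
  expect_error(build_feature_groups(imgs[c(1, 1)], atl), "Duplicate study_id")
  expect_error(build_feature_groups(imgs[1], atl), "At least 2")
})

test_that("adding a constant shifts M, leaves raw S and A unchanged", {
  atl <- tiny_atlas()
  set.seed(10)
  base <- lapply(1:2, function(i)
    array(rnorm(prod(dim(atl$label_volume)), 15, 3), dim(atl$label_volume)))
  imgs <- lapply(1:2, function(i) parametric_image(base[[i]], paste0("s", i)))
  imgs_c <- lapply(1:2, function(i) parametric_image(base[[i]] + 7, paste0("s", i)))
  fg <- build_feature_groups(imgs, atl)
  fg_c <- build_feature_groups(imgs_c, atl)
  expect_equal(fg_c$M, fg$M + 7)
  expect_equal(fg_c$S, fg$S, tolerance = 1e-10)
  expect_equal(fg_c$A, fg$A, tolerance = 1e-10)
})

test_that("z-scoring centers and scales fit rows and transfers to held-out rows", {
  set.seed(2)
  n <- 10
  M <- matrix(rnorm(n * 3, 20, 4), n, 3)
  S <- matrix(abs(rnorm(n * 3, 2)), n, 3)
  A <- matrix(rnorm(n * 2), n, 2)
  fg <- feature_groups(M, S, A, paste0("s", 1:n), rep(c("AD", "NC"), 5))
  z <- zscore_features(fg, fit_rows = 1:8)
  for (g in c("M", "S", "A")) {
    expect_lt(max(abs(colMeans(z[[g]][1:8, , drop = FALSE]))), 1e-9)
    expect_lt(max(abs(apply(z[[g]][1:8, , drop = FALSE], 2, sd) - 1)), 1e-9)
  }
  # two-point closed form under the sample-sd convention
  fg2 <- feature_groups(matrix(c(2, 4), 2, 1), matrix(1, 2, 1),
                        matrix(0, 2, 1), c("a", "b"))
  z2 <- suppressWarnings(zscore_features(fg2))
  expect_equal(unname(z2$M[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # held-out row equal to the fit mean maps to zero
  M3 <- rbind(M[1:8, ], colMeans(M[1:8, ]), M[10, ])
  fg3 <- feature_groups(M3, S, A, paste0("s", 1:n), NULL)
  z3 <- zscore_features(fg3, fit_rows = 1:8)
  expect_equal(unname(z3$M[9, ]), rep(0, 3), tolerance = 1e-12)
  # constant column passes through as zeros with a warning
  M4 <- M; M4[, 2] <- 5
  fg4 <- feature_groups(M4, S, A, paste0("s", 1:n), NULL)
  expect_warning(z4 <- zscore_features(fg4), "constant")
  expect_equal(unname(z4$M[, 2]), rep(0, n))
  # already-normalized input is refused
  expect_error(zscore_features(z), "already normalized")
})

test_that("an already-centered unit-variance column is unchanged", {
  x <- scale(rnorm(12))                    # exactly mean 0, sd 1
  fg <- feature_groups(matrix(x, 12, 1), matrix(1, 12, 1), matrix(0, 12, 1),
                       paste0("s", 1:12))
  z <- suppressWarnings(zscore_features(fg))
  expect_equal(unname(z$M[, 1]), as.numeric(x), tolerance = 1e-12)
})

test_that("feature CSV round trip preserves blocks, ids and labels", {
  z <- small_zscored_cohort(n = 3)
  d <- withr::local_tempdir()
  raw <- simulate_feature_table(cohort_spec(n_per_class = c(AD = 3, FTD = 3, NC = 3),
                                            seed = 5))$features
  write_feature_csv(raw, file.path(d, "f.csv"))
  back <- read_feature_csv(file.path(d, "f.csv"))
  expect_equal(unname(back$M), unname(raw$M), tolerance = 1e-12)
  expect_equal(unname(back$A), unname(raw$A), tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(raw$labels))
  expect_equal(back$study_id, raw$study_id)
})
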
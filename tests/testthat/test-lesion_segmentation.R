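# GM peak, thresholding, component labeling and the two refinement filters

test_that("GM peak recovery on sampled Gaussians (closed-form FWHM oracle)", {
  # FWHM of a Gaussian = 2*sqrt(2 ln 2) * sigma is the oracle behind sigma
  errs_mu <- errs_sigma <- numeric(5)
  for (i in 1:5) {
    set.seed(200 + i)
    x <- rnorm(1e5, 100, 10)
    v <- volume(array(x, dim = c(100, 100, 10)))
    pk <- estimate_gm_peak(v, full_mask(c(100, 100, 10)))
    errs_mu[i] <- abs(pk$mu - 100)
    errs_sigma[i] <- abs(pk$sigma - 10) / 10
    expect_equal(pk$sigma, pk$fwhm / (2 * sqrt(2 * log(2))), tolerance = 1e-9)
  }
  expect_lt(mean(errs_mu), 0.5)
  expect_lt(mean(errs_sigma), 0.02)
})

test_that("exact Gaussian quantile sample gives sigma within 0.1%", {
  n <- 2e5
  x <- qnorm((seq_len(n) - 0.5) / n, 100, 10)
  v <- volume(array(x, dim = c(200, 100, 10)))
  pk <- estimate_gm_peak(v, full_mask(c(200, 100, 10)))
  expect_lt(abs(pk$sigma - 10) / 10, 0.001)
  expect_lt(abs(pk$mu - 100), 0.05)
})

test_that("bimodal histogram: the dominant mode is chosen", {
  set.seed(5)
  x <- c(rnorm(9e4, 100, 10), rnorm(1e4, 160, 5))
  v <- volume(array(x, dim = c(100, 100, 10)))
  pk <- estimate_gm_peak(v, full_mask(c(100, 100, 10)))
  expect_lt(abs(pk$mu - 100), 2)
})

test_that("edge peaks and empty masks are errors, small masks warn", {
  # strictly increasing histogram: peak at the right edge
  x <- sqrt(seq(0, 1, length.out = 5000))
  v <- volume(array(x, dim = c(50, 10, 10)))
  expect_error(suppressWarnings(estimate_gm_peak(v, full_mask(c(50, 10, 10)))),
               "edge")
  empty <- binary_mask(array(0L, dim = c(8, 8, 8)))
  expect_error(estimate_gm_peak(rand_volume(), empty), "empty GM mask")
  set.seed(1)
  small <- volume(array(rnorm(512, 100, 10), dim = c(8, 8, 8)))
  expect_warning(estimate_gm_peak(small, full_mask(c(8, 8, 8))), "unstable")
})

test_that("compute_threshold is mu + alpha*sigma", {
  pk <- structure(list(mu = 100, fwhm = 10 * 2 * sqrt(2 * log(2)),
                       sigma = 10, bin_width = 0.5, n = 1000L),
                  class = "wml_gm_peak")
  expect_equal(compute_threshold(pk, 2.5), 125)
  expect_equal(compute_threshold(pk, 1e-9), 100, tolerance = 1e-6)
  expect_error(compute_threshold(pk, 0), "> 0")
  # default threshold covers > 98% of a Gaussian GM model
  expect_gt(pnorm(2.5), 0.98)
})

test_that("detect_candidates applies threshold, brain mask and exclusion", {
  shape <- c(10, 10, 10)
  a <- array(100, dim = shape)
  a[5, 5, 5] <- 130; a[2, 2, 2] <- 130
  flair <- volume(a)
  brain <- full_mask(shape)
  none <- detect_candidates(volume(array(100, dim = shape)), 120, brain)
  expect_equal(sum(none$data), 0)
  got <- detect_candidates(flair, 120, brain)
  expect_setequal(which(got$data == 1L), which(a == 130))
  excl <- array(0L, dim = shape); excl[2, 2, 2] <- 1L
  got2 <- detect_candidates(flair, 120, brain, binary_mask(excl))
  expect_equal(sum(got2$data), 1)
  expect_equal(got2$data[5, 5, 5], 1L)
  # threshold comparison is >= (exact boundary voxel is a candidate)
  a2 <- array(0, dim = shape); a2[3, 3, 3] <- 120
  expect_equal(sum(detect_candidates(volume(a2), 120, brain)$data), 1)
  small_brain <- binary_mask(array(0L, dim = c(9, 9, 9)))
  expect_error(detect_candidates(flair, 120, small_brain), "not co-registered")
})

test_that("phantom blob of 10 hyperintense voxels is flagged exactly", {
  spec <- phantom_spec(shape = c(32, 32, 32), seed = 6,
                       lesions = list(list(n_voxels = 10, offset = 8,
                                           placement = "deep")))
  ph <- generate_phantom(spec)
  vox <- which(ph$lesion_gt$labels == 1L)
  brain <- binary_mask(array(as.integer(ph$tissue_gt$labels > 0L),
                             dim = c(32, 32, 32)))
  # threshold between the GM tail (100 +- 5) and the blob (140 +- 5)
  cand <- detect_candidates(ph$flair, 122, brain)
  expect_setequal(which(cand$data == 1L), vox)
})

test_that("connected components: counts, connectivity, corner case", {
  shape <- c(10, 10, 10)
  m <- array(0L, dim = shape)
  m[2:3, 2:3, 2:3] <- 1L
  m[7:8, 7:8, 7:8] <- 1L
  les <- label_components(binary_mask(m))
  expect_equal(nrow(les$components), 2)
  expect_equal(sort(les$components$n_voxels), c(8, 8))
  expect_true(all(les$components$status == "candidate"))
  # two voxels touching only at a corner
  corner <- array(0L, dim = shape)
  corner[4, 4, 4] <- 1L; corner[5, 5, 5] <- 1L
  expect_equal(nrow(label_components(binary_mask(corner), 26)$components), 1)
  expect_equal(nrow(label_components(binary_mask(corner), 6)$components), 2)
  expect_equal(nrow(label_components(binary_mask(corner), 18)$components), 2)
  # edge-touching pair: one component at 18, two at 6
  edge <- array(0L, dim = shape)
  edge[4, 4, 4] <- 1L; edge[5, 5, 4] <- 1L
  expect_equal(nrow(label_components(binary_mask(edge), 18)$components), 1)
  expect_equal(nrow(label_components(binary_mask(edge), 6)$components), 2)
  empty <- label_components(binary_mask(array(0L, dim = shape)))
  expect_equal(nrow(empty$components), 0)
  expect_error(label_components(binary_mask(m), 10), "connectivity")
})

test_that("component volume equals count times voxel volume; ids contiguous", {
  m <- array(0L, dim = c(12, 12, 12))
  m[2:4, 2, 2] <- 1L
  m[8, 8, 8] <- 1L
  les <- label_components(binary_mask(m, spacing = c(0.5, 0.7, 1.1)))
  expect_equal(les$components$id, seq_len(nrow(les$components)))
  expect_equal(les$components$volume_mm3,
               les$components$n_voxels * 0.5 * 0.7 * 1.1, tolerance = 1e-9)
})

test_that("size filter removes below 3 mm^3 with strict-less-than semantics", {
  m <- array(0L, dim = c(16, 16, 16))
  m[2:3, 2, 2] <- 1L          # 2 voxels = 2 mm^3 -> removed
  m[6:8, 6, 6] <- 1L          # 3 voxels = 3 mm^3 -> kept (boundary)
  m[10:13, 10, 10] <- 1L      # 4 voxels -> kept
  m[2:6, 14, 14] <- 1L        # 5 voxels -> kept
  les <- filter_by_size(label_components(binary_mask(m)), 3)
  st <- les$components$status[order(les$components$n_voxels)]
  expect_equal(st, c("removed_size", "candidate", "candidate", "candidate"))
  # non-unit spacing: volume is what counts, not voxels
  les2 <- filter_by_size(label_components(binary_mask(m, spacing = c(2, 1, 1))), 3)
  expect_true(all(les2$components$status == "candidate"))
})

test_that("neighborhood WM ratio counts the 26-shell, background excluded", {
  shape <- c(7, 7, 7)
  lab <- array(0L, dim = shape)
  lab[4, 4, 4] <- 1L
  # single voxel: shell of 26; 20 WM, 6 GM
  tis <- array(3L, dim = shape)
  tis[3:4, 3:5, 3] <- 2L  # 6 GM voxels inside the shell
  expect_equal(sum(tis[3:5, 3:5, 3:5] == 2L), 6)
  les <- lesions_from_labels(lab)
  les <- neighborhood_wm_ratio(les, tissue_labels_obj(tis))
  expect_equal(les$components$wm_ratio, 20 / 26, tolerance = 1e-12)
  # all-WM shell
  les2 <- neighborhood_wm_ratio(lesions_from_labels(lab),
                                tissue_labels_obj(array(3L, dim = shape)))
  expect_equal(les2$components$wm_ratio, 1)
  # background shell voxels drop out of numerator and denominator
  tis3 <- array(0L, dim = shape)
  tis3[5, 4, 4] <- 3L; tis3[3, 4, 4] <- 2L
  les3 <- neighborhood_wm_ratio(lesions_from_labels(lab),
                                tissue_labels_obj(tis3))
  expect_equal(les3$components$wm_ratio, 0.5)
  # all-background shell -> ratio defined as 0
  les4 <- neighborhood_wm_ratio(lesions_from_labels(lab),
                                tissue_labels_obj(array(0L, dim = shape)))
  expect_equal(les4$components$wm_ratio, 0)
})

test_that("neighborhood filter keeps ratio >= lambda (boundary inclusive)", {
  shape <- c(16, 8, 8)
  lab <- array(0L, dim = shape)
  lab[2, 4, 4] <- 1L; lab[8, 4, 4] <- 2L; lab[14, 4, 4] <- 3L
  tis <- array(3L, dim = shape)
  # comp 2: make exactly half of its 26-voxel shell GM -> ratio 0.5
  tis[7:9, 3:5, 3] <- 2L
  tis[7:9, 3, 4] <- 2L
  tis[7, 5, 4] <- 2L
  expect_equal(sum(tis[7:9, 3:5, 3:5] == 2L), 13)
  les <- lesions_from_labels(lab)
  les <- neighborhood_wm_ratio(les, tissue_labels_obj(tis))
  r <- les$components$wm_ratio
  expect_equal(r[1], 1)
  expect_equal(r[2], 0.5)
  out <- filter_by_neighborhood(les, tissue_labels_obj(tis), lambda = 0.70)
  st <- out$components$status
  expect_equal(st[1], "candidate")           # ratio 1.0 kept
  expect_equal(st[2], "removed_neighborhood") # ratio 0.5 removed
  # exact boundary: ratio == lambda is kept
  out2 <- filter_by_neighborhood(les, tissue_labels_obj(tis), lambda = 0.5)
  expect_equal(out2$components$status[2], "candidate")
})

test_that("full pipeline on a clean phantom keeps exactly the true lesions", {
  ph <- clean_phantom(shape = c(48, 48, 48), seed = 3, sizes = c(4, 8, 15, 30))
  res <- segment_lesions(ph$t1, ph$flair, ph$pf_mask, seed = 3)
  det <- match_lesions(res$lesions, ph$lesion_gt)
  expect_equal(det$tpr, 1)
  expect_equal(det$ppv, 1)
  expect_gte(dice(res$mask, ph$lesion_gt), 0.99)
  # report carries the stage record
  expect_named(res$report,
               c("mu", "sigma", "fwhm", "threshold", "alpha", "lambda",
                 "min_volume_mm3", "seed", "n_candidates", "n_removed_size",
                 "n_removed_neighborhood", "n_kept"))
  expect_equal(res$report$n_kept, 4)
})

test_that("posterior-fossa hyperintensity never reaches the candidate stage", {
  spec <- phantom_spec(shape = c(48, 48, 48), seed = 9,
                       lesions = lapply(c(8, 15), function(k)
                         list(n_voxels = k, offset = 6, placement = "deep")),
                       artifacts = list(list(n_voxels = 15, offset = 6,
                                             placement = "pf")))
  ph <- generate_phantom(spec)
  res <- segment_lesions(ph$t1, ph$flair, ph$pf_mask, seed = 9)
  ctx <- res$context
  thr <- res$report$threshold
  cand <- detect_candidates(ctx$flair_corr, thr, ctx$brain_mask, ctx$exclusion)
  pf_vox <- ph$artifact_voxels[[1]]
  expect_true(all(ctx$flair_corr$data[pf_vox] >= thr))  # it is hyperintense
  expect_equal(sum(cand$data[pf_vox]), 0)               # but never a candidate
  expect_equal(sum(res$mask$data[pf_vox]), 0)
})

test_that("a 2-voxel hyperintensity is reported as removed_size", {
  spec <- phantom_spec(shape = c(48, 48, 48), seed = 13,
                       lesions = list(list(n_voxels = 12, offset = 6,
                                           placement = "deep"),
                                      list(n_voxels = 2, offset = 6,
                                           placement = "deep")))
  ph <- generate_phantom(spec)
  res <- segment_lesions(ph$t1, ph$flair, ph$pf_mask, seed = 13)
  two_vox <- which(ph$lesion_gt$labels == 2L)
  expect_equal(sum(res$mask$data[two_vox]), 0)
  ids <- unique(res$lesions$labels[two_vox])
  ids <- ids[ids > 0]
  expect_gte(length(ids), 1)
  expect_true(all(res$lesions$components$status[ids] == "removed_size"))
})

test_that("filters only remove: mask nesting along the pipeline", {
  ph <- clean_phantom(shape = c(48, 48, 48), seed = 21, sizes = c(5, 12, 20))
  res <- segment_lesions(ph$t1, ph$flair, ph$pf_mask, seed = 21)
  ctx <- res$context
  cand <- detect_candidates(ctx$flair_corr, res$report$threshold,
                            ctx$brain_mask, ctx$exclusion)
  expect_true(all(res$mask$data <= cand$data))
  expect_true(all(cand$data <= ctx$brain_mask$data))
  comp <- res$lesions$components
  kept <- comp[comp$status == "kept", ]
  expect_true(all(kept$volume_mm3 >= 3))
  expect_true(all(kept$wm_ratio >= 0.70))
})

test_that("alpha and lambda monotonicity on a randomized phantom", {
  ph <- generate_suite(1, c(1, 0, 0), shape = c(32, 32, 32), seed = 31)[[1]]
  ctx <- segmentation_context(ph$t1, ph$flair, ph$pf_mask, seed = 31)
  alphas <- c(1, 1.5, 2, 2.5, 3)
  masks <- lapply(alphas, function(a)
    detect_candidates(ctx$flair_corr, compute_threshold(ctx$gm_peak, a),
                      ctx$brain_mask, ctx$exclusion)$data)
  for (i in seq_len(length(alphas) - 1))
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  lambdas <- c(0, 0.3, 0.7, 0.9, 1)
  kept <- lapply(lambdas, function(l) {
    r <- wmlseg:::apply_segmentation(ctx, segmentation_params(lambda = l))
    sum(r$lesions$components$status == "kept")
  })
  expect_true(all(diff(unlist(kept)) <= 0))
})

test_that("segmentation is bit-deterministic for a fixed seed", {
  ph <- clean_phantom(shape = c(32, 32, 32), seed = 17, sizes = c(6, 14))
  a <- segment_lesions(ph$t1, ph$flair, ph$pf_mask, seed = 17)
  b <- segment_lesions(ph$t1, ph$flair, ph$pf_mask, seed = 17)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$report, b$report)
})

test_that("stage failures name the failing stage", {
  bad <- volume(array(1, dim = c(32, 32, 32)))
  ph <- clean_phantom(shape = c(32, 32, 32), seed = 1, sizes = c(5))
  expect_error(segment_lesions(bad, ph$flair, seed = 1),
               "stage 'fit_three_class_em'")
  small <- rand_volume(c(16, 16, 16))
  expect_error(segment_lesions(small, ph$flair, seed = 1),
               "stage 'assert_coregistered'")
})
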
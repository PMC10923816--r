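blob_image <- function(grid, cx, cy, s = 0.02, modality = "beamography") {
  pts <- emibrain:::grid_points(grid)
  v <- exp(-((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) / (2 * s^2))
  intensity_image(matrix(v, length(grid$x), length(grid$y)), grid,
                  modality = modality)
}

test_that("co-registration is the identity on the common grid and normalization idempotent", {
  grid <- t_grid()
  img <- blob_image(grid, 0.02, 0.03)
  out <- coregister_normalize(list(img), grid)[[1]]
  expect_equal(out$values, img$values / max(img$values), tolerance = 1e-12)
  out2 <- coregister_normalize(list(out), grid)[[1]]
  expect_equal(out2$values, out$values, tolerance = 1e-12)
  # constant image -> all zeros with degenerate flag
  const <- intensity_image(matrix(1, length(grid$x), length(grid$y)), grid,
                           "dmm", normalize = FALSE)
  flat <- coregister_normalize(list(const), grid)[[1]]
  expect_true(all(flat$values == 0))
  expect_true(attr(flat, "degenerate"))
  expect_error(coregister_normalize(list(), grid), "empty")
})

test_that("resampling onto a different grid preserves peak location", {
  fine <- make_image_grid(spacing = 0.002)
  coarse <- make_image_grid(spacing = 0.004)
  img <- blob_image(fine, 0.024, -0.036)
  out <- coregister_normalize(list(img), coarse)[[1]]
  expect_lte(max(abs(image_peak(out) - c(0.024, -0.036))), 0.004 + 1e-12)
})

test_that("agreement region follows the K-of-N rule with fallback and tau monotonicity", {
  grid <- t_grid()
  same <- lapply(c("linecross", "dmm", "beamography", "evsla"), function(m)
    blob_image(grid, 0.02, 0.02, modality = m))
  same <- coregister_normalize(same, grid)
  mask <- agreement_region(same, tau = 0.5, min_agree = 3)
  expect_equal(attr(mask, "k_used"), 3)
  expect_false(attr(mask, "fallback"))
  expect_equal(unname(mask), unname(same[[1]]$values > 0.5), ignore_attr = TRUE)
  # pairwise-disjoint blobs: fallback to K = 1, union reported
  corners <- list(c(0.06, 0.08), c(-0.06, 0.08), c(0.06, -0.08), c(-0.06, -0.08))
  disjoint <- coregister_normalize(lapply(seq_along(corners), function(i)
    blob_image(grid, corners[[i]][1], corners[[i]][2], s = 0.008)), grid)
  mask2 <- agreement_region(disjoint, tau = 0.5, min_agree = 3)
  expect_equal(attr(mask2, "k_used"), 1)
  expect_true(attr(mask2, "fallback"))
  union <- Reduce(`|`, lapply(disjoint, function(im) im$values > 0.5))
  expect_equal(unname(mask2), unname(union), ignore_attr = TRUE)
  # monotone non-increasing in tau
  a1 <- sum(agreement_region(same, tau = 0.3, min_agree = 3))
  a2 <- sum(agreement_region(same, tau = 0.6, min_agree = 3))
  a3 <- sum(agreement_region(same, tau = 0.9, min_agree = 3))
  expect_true(a1 >= a2 && a2 >= a3)
})

test_that("smooth/dilate heatmap is supported on the dilated mask and dilation is monotone", {
  grid <- t_grid()
  imgs <- coregister_normalize(list(blob_image(grid, 0.02, 0.02),
                                    blob_image(grid, 0.022, 0.018)), grid)
  mask <- agreement_region(imgs, tau = 0.5, min_agree = 2)
  out <- smooth_dilate_overlay(imgs, mask, grid)
  expect_true(all(out$heatmap$values[!out$mask_dilated] == 0))
  expect_true(all(out$mask_dilated[mask]))
  out4 <- smooth_dilate_overlay(imgs, mask, grid, dilate_px = 4)
  expect_gte(sum(out4$mask_dilated), sum(out$mask_dilated))
  # zero images -> zero heatmap
  z <- intensity_image(matrix(0, length(grid$x), length(grid$y)), grid,
                       "dmm", normalize = FALSE)
  zz <- smooth_dilate_overlay(list(z, z), mask, grid)
  expect_equal(max(zz$heatmap$values), 0)
})

test_that("decision fusion combines ensemble and DMM votes as specified", {
  mk_ens <- function(p, lab) {
    list(fused = stats::setNames(p, c("healthy", "ICH", "IS")), label = lab,
         certainty = max(p))
  }
  # both agree on ICH
  f1 <- fuse_decisions(mk_ens(c(0.05, 0.9, 0.05), "ICH"), "ICH", TRUE)
  expect_equal(f1$label, "ICH")
  # ensemble healthy + DMM no detection
  f2 <- fuse_decisions(mk_ens(c(0.9, 0.05, 0.05), "healthy"), "n/a", FALSE)
  expect_equal(f2$label, "healthy")
  # lukewarm ensemble ICH backed by DMM ICH: certainty rises above 0.5
  f3 <- fuse_decisions(mk_ens(c(0.3, 0.5, 0.2), "ICH"), "ICH", TRUE)
  expect_equal(f3$label, "ICH")
  expect_gt(f3$certainty, 0.5)
  # stated arithmetic: weights are the two certainties
  manual <- (0.5 * c(0.3, 0.5, 0.2) + 0.8 * c(0.1, 0.8, 0.1)) / 1.3
  expect_equal(unname(f3$probs), manual / sum(manual), tolerance = 1e-12)
  expect_equal(sum(f3$probs), 1, tolerance = 1e-9)
})

mini_models <- function() memo("mini_models", {
  suppressWarnings(train_models(
    seed = 42L, sweep = t_sweep(), array = t_array(), prop = t_prop(),
    n_train_ensemble = 12L, n_boundary = 60L, n_dmm_null = 10L,
    grid_spacing = t_spacing))
})

mini_patient <- function(stroke_class, seed) {
  coh <- generate_cohort(1, stats::setNames(1, stroke_class),
                         scans_per_patient = 5L, seed = seed,
                         sweep = t_sweep(), array = t_array(),
                         prop = t_prop(), outlier_prob = 0,
                         grid_spacing = t_spacing)
  coh$patients[[1]]
}

test_that("pipeline rerun with identical inputs is byte-identical, heatmap peak in mask", {
  models <- mini_models()
  p <- mini_patient("ICH", 77L)
  grid <- t_grid()
  out1 <- run_pipeline(p$scans, p$cal, models, grid)
  out2 <- run_pipeline(p$scans, p$cal, models, grid)
  r1 <- pipeline_report(out1)
  r2 <- pipeline_report(out2)
  expect_identical(r1, r2)
  expect_identical(charToRaw(r1), charToRaw(r2))
  # fused heatmap argmax lies inside the dilated agreement region
  idx <- which(out1$heatmap$values == max(out1$heatmap$values),
               arr.ind = TRUE)[1, ]
  expect_true(out1$mask_dilated[idx[1], idx[2]])
  # JSON report fields
  js <- jsonlite::fromJSON(r1)
  expect_true(all(c("fused_class", "certainty", "quadrant", "peak_xy_m",
                    "modality_peaks", "dmm_detect", "boundary_mm") %in%
                    names(js)))
  # render writes a PNG
  png_path <- withr::local_tempfile(fileext = ".png")
  render_fusion(out1, png_path)
  expect_gt(file.info(png_path)$size, 100)
})

test_that("pipeline stage failures are reported with the stage name", {
  models <- mini_models()
  p <- mini_patient("ICH", 78L)
  bad_cal <- p$cal
  bad_cal$low$sweep <- bad_cal$low$sweep * 2
  expect_error(run_pipeline(p$scans, bad_cal, models, t_grid()),
               "stage 'calibrate'")
})

test_that("healthy patients come out healthy with a quiet heatmap", {
  models <- mini_models()
  p <- mini_patient("healthy", 79L)
  out <- run_pipeline(p$scans, p$cal, models, t_grid())
  expect_equal(out$fused_class, "healthy")
  expect_false(out$dmm$detect$detect)
})
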
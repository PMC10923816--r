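diff_for <- function(ds) {
  tds <- to_time_domain(ds)
  differential_matrices(channel_metric_matrices(tds), ds$array)
}

test_that("mirror-symmetric phantoms give near-vanishing differential matrices", {
  ds <- memo("sym_ds", t_forward(t_symmetric_phantom()))
  dm <- memo("sym_dm", diff_for(ds))
  for (nm in c("degree", "strength", "entropy")) {
    ratio <- norm(dm[[paste0("D_", nm)]], "F") / norm(dm$M[[nm]], "F")
    expect_lt(ratio, 0.05)
  }
})

test_that("mirror conjugation negates D (P D P' = -D)", {
  ds <- memo("lc_ich_ds", t_forward(t_diseased_phantom(31)))
  dm <- memo("lc_ich_dm", diff_for(ds))
  m <- mirror_index(seq_len(ds$array$n), ds$array)
  for (nm in c("D_degree", "D_strength", "D_entropy")) {
    D <- dm[[nm]]
    expect_lt(max(abs(D[m, m] + D)), 1e-9)
  }
  # permuting the dataset by the mirror permutation negates D too
  ds2 <- ds
  ds2$s <- ds$s[m, m, , drop = FALSE]
  D2 <- diff_for(ds2)$D_entropy
  expect_equal(D2, -dm$D_entropy, tolerance = 1e-9)
})

test_that("a unilateral bleed pushes differential entropy past the healthy null", {
  # acquisition as in the clinical protocol: full band, 20 averaged scans
  sw <- frequency_sweep(n = 41L)
  avg_scans <- function(ph, seed0) {
    base <- forward_scatter(ph, t_array(), sw, t_prop(), 0.002)
    average_scans(lapply(1:20, function(k)
      add_noise(base, noise_model(snr_db = 30), seed = seed0 + k)))
  }
  bnd <- list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0)
  healthy_norms <- memo("lc_healthy_norms", vapply(1:8, function(k) {
    ds <- avg_scans(head_phantom(bnd), 400 + 10 * k)
    norm(diff_for(ds)$D_entropy, "F")
  }, 0))
  inc <- stroke_inclusion("ICH", c(0.035, 0.020), 0.018)
  ds <- avg_scans(head_phantom(bnd, inc), 900)
  ich_norm <- norm(diff_for(ds)$D_entropy, "F")
  expect_gt(ich_norm, stats::quantile(healthy_norms, 0.95))
})

test_that("features are deterministic and 39-dimensional", {
  dm <- memo("lc_ich_dm", diff_for(memo("lc_ich_ds",
                                        t_forward(t_diseased_phantom(31)))))
  f <- feature_vector(dm)
  expect_length(f, 39L)
  expect_identical(f, feature_vector(dm))
  expect_true(all(is.finite(f)))
})

toy_features <- function(n_per, seed) {
  # linearly separable 3-class toy set
  set.seed(seed)
  lab <- rep(c("healthy", "ICH", "IS"), each = n_per)
  mu <- rbind(healthy = c(0, 0), ICH = c(6, 0), IS = c(0, 6))
  x <- mu[lab, ] + matrix(stats::rnorm(2 * length(lab), 0, 0.5),
                          ncol = 2)
  x <- cbind(x, x[, 1] - x[, 2])
  colnames(x) <- c("f1", "f2", "f3")
  list(x = x, lab = lab)
}

test_that("every classifier separates a separable toy set and training is seeded", {
  tr <- toy_features(20, 1)
  te <- toy_features(10, 2)
  ens <- train_ensemble(tr$x, tr$lab, seed = 3)
  per_cls_hits <- matrix(0, nrow(te$x), 4,
                         dimnames = list(NULL, c("rf", "knn", "nb", "svm")))
  fused_hits <- logical(nrow(te$x))
  for (i in seq_len(nrow(te$x))) {
    res <- classify_ensemble(te$x[i, ], ens)
    fused_hits[i] <- res$label == te$lab[i]
    per_cls_hits[i, ] <- vapply(rownames(res$per_classifier), function(cl)
      names(which.max(res$per_classifier[cl, ])) == te$lab[i], TRUE)
  }
  expect_true(all(colMeans(per_cls_hits) >= 0.95))
  expect_true(all(fused_hits))
  # retraining with the same seed reproduces the model decisions
  ens2 <- train_ensemble(tr$x, tr$lab, seed = 3)
  res1 <- classify_ensemble(te$x[1, ], ens)
  res2 <- classify_ensemble(te$x[1, ], ens2)
  expect_identical(res1$fused, res2$fused)
})

test_that("label permutation drops accuracy to chance level", {
  tr <- toy_features(40, 1)
  te <- toy_features(40, 2)
  accs <- vapply(1:6, function(p) {
    set.seed(p + 10)
    ens <- train_ensemble(tr$x, sample(tr$lab), seed = p)
    mean(vapply(seq_len(nrow(te$x)), function(i)
      classify_ensemble(te$x[i, ], ens)$label == te$lab[i], TRUE))
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.1)
})

test_that("probability fusion follows the certainty-weighted mean and its invariances", {
  lv <- c("healthy", "ICH", "IS")
  mk <- function(...) {
    per <- rbind(...)
    colnames(per) <- lv
    rownames(per) <- c("rf", "knn", "nb", "svm")
    per
  }
  # unanimous certainty-1 votes
  res <- emibrain:::fuse_probability_rows(mk(c(0, 1, 0), c(0, 1, 0),
                                             c(0, 1, 0), c(0, 1, 0)))
  expect_equal(res$label, "ICH")
  expect_equal(res$certainty, 1)
  # two ICH @ 0.9 vs two IS @ 0.6: ICH wins the certainty-weighted mean
  per <- mk(c(0.05, 0.9, 0.05), c(0.05, 0.9, 0.05),
            c(0.2, 0.2, 0.6), c(0.2, 0.2, 0.6))
  res2 <- emibrain:::fuse_probability_rows(per)
  expect_equal(res2$label, "ICH")
  manual <- colSums(per * c(0.9, 0.9, 0.6, 0.6)) / 3
  expect_equal(unname(res2$fused), unname(manual / sum(manual)),
               tolerance = 1e-12)
  expect_equal(sum(res2$fused), 1, tolerance = 1e-9)
  # order invariance
  res3 <- emibrain:::fuse_probability_rows(per[c(3, 1, 4, 2), ])
  expect_equal(res3$fused, res2$fused, tolerance = 1e-12)
})

test_that("training refuses a single-class set and inference checks dimensions", {
  tr <- toy_features(10, 1)
  expect_error(train_ensemble(tr$x[1:10, ], tr$lab[1:10], seed = 1),
               "single class")
  ens <- train_ensemble(tr$x, tr$lab, seed = 1)
  expect_error(classify_ensemble(c(1, 2), ens), "dimension")
})

test_that("line-crossing maps: flat for uniform weights, corridor support, null for symmetric input", {
  arr <- t_array()
  bnd <- list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0)
  grid <- t_grid()
  # uniform weights -> near-flat map after coverage normalization
  W <- matrix(1, arr$n, arr$n)
  img <- linecross_map(W, arr, bnd, grid)
  inside <- ellipse_norm(emibrain:::grid_points(grid)[, 1],
                         emibrain:::grid_points(grid)[, 2], bnd) < 1
  covered <- as.vector(img$values)[inside]
  covered <- covered[covered > 0]
  expect_lt(max(covered) - min(covered), 0.1)
  # single nonzero channel -> support only inside that ray corridor
  W2 <- matrix(0, arr$n, arr$n); W2[2, 9] <- 1
  img2 <- linecross_map(W2, arr, bnd, grid)
  pts <- emibrain:::grid_points(grid)
  d <- emibrain:::dist_point_segment(pts, arr$positions[2, ], arr$positions[9, ])
  on_support <- as.vector(img2$values) > 0
  expect_true(all(d[on_support] <= 0.006 + 1e-12))
  # symmetric phantom -> essentially flat weights, no dominant corridor
  dm <- memo("sym_dm", diff_for(memo("sym_ds", t_forward(t_symmetric_phantom()))))
  img3 <- linecross_map(dm$D_entropy, arr, bnd, grid)
  expect_lt(attr(img3, "max_raw"),
            attr(linecross_map(memo("lc_ich_dm", diff_for(memo("lc_ich_ds",
              t_forward(t_diseased_phantom(31)))))$D_entropy,
              arr, bnd, grid), "max_raw"))
})

test_that("missing boundary falls back to the default ellipse with a warning", {
  arr <- t_array()
  W <- matrix(1, arr$n, arr$n)
  expect_warning(linecross_map(W, arr, NULL, t_grid()), "boundary")
})
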
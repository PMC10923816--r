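test_that("distance correlation matches the naive oracle and its identities", {
  set.seed(4)
  for (rep_i in 1:5) {
    x <- stats::rnorm(40)
    y <- 0.5 * x + stats::rnorm(40)
    expect_equal(distance_correlation(x, y), dcor_oracle(x, y),
                 tolerance = 1e-12)
  }
  x <- stats::rnorm(60)
  expect_equal(distance_correlation(x, x), 1, tolerance = 1e-12)
  expect_true(is.na(distance_correlation(rep(1, 30), stats::rnorm(30))))
})

test_that("mirror-symmetric data yield an ambiguous side call; lesions pick their side", {
  ds <- memo("sym_ds", t_forward(t_symmetric_phantom()))
  aff <- affected_side(ds)
  expect_true(aff$ambiguous)
  expect_equal(aff$side, "left")  # stated default under ties
  hits <- 0
  for (seed in c(31, 44, 57)) {
    ph <- t_diseased_phantom(seed)
    dsd <- add_noise(t_forward(ph), noise_model(30), seed)
    truth <- if (ph$inclusion$center[1] > 0) "left" else "right"
    hits <- hits + (affected_side(dsd)$side == truth)
  }
  expect_gte(hits, 2)
})

test_that("symmetry subtraction nulls symmetric data and is mirror-antisymmetric", {
  ds <- memo("sym_ds", t_forward(t_symmetric_phantom()))
  csd <- symmetry_subtract(ds, "left")
  expect_lt(max(Mod(csd$dS$s)), 1e-12 * max(Mod(ds$s)))
  dsd <- t_forward(t_diseased_phantom(44))
  csd2 <- symmetry_subtract(dsd, "left")
  m <- mirror_index(seq_len(ds$array$n), ds$array)
  expect_lt(max(Mod(csd2$dS$s[m, m, , drop = FALSE] + csd2$dS$s)), 1e-12)
  # redundancy down-weights: healthy-side channels at 1/2
  side <- antenna_side(ds$array)
  expect_true(all(csd2$u[side == "right", side == "right"] == 0.5))
  expect_true(all(csd2$u[side == "left", side == "left"] == 1))
})

test_that("symmetric clutter cancels exactly, leaving only the target differential", {
  bnd <- list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0)
  inc <- stroke_inclusion("ICH", c(0.04, 0.03), 0.012)
  full <- t_forward(head_phantom(bnd, inc))
  # same target in a transparent head: scattered-only reference (Born oracle
  # with vs without the boundary term)
  target_only <- t_forward(head_phantom(bnd, inc,
                                        eps_brain = t_prop()$eps_b,
                                        sigma_brain = t_prop()$sigma_b))
  d_full <- symmetry_subtract(full, "left")$dS$s
  d_target <- symmetry_subtract(target_only, "left")$dS$s
  scale <- max(Mod(target_only$s))
  # the symmetric clutter term drops out of the differential entirely
  expect_lt(max(Mod(d_full - d_target)) / scale, 1e-9)
  # and the surviving signal is of the target's own order: at least the raw
  # target response, at most twice it (target plus coherent mirror ghost)
  expect_gte(max(Mod(d_full)) / scale, 1)
  expect_lte(max(Mod(d_full)) / scale, 2)
})

test_that("average subtraction zeroes the channel mean, kills constants, and is idempotent", {
  dsd <- t_forward(t_diseased_phantom(44))
  csd <- average_subtract(symmetry_subtract(dsd, "left"))
  mu <- apply(csd$dS$s, 3, mean)
  expect_lt(max(Mod(mu)), 1e-12 * max(Mod(dsd$s)))
  csd2 <- average_subtract(csd)
  expect_equal(csd2$dS$s, csd$dS$s, tolerance = 1e-12)
  const <- scattering_dataset(array(0.3 + 0.1i, c(16, 16, length(t_sweep()))),
                              t_sweep(), t_array())
  expect_lt(max(Mod(average_subtract(const)$s)), 1e-12)
})

test_that("back-propagation focuses a noise-free Born point target within one pixel", {
  arr <- t_array(); prop <- t_prop()
  sw <- frequency_sweep(0.7e9, 1.2e9, n = 11L)
  grid <- make_image_grid(spacing = 0.002)
  r0 <- c(0.030, 0.040)
  sp <- 0.0035
  ph <- head_phantom(boundary = list(cx = r0[1], cy = r0[2], a = 0.6 * sp,
                                     b = 0.6 * sp, rot = 0),
                     eps_brain = 55, sigma_brain = 0.3)
  ds <- forward_scatter(ph, arr, sw, prop, sp)
  img <- backpropagate(ds, prop, grid)
  expect_lte(max(abs(image_peak(img) - r0)), grid$spacing + 1e-12)
  # zero data -> zero image
  z <- scattering_dataset(array(0 + 0i, dim(ds$s)), sw, arr)
  expect_equal(max(backpropagate(z, prop, t_grid())$values), 0)
})

test_that("two well-separated scatterers appear as two local maxima near truth", {
  arr <- t_array(); prop <- t_prop()
  sw <- frequency_sweep(0.7e9, 1.2e9, n = 11L)
  grid <- make_image_grid(spacing = 0.002)
  sp <- 0.0035
  mk <- function(r0) forward_scatter(
    head_phantom(boundary = list(cx = r0[1], cy = r0[2], a = 0.6 * sp,
                                 b = 0.6 * sp, rot = 0),
                 eps_brain = 55, sigma_brain = 0.3), arr, sw, prop, sp)
  r1 <- c(-0.030, 0.040); r2 <- c(0.025, -0.035)
  ds <- mk(r1)
  ds2 <- mk(r2)
  both <- scattering_dataset(ds$s + ds2$s, sw, arr)
  img <- backpropagate(both, prop, grid)
  near <- function(r) {
    pts <- emibrain:::grid_points(grid)
    sel <- (pts[, 1] - r[1])^2 + (pts[, 2] - r[2])^2 < 0.004^2
    max(as.vector(img$values)[sel])
  }
  # both truth neighbourhoods carry near-maximal intensity
  expect_gt(near(r1), 0.7)
  expect_gt(near(r2), 0.7)
})

test_that("a common phase factor on all channels leaves the image unchanged", {
  dsd <- t_forward(t_diseased_phantom(57))
  csd <- average_subtract(symmetry_subtract(dsd, "left"))
  img1 <- backpropagate(csd, t_prop(), t_grid())
  csd$dS$s <- csd$dS$s * exp(1i * 0.83)
  img2 <- backpropagate(csd, t_prop(), t_grid())
  expect_equal(img2$values, img1$values, tolerance = 1e-9)
  expect_equal(attr(img2, "max_raw"), attr(img1, "max_raw"), tolerance = 1e-9)
})

test_that("symmetric phantoms image to at most 5% of a matched diseased phantom", {
  grid <- t_grid()
  sym <- memo("sym_ds", t_forward(t_symmetric_phantom()))
  img_null <- backpropagate(average_subtract(symmetry_subtract(sym, "left")),
                            t_prop(), grid)
  dis <- t_forward(t_diseased_phantom(44))
  img_dis <- backpropagate(average_subtract(symmetry_subtract(dis, "left")),
                           t_prop(), grid)
  expect_lt(attr(img_null, "max_raw"), 0.05 * attr(img_dis, "max_raw"))
})

test_that("pixels within the antenna guard ring are excluded", {
  dsd <- t_forward(t_diseased_phantom(44))
  csd <- average_subtract(symmetry_subtract(dsd, "left"))
  grid <- make_image_grid(spacing = 0.004, half_x = 0.14, half_y = 0.16)
  img <- backpropagate(csd, t_prop(), grid, guard = 0.006)
  pts <- emibrain:::grid_points(grid)
  for (a in seq_len(dsd$array$n)) {
    d2 <- (pts[, 1] - dsd$array$positions[a, 1])^2 +
      (pts[, 2] - dsd$array$positions[a, 2])^2
    expect_true(all(as.vector(img$values)[d2 <= 0.006^2] == 0))
  }
})
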
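#' Polar map configuration for the Direct Mapping Method
#'
#' Antennas close to each other are sensitive to shallow anomalies, antennas
#' far apart to deep ones: each ordered transmit-receive pair maps to one
#' polar cell with angle = the pair's circular-midpoint angle and radius
#' decreasing with antenna separation (`r = R (1 - sep/sep_max)`, so
#' separation 0 is the outermost ring and the diametric pair the centre).
#'
#' @param n_sectors angular sectors (default 16).
#' @param n_rings radial rings (default 9, separations 0..8 of a 16-element
#'   array).
#' @return class `"polar_map"`.
#' @export
polar_map <- function(n_sectors = 16L, n_rings = 9L) {
  structure(list(n_sectors = as.integer(n_sectors),
                 n_rings = as.integer(n_rings)),
            class = "polar_map")
}

#' Polar cell of a transmit-receive antenna pair
#'
#' @param i,j antenna indices (1-based; i = j allowed, a reflection channel).
#' @param array the [antenna_array()].
#' @param polar a [polar_map()].
#' @return integer vector `(theta_idx, rho_idx)`, both 1-based;
#'   `rho_idx = 1` is the outermost ring (separation 0).
#' @export
pair_to_polar_cell <- function(i, j, array, polar = polar_map()) {
  na <- array$n
  sep <- pmin(abs(i - j), na - abs(i - j))
  # circular midpoint along the shorter arc between the two placement angles
  ti <- array$angles_deg[i]; tj <- array$angles_deg[j]
  d <- ((tj - ti + 180) %% 360) - 180
  mid <- (ti + d / 2) %% 360
  # floor(x + 0.5): midpoints of odd-separation pairs sit exactly on sector
  # edges and must tie-break consistently for rotation equivariance
  sector <- (floor(mid / (360 / polar$n_sectors) + 0.5) %% polar$n_sectors) + 1L
  c(theta_idx = as.integer(sector), rho_idx = as.integer(sep) + 1L)
}

#' Receiver sensitivity profile
#'
#' Array-specific per-pair weight compensating channel sensitivity,
#' defined as the inverse mean magnitude of the low calibration phantom's
#' response, clipped to [1, 100].
#'
#' @param cal_low the measured (or synthesized) low-reference
#'   [scattering_dataset()].
#' @return Na x Na positive matrix.
#' @export
sensitivity_profile <- function(cal_low) {
  m <- apply(Mod(cal_low$s), c(1, 2), mean)
  w <- 1 / pmax(m, 1e-12)
  w <- w / min(w)                 # dimensionless, >= 1
  pmin(pmax(w, 1), 100)
}

#' Direct Mapping Method image
#'
#' Applies the polar re-mapping to differential data for all frequency
#' points individually and aggregates: cell value = `w_ij sum_f |dS_ij(f)|`,
#' pairs sharing a cell averaged, then resampled to the Cartesian head grid
#' by nearest sector/ring lookup (radius normalized by the boundary
#' ellipse).
#'
#' @param dS differential [scattering_dataset()] (patient calibrated data
#'   minus symmetric or background reference, see [dmm_reference_delta()]).
#' @param profile a [sensitivity_profile()] matrix.
#' @param boundary boundary ellipse (list or [estimate_boundary()]).
#' @param grid an [make_image_grid()].
#' @param polar a [polar_map()].
#' @return class `"dmm_result"` with the `"dmm"`-modality image, the polar
#'   cell table, and `intensity_stat` (total unnormalized image mass).
#' @export
dmm_image <- function(dS, profile, boundary = NULL, grid = make_image_grid(),
                      polar = polar_map()) {
  if (is.null(profile)) stop("missing calibration: sensitivity profile required")
  na <- dS$array$n
  cells <- matrix(0, polar$n_sectors, polar$n_rings)
  counts <- matrix(0, polar$n_sectors, polar$n_rings)
  tab <- vector("list", na * na)
  idx <- 0
  for (i in seq_len(na)) for (j in seq_len(na)) {
    cell <- pair_to_polar_cell(i, j, dS$array, polar)
    v <- profile[i, j] * sum(Mod(dS$s[i, j, ]))
    cells[cell[1], cell[2]] <- cells[cell[1], cell[2]] + v
    counts[cell[1], cell[2]] <- counts[cell[1], cell[2]] + 1
    idx <- idx + 1
    tab[[idx]] <- data.frame(i = i, j = j, theta_idx = cell[1],
                             rho_idx = cell[2], value = v)
  }
  inner <- polar$n_rings
  if (any(counts[, inner] > 0)) {
    # the innermost ring is the single centre point: all sectors coincide,
    # so pool their mass before the per-cell averaging
    cells[, inner] <- sum(cells[, inner]) / sum(counts[, inner])
    counts[, inner] <- 1
  }
  cells <- ifelse(counts > 0, cells / counts, 0)
  if (is.null(boundary))
    boundary <- list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0)
  pts <- grid_points(grid)
  rho_n <- ellipse_norm(pts[, 1], pts[, 2], boundary)
  inside <- rho_n < 1
  th <- (atan2(pts[, 2] - boundary$cy, pts[, 1] - boundary$cx) * 180 / pi) %% 360
  sector <- (floor(th / (360 / polar$n_sectors) + 0.5) %% polar$n_sectors) + 1L
  ring <- pmin(pmax(floor((1 - rho_n) * (polar$n_rings - 1) + 0.5) + 1L, 1L),
               polar$n_rings)
  val <- numeric(nrow(pts))
  val[inside] <- cells[cbind(sector[inside], ring[inside])]
  img <- intensity_image(matrix(val, length(grid$x), length(grid$y)), grid,
                         modality = "dmm")
  structure(list(image = img, cells = cells,
                 table = do.call(rbind, tab),
                 intensity_stat = sum(cells)),
            class = "dmm_result")
}

#' @export
print.dmm_result <- function(x, ...) {
  cat(sprintf("<dmm_result> intensity stat %.3g, peak at (%.1f, %.1f) mm\n",
              x$intensity_stat, 1000 * image_peak(x$image)[1],
              1000 * image_peak(x$image)[2]))
  invisible(x)
}

#' Differential data for the DMM
#'
#' The background-field mitigation can use brain symmetry (self-reference;
#' default) or a uniform background reference dataset.
#'
#' @param patient calibrated patient [scattering_dataset()].
#' @param reference `"symmetry"` or a reference [scattering_dataset()]
#'   (e.g. the synthesized homogeneous-head response).
#' @return a differential [scattering_dataset()].
#' @export
dmm_reference_delta <- function(patient, reference = "symmetry") {
  if (identical(reference, "symmetry")) {
    m <- mirror_index(seq_len(patient$array$n), patient$array)
    s <- patient$s - patient$s[m, m, , drop = FALSE]
  } else {
    stopifnot(inherits(reference, "scattering_dataset"))
    s <- patient$s - reference$s
  }
  scattering_dataset(s, patient$sweep, patient$array,
                     label = paste0(patient$label, "+delta"))
}

#' Healthy reference distribution for DMM detection
#'
#' Simulates `n_healthy` healthy phantoms through the same acquisition and
#' DMM chain and records the intensity statistic, giving the null mean and
#' spread for the 3-sigma detection rule, plus the phase-sign convention
#' checked on one ICH and one IS phantom.
#'
#' @param n_healthy number of healthy phantoms (>= 30 recommended).
#' @param seed integer seed.
#' @param sweep,array,prop,snr_db,grid_spacing acquisition configuration.
#' @param grid image grid.
#' @return class `"dmm_reference"`: `mu`, `sigma`, `stats`, `sign`.
#' @export
build_dmm_reference <- function(n_healthy = 30L, seed = 1L,
                                sweep = frequency_sweep(n = 41L),
                                array = antenna_array(),
                                prop = propagation_model(), snr_db = 30,
                                grid_spacing = 0.002,
                                grid = make_image_grid()) {
  cal <- make_calibration_record(sweep, array, prop, snr_db = Inf,
                                 seed = seed, grid_spacing = grid_spacing)
  profile <- sensitivity_profile(cal$low)
  stats_null <- vapply(seq_len(n_healthy), function(k) {
    ph <- make_phantom(seed * 100000L + k, "healthy")
    ds <- forward_scatter(ph, array, sweep, prop, grid_spacing)
    ds <- add_noise(ds, noise_model(snr_db = snr_db), seed * 100000L + 500L + k)
    dS <- dmm_reference_delta(ds, "symmetry")
    dmm_image(dS, profile, ph$boundary, grid)$intensity_stat
  }, 0)
  sgn <- dmm_sign_convention(array, sweep, prop, grid_spacing, grid, profile,
                             seed)
  structure(list(mu = mean(stats_null), sigma = stats::sd(stats_null),
                 stats = stats_null, sign = sgn, n = n_healthy,
                 snr_db = snr_db, version = "1"),
            class = "dmm_reference")
}

# one-time check of the phase-sign convention on noise-free phantoms
dmm_sign_convention <- function(array, sweep, prop, grid_spacing, grid,
                                profile, seed) {
  res <- vapply(c("ICH", "IS"), function(cl) {
    ph <- make_phantom(seed + 17L, cl,
                       boundary = list(cx = 0, cy = 0, a = 0.080, b = 0.100,
                                       rot = 0))
    ds <- forward_scatter(ph, array, sweep, prop, grid_spacing)
    dS <- dmm_reference_delta(ds, "symmetry")
    r <- dmm_image(dS, profile, ph$boundary, grid)
    # restrict to the true side: the mirror ghost has the opposite sign
    v <- r$image$values
    truth_left <- ph$inclusion$center[1] > 0
    v[if (truth_left) r$image$grid$x < 0 else r$image$grid$x > 0, ] <- 0
    img <- intensity_image(v, r$image$grid, modality = "dmm",
                           normalize = FALSE)
    Re(dmm_refine_peak(dS, profile, image_peak(img), prop, grid,
                       boundary = ph$boundary,
                       side = if (truth_left) "left" else "right")$t)
  }, 0)
  if (res[["ICH"]] > 0 && res[["IS"]] < 0) 1 else -1
}

# T(r) = sum_f sum_ij w_ij dS_ij(f) conj(G(r_i, r) G(r, r_j)) at one or
# more candidate points (rows of pts)
dmm_phase_sum <- function(dS, profile, pts, prop) {
  pts <- matrix(pts, ncol = 2)
  k <- wavenumber(prop, dS$sweep)
  backprop_cpp(dS$array$positions, pts, dS$s, profile, k)
}

# refine the typing location: the phase statistic is only meaningful where
# the kernel correlation is coherent, so evaluate T on a neighbourhood of
# the image peak (restricted to the head interior and, when known, the
# affected side) and keep the |T| maximum
dmm_refine_peak <- function(dS, profile, peak, prop, grid, radius = 0.12,
                            boundary = NULL, side = NULL) {
  pts <- grid_points(grid)
  near <- (pts[, 1] - peak[1])^2 + (pts[, 2] - peak[2])^2 <= radius^2
  if (!is.null(boundary))
    near <- near & ellipse_norm(pts[, 1], pts[, 2], boundary) < 1
  if (!is.null(side))
    near <- near & (if (side == "left") pts[, 1] > 0 else pts[, 1] < 0)
  if (!any(near))
    near <- (pts[, 1] - peak[1])^2 + (pts[, 2] - peak[2])^2 <= radius^2
  pts <- pts[near, , drop = FALSE]
  tv <- dmm_phase_sum(dS, profile, pts, prop)
  i <- which.max(Mod(tv))
  list(point = pts[i, ], t = tv[i])
}

#' DMM stroke detection
#'
#' Detects a stroke when the overall image intensity exceeds the healthy
#' null by 3 standard deviations.
#'
#' @param result a [dmm_image()] result.
#' @param reference a [build_dmm_reference()] object.
#' @return list `detect` (logical), `intensity_stat`, `threshold`.
#' @export
dmm_detect <- function(result, reference) {
  if (is.null(reference) || !inherits(reference, "dmm_reference"))
    stop("missing healthy reference distribution")
  thr <- reference$mu + 3 * reference$sigma
  list(detect = result$intensity_stat > thr,
       intensity_stat = result$intensity_stat, threshold = thr)
}

#' DMM stroke typing from phase information
#'
#' The phase statistic correlates the differential data with the
#' forward-model kernel at the image peak; a hemorrhage (raised properties,
#' positive contrast) gives a positive real part, an ischemia a negative
#' one. Returns `"n/a"` when no stroke was detected.
#'
#' @param dS differential [scattering_dataset()] used for the image.
#' @param profile the [sensitivity_profile()] used.
#' @param result the [dmm_image()] result (for the peak).
#' @param reference a [build_dmm_reference()] (sign convention).
#' @param prop the [propagation_model()].
#' @param detect logical from [dmm_detect()].
#' @param side optional affected hemisphere ("left"/"right"). Symmetry
#'   referencing cannot distinguish a positive-contrast target from a
#'   negative-contrast mirror ghost, so when the affected side is known
#'   (e.g. from [affected_side()]) the typing peak is restricted to it.
#' @return list `stroke_type` ("ICH"/"IS"/"n/a") and `phase_stat` (radians).
#' @export
dmm_classify <- function(dS, profile, result, reference, prop, detect = TRUE,
                         side = NULL, boundary = NULL) {
  if (!detect) return(list(stroke_type = "n/a", phase_stat = NA_real_))
  img <- result$image
  if (!is.null(side)) {
    v <- img$values
    xneg <- if (side == "left") img$grid$x < 0 else img$grid$x > 0
    v[xneg, ] <- 0
    img <- intensity_image(v, img$grid, modality = img$modality,
                           normalize = FALSE)
  }
  ref <- dmm_refine_peak(dS, profile, image_peak(img), prop, img$grid,
                         boundary = boundary, side = side)
  tot <- ref$t
  sgn <- if (inherits(reference, "dmm_reference")) reference$sign else 1
  list(stroke_type = if (sgn * Re(tot) > 0) "ICH" else "IS",
       phase_stat = Arg(tot), peak = ref$point)
}
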
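#' Born-approximation forward scattering
#'
#' Linear single-scattering surrogate for the physical device:
#' S_ij(f) = k_b^2 sum_pixels G(r_i, r') chi(r') G(r', r_j) dA with the 2-D
#' background Green's function G = (j/4) H0^(1)(k_b |r - r'|) and contrast
#' chi = (eps(r') - eps_b)/eps_b (complex permittivities). The boundary
#' (brain vs coupling medium) contributes through the same sum, so "healthy"
#' heads still scatter; a phantom identical to the background gives exactly
#' zero. Reciprocity S_ij = S_ji holds by construction.
#'
#' @param phantom a [head_phantom()].
#' @param array an [antenna_array()]; all antennas must lie outside the head.
#' @param sweep frequency grid, Hz.
#' @param prop a [propagation_model()].
#' @param grid_spacing rasterization pixel size, metres; must satisfy
#'   spacing <= lambda_background/10 at the top of the band.
#' @return a [scattering_dataset()] (scattered field only).
#' @export
forward_scatter <- function(phantom, array, sweep, prop = propagation_model(),
                            grid_spacing = 0.002) {
  validate_sweep(sweep)
  lam_min <- 299792458 / (max(sweep) * sqrt(prop$eps_b))
  if (grid_spacing > lam_min / 10 + 1e-12)
    stop(sprintf("grid spacing %.1f mm exceeds lambda/10 = %.1f mm at %.2f GHz",
                 1000 * grid_spacing, 1000 * lam_min / 10, max(sweep) / 1e9))
  bnd <- phantom$boundary
  if (any(ellipse_norm(array$positions[, 1], array$positions[, 2], bnd) <= 1))
    stop("geometry error: antenna inside the head boundary")
  # rasterize: pixels inside the boundary ellipse (region 1) and inclusion
  # (2); the lattice is symmetric about the boundary centre so a symmetric
  # phantom yields an exactly mirror-symmetric pixel set
  half_x <- seq(0, bnd$a, by = grid_spacing)
  half_y <- seq(0, bnd$b, by = grid_spacing)
  xs <- bnd$cx + c(-rev(half_x[-1]), half_x)
  ys <- bnd$cy + c(-rev(half_y[-1]), half_y)
  pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  inside <- ellipse_norm(pts[, 1], pts[, 2], bnd) < 1
  pts <- pts[inside, , drop = FALSE]
  region <- rep(1L, nrow(pts))
  if (!is.null(phantom$inclusion)) {
    inc <- phantom$inclusion
    d2 <- (pts[, 1] - inc$center[1])^2 + (pts[, 2] - inc$center[2])^2
    region[d2 < inc$radius^2] <- 2L
  }
  nf <- length(sweep)
  eps_b <- complex_permittivity(prop$eps_b, prop$sigma_b, sweep)
  eps_brain <- complex_permittivity(phantom$eps_brain, phantom$sigma_brain, sweep)
  chi_brain <- (eps_brain - eps_b) / eps_b
  chi <- matrix(chi_brain, nrow(pts), nf, byrow = TRUE)
  if (!is.null(phantom$inclusion)) {
    inc <- phantom$inclusion
    eps_inc <- complex_permittivity(phantom$eps_brain + inc$delta_eps,
                                    phantom$sigma_brain + inc$delta_sigma, sweep)
    chi_inc <- (eps_inc - eps_b) / eps_b
    chi[region == 2L, ] <- matrix(chi_inc, sum(region == 2L), nf, byrow = TRUE)
  }
  k <- wavenumber(prop, sweep)
  s <- born_scatter_cpp(array$positions, pts, chi, k, grid_spacing^2)
  scattering_dataset(s, sweep, array,
                     label = if (is.null(phantom$inclusion)) "healthy"
                             else phantom$inclusion$stroke_class)
}

#' Measurement noise and drift model
#'
#' @param snr_db additive complex Gaussian noise level relative to the
#'   per-channel RMS of the clean data; `Inf` disables noise.
#' @param drift_gain_sd sd of per-port log-normal-ish complex gain
#'   perturbations (gains `g_i`, applied as `g_i g_j S_ij`); 0 disables.
#' @param drift_offset_sd sd of per-channel additive complex offsets; 0 disables.
#' @param jump_scale relative magnitude of a motion-corrupted scan jump.
#' @return class `"noise_model"`.
#' @export
noise_model <- function(snr_db = 30, drift_gain_sd = 0, drift_offset_sd = 0,
                        jump_scale = 10) {
  stopifnot(!is.na(snr_db))
  structure(list(snr_db = snr_db, drift_gain_sd = drift_gain_sd,
                 drift_offset_sd = drift_offset_sd, jump_scale = jump_scale),
            class = "noise_model")
}

rcnorm <- function(n, sd = 1) complex(real = stats::rnorm(n, 0, sd / sqrt(2)),
                                      imaginary = stats::rnorm(n, 0, sd / sqrt(2)))

#' Add measurement noise and per-port drift to a dataset
#'
#' Per-port drift is applied first (`S' = g_i g_j S + o_ij`), then complex
#' Gaussian noise at the requested per-channel SNR. Deterministic given
#' `seed`.
#'
#' @param ds a [scattering_dataset()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return a [scattering_dataset()].
#' @export
add_noise <- function(ds, noise = noise_model(), seed = 1L) {
  set.seed(as.integer(seed))
  s <- ds$s
  na <- ds$array$n
  nf <- length(ds$sweep)
  if (noise$drift_gain_sd > 0) {
    g <- 1 + rcnorm(na, noise$drift_gain_sd)
    gg <- outer(g, g)
    s <- s * array(rep(gg, nf), dim(s))
  }
  if (noise$drift_offset_sd > 0) {
    o <- array(rcnorm(na * na, noise$drift_offset_sd), c(na, na))
    s <- s + array(rep(o, nf), dim(s))
  }
  if (is.finite(noise$snr_db)) {
    # per-channel RMS over frequency defines the signal power
    rms <- sqrt(apply(Mod(ds$s)^2, c(1, 2), mean))
    nsd <- rms * 10^(-noise$snr_db / 20)
    nz <- array(rcnorm(length(s)), dim(s)) *
      array(rep(nsd, nf), dim(s))
    s <- s + nz
  }
  out <- scattering_dataset(s, ds$sweep, ds$array,
                            label = paste0(ds$label, "+noise"))
  out
}

corrupt_scan <- function(ds, noise, seed) {
  set.seed(as.integer(seed))
  s <- ds$s
  amp <- noise$jump_scale * sqrt(mean(Mod(s)^2))
  s <- s + array(rcnorm(length(s), amp), dim(s))
  scattering_dataset(s, ds$sweep, ds$array, label = paste0(ds$label, "+jump"))
}

#' Generate a synthetic patient cohort
#'
#' Emulates the clinical acquisition protocol: per patient, 20 consecutive
#' noisy scan replicates of the same head (optionally one motion-corrupted
#' outlier), plus two homogeneous calibration-phantom sweeps measured with
#' the same noise level and their noise-free synthesized responses. Ground
#' truth (class, centre, radius, quadrant) is returned as a manifest data
#' frame. Bit-identical under a fixed seed.
#'
#' @param n_patients number of patients.
#' @param class_mix named proportions over healthy/ICH/IS (must sum to 1);
#'   counts are rounded deterministically.
#' @param scans_per_patient scan replicates per patient (device protocol: 20).
#' @param seed integer master seed.
#' @param sweep,array,prop acquisition configuration.
#' @param snr_db per-scan SNR (dB).
#' @param outlier_prob probability that a patient has one motion-corrupted scan.
#' @param grid_spacing forward-model rasterization, metres.
#' @param radius_range inclusion radius range, metres.
#' @return class `"em_cohort"`: list of patients (each with `phantom`,
#'   `truth`, `scans`, `cal`) and `manifest`.
#' @export
generate_cohort <- function(n_patients,
                            class_mix = c(healthy = 1/3, ICH = 1/3, IS = 1/3),
                            scans_per_patient = 20L, seed = 1L,
                            sweep = frequency_sweep(), array = antenna_array(),
                            prop = propagation_model(), snr_db = 30,
                            outlier_prob = 0.1, grid_spacing = 0.002,
                            radius_range = c(0.0075, 0.025)) {
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("config error: class_mix must sum to 1")
  classes <- names(class_mix)
  stopifnot(all(classes %in% c("healthy", "ICH", "IS")))
  counts <- floor(class_mix * n_patients)
  while (sum(counts) < n_patients)
    counts[which.max(class_mix * n_patients - counts)] <-
      counts[which.max(class_mix * n_patients - counts)] + 1
  labels <- rep(classes, counts)
  cal <- make_calibration_record(sweep, array, prop, snr_db,
                                 seed = as.integer(seed) * 1000L + 1L,
                                 grid_spacing = grid_spacing)
  patients <- vector("list", n_patients)
  man <- vector("list", n_patients)
  for (p in seq_len(n_patients)) {
    pseed <- as.integer(seed) * 1000L + 10L * p
    ph <- make_phantom(pseed, labels[p], radius_range = radius_range)
    base <- forward_scatter(ph, array, sweep, prop, grid_spacing)
    set.seed(pseed + 1L)
    has_outlier <- stats::runif(1) < outlier_prob
    jump_at <- if (has_outlier) sample(scans_per_patient, 1) else NA_integer_
    nm <- noise_model(snr_db = snr_db)
    scans <- lapply(seq_len(scans_per_patient), function(k) {
      if (!is.na(jump_at) && k == jump_at) corrupt_scan(base, nm, pseed + 100L + k)
      else add_noise(base, nm, pseed + 100L + k)
    })
    truth <- list(patient_id = p, class = labels[p],
                  cx = if (is.null(ph$inclusion)) NA_real_ else ph$inclusion$center[1],
                  cy = if (is.null(ph$inclusion)) NA_real_ else ph$inclusion$center[2],
                  radius = if (is.null(ph$inclusion)) NA_real_ else ph$inclusion$radius,
                  quadrant = if (is.null(ph$inclusion)) NA_character_
                             else quadrant_of_point(ph$inclusion$center)$quadrant,
                  seed = pseed, jump_scan = jump_at)
    patients[[p]] <- list(phantom = ph, truth = truth, scans = scans, cal = cal)
    man[[p]] <- as.data.frame(truth, stringsAsFactors = FALSE)
  }
  structure(list(patients = patients,
                 manifest = do.call(rbind, man),
                 sweep = as.numeric(sweep), array = array, prop = prop,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "em_cohort")
}

#' @export
print.em_cohort <- function(x, ...) {
  cat(sprintf("<em_cohort> %d patients (%s), %d scans each, SNR %g dB\n",
              nrow(x$manifest),
              paste(names(table(x$manifest$class)),
                    table(x$manifest$class), sep = ":", collapse = " "),
              length(x$patients[[1]]$scans), x$snr_db))
  invisible(x)
}

#' Write a cohort ground-truth manifest to CSV
#' @param cohort an [generate_cohort()] result.
#' @param path output CSV path.
#' @export
write_manifest_csv <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
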
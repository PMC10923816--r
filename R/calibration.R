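#' Two-phantom calibration record
#'
#' Measured sweeps of the low and high reference phantoms together with
#' their known dielectric properties and model-predicted (synthesized)
#' ideal responses. Low/high must share sweep and array with patient data.
#'
#' @param low,high measured [scattering_dataset()]s of the two references.
#' @param synth_low,synth_high noise-free synthesized responses.
#' @param low_props,high_props named `(eps_r, sigma)` of each reference.
#' @return class `"calibration_record"`.
#' @export
calibration_record <- function(low, high, synth_low, synth_high,
                               low_props = c(eps_r = 38, sigma = 0.5),
                               high_props = c(eps_r = 52, sigma = 0.9)) {
  stopifnot(identical(low$sweep, high$sweep),
            identical(low$sweep, synth_low$sweep),
            identical(low$sweep, synth_high$sweep),
            low$array$n == high$array$n)
  structure(list(low = low, high = high, synth_low = synth_low,
                 synth_high = synth_high, low_props = low_props,
                 high_props = high_props),
            class = "calibration_record")
}

#' Build a calibration record from the synthetic device model
#'
#' Simulates the two homogeneous reference phantoms, adds measurement noise
#' to form the "measured" sweeps, and keeps the noise-free responses as the
#' synthesized ideals.
#'
#' @param sweep,array,prop acquisition configuration.
#' @param snr_db measurement SNR for the reference sweeps.
#' @param seed integer seed.
#' @param grid_spacing forward-model rasterization.
#' @param drift optional [noise_model()] whose gain/offset terms distort the
#'   measured references (the same instrument state as the patient scan).
#' @return a [calibration_record()].
#' @export
make_calibration_record <- function(sweep, array, prop = propagation_model(),
                                    snr_db = Inf, seed = 1L,
                                    grid_spacing = 0.002, drift = NULL) {
  lo <- calibration_phantom("low")
  hi <- calibration_phantom("high")
  syn_lo <- forward_scatter(lo, array, sweep, prop, grid_spacing)
  syn_hi <- forward_scatter(hi, array, sweep, prop, grid_spacing)
  meas_lo <- syn_lo; meas_hi <- syn_hi
  if (!is.null(drift)) {
    meas_lo <- apply_drift(meas_lo, drift, seed)
    meas_hi <- apply_drift(meas_hi, drift, seed)
  }
  if (is.finite(snr_db)) {
    meas_lo <- add_noise(meas_lo, noise_model(snr_db = snr_db), seed + 1L)
    meas_hi <- add_noise(meas_hi, noise_model(snr_db = snr_db), seed + 2L)
  }
  calibration_record(meas_lo, meas_hi, syn_lo, syn_hi,
                     attr(lo, "cal_props"), attr(hi, "cal_props"))
}

# deterministic drift shared across datasets (same instrument state)
apply_drift <- function(ds, noise, seed) {
  set.seed(as.integer(seed))
  na <- ds$array$n
  nf <- length(ds$sweep)
  g <- 1 + rcnorm(na, noise$drift_gain_sd)
  o <- array(rcnorm(na * na, noise$drift_offset_sd), c(na, na))
  s <- ds$s * array(rep(outer(g, g), nf), dim(ds$s)) +
    array(rep(o, nf), dim(ds$s))
  scattering_dataset(s, ds$sweep, ds$array, label = paste0(ds$label, "+drift"))
}

#' Two-phantom affine calibration
#'
#' Per channel and frequency solves the complex affine map
#' `m(S) = g S + o` such that `m(measured_low) = synthesized_low` and
#' `m(measured_high) = synthesized_high`, and applies it to the patient
#' sweep. This removes any per-channel affine instrument distortion (e.g.
#' port gain products and offsets) exactly. Channels where the two
#' references are numerically indistinguishable are flagged uncalibratable
#' (attribute `uncalibratable`, logical Na x Na) and zeroed.
#'
#' @param patient a [scattering_dataset()] sharing sweep/array with `cal`.
#' @param cal a [calibration_record()].
#' @return calibrated [scattering_dataset()].
#' @export
two_phantom_calibrate <- function(patient, cal) {
  stopifnot(identical(patient$sweep, cal$low$sweep),
            patient$array$n == cal$low$array$n)
  dm <- cal$high$s - cal$low$s
  scale <- sqrt(mean(Mod(cal$high$s)^2 + Mod(cal$low$s)^2))
  degen <- Mod(dm) < 1e-12 * scale
  dm[degen] <- 1  # placeholder; flagged channels are zeroed below
  g <- (cal$synth_high$s - cal$synth_low$s) / dm
  o <- cal$synth_low$s - g * cal$low$s
  s <- g * patient$s + o
  s[degen] <- 0
  bad <- apply(degen, c(1, 2), any)
  out <- scattering_dataset(s, patient$sweep, patient$array,
                            label = paste0(patient$label, "+cal"))
  attr(out, "uncalibratable") <- bad
  out
}

#' Scan-stability gating
#'
#' Monitors consecutive scans: the RMS delta between scans k and k+1,
#' expressed in dB relative to the mean signal power, must stay below the
#' threshold. A scan whose adjacent deltas all exceed the threshold is
#' treated as a motion outlier and dropped.
#'
#' @param scans list of [scattering_dataset()]s, acquisition order.
#' @param threshold_db relative delta threshold, dB (default -35).
#' @return class `"stability_report"`: `deltas_db`, `threshold_db`,
#'   `kept_indices`, `dropped_indices`.
#' @export
stability_gate <- function(scans, threshold_db = -35) {
  n <- length(scans)
  if (n < 2) stop("stability gating needs at least 2 scans")
  pow <- mean(vapply(scans, function(d) mean(Mod(d$s)^2), 0))
  deltas <- vapply(seq_len(n - 1), function(k)
    mean(Mod(scans[[k + 1]]$s - scans[[k]]$s)^2), 0)
  deltas_db <- 10 * log10(deltas / pow)
  exceed <- deltas_db > threshold_db
  drop <- logical(n)
  for (k in seq_len(n)) {
    adj <- exceed[c(if (k > 1) k - 1, if (k < n) k)]
    drop[k] <- length(adj) > 0 && all(adj)
  }
  kept <- which(!drop)
  if (length(kept) == 0)
    stop("unstable acquisition: all scans exceeded the stability threshold")
  structure(list(deltas_db = deltas_db, threshold_db = threshold_db,
                 kept_indices = kept, dropped_indices = which(drop)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> kept %d scans, dropped %s (threshold %g dB)\n",
              length(x$kept_indices),
              if (length(x$dropped_indices)) paste(x$dropped_indices, collapse = ",")
              else "none", x$threshold_db))
  invisible(x)
}

#' Average the retained scans
#'
#' Complex mean over scans; averaging N i.i.d. noisy scans lowers the noise
#' floor by 10 log10(N) dB.
#'
#' @param scans non-empty list of [scattering_dataset()]s (e.g. the kept ones).
#' @return a [scattering_dataset()] labelled with the scan count.
#' @export
average_scans <- function(scans) {
  if (length(scans) == 0) stop("cannot average an empty scan list")
  s <- Reduce(`+`, lapply(scans, `[[`, "s")) / length(scans)
  scattering_dataset(s, scans[[1]]$sweep, scans[[1]]$array,
                     label = sprintf("mean-of-%d", length(scans)))
}
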
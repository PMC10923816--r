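#' Train all model components on synthetic cohorts
#'
#' Boundary regressor, stroke classifier ensemble (trained on
#' hemisphere-differential HVG features of a seeded synthetic cohort), and
#' the DMM healthy-null reference. All training is deterministic given
#' `seed`.
#'
#' @param seed integer master seed.
#' @param sweep,array,prop acquisition configuration for the training data.
#' @param n_train_ensemble training subjects for the ensemble (balanced
#'   across the three classes).
#' @param n_boundary boundary-regressor training phantoms.
#' @param n_dmm_null healthy phantoms for the DMM null.
#' @param snr_db training noise level.
#' @param grid_spacing forward-model rasterization.
#' @param verbose print progress.
#' @return class `"emibrain_models"`.
#' @export
train_models <- function(seed = 1L, sweep = frequency_sweep(n = 41L),
                         array = antenna_array(), prop = propagation_model(),
                         n_train_ensemble = 60L, n_boundary = 300L,
                         n_dmm_null = 30L, snr_db = 30,
                         grid_spacing = 0.002, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("training boundary regressor (%d phantoms)", n_boundary)
  bm <- train_boundary_model(n_train = n_boundary, seed = seed,
                             sweep = frequency_sweep(min(sweep), max(sweep),
                                                     n = 6L),
                             array = array, prop = prop,
                             grid_spacing = grid_spacing)
  say("simulating ensemble training cohort (%d subjects)", n_train_ensemble)
  coh <- generate_cohort(n_train_ensemble,
                         scans_per_patient = 20L, seed = seed + 1L,
                         sweep = sweep, array = array, prop = prop,
                         snr_db = snr_db, outlier_prob = 0,
                         grid_spacing = grid_spacing)
  fl <- cohort_features(coh)
  say("fitting classifier ensemble")
  ens <- train_ensemble(fl$features, fl$labels, seed = seed)
  say("building DMM healthy reference (%d phantoms)", n_dmm_null)
  ref <- build_dmm_reference(n_dmm_null, seed = seed + 2L, sweep = sweep,
                             array = array, prop = prop, snr_db = snr_db,
                             grid_spacing = grid_spacing)
  structure(list(boundary = bm, ensemble = ens, dmm_ref = ref,
                 sweep = as.numeric(sweep), array = array, prop = prop,
                 seed = as.integer(seed), version = "1"),
            class = "emibrain_models")
}

#' @export
print.emibrain_models <- function(x, ...) {
  cat(sprintf("<emibrain_models> v%s (seed %d)\n", x$version, x$seed))
  print(x$boundary)
  print(x$ensemble)
  cat(sprintf("  DMM null: mu %.3g sd %.3g (n = %d), sign %+d\n",
              x$dmm_ref$mu, x$dmm_ref$sigma, x$dmm_ref$n, x$dmm_ref$sign))
  invisible(x)
}

#' Hemisphere-differential feature table for a cohort
#'
#' Calibrates each patient (stability gate, scan averaging, two-phantom
#' calibration), extracts HVG differential features.
#'
#' @param cohort a [generate_cohort()] result.
#' @return list `features` (matrix), `labels` (character).
#' @export
cohort_features <- function(cohort) {
  bnd0 <- list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0)
  ref0 <- synthesize_reference(bnd0, cohort$sweep, cohort$array, cohort$prop)
  rows <- lapply(cohort$patients, function(p) {
    ds <- preprocess_patient(p$scans, p$cal)
    tds <- to_time_domain(ds)
    dm <- differential_matrices(channel_metric_matrices(tds), ds$array)
    c(feature_vector(dm),
      contrast_phase_features(ds, cohort$prop, reference = ref0))
  })
  list(features = do.call(rbind, rows),
       labels = cohort$manifest$class)
}

# stability gate -> average kept scans -> two-phantom calibration
preprocess_patient <- function(scans, cal, threshold_db = -15) {
  rep <- stability_gate(scans, threshold_db)
  avg <- average_scans(scans[rep$kept_indices])
  list(ds = two_phantom_calibrate(avg, cal), stability = rep)$ds
}

#' Run the full pipeline on one patient
#'
#' Calibrate (stability gate, scan averaging, two-phantom map), estimate
#' the boundary, run the four parallel algorithms (line crossing, DMM,
#' beamography, EVSLA), and fuse images and decisions. Deterministic given
#' the inputs.
#'
#' @param scans list of [scattering_dataset()] scan replicates.
#' @param cal a [calibration_record()].
#' @param models an [train_models()] bundle.
#' @param grid image grid.
#' @param stability_threshold_db scan-stability threshold.
#' @param tau,min_agree fusion parameters, see [agreement_region()].
#' @param grid_spacing rasterization of the synthesized background
#'   reference, metres.
#' @param cache optional environment for quantities shared across patients
#'   of one cohort (the EVSLA calibration metric matrix).
#' @return class `"fusion_output"`.
#' @export
run_pipeline <- function(scans, cal, models, grid = make_image_grid(),
                         stability_threshold_db = -15, tau = 0.5,
                         min_agree = 3L, grid_spacing = 0.002,
                         cache = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", nm, conditionMessage(e)),
           call. = FALSE))
  }
  timings <- c()
  tick <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    timings[[nm]] <<- t1 - t0
    t0 <<- t1
  }
  rep <- stage("stability", stability_gate(scans, stability_threshold_db))
  avg <- stage("average", average_scans(scans[rep$kept_indices]))
  ds <- stage("calibrate", two_phantom_calibrate(avg, cal))
  tick("calibration")
  bnd <- stage("boundary", estimate_boundary(ds, models$boundary))
  ref_bg <- stage("boundary", synthesize_reference(bnd, ds$sweep, ds$array,
                                                   models$prop,
                                                   grid_spacing = grid_spacing))
  aff_bg <- stage("boundary", affected_side_reference(ds, ref_bg, models$prop,
                                                      grid, bnd))
  tick("boundary")
  tds <- stage("timedomain", to_time_domain(ds))
  metrics <- stage("hvg", channel_metric_matrices(tds))
  dm <- stage("differential", differential_matrices(metrics, ds$array))
  ens <- stage("classify", classify_ensemble(
    c(feature_vector(dm),
      contrast_phase_features(ds, models$prop, side = aff_bg$side)),
    models$ensemble))
  img_lc <- stage("linecross", linecross_map(dm$D_entropy, ds$array, bnd, grid))
  tick("linecross")
  aff <- stage("affected_side", affected_side(ds))
  profile <- stage("dmm", sensitivity_profile(cal$low))
  dS <- stage("dmm", dmm_reference_delta(ds, "symmetry"))
  dmmres <- stage("dmm", dmm_image(dS, profile, bnd, grid))
  det <- stage("dmm", dmm_detect(dmmres, models$dmm_ref))
  typ <- stage("dmm", dmm_classify(dS, profile, dmmres, models$dmm_ref,
                                   models$prop, det$detect,
                                   side = aff_bg$side, boundary = bnd))
  tick("dmm")
  beam <- stage("beamography", beamography(ds, models$prop, grid, bnd,
                                           aff = aff))
  tick("beamography")
  ev <- stage("evsla", {
    M_ref <- if (!is.null(cache) && !is.null(cache$evsla_M_ref)) {
      cache$evsla_M_ref
    } else {
      mr <- channel_metric_matrix(to_time_domain(
        two_phantom_calibrate(cal$low, cal)), "entropy")
      if (!is.null(cache)) cache$evsla_M_ref <- mr
      mr
    }
    patches <- make_patch_pairs(ds$array, bnd)
    st <- patch_statistic(metrics$entropy, M_ref, patches)
    list(image = expected_value_image(st, patches, grid), stats = st)
  })
  tick("evsla")
  fus <- stage("fusion", {
    imgs <- coregister_normalize(list(img_lc, dmmres$image, beam$image,
                                      ev$image), grid)
    mask <- agreement_region(imgs, tau, min_agree)
    sd <- smooth_dilate_overlay(imgs, mask, grid)
    list(images = imgs, mask = mask, heat = sd)
  })
  decision <- stage("fusion", fuse_decisions(ens, typ$stroke_type, det$detect))
  # agreed target location: the smoothed localization modality (beamography)
  # inside the dilated agreement region, on the affected hemisphere from the
  # ghost-free background-referenced side call; the symmetry-referenced
  # modalities are left-right ambiguous and cannot break that tie themselves
  loc <- stage("fusion", {
    drop_side <- if (aff_bg$side == "left") grid$x < 0 else grid$x > 0
    side_only <- function(v) {
      if (any(v[!drop_side, ] > 0)) v[drop_side, ] <- 0
      v
    }
    # ghost-free background-referenced residual, affected side only; the
    # agreement mask is built from the coarse modalities and would drag
    # this (much sharper) peak onto its own edges
    v <- side_only(aff_bg$core / max(aff_bg$core, 1e-300))
    if (max(v) == 0)
      v <- side_only(EBImage::gblur(fus$images[[3]]$values, sigma = 2) *
                       fus$heat$mask_dilated)
    if (max(v) == 0) v <- fus$heat$heatmap$values
    intensity_image(v, grid, modality = "fused", normalize = FALSE)
  })
  peak <- image_peak(loc)
  quad <- quadrant_of_point(peak)
  tick("fusion")
  structure(list(
    fused_class = decision$label, certainty = decision$certainty,
    probs = decision$probs, quadrant = quad, heatmap = fus$heat$heatmap,
    agreement_mask = fus$mask, mask_dilated = fus$heat$mask_dilated,
    images = list(linecross = img_lc, dmm = dmmres$image,
                  beamography = beam$image, evsla = ev$image),
    ensemble = ens, dmm = list(detect = det, type = typ),
    beamography_side = beam$side, affected_side = aff_bg$side,
    boundary = bnd,
    stability = rep, timings = timings),
    class = "fusion_output")
}

#' @export
print.fusion_output <- function(x, ...) {
  cat(sprintf("<fusion_output> %s (certainty %.2f), %s, peak (%.1f, %.1f) mm\n",
              x$fused_class, x$certainty, x$quadrant$quadrant,
              1000 * x$quadrant$peak[1], 1000 * x$quadrant$peak[2]))
  invisible(x)
}

#' Canonical JSON report of a pipeline run
#'
#' Byte-identical across reruns with identical inputs: contains the fused
#' class, certainty, probabilities, quadrant, peak and per-modality peaks
#' (timings are deliberately excluded from the canonical report; see the
#' `timings` field of [run_pipeline()]).
#'
#' @param out a [run_pipeline()] result.
#' @param path optional file to write to.
#' @return the JSON string, invisibly if written.
#' @export
pipeline_report <- function(out, path = NULL) {
  rpt <- list(
    fused_class = out$fused_class,
    certainty = round(out$certainty, 10),
    probabilities = as.list(round(out$probs, 10)),
    quadrant = out$quadrant$quadrant,
    peak_xy_m = round(out$quadrant$peak, 10),
    modality_peaks = lapply(out$images, function(im)
      round(image_peak(im), 10)),
    dmm_detect = out$dmm$detect$detect,
    dmm_type = out$dmm$type$stroke_type,
    beamography_side = out$beamography_side,
    affected_side = out$affected_side,
    boundary_mm = round(1000 * c(cx = out$boundary$cx, cy = out$boundary$cy,
                                 a = out$boundary$a, b = out$boundary$b), 6),
    scans_kept = length(out$stability$kept_indices))
  js <- jsonlite::toJSON(rpt, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Render the fused result as a red/blue PNG overlay
#'
#' Red encodes hemorrhagic, blue ischemic; intensity follows the fused
#' heatmap. The head boundary and agreement region are sketched in grey.
#'
#' @param out a [run_pipeline()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_fusion <- function(out, path) {
  v <- t(out$heatmap$values)[rev(seq_along(out$heatmap$grid$y)), ]
  col <- switch(out$fused_class, ICH = c(1, 0, 0), IS = c(0, 0, 1),
                c(0.5, 0.5, 0.5))
  img <- array(0, c(nrow(v), ncol(v), 3))
  for (ch in 1:3) img[, , ch] <- v * col[ch] + (1 - v) * 1
  png::writePNG(img, path)
  invisible(path)
}

#' Evaluate the pipeline on a synthetic cohort
#'
#' Runs every patient through [run_pipeline()] and scores 3-class accuracy,
#' quadrant accuracy (diseased patients whose fused-image peak falls in the
#' ground-truth quadrant) and median peak-to-truth distance.
#'
#' @param cohort a [generate_cohort()] result.
#' @param models an [train_models()] bundle.
#' @param grid image grid.
#' @param verbose print per-patient progress.
#' @return class `"cohort_evaluation"`: per-patient data frame and summary
#'   metrics.
#' @export
evaluate_cohort <- function(cohort, models, grid = make_image_grid(),
                            verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_along(cohort$patients), function(i) {
    p <- cohort$patients[[i]]
    out <- run_pipeline(p$scans, p$cal, models, grid, cache = cache)
    err <- if (p$truth$class == "healthy") NA_real_
           else sqrt((out$quadrant$peak[1] - p$truth$cx)^2 +
                     (out$quadrant$peak[2] - p$truth$cy)^2)
    if (verbose)
      message(sprintf("patient %d: truth %s -> %s (err %.1f mm)", i,
                      p$truth$class, out$fused_class,
                      if (is.na(err)) NA else 1000 * err))
    data.frame(patient_id = p$truth$patient_id, truth = p$truth$class,
               predicted = out$fused_class,
               ensemble_label = out$ensemble$label,
               dmm_detect = out$dmm$detect$detect,
               dmm_type = out$dmm$type$stroke_type,
               truth_quadrant = p$truth$quadrant,
               predicted_quadrant = out$quadrant$quadrant,
               peak_error_m = err)
  })
  d <- do.call(rbind, rows)
  diseased <- d[d$truth != "healthy", , drop = FALSE]
  structure(list(
    per_patient = d,
    class_accuracy = mean(d$predicted == d$truth),
    quadrant_accuracy = if (nrow(diseased))
      mean(diseased$predicted_quadrant == diseased$truth_quadrant)
      else NA_real_,
    median_peak_error_m = if (nrow(diseased))
      stats::median(diseased$peak_error_m) else NA_real_),
    class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation> n = %d: class accuracy %.2f, quadrant accuracy %.2f, median peak error %.1f mm\n",
              nrow(x$per_patient), x$class_accuracy, x$quadrant_accuracy,
              1000 * x$median_peak_error_m))
  invisible(x)
}
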
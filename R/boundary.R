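#' Boundary-estimate features from reflection coefficients
#'
#' Reflection coefficients S_ii carry the strongest boundary information:
#' their magnitude profile and phase slope over frequency encode the
#' antenna-to-skin distance. Per antenna the features are mean log
#' magnitude, unwrapped phase slope, and magnitudes at `n_freq` fixed band
#' positions (interpolated, so the feature length is sweep-independent).
#'
#' @param ds a calibrated [scattering_dataset()].
#' @param n_freq magnitude samples per antenna.
#' @return numeric feature vector, length `Na * (2 + n_freq)`.
#' @export
boundary_features <- function(ds, n_freq = 4L) {
  na <- ds$array$n
  f <- ds$sweep
  fq <- seq(min(f), max(f), length.out = n_freq)
  feats <- lapply(seq_len(na), function(i) {
    sii <- ds$s[i, i, ]
    mag <- Mod(sii)
    ph <- unwrap_phase(Arg(sii))
    slope <- stats::coef(stats::lm.fit(cbind(1, (f - mean(f)) / 1e9),
                                       ph))[2]
    c(mean(log(pmax(mag, 1e-12))), slope,
      stats::approx(f, mag, xout = fq, rule = 2)$y)
  })
  unlist(feats)
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Train the head-boundary regressor
#'
#' Stand-in for the clinical deep-network boundary detector: a gradient
#' boosted regressor per ellipse parameter (cx, cy, a, b), trained on
#' randomized synthetic phantoms. Rotation is fixed at 0 in this 2-D
#' surrogate. Seeded and reproducible.
#'
#' @param n_train number of synthetic phantoms (>= 2000 recommended for the
#'   reported accuracy; smaller runs train proportionally faster).
#' @param seed integer seed.
#' @param sweep,array,prop acquisition configuration; a short sweep suffices
#'   since only smooth reflection features are used.
#' @param snr_db training-data noise level.
#' @param a_range,b_range semi-axis ranges (metres), within anatomical bounds.
#' @param center_sd head-centre offset sd (metres).
#' @param nrounds,max_depth xgboost settings.
#' @param grid_spacing forward-model rasterization.
#' @return class `"boundary_model"` with a `validation` summary (held-out
#'   mean absolute errors per parameter, metres).
#' @export
train_boundary_model <- function(n_train = 2000L, seed = 1L,
                                 sweep = frequency_sweep(n = 6L),
                                 array = antenna_array(),
                                 prop = propagation_model(), snr_db = 40,
                                 a_range = c(0.065, 0.095),
                                 b_range = c(0.085, 0.115),
                                 center_sd = 0.004,
                                 nrounds = 300L, max_depth = 4L,
                                 grid_spacing = 0.002) {
  set.seed(as.integer(seed))
  n_all <- n_train + max(20L, round(n_train * 0.15))
  pars <- cbind(cx = stats::rnorm(n_all, 0, center_sd),
                cy = stats::rnorm(n_all, 0, center_sd),
                a = stats::runif(n_all, a_range[1], a_range[2]),
                b = stats::runif(n_all, b_range[1], b_range[2]))
  feats <- matrix(NA_real_, n_all, array$n * 6)
  for (i in seq_len(n_all)) {
    ph <- head_phantom(boundary = list(cx = pars[i, 1], cy = pars[i, 2],
                                       a = pars[i, 3], b = pars[i, 4], rot = 0))
    ds <- forward_scatter(ph, array, sweep, prop, grid_spacing)
    ds <- add_noise(ds, noise_model(snr_db = snr_db), seed = seed + 7L * i)
    feats[i, ] <- boundary_features(ds)
  }
  idx_tr <- seq_len(n_train)
  models <- lapply(colnames(pars), function(nm) {
    dtr <- xgboost::xgb.DMatrix(feats[idx_tr, , drop = FALSE],
                                label = pars[idx_tr, nm], nthread = 1)
    xgboost::xgb.train(params = list(objective = "reg:squarederror",
                                     max_depth = max_depth, eta = 0.1,
                                     subsample = 0.8, colsample_bytree = 0.8,
                                     nthread = 1, seed = as.integer(seed)),
                       data = dtr, nrounds = nrounds, verbose = 0)
  })
  names(models) <- colnames(pars)
  dva <- xgboost::xgb.DMatrix(feats[-idx_tr, , drop = FALSE], nthread = 1)
  pred <- vapply(models, function(m)
    stats::predict(m, dva), numeric(n_all - n_train))
  mae <- colMeans(abs(pred - pars[-idx_tr, , drop = FALSE]))
  structure(list(models = models, sweep = as.numeric(sweep),
                 n_freq = 4L, seed = as.integer(seed),
                 bounds = c(min = 0.060, max = 0.120),
                 validation = mae, version = "1"),
            class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf("<boundary_model> v%s, held-out MAE (mm): %s\n", x$version,
              paste(names(x$validation),
                    sprintf("%.1f", 1000 * x$validation), collapse = " ")))
  invisible(x)
}

#' Estimate the head boundary from reflection coefficients
#'
#' Inference is deterministic. Predicted semi-axes are clamped to the
#' anatomical bounds (60--120 mm) with a warning if the raw prediction
#' falls outside.
#'
#' @param ds a calibrated [scattering_dataset()].
#' @param model a trained [train_boundary_model()] object.
#' @return class `"boundary_estimate"`: ellipse `(cx, cy, a, b, rot)` and
#'   the model's held-out fit residual summary.
#' @export
estimate_boundary <- function(ds, model) {
  if (!inherits(model, "boundary_model"))
    stop("estimate_boundary requires a trained boundary_model")
  fe <- xgboost::xgb.DMatrix(matrix(boundary_features(ds, model$n_freq),
                                    nrow = 1), nthread = 1)
  est <- vapply(model$models, function(m) stats::predict(m, fe), 0)
  clamped <- FALSE
  for (nm in c("a", "b")) {
    if (est[nm] < model$bounds["min"] || est[nm] > model$bounds["max"]) {
      clamped <- TRUE
      est[nm] <- min(max(est[nm], model$bounds["min"]), model$bounds["max"])
    }
  }
  if (clamped) warning("boundary prediction outside anatomical bounds; clamped")
  structure(list(cx = unname(est["cx"]), cy = unname(est["cy"]),
                 a = unname(est["a"]), b = unname(est["b"]), rot = 0,
                 fit_residual = unname(mean(model$validation[c("a", "b")]))),
            class = "boundary_estimate")
}

#' @export
print.boundary_estimate <- function(x, ...) {
  cat(sprintf("<boundary_estimate> centre (%.1f, %.1f) mm, semi-axes %.1f x %.1f mm\n",
              1000 * x$cx, 1000 * x$cy, 1000 * x$a, 1000 * x$b))
  invisible(x)
}
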
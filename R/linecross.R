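#' Hemisphere-differential HVG matrices and features
#'
#' Healthy heads are approximately mirror-symmetric across the sagittal
#' plane, so each channel metric matrix M should commute with the mirror
#' permutation P. The differential matrix D = M - P M P' vanishes for
#' symmetric heads and grows with unilateral anomalies; it is antisymmetric
#' under mirror conjugation (P D P' = -D) by construction.
#'
#' @param metrics list of the three metric matrices, see
#'   [channel_metric_matrices()].
#' @param array the [antenna_array()] defining the mirror permutation.
#' @return class `"differential_features"`: matrices `D_degree`,
#'   `D_strength`, `D_entropy`, the originals, and a 39-element `features`
#'   vector (13 summaries per matrix).
#' @export
differential_matrices <- function(metrics, array) {
  m <- mirror_index(seq_len(array$n), array)
  D <- lapply(metrics, function(M) M - M[m, m])
  names(D) <- paste0("D_", names(metrics))
  side <- antenna_side(array)
  feats <- unlist(lapply(names(D), function(nm) {
    s <- matrix_summary(D[[nm]], side)
    stats::setNames(s, paste0(nm, "_", names(s)))
  }))
  structure(c(D, list(M = metrics, features = feats, array = array)),
            class = "differential_features")
}

# 13 scalar summaries of a differential matrix; the hemisphere feature uses
# signed row sums (row norms are mirror-invariant and carry no side signal)
matrix_summary <- function(D, side) {
  a <- abs(D)
  rn <- sqrt(rowSums(D^2))
  rs <- rowSums(D)
  p <- a / max(sum(a), 1e-300)
  ent <- -sum(ifelse(p > 0, p * log(p), 0))
  c(frob = sqrt(sum(D^2)), max = max(a), mean = mean(a), sd = stats::sd(a),
    rowmax = max(rn), rowmean = mean(rn), rowsd = stats::sd(rn),
    hemi = mean(rs[side == "left"]) - mean(rs[side == "right"]),
    q25 = unname(stats::quantile(a, 0.25)),
    q50 = unname(stats::quantile(a, 0.50)),
    q75 = unname(stats::quantile(a, 0.75)),
    q90 = unname(stats::quantile(a, 0.90)),
    entdist = ent)
}

#' Feature vector for the classifier ensemble
#' @param diff a [differential_matrices()] result.
#' @return named numeric vector (39 features by default).
#' @export
feature_vector <- function(diff) diff$features

#' Kernel-coherence contrast features
#'
#' The hemisphere-differential magnitude features are blind to the sign of
#' the dielectric contrast (a small bleed and a larger ischemic region can
#' carry equal asymmetry energy), so the classifier feature vector is
#' extended with three features from the matched-filter coherence
#' `T(r) = sum_f sum_ij dS_ij(f) conj(G_i(r) G_j(r))` of the
#' mirror-differenced data, evaluated at its own maximum over the head
#' interior (restricted to the affected hemisphere when unambiguous):
#' `cos(arg T)` and `sin(arg T)` carry the contrast sign (raised properties
#' give a positive real part), `log |T|` the anomaly scale.
#'
#' @param ds calibrated [scattering_dataset()].
#' @param prop the [propagation_model()].
#' @param boundary head boundary (default ellipse when `NULL`).
#' @param spacing coherence search grid spacing, metres.
#' @param side optional affected side ("left"/"right"); when a
#'   [synthesize_reference()] dataset is supplied instead, the ghost-free
#'   background-referenced side call is used (mirror-based dCor coin-flips
#'   for near-axis lesions, which flips the coherence sign); with neither,
#'   the self-contained [affected_side()] decides.
#' @param reference optional [synthesize_reference()] dataset for the side
#'   call.
#' @return named numeric length-3 vector.
#' @export
contrast_phase_features <- function(ds, prop = propagation_model(),
                                    boundary = NULL, spacing = 0.006,
                                    side = NULL, reference = NULL) {
  if (is.null(boundary))
    boundary <- list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0)
  dS <- dmm_reference_delta(ds, "symmetry")
  grid <- make_image_grid(spacing = spacing)
  if (is.null(side)) {
    side <- if (!is.null(reference)) {
      affected_side_reference(ds, reference, prop, grid, boundary)$side
    } else {
      aff <- affected_side(ds)
      if (aff$ambiguous) NULL else aff$side
    }
  }
  pts <- grid_points(grid)
  keep <- ellipse_norm(pts[, 1], pts[, 2], boundary) < 1
  if (!is.null(side))
    keep <- keep & (if (side == "left") pts[, 1] > 0 else pts[, 1] < 0)
  pts <- pts[keep, , drop = FALSE]
  tv <- backprop_cpp(ds$array$positions, pts, dS$s,
                     matrix(1, ds$array$n, ds$array$n),
                     wavenumber(prop, ds$sweep))
  tstar <- tv[which.max(Mod(tv))]
  mag <- Mod(tstar)
  c(coh_cos = if (mag > 0) Re(tstar) / mag else 0,
    coh_sin = if (mag > 0) Im(tstar) / mag else 0,
    coh_logmag = log(mag + 1e-300))
}

#' Train the four-classifier stroke ensemble
#'
#' Random forest, k-nearest-neighbour, naive Bayes and support vector
#' machine, all with probability outputs over healthy/ICH/IS, trained on
#' standardized hemisphere-differential features. Training is seeded and
#' reproducible.
#'
#' @param features numeric matrix (subjects x features).
#' @param labels factor/character over `"healthy"`, `"ICH"`, `"IS"`.
#' @param seed integer seed.
#' @param k neighbours for kNN.
#' @param n_select features kept after the supervised screening step. The
#'   distance- and likelihood-based classifiers (kNN, naive Bayes, SVM)
#'   degrade badly when dozens of weakly informative summaries drown the
#'   few decisive ones, so a seeded random-forest importance ranking keeps
#'   the top `n_select` standardized features for all four classifiers.
#' @return class `"stroke_ensemble"`.
#' @export
train_ensemble <- function(features, labels, seed = 1L, k = 5L,
                           n_select = 8L) {
  labels <- factor(labels, levels = c("healthy", "ICH", "IS"))
  labels <- droplevels(labels)
  if (nlevels(labels) < 2)
    stop("training set contains a single class")
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv == 0] <- 1
  z <- scale(features, mu, sdv)
  set.seed(as.integer(seed))
  n_select <- min(as.integer(n_select), ncol(z))
  imp <- randomForest::importance(
    randomForest::randomForest(z, labels, ntree = 1000))
  selected <- names(sort(imp[, 1], decreasing = TRUE))[seq_len(n_select)]
  z <- z[, selected, drop = FALSE]
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(z, labels, ntree = 500)
  nb <- e1071::naiveBayes(z, labels)
  sv <- e1071::svm(z, labels, probability = TRUE, kernel = "radial")
  kn <- caret::knn3(z, labels, k = min(k, nrow(z) - 1))
  structure(list(rf = rf, nb = nb, svm = sv, knn = kn,
                 mu = mu, sd = sdv, selected = selected,
                 levels = levels(labels),
                 seed = as.integer(seed), version = "2"),
            class = "stroke_ensemble")
}

#' @export
print.stroke_ensemble <- function(x, ...) {
  cat(sprintf("<stroke_ensemble> RF + kNN + naive Bayes + SVM over {%s}\n",
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Classify with the ensemble and fuse probabilities
#'
#' Each classifier emits a probability vector over the classes; the fused
#' probability is the certainty-weighted mean (weight = that classifier's
#' maximum probability), renormalized. The fusion is invariant to
#' classifier ordering.
#'
#' @param features numeric vector or 1-row matrix.
#' @param ensemble a [train_ensemble()] object.
#' @return class `"ensemble_result"`: `per_classifier` probability matrix,
#'   `fused` probabilities, `label`, `certainty`.
#' @export
classify_ensemble <- function(features, ensemble) {
  z <- matrix(as.numeric(features), nrow = 1)
  if (ncol(z) != length(ensemble$mu))
    stop("feature dimension mismatch")
  z <- scale(z, ensemble$mu, ensemble$sd)
  colnames(z) <- names(ensemble$mu)
  z <- z[, ensemble$selected, drop = FALSE]
  lv <- ensemble$levels
  p_rf <- stats::predict(ensemble$rf, z, type = "prob")[1, lv]
  p_nb <- stats::predict(ensemble$nb, z, type = "raw")[1, lv]
  sv_pred <- stats::predict(ensemble$svm, z, probability = TRUE)
  p_sv <- attr(sv_pred, "probabilities")[1, lv]
  p_kn <- stats::predict(ensemble$knn, z, type = "prob")[1, lv]
  per <- rbind(rf = p_rf, knn = p_kn, nb = p_nb, svm = p_sv)
  per <- per / rowSums(per)
  fuse_probability_rows(per)
}

# certainty-weighted mean of probability rows, renormalized
fuse_probability_rows <- function(per) {
  wts <- apply(per, 1, max)
  fused <- colSums(per * wts) / sum(wts)
  fused <- fused / sum(fused)
  structure(list(per_classifier = per, fused = fused,
                 label = names(fused)[which.max(fused)],
                 certainty = max(fused)),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %s (certainty %.2f); fused p = [%s]\n",
              x$label, x$certainty,
              paste(sprintf("%s %.2f", names(x$fused), x$fused), collapse = ", ")))
  invisible(x)
}

#' Line-crossing localization map
#'
#' Signal paths (straight antenna-to-antenna corridors) that cross a stroke
#' carry a significantly larger hemisphere-differential entropy than paths
#' that do not. Each channel's weight `|D_entropy[i, j]|` is painted onto
#' every pixel within `half_width` of the segment between antennas i and j
#' (restricted to the head boundary), the per-pixel sum is divided by the
#' ray-coverage count, and the image is normalized to maximum 1.
#'
#' @param D_entropy Na x Na differential entropy matrix.
#' @param array the [antenna_array()].
#' @param boundary a [estimate_boundary()] result (or boundary list).
#' @param grid an [make_image_grid()].
#' @param half_width corridor half-width, metres (default 6 mm).
#' @return an [intensity_image()] with modality `"linecross"`.
#' @export
linecross_map <- function(D_entropy, array, boundary = NULL,
                          grid = make_image_grid(), half_width = 0.006) {
  if (is.null(boundary)) {
    warning("boundary missing; using default head ellipse")
    boundary <- list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0)
  }
  pts <- grid_points(grid)
  inside <- ellipse_norm(pts[, 1], pts[, 2], boundary) < 1
  acc <- numeric(nrow(pts))
  cov <- numeric(nrow(pts))
  na <- array$n
  pos <- array$positions
  for (i in seq_len(na - 1)) for (j in (i + 1):na) {
    wij <- max(0, (abs(D_entropy[i, j]) + abs(D_entropy[j, i])) / 2)
    d <- dist_point_segment(pts, pos[i, ], pos[j, ])
    hit <- inside & (d <= half_width)
    cov[hit] <- cov[hit] + 1
    acc[hit] <- acc[hit] + wij
  }
  val <- ifelse(cov > 0, acc / cov, 0)
  intensity_image(matrix(val, length(grid$x), length(grid$y)), grid,
                  modality = "linecross")
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
}
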
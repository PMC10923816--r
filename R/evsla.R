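#' Symmetric quadrilateral patch pairs
#'
#' For every same-hemisphere antenna pair (i, j) with circular separation in
#' `sep_range`, a wedge quadrilateral is built from the two antenna
#' positions and their radial contractions toward the head centre
#' (`alpha` times the position), clipped to the head boundary. Its partner
#' is the wedge of the mirrored pair, so the pairing is a bijection and the
#' two patches are exact mirror images. Degenerate patches (area < 1 cm^2
#' after clipping) are dropped together with their partners.
#'
#' @param array the [antenna_array()].
#' @param boundary head boundary ellipse (list or [estimate_boundary()]).
#' @param sep_range circular separation range (default 1--3).
#' @param alpha radial contraction factor for the inner vertices.
#' @return list of patch pairs; each element has `left`, `right` (polygons,
#'   n x 2), `antennas` (i, j of the left patch), `channels` (bounding
#'   channel index pairs for each side).
#' @export
make_patch_pairs <- function(array, boundary, sep_range = c(1, 3),
                             alpha = 0.1) {
  na <- array$n
  side <- antenna_side(array)
  m <- mirror_index(seq_len(na), array)
  ctr <- c(boundary$cx, boundary$cy)
  pairs <- list()
  for (i in seq_len(na - 1)) for (j in (i + 1):na) {
    sep <- min(abs(i - j), na - abs(i - j))
    if (sep < sep_range[1] || sep > sep_range[2]) next
    if (side[i] != "left" || side[j] != "left") next
    left <- wedge_polygon(i, j, array, boundary, alpha, ctr)
    right <- wedge_polygon(m[i], m[j], array, boundary, alpha, ctr)
    if (is.null(left) || is.null(right)) next
    pairs[[length(pairs) + 1]] <-
      list(left = left, right = right, antennas = c(i, j),
           channels = list(left = rbind(c(i, i), c(j, j), c(i, j)),
                           right = rbind(c(m[i], m[i]), c(m[j], m[j]),
                                         c(m[i], m[j]))))
  }
  pairs
}

# wedge between two antennas: outer edge at the antennas (pulled just inside
# the boundary), inner edge contracted toward the centre; NULL if degenerate
wedge_polygon <- function(i, j, array, boundary, alpha, ctr) {
  pi_ <- array$positions[i, ]
  pj <- array$positions[j, ]
  pull <- function(p) {
    # move the vertex onto the boundary ellipse if it lies outside
    en <- ellipse_norm(p[1], p[2], boundary)
    if (en >= 1) ctr + (p - ctr) / (en * 1.001) else p
  }
  poly <- rbind(pull(pi_), pull(pj),
                ctr + alpha * (pj - ctr), ctr + alpha * (pi_ - ctr))
  if (polygon_area(poly) < 1e-4) return(NULL)
  poly
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  0.5 * abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y))
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Patch anomaly statistics (statistical fields)
#'
#' For each patch side the bounding channels' HVG entropy metrics of the
#' patient data are compared to the calibration reference
#' (`mean |metric_patient - metric_reference|`), then the mirror patch's
#' value is subtracted and the result floored at zero -- a patch is
#' anomalous only if it is more dissimilar from the reference than its
#' mirror. Patches with statistic at or below the median over all patches
#' are deactivated ("regions with higher dissimilarity are kept active").
#'
#' @param M_patient,M_reference Na x Na entropy metric matrices (see
#'   [channel_metric_matrix()]) for patient and calibration data.
#' @param patches a [make_patch_pairs()] result.
#' @return data frame with one row per patch side: `pair`, `side`,
#'   `statistic`, `active`.
#' @export
patch_statistic <- function(M_patient, M_reference, patches) {
  rows <- list()
  for (p in seq_along(patches)) {
    pp <- patches[[p]]
    dis <- vapply(c("left", "right"), function(sd) {
      ch <- pp$channels[[sd]]
      mean(abs(M_patient[ch] - M_reference[ch]))
    }, 0)
    rows[[length(rows) + 1]] <-
      data.frame(pair = p, side = c("left", "right"),
                 statistic = c(max(0, dis[["left"]] - dis[["right"]]),
                               max(0, dis[["right"]] - dis[["left"]])))
  }
  out <- do.call(rbind, rows)
  out$statistic[out$statistic < 1e-12] <- 0   # numerical dust is not anomaly
  med <- stats::median(out$statistic)
  out$active <- out$statistic > med & out$statistic > 0
  out
}

#' Expected-value fusion of statistical fields
#'
#' The imaging domain is discretized into pixels; each pixel's value is the
#' mean statistic of all active patches covering it (0 if none), i.e. the
#' expected anomaly statistic at that pixel. Higher intensity means higher
#' expectancy of an anomaly.
#'
#' @param stats a [patch_statistic()] data frame.
#' @param patches the matching [make_patch_pairs()] list.
#' @param grid an [make_image_grid()].
#' @return an [intensity_image()] with modality `"evsla"`.
#' @export
expected_value_image <- function(stats, patches, grid) {
  pts <- grid_points(grid)
  acc <- numeric(nrow(pts))
  cnt <- numeric(nrow(pts))
  act <- stats[stats$active & stats$statistic > 0, , drop = FALSE]
  if (nrow(act) > 0) {
    for (r in seq_len(nrow(act))) {
      poly <- patches[[act$pair[r]]][[act$side[r]]]
      hit <- point_in_polygon(pts[, 1], pts[, 2], poly)
      acc[hit] <- acc[hit] + act$statistic[r]
      cnt[hit] <- cnt[hit] + 1
    }
  }
  val <- ifelse(cnt > 0, acc / cnt, 0)
  intensity_image(matrix(val, length(grid$x), length(grid$y)), grid,
                  modality = "evsla", normalize = TRUE)
}

#' Full EVSLA chain
#'
#' Converts patient and calibration-reference sweeps to time domain, builds
#' HVG entropy matrices, forms symmetric-patch statistics and fuses them
#' into the expected-value image.
#'
#' @param patient calibrated patient [scattering_dataset()].
#' @param reference calibration reference [scattering_dataset()] (e.g. the
#'   measured low phantom).
#' @param boundary head boundary ellipse.
#' @param grid an [make_image_grid()].
#' @param M_patient optional precomputed patient entropy matrix (skips the
#'   HVG recomputation when the caller already has it).
#' @return list `image`, `stats`, `patches`.
#' @export
evsla <- function(patient, reference, boundary, grid = make_image_grid(),
                  M_patient = NULL) {
  if (is.null(reference)) stop("missing calibration reference")
  if (is.null(M_patient))
    M_patient <- channel_metric_matrix(to_time_domain(patient), "entropy")
  M_ref <- channel_metric_matrix(to_time_domain(reference), "entropy")
  patches <- make_patch_pairs(patient$array, boundary)
  st <- patch_statistic(M_patient, M_ref, patches)
  list(image = expected_value_image(st, patches, grid),
       stats = st, patches = patches)
}
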
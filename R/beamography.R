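#' Szekely distance correlation
#'
#' Sample distance correlation between two real vectors (double-centered
#' distance matrices, V-statistics). Returns a value in [0, 1]; 1 for
#' identical (non-constant) inputs. Undefined (NA) for constant inputs.
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar dCor(x, y).
#' @export
distance_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  A <- dc_center(abs(outer(x, x, "-")))
  B <- dc_center(abs(outer(y, y, "-")))
  vxy <- mean(A * B)
  vx <- mean(A * A)
  vy <- mean(B * B)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sqrt(vxy / sqrt(vx * vy))
}

dc_center <- function(d) {
  d - rowMeans(d) - rep(colMeans(d), each = nrow(d)) + mean(d)
}

#' Affected-hemisphere detection via distance correlation
#'
#' Each channel's magnitude-over-frequency sequence is compared (distance
#' correlation) against the cross-hemisphere template for its antenna
#' separation -- the mean |S| profile over all channels with the same
#' circular separation. Channels on the stroke side deviate more from the
#' template, so the hemisphere with the lower mean dCor is called affected.
#' A difference below `tie_tol` is flagged ambiguous (default side: left).
#' Constant channels (dCor undefined) are masked.
#'
#' @param ds calibrated [scattering_dataset()].
#' @param tie_tol ambiguity tolerance on the hemisphere score difference.
#' @return list `side` ("left"/"right"), `scores` (named), `ambiguous`.
#' @export
affected_side <- function(ds, tie_tol = 0.01) {
  arr <- ds$array
  na <- arr$n
  side <- antenna_side(arr)
  mag <- Mod(ds$s)
  sep <- outer(seq_len(na), seq_len(na),
               function(i, j) pmin(abs(i - j), na - abs(i - j)))
  # per-separation template profiles
  templates <- lapply(0:(na %/% 2), function(s) {
    ch <- which(sep == s, arr.ind = TRUE)
    prof <- colMeans(t(apply(ch, 1, function(ij) mag[ij[1], ij[2], ])))
    prof
  })
  score_for <- function(hemi) {
    vals <- c()
    for (i in seq_len(na)) for (j in seq_len(na)) {
      if (side[i] != hemi || side[j] != hemi) next
      v <- distance_correlation(mag[i, j, ], templates[[sep[i, j] + 1]])
      if (!is.na(v)) vals <- c(vals, v)
    }
    mean(vals)
  }
  scores <- c(left = score_for("left"), right = score_for("right"))
  ambiguous <- abs(scores["left"] - scores["right"]) < tie_tol
  side_out <- if (ambiguous) "left"
              else names(scores)[which.min(scores)]
  list(side = unname(side_out), scores = scores,
       ambiguous = unname(ambiguous))
}

#' Synthesize the uniform background reference
#'
#' Forward-models a homogeneous brain-average head at a given boundary --
#' the "uniform background reference" alternative to brain-symmetry
#' self-referencing. Subtracting it from calibrated patient data leaves the
#' inclusion response without the mirror ghost that symmetry referencing
#' introduces.
#'
#' @param boundary ellipse list or [estimate_boundary()] result.
#' @param sweep,array,prop acquisition configuration.
#' @param eps_brain,sigma_brain assumed brain-average properties.
#' @param grid_spacing forward rasterization, metres.
#' @return a [scattering_dataset()].
#' @export
synthesize_reference <- function(boundary, sweep, array,
                                 prop = propagation_model(),
                                 eps_brain = 42, sigma_brain = 0.6,
                                 grid_spacing = 0.002) {
  ph <- head_phantom(boundary = list(cx = boundary$cx, cy = boundary$cy,
                                     a = boundary$a, b = boundary$b,
                                     rot = 0),
                     eps_brain = eps_brain, sigma_brain = sigma_brain)
  forward_scatter(ph, array, sweep, prop, grid_spacing)
}

#' Affected side from the uniform background reference
#'
#' Back-propagates the background-referenced residual (patient minus
#' synthesized homogeneous head) and compares hemisphere image energies;
#' a rim band inside the boundary is excluded because boundary-estimate
#' mismatch concentrates there. Ghost-free, so more decisive than the
#' mirror-based score when a boundary estimate is available.
#'
#' @param ds calibrated [scattering_dataset()].
#' @param reference a [synthesize_reference()] dataset.
#' @param prop the [propagation_model()].
#' @param grid an [make_image_grid()].
#' @param boundary the boundary used for the reference.
#' @param rim excluded band inside the boundary, metres.
#' @return list `side`, `energies`, `image` (the residual backprojection),
#'   `peak` (its rim-excluded maximum).
#' @export
affected_side_reference <- function(ds, reference, prop = propagation_model(),
                                    grid = make_image_grid(),
                                    boundary = NULL, rim = 0.012) {
  stopifnot(identical(ds$sweep, reference$sweep))
  dbg <- scattering_dataset(ds$s - reference$s, ds$sweep, ds$array,
                            label = paste0(ds$label, "+bgref"))
  img <- backpropagate(dbg, prop, grid, boundary = boundary)
  pts <- grid_points(grid)
  v <- as.vector(img$values)
  if (!is.null(boundary)) {
    core <- list(cx = boundary$cx, cy = boundary$cy,
                 a = max(boundary$a - rim, 0.01),
                 b = max(boundary$b - rim, 0.01), rot = 0)
    v[ellipse_norm(pts[, 1], pts[, 2], core) >= 1] <- 0
  }
  e_left <- sum(v[pts[, 1] > 0]^2)
  e_right <- sum(v[pts[, 1] < 0]^2)
  peak <- pts[which.max(v), ]
  list(side = if (e_left >= e_right) "left" else "right",
       energies = c(left = e_left, right = e_right),
       image = img, peak = as.numeric(peak),
       core = matrix(v, length(grid$x), length(grid$y)))
}

#' Symmetry subtraction (clutter mitigation, step 1)
#'
#' The healthy-side signals, including those crossing the central line, are
#' subtracted from the stroke-side signals: for every channel (i, j),
#' `dS_ij = S_ij - S_mirror(i), mirror(j)`. Symmetric clutter cancels
#' exactly; channels entirely on the healthy side carry a redundant negated
#' copy and are down-weighted by 1/2 during imaging.
#'
#' @param ds calibrated [scattering_dataset()].
#' @param side affected side ("left"/"right"), see [affected_side()].
#' @return class `"clutter_suppressed"`: `dS` (dataset), `u` (Na x Na
#'   redundancy weights), `side`.
#' @export
symmetry_subtract <- function(ds, side = "left") {
  arr <- ds$array
  m <- mirror_index(seq_len(arr$n), arr)
  s <- ds$s - ds$s[m, m, , drop = FALSE]
  hemi <- antenna_side(arr)
  healthy <- if (side == "left") "right" else "left"
  u <- matrix(1, arr$n, arr$n)
  u[hemi == healthy, hemi == healthy] <- 0.5
  dS <- scattering_dataset(s, ds$sweep, arr, label = paste0(ds$label, "+sym"))
  structure(list(dS = dS, u = u, side = side), class = "clutter_suppressed")
}

#' Average subtraction (clutter mitigation, step 2)
#'
#' Subtracts, per frequency sample, the average over all channels from each
#' channel: residual anatomical asymmetry and head-displacement clutter is
#' common-mode across channels and is removed. Idempotent.
#'
#' @param csd a [symmetry_subtract()] result (or a dataset).
#' @return same class as the input, channel-mean-free per frequency.
#' @export
average_subtract <- function(csd) {
  ds <- if (inherits(csd, "clutter_suppressed")) csd$dS else csd
  s <- ds$s
  mu <- apply(s, 3, mean)
  s <- s - rep(mu, each = dim(s)[1] * dim(s)[2])
  out <- scattering_dataset(s, ds$sweep, ds$array,
                            label = paste0(ds$label, "+avg"))
  if (inherits(csd, "clutter_suppressed")) {
    csd$dS <- out
    csd
  } else out
}

#' Green's-function back-propagation (target focusing)
#'
#' Phase-conjugate (matched-filter) back-propagation of the
#' clutter-suppressed data: the field observed at each image point for each
#' transmitter-receiver pair and frequency sample is computed with the
#' background Green's function and superposed,
#' `I(r) = |sum_f sum_ij u_ij dS_ij(f) conj(G(r_i, r) G(r, r_j))|`.
#' Pixels within 3 mm of an antenna are excluded (Green's-function
#' singularity guard).
#'
#' @param csd a [symmetry_subtract()]/[average_subtract()] result, or a
#'   differential dataset.
#' @param prop the [propagation_model()].
#' @param grid an [make_image_grid()].
#' @param boundary optional boundary ellipse; image restricted inside it.
#' @param guard antenna guard radius, metres.
#' @return an [intensity_image()] with modality `"beamography"`.
#' @export
backpropagate <- function(csd, prop = propagation_model(),
                          grid = make_image_grid(), boundary = NULL,
                          guard = 0.003) {
  if (inherits(csd, "clutter_suppressed")) {
    ds <- csd$dS; u <- csd$u
  } else {
    ds <- csd; u <- matrix(1, ds$array$n, ds$array$n)
  }
  pts <- grid_points(grid)
  keep <- rep(TRUE, nrow(pts))
  if (!is.null(boundary))
    keep <- ellipse_norm(pts[, 1], pts[, 2], boundary) < 1
  for (a in seq_len(ds$array$n)) {
    d2 <- (pts[, 1] - ds$array$positions[a, 1])^2 +
      (pts[, 2] - ds$array$positions[a, 2])^2
    keep <- keep & (d2 > guard^2)
  }
  k <- wavenumber(prop, ds$sweep)
  val <- numeric(nrow(pts))
  if (any(keep)) {
    acc <- backprop_cpp(ds$array$positions, pts[keep, , drop = FALSE],
                        ds$s, u, k)
    val[keep] <- Mod(acc)
  }
  intensity_image(matrix(val, length(grid$x), length(grid$y)), grid,
                  modality = "beamography")
}

#' Full beamography chain
#'
#' Affected-side detection, symmetry + average subtraction, and
#' back-propagation.
#'
#' @param ds calibrated [scattering_dataset()].
#' @param prop,grid,boundary see [backpropagate()].
#' @param aff optional precomputed [affected_side()] result.
#' @return list `image`, `side`, `scores`, `ambiguous`.
#' @export
beamography <- function(ds, prop = propagation_model(),
                        grid = make_image_grid(), boundary = NULL,
                        aff = NULL) {
  if (is.null(aff)) aff <- affected_side(ds)
  csd <- average_subtract(symmetry_subtract(ds, aff$side))
  img <- backpropagate(csd, prop, grid, boundary)
  list(image = img, side = aff$side, scores = aff$scores,
       ambiguous = aff$ambiguous)
}
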
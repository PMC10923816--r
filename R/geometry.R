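#' Frequency sweep
#'
#' Strictly ascending frequency grid in Hz. The device band is 0.7--1.8 GHz;
#' the default grid has 201 points over that band.
#'
#' @param f_start,f_stop band edges in Hz (both positive).
#' @param n number of frequency points (>= 2).
#' @return numeric vector of frequencies (Hz), class `"em_sweep"`.
#' @export
frequency_sweep <- function(f_start = 0.7e9, f_stop = 1.8e9, n = 201L) {
  stopifnot(n >= 2, f_start > 0, f_stop > f_start)
  f <- seq(f_start, f_stop, length.out = n)
  structure(f, class = "em_sweep")
}

validate_sweep <- function(f) {
  if (length(f) < 2) stop("frequency sweep needs at least 2 points")
  if (any(!is.finite(f)) || any(f <= 0)) stop("frequencies must be finite and positive")
  if (any(diff(f) <= 0)) stop("frequencies must be strictly ascending")
  invisible(f)
}

#' Antenna array on an ellipse around the head
#'
#' Default layout: 16 elements on an ellipse with semi-axes 110 mm (x) by
#' 130 mm (y), at angles 11.25 + k*22.5 degrees so that no element sits on
#' the sagittal axis (the y-axis). Coordinates are head-centered metres with
#' +y anterior and +x patient-left.
#'
#' @param n number of antennas (even).
#' @param semi_x,semi_y ellipse semi-axes in metres.
#' @param angle0 angle of the first element in degrees.
#' @return object of class `"antenna_array"` with `positions` (n x 2 metres),
#'   `angles_deg`, `n` and the semi-axes.
#' @export
antenna_array <- function(n = 16L, semi_x = 0.110, semi_y = 0.130,
                          angle0 = 11.25) {
  stopifnot(n >= 2, n %% 2 == 0, semi_x > 0, semi_y > 0)
  ang <- (angle0 + (seq_len(n) - 1) * 360 / n) %% 360
  th <- ang * pi / 180
  pos <- cbind(x = semi_x * cos(th), y = semi_y * sin(th))
  if (any(abs(pos[, 1]) < 1e-9))
    stop("configuration error: an antenna lies on the sagittal axis")
  arr <- structure(list(positions = pos, angles_deg = ang, n = n,
                        semi_x = semi_x, semi_y = semi_y),
                   class = "antenna_array")
  # mirror pairing must be an involution covering all antennas
  m <- mirror_index(seq_len(n), arr)
  if (any(m == seq_len(n)) || !all(sort(m) == seq_len(n)) ||
      !all(mirror_index(m, arr) == seq_len(n)))
    stop("configuration error: mirror pairing is not a fixed-point-free involution")
  arr
}

#' @export
print.antenna_array <- function(x, ...) {
  cat(sprintf("<antenna_array> %d elements on %.0f x %.0f mm ellipse\n",
              x$n, 1000 * x$semi_x, 1000 * x$semi_y))
  invisible(x)
}

#' Mirror antenna index across the sagittal axis
#'
#' For an antenna at placement angle theta the mirror partner sits at
#' 180 - theta (mod 360). Symmetric antenna pairs are the backbone of the
#' hemisphere-differential algorithms.
#'
#' @param k antenna index (1-based), vectorized.
#' @param array an [antenna_array()].
#' @return integer vector of mirror indices.
#' @export
mirror_index <- function(k, array) {
  target <- (180 - array$angles_deg[k]) %% 360
  d <- abs(outer(target, array$angles_deg, "-"))
  d <- pmin(d, 360 - d)
  out <- apply(d, 1, which.min)
  if (any(d[cbind(seq_along(k), out)] > 1e-6))
    stop("configuration error: layout has no mirror partner for some antenna")
  as.integer(out)
}

#' Hemisphere membership of each antenna
#'
#' Left hemisphere is x > 0 under the +x = patient-left convention.
#' @param array an [antenna_array()].
#' @return character vector "left"/"right" per antenna.
#' @export
antenna_side <- function(array) {
  ifelse(array$positions[, 1] > 0, "left", "right")
}

#' Quadrant of a head-centered point
#'
#' Convention: +y = anterior, +x = patient-left, origin at head centre.
#' On-axis ties break toward anterior then left and are flagged.
#'
#' @param p numeric length-2 (x, y) in metres.
#' @return list with `quadrant`, `peak`, `on_axis`.
#' @export
quadrant_of_point <- function(p) {
  stopifnot(length(p) == 2, all(is.finite(p)))
  on_axis <- (p[1] == 0 || p[2] == 0)
  ap <- if (p[2] >= 0) "anterior" else "posterior"
  lr <- if (p[1] >= 0) "left" else "right"
  structure(list(quadrant = paste(ap, lr, sep = "-"),
                 peak = as.numeric(p), on_axis = on_axis),
            class = "quadrant_call")
}

#' @export
print.quadrant_call <- function(x, ...) {
  cat(sprintf("<quadrant_call> %s at (%.1f, %.1f) mm%s\n", x$quadrant,
              1000 * x$peak[1], 1000 * x$peak[2],
              if (x$on_axis) " [on axis]" else ""))
  invisible(x)
}

#' Regular head-centered image grid
#'
#' @param spacing pixel size in metres (default 2 mm).
#' @param half_x,half_y half-extents in metres.
#' @return class `"image_grid"`: pixel-centre coordinates `x`, `y` and `spacing`.
#' @export
make_image_grid <- function(spacing = 0.002, half_x = 0.132, half_y = 0.152) {
  stopifnot(spacing > 0)
  structure(list(x = seq(-half_x, half_x, by = spacing),
                 y = seq(-half_y, half_y, by = spacing),
                 spacing = spacing),
            class = "image_grid")
}

grid_points <- function(grid) {
  cbind(x = rep(grid$x, times = length(grid$y)),
        y = rep(grid$y, each = length(grid$x)))
}

#' Normalized 2-D stroke-likelihood image
#'
#' Values are non-negative; after normalization the maximum is 1 unless the
#' image is identically zero. The raw (pre-normalization) maximum is kept in
#' attribute `max_raw` for null-versus-diseased comparisons.
#'
#' @param values matrix `length(grid$x)` x `length(grid$y)` of non-negative reals.
#' @param grid an [make_image_grid()].
#' @param modality one of `"linecross"`, `"dmm"`, `"beamography"`, `"evsla"`, `"fused"`.
#' @param normalize divide by the maximum (if positive).
#' @return class `"intensity_image"`.
#' @export
intensity_image <- function(values, grid,
                            modality = c("linecross", "dmm", "beamography",
                                         "evsla", "fused"),
                            normalize = TRUE) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(values),
            nrow(values) == length(grid$x), ncol(values) == length(grid$y))
  if (any(!is.finite(values)) || any(values < -1e-12))
    stop("intensity values must be finite and non-negative")
  values[values < 0] <- 0
  mx <- max(values)
  if (normalize && mx > 0) values <- values / mx
  structure(list(values = values, grid = grid, modality = modality),
            class = "intensity_image", max_raw = mx)
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %s, %d x %d px, %.0f mm pixels, peak at (%.1f, %.1f) mm\n",
              x$modality, length(x$grid$x), length(x$grid$y),
              1000 * x$grid$spacing,
              1000 * image_peak(x)[1], 1000 * image_peak(x)[2]))
  invisible(x)
}

#' @export
plot.intensity_image <- function(x, ...) {
  graphics::image(x$grid$x, x$grid$y, x$values, asp = 1,
                  xlab = "x (m, +left)", ylab = "y (m, +anterior)",
                  main = x$modality, ...)
  invisible(x)
}

#' Coordinates of the image maximum
#' @param img an [intensity_image()].
#' @return numeric (x, y) in metres.
#' @export
image_peak <- function(img) {
  idx <- which(img$values == max(img$values))[1]
  i <- (idx - 1) %% length(img$grid$x) + 1
  j <- (idx - 1) %/% length(img$grid$x) + 1
  c(img$grid$x[i], img$grid$y[j])
}

#' Write an antenna geometry table to CSV
#' @param array an [antenna_array()].
#' @param path output path.
#' @export
write_array_csv <- function(array, path) {
  utils::write.csv(data.frame(index = seq_len(array$n),
                              x_m = array$positions[, 1],
                              y_m = array$positions[, 2],
                              angle_deg = array$angles_deg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an antenna geometry table from CSV
#' @param path CSV with columns index, x_m, y_m, angle_deg.
#' @return an object of class `"antenna_array"`.
#' @export
read_array_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("index", "x_m", "y_m", "angle_deg") %in% names(d)))
  d <- d[order(d$index), ]
  arr <- structure(list(positions = cbind(x = d$x_m, y = d$y_m),
                        angles_deg = d$angle_deg, n = nrow(d),
                        semi_x = max(abs(d$x_m)), semi_y = max(abs(d$y_m))),
                   class = "antenna_array")
  arr
}
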
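#' Stroke inclusion (dielectric anomaly)
#'
#' Hemorrhage (ICH) raises both permittivity and conductivity of tissue;
#' ischemia (IS) lowers both. Contrast magnitudes at ~1 GHz are not published
#' for the clinical device, so the defaults (+18 / +0.8 S/m for ICH,
#' -12 / -0.4 S/m for IS) are plausible assumptions, exposed as arguments.
#'
#' @param stroke_class `"ICH"` or `"IS"`.
#' @param center (x, y) metres.
#' @param radius metres.
#' @param delta_eps,delta_sigma signed contrasts relative to brain average;
#'   defaults depend on class.
#' @return class `"stroke_inclusion"`.
#' @export
stroke_inclusion <- function(stroke_class = c("ICH", "IS"), center, radius,
                             delta_eps = NULL, delta_sigma = NULL) {
  stroke_class <- match.arg(stroke_class)
  if (is.null(delta_eps)) delta_eps <- if (stroke_class == "ICH") 18 else -12
  if (is.null(delta_sigma)) delta_sigma <- if (stroke_class == "ICH") 0.8 else -0.4
  if (stroke_class == "ICH" && (delta_eps <= 0 || delta_sigma <= 0))
    stop("ICH requires positive permittivity and conductivity contrast")
  if (stroke_class == "IS" && (delta_eps >= 0 || delta_sigma >= 0))
    stop("IS requires negative permittivity and conductivity contrast")
  stopifnot(radius > 0)
  structure(list(stroke_class = stroke_class, center = as.numeric(center),
                 radius = radius, delta_eps = delta_eps,
                 delta_sigma = delta_sigma),
            class = "stroke_inclusion")
}

#' Elliptical head phantom
#'
#' Two-layer model: coupling medium outside the elliptical boundary, a
#' homogeneous brain-average interior, and optionally one circular stroke
#' inclusion. The permittivity map is rasterized lazily by the forward model.
#'
#' @param boundary list `(cx, cy, a, b, rot)` metres/radians.
#' @param inclusion a [stroke_inclusion()] or `NULL` (healthy).
#' @param eps_brain,sigma_brain brain-average dielectric properties.
#' @param seed integer recorded for provenance.
#' @return class `"head_phantom"`.
#' @export
head_phantom <- function(boundary = list(cx = 0, cy = 0, a = 0.080, b = 0.100,
                                         rot = 0),
                         inclusion = NULL, eps_brain = 42, sigma_brain = 0.6,
                         seed = NA_integer_) {
  stopifnot(boundary$a > 0, boundary$b > 0)
  if (!is.null(inclusion)) {
    if (!inclusion_inside(inclusion, boundary))
      stop("inclusion crosses the head boundary")
  }
  structure(list(boundary = boundary, inclusion = inclusion,
                 eps_brain = eps_brain, sigma_brain = sigma_brain,
                 seed = seed),
            class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  inc <- if (is.null(x$inclusion)) "healthy"
         else sprintf("%s r=%.0f mm at (%.0f, %.0f) mm", x$inclusion$stroke_class,
                      1000 * x$inclusion$radius, 1000 * x$inclusion$center[1],
                      1000 * x$inclusion$center[2])
  cat(sprintf("<head_phantom> %.0f x %.0f mm ellipse, %s\n",
              1000 * x$boundary$a, 1000 * x$boundary$b, inc))
  invisible(x)
}

ellipse_norm <- function(x, y, boundary) {
  ct <- cos(boundary$rot); st <- sin(boundary$rot)
  xr <- ct * (x - boundary$cx) + st * (y - boundary$cy)
  yr <- -st * (x - boundary$cx) + ct * (y - boundary$cy)
  sqrt((xr / boundary$a)^2 + (yr / boundary$b)^2)
}

inclusion_inside <- function(inc, boundary) {
  # inclusion disk entirely inside the ellipse: check worst-case radial push
  th <- seq(0, 2 * pi, length.out = 64)
  px <- inc$center[1] + inc$radius * cos(th)
  py <- inc$center[2] + inc$radius * sin(th)
  all(ellipse_norm(px, py, boundary) < 1)
}

#' Draw a random head phantom
#'
#' Deterministic given `seed`. For diseased classes the inclusion centre is
#' drawn uniformly inside 80% of the boundary ellipse and the radius from
#' U(7.5, 25) mm; draws that would cross the boundary are rejected and
#' redrawn (bounded retries).
#'
#' @param seed integer seed.
#' @param stroke_class `"healthy"`, `"ICH"` or `"IS"`.
#' @param boundary geometry override, see [head_phantom()]; if `NULL` the
#'   head size is randomized (semi-axes U(72, 88) x U(92, 108) mm, centre on
#'   the sagittal axis so healthy heads stay mirror-symmetric).
#' @param radius_range inclusion radius range, metres.
#' @param delta_eps,delta_sigma contrast overrides, see [stroke_inclusion()].
#' @param eps_brain,sigma_brain interior override.
#' @return a [head_phantom()].
#' @export
make_phantom <- function(seed, stroke_class = c("healthy", "ICH", "IS"),
                         boundary = NULL, radius_range = c(0.0075, 0.025),
                         delta_eps = NULL, delta_sigma = NULL,
                         eps_brain = 42, sigma_brain = 0.6) {
  stroke_class <- match.arg(stroke_class)
  set.seed(as.integer(seed))
  if (is.null(boundary)) {
    # randomized anatomy: head size varies, centre stays on the sagittal
    # axis (cx = 0) so healthy heads remain mirror-symmetric
    boundary <- list(cx = 0,
                     cy = stats::rnorm(1, 0, 0.003),
                     a = stats::runif(1, 0.072, 0.088),
                     b = stats::runif(1, 0.092, 0.108), rot = 0)
  }
  inclusion <- NULL
  if (stroke_class != "healthy") {
    for (try in 1:200) {
      # uniform in the 80%-scaled ellipse via rejection from its bounding box
      repeat {
        cx <- stats::runif(1, -0.8 * boundary$a, 0.8 * boundary$a)
        cy <- stats::runif(1, -0.8 * boundary$b, 0.8 * boundary$b)
        if (ellipse_norm(boundary$cx + cx, boundary$cy + cy, boundary) < 0.8) break
      }
      r <- stats::runif(1, radius_range[1], radius_range[2])
      inc <- stroke_inclusion(stroke_class,
                              c(boundary$cx + cx, boundary$cy + cy), r,
                              delta_eps, delta_sigma)
      if (inclusion_inside(inc, boundary)) { inclusion <- inc; break }
    }
    if (is.null(inclusion))
      stop("could not place inclusion inside boundary after 200 retries")
  }
  head_phantom(boundary, inclusion, eps_brain, sigma_brain,
               seed = as.integer(seed))
}

#' Homogeneous calibration phantom
#'
#' Two reference phantoms with well-known properties above and below the
#' average dielectric properties of the head; implemented as homogeneous
#' disks (radius 90 mm) at eps_r = 38 (low) and 52 (high). Exact clinical
#' values are unpublished; these bracket the brain-average default of 42.
#'
#' @param which `"low"` or `"high"`.
#' @param radius disk radius, metres.
#' @return a [head_phantom()] with `cal_props` attribute `(eps_r, sigma)`.
#' @export
calibration_phantom <- function(which = c("low", "high"), radius = 0.090) {
  which <- match.arg(which)
  props <- if (which == "low") c(eps_r = 38, sigma = 0.5)
           else c(eps_r = 52, sigma = 0.9)
  ph <- head_phantom(boundary = list(cx = 0, cy = 0, a = radius, b = radius,
                                     rot = 0),
                     inclusion = NULL,
                     eps_brain = props[["eps_r"]], sigma_brain = props[["sigma"]])
  attr(ph, "cal_props") <- props
  ph
}
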
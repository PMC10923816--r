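EPS0 <- 8.8541878128e-12
MU0 <- 1.25663706212e-6

#' Background propagation model (coupling medium)
#'
#' The coupling medium between the antennas and the head has a dielectric
#' constant of 45 and a conductivity of 0.15 S/m around 1 GHz. The complex
#' background wavenumber uses the e^{-j omega t} convention with an outgoing
#' H0^(1) Green's function, so Im(k_b) > 0 and waves decay with distance.
#'
#' @param eps_b background relative permittivity.
#' @param sigma_b background conductivity, S/m.
#' @return class `"propagation_model"`.
#' @export
propagation_model <- function(eps_b = 45, sigma_b = 0.15) {
  stopifnot(eps_b > 0, sigma_b >= 0)
  structure(list(eps_b = eps_b, sigma_b = sigma_b), class = "propagation_model")
}

#' Complex background wavenumber
#'
#' k_b(f) = 2 pi f sqrt(mu0 eps0 (eps_b + j sigma_b / (2 pi f eps0))),
#' branch with Re(k_b) > 0 and Im(k_b) >= 0 (lossy, decaying).
#'
#' @param prop a [propagation_model()].
#' @param f frequencies in Hz (vectorized).
#' @return complex vector.
#' @export
wavenumber <- function(prop, f) {
  w <- 2 * pi * f
  eps_c <- complex(real = prop$eps_b, imaginary = prop$sigma_b / (w * EPS0))
  k <- w * sqrt(MU0 * EPS0 * eps_c)
  k <- ifelse(Re(k) < 0, -k, k)
  k
}

#' Complex relative permittivity of a material at frequency f
#' @param eps_r real relative permittivity.
#' @param sigma conductivity S/m.
#' @param f frequency Hz.
#' @return complex scalar/vector.
#' @export
complex_permittivity <- function(eps_r, sigma, f) {
  complex(real = eps_r, imaginary = sigma / (2 * pi * f * EPS0))
}

#' Hankel function of the first kind, order zero
#'
#' Valid for complex arguments with positive real part (power series for
#' small |z|, asymptotic expansion beyond).
#' @param z complex vector.
#' @return complex vector H0^(1)(z).
#' @export
hankel0 <- function(z) {
  hankel0_cpp(as.complex(z))
}

#' 2-D background Green's function matrix
#'
#' G(r, r') = (j/4) H0^(1)(k_b |r - r'|) between two point sets.
#' @param prop a [propagation_model()].
#' @param f a single frequency, Hz.
#' @param a,b matrices of points (rows = points, cols = x, y).
#' @return complex matrix `nrow(a)` x `nrow(b)`.
#' @export
greens_matrix <- function(prop, f, a, b) {
  k <- wavenumber(prop, f)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  r <- sqrt(dx^2 + dy^2)
  g <- (0.25i) * hankel0(k * as.vector(r))
  matrix(g, nrow(a), nrow(b))
}
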
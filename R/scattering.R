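#' Multi-port scattering-parameter dataset
#'
#' The universal measurement currency: a complex Na x Na x Nf tensor of
#' S-parameters on an ascending frequency grid, tied to an antenna array.
#'
#' @param s complex array Na x Na x Nf (linear complex ratios).
#' @param sweep frequency grid (Hz), see [frequency_sweep()].
#' @param array an [antenna_array()].
#' @param label free-text scan/phantom identifier.
#' @return class `"scattering_dataset"`.
#' @export
scattering_dataset <- function(s, sweep, array, label = "") {
  validate_sweep(sweep)
  if (length(dim(s)) != 3)
    stop("dimension error: s must be a 3-d complex array")
  d <- dim(s)
  if (d[1] != array$n || d[2] != array$n)
    stop("dimension error: S tensor does not match antenna count")
  if (d[3] != length(sweep))
    stop("dimension error: S tensor does not match frequency grid")
  if (any(!is.finite(Re(s))) || any(!is.finite(Im(s))))
    stop("S-parameters must be finite")
  if (max(Mod(s)) > 10)
    stop("implausible S-parameter magnitude (> 10); rejecting dataset")
  structure(list(s = s, sweep = as.numeric(sweep), array = array,
                 label = label),
            class = "scattering_dataset")
}

#' @export
print.scattering_dataset <- function(x, ...) {
  cat(sprintf("<scattering_dataset> %s: %d ports, %d freqs (%.2f-%.2f GHz), max|S| = %.3g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$array$n, length(x$sweep),
              min(x$sweep) / 1e9, max(x$sweep) / 1e9, max(Mod(x$s))))
  invisible(x)
}

#' Read a Touchstone .sNp file (version 1, any N)
#'
#' Supports the RI/MA/DB formats and Hz/kHz/MHz/GHz units of the v1 option
#' line. Data are returned as linear complex ratios on an ascending grid;
#' descending input files are re-sorted (flagged via attribute `resorted`).
#'
#' @param path path to a `.sNp` file.
#' @param array optional [antenna_array()]; port count must match. If absent,
#'   a default layout with the file's port count is used.
#' @return a [scattering_dataset()].
#' @export
read_touchstone <- function(path, array = NULL) {
  nports <- sub(".*\\.s([0-9]+)p$", "\\1", tolower(path))
  if (identical(nports, tolower(path)))
    stop("parse error: file name must end in .sNp")
  n <- as.integer(nports)
  lines <- readLines(path, warn = FALSE)
  unit_mult <- c(hz = 1, khz = 1e3, mhz = 1e6, ghz = 1e9)
  fmt <- "ma"; mult <- 1e9  # Touchstone defaults: GHz, MA
  values <- numeric(0)
  for (li in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[li])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      tok <- tolower(strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]])
      u <- tok[tok %in% names(unit_mult)]
      if (length(u)) mult <- unit_mult[[u[1]]]
      f <- tok[tok %in% c("ri", "ma", "db")]
      if (length(f)) fmt <- f[1]
      if (!("s" %in% tok))
        stop(sprintf("parse error at line %d: only S-parameters supported", li))
      next
    }
    v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (any(is.na(v)))
      stop(sprintf("parse error at line %d: non-numeric field", li))
    values <- c(values, v)
  }
  per_block <- 1 + 2 * n * n
  if (length(values) %% per_block != 0)
    stop("parse error: data length is not a whole number of frequency blocks")
  nf <- length(values) %/% per_block
  if (nf < 2) stop("parse error: need at least 2 frequency points")
  blocks <- matrix(values, nrow = per_block)
  freqs <- blocks[1, ] * mult
  raw <- blocks[-1, , drop = FALSE]
  a <- raw[seq(1, 2 * n * n, by = 2), , drop = FALSE]
  b <- raw[seq(2, 2 * n * n, by = 2), , drop = FALSE]
  cplx <- switch(fmt,
    ri = complex(real = a, imaginary = b),
    ma = a * exp(1i * b * pi / 180),
    db = 10^(a / 20) * exp(1i * b * pi / 180))
  # v1 layout: within each frequency block values run row-major over (i, j)
  s <- array(NA_complex_, c(n, n, nf))
  for (f in seq_len(nf)) {
    m <- matrix(cplx[(f - 1) * n * n + seq_len(n * n)], n, n, byrow = TRUE)
    s[, , f] <- m
  }
  resorted <- FALSE
  ord <- order(freqs)
  if (any(ord != seq_len(nf))) {
    resorted <- TRUE
    freqs <- freqs[ord]
    s <- s[, , ord, drop = FALSE]
    message("read_touchstone: frequency grid was not ascending; re-sorted")
  }
  if (is.null(array)) array <- default_array_for(n)
  if (array$n != n)
    stop(sprintf("dimension error: file has %d ports but array has %d", n, array$n))
  ds <- scattering_dataset(s, freqs, array, label = basename(path))
  attr(ds, "resorted") <- resorted
  ds
}

# I/O fallback: port counts that cannot form a valid mirror-paired layout
# (anything but the device geometry) still get a placeholder ring so the
# file can be inspected; mirror-based algorithms require a real array.
default_array_for <- function(n) {
  tryCatch(antenna_array(n = n), error = function(e) {
    ang <- (360 * (seq_len(n) - 1) / n + 5.73) %% 360
    structure(list(positions = cbind(x = cos(ang * pi / 180),
                                     y = sin(ang * pi / 180)),
                   angles_deg = ang, n = n, semi_x = 1, semi_y = 1),
              class = "antenna_array")
  })
}

#' Write a Touchstone .sNp file (RI format, Hz)
#'
#' @param ds a [scattering_dataset()].
#' @param path output path ending in `.sNp` with N = port count.
#' @export
write_touchstone <- function(ds, path) {
  s <- ds$s
  if (any(!is.finite(Re(s))) || any(!is.finite(Im(s))))
    stop("refusing to write non-finite S-parameters")
  n <- ds$array$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("! %s", ds$label), con)
  writeLines("# Hz S RI R 50", con)
  for (f in seq_along(ds$sweep)) {
    m <- t(s[, , f])  # row-major over (i, j)
    vals <- as.vector(rbind(Re(as.vector(m)), Im(as.vector(m))))
    writeLines(paste(format(c(ds$sweep[f], vals), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Convert a frequency sweep to real time-domain signals
#'
#' Per channel the band-limited spectrum is windowed, zero-padded below the
#' band and beyond it, hermitian-extended and inverse-transformed, giving a
#' real signal of length 2 (Nf_padded - 1). The band is placed at the nearest
#' integer FFT bin (offset at most half a bin, < 0.4% of the carrier).
#'
#' @param ds a [scattering_dataset()].
#' @param window `"hamming"`, `"hann"` or `"none"`.
#' @param pad_factor integer >= 1 spectral zero-padding factor.
#' @return class `"time_domain_signals"`: `t` (seconds) and `x`, a real array
#'   Na x Na x length(t).
#' @export
to_time_domain <- function(ds, window = c("hamming", "hann", "none"),
                           pad_factor = 4L) {
  window <- match.arg(window)
  stopifnot(pad_factor >= 1)
  f <- ds$sweep
  nf <- length(f)
  df <- diff(f)
  if (max(abs(df - df[1])) > 1e-6 * df[1])
    stop("resampling error: frequency grid is not uniform")
  df <- df[1]
  k0 <- as.integer(round(f[1] / df))
  w <- switch(window,
    none = rep(1, nf),
    hamming = 0.54 - 0.46 * cos(2 * pi * (seq_len(nf) - 1) / (nf - 1)),
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(nf) - 1) / (nf - 1)))
  npos <- as.integer(pad_factor) * (k0 + nf)   # one-sided bins 0..npos-1
  L <- 2L * (npos - 1L)
  na <- ds$array$n
  sm <- matrix(ds$s, na * na, nf)              # channels x freqs
  spec <- matrix(0 + 0i, na * na, npos)
  spec[, k0 + seq_len(nf)] <- sweep_cols(sm, w)
  full <- cbind(spec, Conj(spec[, (npos - 1L):2L, drop = FALSE]))
  x <- t(Re(stats::mvfft(t(full), inverse = TRUE))) / L
  dt <- 1 / (L * df)
  structure(list(t = dt * (0:(L - 1L)),
                 x = array(x, c(na, na, L)),
                 array = ds$array, window = window),
            class = "time_domain_signals")
}

sweep_cols <- function(m, w) m * rep(w, each = nrow(m))

#' @export
print.time_domain_signals <- function(x, ...) {
  cat(sprintf("<time_domain_signals> %d channels, %d samples, dt = %.3g ns\n",
              x$array$n^2, length(x$t), 1e9 * (x$t[2] - x$t[1])))
  invisible(x)
}
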
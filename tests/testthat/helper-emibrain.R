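# Shared fixtures (built in code, cached per test run) and independent
# oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# cheap acquisition configuration for unit tests: short sweep, low top
# frequency so the forward rasterization can be coarser (lambda/10 rule)
t_array <- function() antenna_array()
t_sweep <- function() frequency_sweep(0.7e9, 1.2e9, n = 11L)
t_prop <- function() propagation_model()
t_spacing <- 0.0035
t_grid <- function() make_image_grid(spacing = 0.004)

t_cal <- function() memo("cal", make_calibration_record(
  t_sweep(), t_array(), t_prop(), snr_db = Inf, seed = 1L,
  grid_spacing = t_spacing))

t_forward <- function(phantom) forward_scatter(phantom, t_array(), t_sweep(),
                                               t_prop(), t_spacing)

# centered, mirror-symmetric head (no inclusion)
t_symmetric_phantom <- function() head_phantom(
  boundary = list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0))

# diseased phantom with a fixed, centred boundary (mirror-symmetric clutter)
t_diseased_phantom <- function(seed, class = "ICH")
  make_phantom(seed, class,
               boundary = list(cx = 0, cy = 0, a = 0.080, b = 0.100, rot = 0),
               radius_range = c(0.010, 0.025))

# brute-force O(n^2) horizontal-visibility oracle straight from the
# definition: edge (i, j) iff all strictly-between samples are below both
hvg_oracle_edges <- function(x) {
  n <- length(x)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      between <- if (j > i + 1) x[(i + 1):(j - 1)] else numeric(0)
      if (all(between < min(x[i], x[j]))) {
        ei <- c(ei, i); ej <- c(ej, j)
      }
    }
  }
  cbind(i = ei, j = ej)
}

edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

# same brute-force definition, vectorized per left endpoint (cummax of the
# in-between running maximum); used for the large oracle-equivalence sweep
hvg_oracle_fast <- function(x) {
  n <- length(x)
  ei <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    xs <- x[(i + 1):n]
    B <- c(-Inf, utils::head(cummax(xs), -1))  # max strictly between i and j
    sel <- B < pmin(x[i], xs)
    ei[[i]] <- if (any(sel)) cbind(i, i + which(sel)) else NULL
  }
  do.call(rbind, ei)
}

# naive double-loop distance correlation (V-statistic definition)
dcor_oracle <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  sqrt(mean(A * B) / sqrt(mean(A * A) * mean(B * B)))
}

# nearest mirrored-angle oracle for antenna mirror pairing
mirror_oracle <- function(k, array) {
  target <- (180 - array$angles_deg[k]) %% 360
  diffs <- abs(array$angles_deg - target)
  diffs <- pmin(diffs, 360 - diffs)
  which.min(diffs)
}
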
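#' Build a weighted horizontal visibility graph
#'
#' Nodes are time samples; samples i < j are linked iff every intermediate
#' sample is strictly lower than both (`x_k < min(x_i, x_j)`). Construction
#' is stack-based and touches each element O(1) times amortized. Edge
#' weights are amplitude differences `|x_i - x_j|` plus a small floor
#' (1e-12) so node strengths stay positive.
#'
#' @param x real series, length >= 2, finite.
#' @return class `"hvg"`: node count `n`, edge endpoints `i < j`, weights `w`.
#' @export
build_hvg <- function(x) {
  if (length(x) < 2) stop("series must have length >= 2")
  if (any(!is.finite(x))) stop("NaN/Inf in series")
  e <- hvg_edges_cpp(as.numeric(x))
  w <- abs(x[e$i] - x[e$j]) + 1e-12
  structure(list(n = length(x), i = e$i, j = e$j, w = w), class = "hvg")
}

#' @export
print.hvg <- function(x, ...) {
  cat(sprintf("<hvg> %d nodes, %d edges\n", x$n, length(x$i)))
  invisible(x)
}

#' Node-level metrics of a horizontal visibility graph
#'
#' Degree `k_i`, strength `s_i = sum_j w_ij`, and per-node entropy
#' `H_i = -sum_j p_ij ln p_ij` (nats) of the incident-edge weight
#' distribution `p_ij = w_ij / s_i`. `H_i = 0` for degree-1 nodes and
#' `H_i <= ln k_i` always.
#'
#' @param g an [build_hvg()] result.
#' @return class `"graph_metrics"`: vectors `degree`, `strength`, `entropy`
#'   and scalar summaries `mean_degree`, `mean_strength`, `mean_entropy`,
#'   `max_degree`, `max_strength`, `max_entropy`.
#' @export
graph_metrics <- function(g) {
  if (g$n < 1 || length(g$i) == 0) stop("empty graph")
  nodes <- seq_len(g$n)
  ends <- c(g$i, g$j)
  wall <- c(g$w, g$w)
  degree <- tabulate(ends, g$n)
  strength <- as.numeric(rowsum(wall, ends, reorder = TRUE))
  # rowsum only returns groups present; degree >= 1 for every node in an HVG
  p <- wall / strength[ends]
  plogp <- ifelse(p > 0, p * log(p), 0)
  entropy <- -as.numeric(rowsum(plogp, ends, reorder = TRUE))
  entropy[degree <= 1] <- 0
  entropy[entropy < 0] <- 0
  structure(list(degree = degree, strength = strength, entropy = entropy,
                 mean_degree = mean(degree), mean_strength = mean(strength),
                 mean_entropy = mean(entropy),
                 max_degree = max(degree), max_strength = max(strength),
                 max_entropy = max(entropy)),
            class = "graph_metrics")
}

#' Per-channel HVG metric matrix
#'
#' For every transmit-receive channel (i, j) the time-domain signal is
#' converted to an HVG and summarized by the chosen node metric, giving an
#' Na x Na real matrix. All-constant (flat) channels are degenerate for the
#' visibility criterion; they are computed as usual and flagged via the
#' `flat_channels` attribute.
#'
#' @param tds a [to_time_domain()] result.
#' @param metric `"degree"`, `"strength"` or `"entropy"`.
#' @param summary `"mean"` (default), `"max"` or `"median"` over nodes.
#' @return Na x Na numeric matrix.
#' @export
channel_metric_matrix <- function(tds,
                                  metric = c("degree", "strength", "entropy"),
                                  summary = c("mean", "max", "median")) {
  metric <- match.arg(metric)
  summary <- match.arg(summary)
  na <- dim(tds$x)[1]
  M <- matrix(NA_real_, na, na)
  flat <- matrix(FALSE, na, na)
  sfun <- switch(summary, mean = mean, max = max, median = stats::median)
  for (i in seq_len(na)) for (j in seq_len(na)) {
    xs <- tds$x[i, j, ]
    flat[i, j] <- (max(xs) - min(xs)) == 0
    g <- build_hvg(xs)
    M[i, j] <- sfun(graph_metrics(g)[[metric]])
  }
  attr(M, "flat_channels") <- flat
  M
}

#' All three channel metric matrices at once
#' @param tds a [to_time_domain()] result.
#' @param summary node summary, see [channel_metric_matrix()].
#' @return named list of Na x Na matrices `degree`, `strength`, `entropy`.
#' @export
channel_metric_matrices <- function(tds, summary = "mean") {
  na <- dim(tds$x)[1]
  out <- list(degree = matrix(NA_real_, na, na),
              strength = matrix(NA_real_, na, na),
              entropy = matrix(NA_real_, na, na))
  sfun <- switch(summary, mean = mean, max = max, median = stats::median)
  for (i in seq_len(na)) for (j in seq_len(na)) {
    m <- graph_metrics(build_hvg(tds$x[i, j, ]))
    out$degree[i, j] <- sfun(m$degree)
    out$strength[i, j] <- sfun(m$strength)
    out$entropy[i, j] <- sfun(m$entropy)
  }
  out
}
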
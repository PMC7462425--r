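#' Region-of-interest time series container
#'
#' A samples x regions numeric matrix with region labels. Only a light
#' wrapper: connectivity functions also accept a plain matrix.
#'
#' @param data numeric matrix, rows = time points, columns = regions; no NA.
#' @param labels region labels (default from colnames).
#' @param sample_interval sampling interval in seconds (metadata only).
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, labels = NULL, sample_interval = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data))
    stopf("time-series data must be numeric with no missing values")
  labels <- labels %||% colnames(data) %||% paste0("r", seq_len(ncol(data)))
  if (length(labels) != ncol(data)) stopf("one label per region required")
  if (any(!nzchar(labels)) || anyDuplicated(labels))
    labels <- make.unique(ifelse(nzchar(labels), labels,
                                 paste0("r", seq_len(ncol(data)))), sep = "_")
  colnames(data) <- labels
  if (nrow(data) <= ncol(data))
    warnf("fewer samples (%d) than regions (%d): correlations will be unstable",
          nrow(data), ncol(data))
  structure(list(data = data, labels = as.character(labels),
                 sample_interval = sample_interval),
            class = "roi_timeseries")
}

as_roi <- function(ts) {
  if (inherits(ts, "roi_timeseries")) ts else roi_timeseries(ts)
}

#' Regress out the global signal
#'
#' The global signal is the mean across regions at each time point. Each
#' region's series is replaced by its ordinary-least-squares residual on
#' (intercept, global signal). Removing the shared component typically
#' increases the number of significant negative correlations.
#'
#' @param ts a [roi_timeseries()] or samples x regions matrix.
#' @return a [roi_timeseries()] of residual series.
#' @export
regress_global_signal <- function(ts) {
  ts <- as_roi(ts)
  x <- ts$data
  if (ncol(x) < 2) stopf("need at least 2 regions")
  g <- rowMeans(x)
  if (sd(g) == 0) {
    warnf("global signal is constant: removing region means only")
    res <- scale(x, center = TRUE, scale = FALSE)
  } else {
    res <- stats::lm.fit(cbind(1, g), x)$residuals
  }
  roi_timeseries(res, labels = ts$labels, sample_interval = ts$sample_interval)
}

#' Build abs/pos/neg connectivity networks from region time series
#'
#' Pearson correlation over all unique region pairs; two-sided p-values
#' from the t distribution with T - 2 degrees of freedom;
#' Benjamini-Hochberg FDR correction over the family of unique pairs.
#' Surviving edges are split by sign: `pos_net` keeps positive
#' correlations, `neg_net` the absolute values of negative ones, and
#' `abs_net` is constructed as their element-wise sum, so
#' `abs = pos + neg` holds exactly. Non-surviving pairs are exactly 0 in
#' all three networks. Zero-variance regions become isolated nodes with a
#' warning.
#'
#' @param ts a [roi_timeseries()] or samples x regions matrix (>= 4 rows).
#' @param q FDR level (default 0.05).
#' @param gsr apply [regress_global_signal()] first.
#' @return object of class `connectivity_set`: `r_matrix` (zero
#'   diagonal), `p_matrix`, `q_threshold`, `abs_net`, `pos_net`,
#'   `neg_net` ([weighted_network()]s), `n_edges` (named counts).
#' @export
build_connectivity <- function(ts, q = 0.05, gsr = FALSE) {
  ts <- as_roi(ts)
  if (gsr) ts <- regress_global_signal(ts)
  x <- ts$data
  Tn <- nrow(x); n <- ncol(x)
  if (Tn < 4) stopf("need at least 4 time points")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    warnf("%d zero-variance region(s): their pairs are treated as non-edges",
          sum(sds == 0))
  r <- suppressWarnings(cor(x))
  df <- Tn - 2
  tt <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  pm <- 2 * pt(tt, df, lower.tail = FALSE)
  pm[abs(r) >= 1] <- 0
  diag(r) <- 0
  diag(pm) <- NA
  ut <- upper.tri(r)
  pvec <- pm[ut]
  padj <- rep(NA_real_, length(pvec))
  ok <- !is.na(pvec)
  padj[ok] <- p.adjust(pvec[ok], method = "BH")
  sig <- matrix(FALSE, n, n)
  sig[ut] <- !is.na(padj) & padj <= q
  sig <- sig | t(sig)
  pos <- ifelse(sig & r > 0, r, 0)
  neg <- ifelse(sig & r < 0, -r, 0)
  absw <- pos + neg
  qm <- matrix(NA_real_, n, n)
  qm[ut] <- padj
  qm[lower.tri(qm)] <- t(qm)[lower.tri(qm)]
  structure(list(r_matrix = r, p_matrix = pm, q_matrix = qm, q_threshold = q,
                 abs_net = weighted_network(absw, labels = ts$labels),
                 pos_net = weighted_network(pos, labels = ts$labels),
                 neg_net = weighted_network(neg, labels = ts$labels),
                 n_edges = c(abs = sum(absw[ut] > 0), pos = sum(pos[ut] > 0),
                             neg = sum(neg[ut] > 0))),
            class = "connectivity_set")
}

#' @export
print.connectivity_set <- function(x, ...) {
  cat(sprintf("<connectivity_set> %d regions | FDR q = %g | edges: abs %d, pos %d, neg %d\n",
              nrow(x$r_matrix), x$q_threshold,
              x$n_edges["abs"], x$n_edges["pos"], x$n_edges["neg"]))
  invisible(x)
}

#' Synthetic correlated region signals
#'
#' Gaussian signals with block correlation structure (groups of regions
#' correlated at `within`, `between` across groups), optional designated
#' negatively correlated pairs, plus a shared global component scaled by
#' `global_amplitude`. Emulates extracted regional signals closely enough
#' to exercise the full connectivity pipeline: with a strong global
#' component, global-signal regression uncovers the negative correlations
#' it masks.
#'
#' @param n_regions number of regions.
#' @param n_samples number of time points.
#' @param block_sizes integer group sizes summing to at most `n_regions`
#'   (remaining regions are uncorrelated background).
#' @param within,between correlation levels inside/between blocks.
#' @param negative_pairs optional 2-column matrix of region index pairs
#'   given correlation `negative_level`.
#' @param negative_level correlation for `negative_pairs`.
#' @param global_amplitude sd multiple of the added shared component.
#' @param seed optional integer seed.
#' @return a [roi_timeseries()].
#' @export
synth_roi_signals <- function(n_regions, n_samples, block_sizes = integer(),
                              within = 0.6, between = 0,
                              negative_pairs = NULL, negative_level = -0.6,
                              global_amplitude = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(block_sizes) > n_regions)
    stopf("block sizes exceed the number of regions")
  Sigma <- matrix(between, n_regions, n_regions)
  at <- 0L
  for (b in seq_along(block_sizes)) {
    idx <- at + seq_len(block_sizes[b])
    Sigma[idx, idx] <- within
    at <- at + block_sizes[b]
  }
  if (at < n_regions) {  # background regions uncorrelated
    bg <- (at + 1L):n_regions
    Sigma[bg, ] <- 0; Sigma[, bg] <- 0
  }
  diag(Sigma) <- 1
  if (!is.null(negative_pairs)) {
    negative_pairs <- as.matrix(negative_pairs)
    for (e in seq_len(nrow(negative_pairs))) {
      i <- negative_pairs[e, 1]; j <- negative_pairs[e, 2]
      Sigma[i, j] <- negative_level; Sigma[j, i] <- negative_level
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stopf("target correlation matrix is not positive semidefinite (min eigenvalue %.3g); weaken the block or negative-pair levels",
          min(ev$values))
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  z <- matrix(rnorm(n_samples * n_regions), n_samples, n_regions)
  x <- z %*% root
  if (global_amplitude != 0)
    x <- x + global_amplitude * rnorm(n_samples)
  roi_timeseries(x, labels = paste0("r", seq_len(n_regions)))
}
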
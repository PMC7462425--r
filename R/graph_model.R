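#' Weighted network
#'
#' Core container: a square nonnegative weight matrix with node labels.
#' Undirected networks (the default) must be symmetric to within `tol` and
#' are stored symmetrized; self-loops are dropped with a warning. Signed
#' matrices are rejected — split them first with [build_connectivity()] or
#' load with `absolute = TRUE`.
#'
#' @param weights square numeric matrix of nonnegative weights `w_ij`.
#' @param labels character vector of node labels; defaults to the matrix
#'   dimnames or `n1, n2, ...`.
#' @param directed logical; if `FALSE` (default) the matrix must be symmetric.
#' @param tol absolute symmetry tolerance for undirected input.
#' @return an object of class `weighted_network` with elements `weights`
#'   (labelled matrix), `n_nodes`, `labels`, `directed`.
#' @export
#' @examples
#' w <- matrix(c(0, 1, 0, 1, 0, 2, 0, 2, 0), 3, 3)
#' net <- weighted_network(w, labels = c("a", "b", "c"))
#' node_strengths(net)$strength
weighted_network <- function(weights, labels = NULL, directed = FALSE,
                             tol = 1e-12) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stopf("weights must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n)
    stopf("weight matrix must be square (got %d x %d)", n, ncol(weights))
  if (anyNA(weights))
    stopf("weight matrix contains NA/NaN entries")
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1L, ]
    stopf("negative weight at [%d, %d]; signed matrices must be split by sign first (or load with absolute = TRUE)",
          bad[1L], bad[2L])
  }
  if (is.null(labels))
    labels <- rownames(weights) %||% paste0("n", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels))
    stopf("labels must be %d unique strings", n)
  if (any(diag(weights) != 0)) {
    warnf("dropping %d self-loop(s)", sum(diag(weights) != 0))
    diag(weights) <- 0
  }
  if (!directed) {
    asym <- max(abs(weights - t(weights)))
    if (asym > tol)
      stopf("matrix is asymmetric (max |w_ij - w_ji| = %g > %g) but directed = FALSE",
            asym, tol)
    weights <- (weights + t(weights)) / 2
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, n_nodes = n, labels = labels,
                 directed = directed),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  m <- edge_count(x)
  cat(sprintf("<weighted_network> %d nodes, %d %s edges, density %.3f\n",
              x$n_nodes, m, if (x$directed) "directed" else "undirected",
              if (x$n_nodes > 1)
                m / (x$n_nodes * (x$n_nodes - 1) / (if (x$directed) 1 else 2))
              else 0))
  s <- node_strengths(x)$strength
  cat(sprintf("  strength: min %.4g, median %.4g, max %.4g\n",
              min(s), stats::median(s), max(s)))
  invisible(x)
}

#' Number of edges of a weighted network
#'
#' Counts nonzero off-diagonal entries; undirected edges are counted once.
#' @param net a [weighted_network()].
#' @return integer edge count.
#' @export
edge_count <- function(net) {
  w <- net$weights
  if (net$directed) sum(w > 0) else sum(w[upper.tri(w)] > 0)
}

#' Node strengths and degrees
#'
#' The strength of node i is the row sum `str_i = sum_j w_ij`; the degree is
#' the number of nonzero off-diagonal entries in row i.
#'
#' @param net a [weighted_network()].
#' @return list with named numeric `strength` and named integer `degree`.
#' @export
node_strengths <- function(net) {
  w <- net$weights
  list(strength = rowSums(w),
       degree = as.integer(rowSums(w > 0)))
}

#' Remove a node and all its connections
#'
#' Returns the (n-1) x (n-1) network obtained by deleting row and column `i`;
#' the input network is unmodified.
#'
#' @param net a [weighted_network()].
#' @param i node index (1-based) or node label.
#' @return a [weighted_network()] on the surviving nodes.
#' @export
remove_node <- function(net, i) {
  if (is.character(i)) {
    idx <- match(i, net$labels)
    if (is.na(idx)) stopf("unknown node label '%s'", i)
    i <- idx
  }
  if (length(i) != 1L || i < 1 || i > net$n_nodes)
    stopf("node index out of range [1, %d]", net$n_nodes)
  weighted_network(net$weights[-i, -i, drop = FALSE],
                   labels = net$labels[-i], directed = net$directed)
}

numeric_like <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a weighted network from disk
#'
#' Supported formats: `matrix-csv` (square numeric CSV, optional header row
#' and leading label column), `edge-list` (whitespace- or tab-separated
#' `source target weight`, one edge per line, each undirected edge listed
#' once), and `graphml` (with a `weight` edge attribute, read via igraph).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"matrix-csv"`, `"edge-list"`, `"graphml"`;
#'   `"auto"` guesses from the extension.
#' @param directed logical.
#' @param absolute if `TRUE`, take absolute values of negative entries
#'   instead of raising an error.
#' @inheritParams weighted_network
#' @return a [weighted_network()].
#' @export
load_network <- function(path,
                         format = c("auto", "matrix-csv", "edge-list", "graphml"),
                         directed = FALSE, absolute = FALSE, tol = 1e-12) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     graphml = "graphml",
                     csv = "matrix-csv",
                     tsv = , txt = , edges = , edgelist = "edge-list",
                     "matrix-csv")
  }
  out <- switch(format,
    "matrix-csv" = read_matrix_csv(path),
    "edge-list" = read_edge_list(path, directed),
    "graphml" = read_graphml(path))
  w <- out$weights
  if (anyNA(w)) stopf("parsed matrix contains NA/NaN entries")
  if (any(w < 0)) {
    if (absolute) {
      w <- abs(w)
    } else {
      bad <- which(w < 0, arr.ind = TRUE)[1L, ]
      stopf("negative entry at [%d, %d] (%g); pass absolute = TRUE to take magnitudes",
            bad[1L], bad[2L], w[bad[1L], bad[2L]])
    }
  }
  weighted_network(w, labels = out$labels, directed = directed, tol = tol)
}

read_matrix_csv <- function(path) {
  first <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  has_header <- !all(numeric_like(first[nzchar(first)]))
  df <- read.csv(path, header = has_header, check.names = FALSE,
                 stringsAsFactors = FALSE)
  labels <- NULL
  if (ncol(df) >= 2 && !all(numeric_like(df[[1L]]))) {
    labels <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  } else if (has_header) {
    labels <- colnames(df)
  }
  w <- as.matrix(df)
  if (!is.numeric(w)) stopf("matrix-csv contains non-numeric entries")
  if (nrow(w) != ncol(w))
    stopf("matrix-csv is not square (%d x %d)", nrow(w), ncol(w))
  dimnames(w) <- NULL
  list(weights = w, labels = labels)
}

read_edge_list <- function(path, directed) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stopf("edge list needs three columns: source target weight")
  from <- as.character(df[[1L]]); to <- as.character(df[[2L]])
  wts <- as.numeric(df[[3L]])
  labels <- unique(c(from, to))
  n <- length(labels)
  w <- matrix(0, n, n)
  fi <- match(from, labels); ti <- match(to, labels)
  for (e in seq_along(fi)) {
    if (w[fi[e], ti[e]] != 0)
      warnf("duplicate edge %s-%s: overwriting", from[e], to[e])
    w[fi[e], ti[e]] <- wts[e]
    if (!directed) w[ti[e], fi[e]] <- wts[e]
  }
  list(weights = w, labels = labels)
}

read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!("weight" %in% igraph::edge_attr_names(g)))
    stopf("graphml file has no 'weight' edge attribute")
  w <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  labels <- if ("name" %in% igraph::vertex_attr_names(g))
    igraph::V(g)$name else NULL
  dimnames(w) <- NULL
  list(weights = w, labels = labels)
}

#' Write a weighted network as matrix-csv
#'
#' Writes the labelled square matrix with a header row and a leading label
#' column, at full double precision so `load_network(save_network(net))`
#' round-trips exactly.
#'
#' @param net a [weighted_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  w <- net$weights
  header <- paste(c("", net$labels), collapse = ",")
  rows <- vapply(seq_len(net$n_nodes), function(i) {
    paste(c(net$labels[i], sprintf("%.17g", w[i, ])), collapse = ",")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}
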
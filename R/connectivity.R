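#' Functional connectivity matrix
#'
#' Zero-lag Pearson correlation between all pairs of node time courses.
#' Nodes with zero variance yield `NA` rows/columns and a warning naming
#' them; the diagonal is 1 by convention.
#'
#' @param ts Numeric matrix, time in rows, nodes in columns (a
#'   [simulate_bnm()] result is also accepted).
#' @param modules Optional module label per node, attached to the result.
#' @return An object of class `"fc_matrix"`: the symmetric correlation
#'   matrix with attributes `modules`.
#' @export
fc_matrix <- function(ts, modules = NULL) {
  if (inherits(ts, "bnm_sim")) {
    modules <- modules %||% ts$modules
    ts <- ts$series
  }
  ts <- as_node_matrix(ts)
  if (nrow(ts) < 3)
    stop("need at least 3 time points for correlation", call. = FALSE)
  v <- apply(ts, 2, stats::var)
  flat <- v == 0 | !is.finite(v)
  r <- suppressWarnings(stats::cor(ts))
  if (any(flat)) {
    warning("zero-variance node(s): ",
            paste(colnames(ts)[flat] %||% which(flat), collapse = ", "),
            call. = FALSE)
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  diag(r) <- 1
  if (!is.null(modules)) {
    if (length(modules) != ncol(ts))
      stop("`modules` must have one label per node", call. = FALSE)
    modules <- factor(modules)
  }
  structure(r, modules = modules, class = c("fc_matrix", "matrix"))
}

#' Mean off-diagonal functional connectivity
#'
#' Mean of the upper-triangle entries of an FC matrix, optionally restricted
#' to a node subset (e.g. one module).
#'
#' @param fc An [fc_matrix()] (or any square correlation matrix).
#' @param nodes Optional subset of node indices, names, or a logical mask.
#' @return A single number.
#' @export
mean_fc <- function(fc, nodes = NULL) {
  m <- unclass(fc)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`fc` must be a square matrix", call. = FALSE)
  if (!is.null(nodes)) m <- m[nodes, nodes, drop = FALSE]
  if (nrow(m) < 2)
    stop("need at least 2 nodes to average connectivity", call. = FALSE)
  mean(m[upper.tri(m)], na.rm = TRUE)
}

#' Seed-based functional connectivity
#'
#' Pearson correlation between the mean time course of a seed node subset
#' and every node in the set.
#'
#' @param ts Numeric matrix, time in rows, nodes in columns.
#' @param seed_nodes Node indices, names, or logical mask of the seed
#'   region (non-empty).
#' @return Named numeric vector of correlations, one per node.
#' @export
seed_fc <- function(ts, seed_nodes) {
  if (inherits(ts, "bnm_sim")) ts <- ts$series
  ts <- as_node_matrix(ts)
  if (nrow(ts) < 3)
    stop("need at least 3 time points for correlation", call. = FALSE)
  seed_ts <- ts[, seed_nodes, drop = FALSE]
  if (ncol(seed_ts) == 0)
    stop("`seed_nodes` selects no node", call. = FALSE)
  s <- rowMeans(seed_ts)
  r <- suppressWarnings(as.vector(stats::cor(s, ts)))
  names(r) <- colnames(ts)
  r
}
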
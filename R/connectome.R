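#' Construct a structural connectome
#'
#' A weighted coupling matrix with a module partition. Weights must be
#' non-negative with a zero diagonal; the matrix need not be symmetric.
#'
#' @param weights Square numeric matrix of non-negative coupling weights,
#'   zero diagonal.
#' @param modules Module label per node (factor or character/integer
#'   vector); `NULL` puts every node in one module.
#' @param names Optional node labels; defaults to the matrix dimnames or
#'   `n1, n2, ...`.
#' @return An object of class `"connectome"` with elements `weights`,
#'   `modules` (factor) and `names`.
#' @export
connectome <- function(weights, modules = NULL, names = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("connectome matrix must be square (got %d x %d)",
                 n, ncol(weights)), call. = FALSE)
  bad <- which(!is.finite(weights), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite weight at [%d, %d]", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative weight at [%d, %d]", neg[1, 1], neg[1, 2]),
         call. = FALSE)
  if (any(diag(weights) != 0))
    stop("connectome diagonal must be zero", call. = FALSE)
  if (is.null(names))
    names <- rownames(weights) %||% paste0("n", seq_len(n))
  if (is.null(modules)) modules <- rep("m1", n)
  if (length(modules) != n)
    stop("`modules` must have one label per node", call. = FALSE)
  dimnames(weights) <- list(names, names)
  structure(list(weights = weights, modules = factor(modules), names = names),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Structural connectome:", length(x$names), "nodes,",
      nlevels(x$modules), "module(s)\n")
  cat("  density:",
      round(mean(x$weights[row(x$weights) != col(x$weights)] > 0), 3), "\n")
  invisible(x)
}

#' Read a structural connectome from delimited text
#'
#' The weight file must parse to a square numeric matrix (any of comma, tab
#' or whitespace separation; lines starting with `#` are ignored). The
#' optional module file has one `node,label` pair per line; without it all
#' nodes form a single module.
#'
#' @param path Path to the weight matrix file.
#' @param module_file Optional path to a two-column `node,label` file.
#' @param sep Field separator (default `","`).
#' @return A [connectome()] object.
#' @export
load_connectome <- function(path, module_file = NULL, sep = ",") {
  raw <- read.table(path, sep = sep, comment.char = "#",
                    header = FALSE, stringsAsFactors = FALSE)
  w <- as.matrix(raw)
  if (!is.numeric(w))
    stop("connectome file contains non-numeric entries", call. = FALSE)
  modules <- NULL
  names <- NULL
  if (!is.null(module_file)) {
    mod <- read.table(module_file, sep = sep, comment.char = "#",
                      header = FALSE, stringsAsFactors = FALSE)
    if (ncol(mod) < 2)
      stop("module file needs two columns: node,label", call. = FALSE)
    if (nrow(mod) != nrow(w))
      stop("module file has ", nrow(mod), " rows but the matrix has ",
           nrow(w), " nodes", call. = FALSE)
    names <- as.character(mod[[1]])
    modules <- as.character(mod[[2]])
  }
  connectome(unname(w), modules = modules, names = names)
}

#' Write a connectome to delimited text
#'
#' @param conn A [connectome()] object.
#' @param path Output path for the weight matrix.
#' @param module_file Optional path for the `node,label` module table.
#' @param sep Field separator.
#' @return `conn`, invisibly.
#' @export
write_connectome <- function(conn, path, module_file = NULL, sep = ",") {
  stopifnot(inherits(conn, "connectome"))
  write.table(conn$weights, path, sep = sep, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(module_file))
    write.table(data.frame(conn$names, as.character(conn$modules)),
                module_file, sep = sep, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  invisible(conn)
}
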
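#' Read node time series from delimited text
#'
#' One column per channel with a header row of labels. Lines starting with
#' `#` are treated as metadata; a `# fs: <Hz>` line, if present, is
#' attached as the `fs` attribute.
#'
#' @param path Input path.
#' @param sep Field separator.
#' @return Time-by-node numeric matrix (attribute `fs` when recorded).
#' @export
read_node_series <- function(path, sep = ",") {
  meta <- grep("^#", readLines(path, n = 20), value = TRUE)
  d <- read.table(path, sep = sep, header = TRUE, comment.char = "#",
                  check.names = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m))
    stop("node series file contains non-numeric entries", call. = FALSE)
  fsline <- grep("^#\\s*fs:", meta, value = TRUE)
  if (length(fsline))
    attr(m, "fs") <- as.numeric(sub("^#\\s*fs:\\s*", "", fsline[1]))
  m
}

#' Write node time series to delimited text
#'
#' @param ts Time-by-node matrix (or [simulate_bnm()] result).
#' @param path Output path.
#' @param fs Sampling rate recorded as a `# fs:` metadata line.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_node_series <- function(ts, path, fs = NULL, sep = ",") {
  if (inherits(ts, "bnm_sim")) {
    fs <- fs %||% ts$fs
    ts <- ts$series
  }
  ts <- as_node_matrix(ts)
  if (is.null(colnames(ts))) colnames(ts) <- paste0("n", seq_len(ncol(ts)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(fs)) writeLines(sprintf("# fs: %g", fs), con)
  write.table(ts, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
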
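# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# population SD (divide by N); deterministic anchor for entropy tolerances
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards; seed = NULL uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

as_node_matrix <- function(ts) {
  if (is.data.frame(ts)) ts <- as.matrix(ts)
  if (!is.matrix(ts) || !is.numeric(ts))
    stop("node time series must be a numeric matrix (time in rows, nodes in columns)",
         call. = FALSE)
  ts
}
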
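# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the ambient RNG state".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Convert a physical distance (um) to a structuring-element radius in pixels.
# Distances > 0 round to the nearest pixel but never below 1 px.
px_radius <- function(um, pixel_size) {
  stopifnot(um >= 0, pixel_size > 0)
  if (um == 0) return(0L)
  max(1L, as.integer(round(um / pixel_size)))
}

# Odd-sized disc brush of radius r pixels (r >= 1).
disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")

# Clamp to the 16-bit camera range and round to integer gray-levels.
clamp16 <- function(x) {
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  storage.mode(x) <- "integer"
  x
}

# Coerce an EBImage result back to a plain integer label matrix.
label_matrix <- function(x) {
  m <- if (inherits(x, "Image")) EBImage::imageData(x) else x
  m <- round(m)
  storage.mode(m) <- "integer"
  m
}

# Relabel a label matrix so labels are contiguous 1..N (order preserved).
relabel_sequential <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
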
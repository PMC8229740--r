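# internal helpers shared across modules

# append a timestamped line to the active run log (if any) and emit as message
rs_log <- function(..., logfile = NULL) {
  txt <- paste0(...)
  if (!is.null(logfile)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), txt, "\n",
        file = logfile, append = TRUE, sep = "")
  }
  message(txt)
  invisible(txt)
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stage sub-seed from a master seed, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 7919) %% 2147483629) + 1L
}

# bounding box of a logical/0-1 3D array: list(lo = c(i,j,k), hi = c(i,j,k))
mask_bbox <- function(m) {
  stopifnot(length(dim(m)) == 3)
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

# crop a 3D array to a bbox expanded by `pad`, clipped to the grid
crop_array <- function(a, bbox, pad = 0) {
  d <- dim(a)
  lo <- pmax(bbox$lo - pad, 1)
  hi <- pmin(bbox$hi + pad, d)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}
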
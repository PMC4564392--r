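`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a 3-D array, zero-filling the vacated slab
#'
#' @param a 3-D array
#' @param dx,dy,dz integer shifts (positive moves content towards higher
#'   indices)
#' @return shifted array of the same dimension
#' @keywords internal
shift3 <- function(a, dx = 0L, dy = 0L, dz = 0L) {
  d <- dim(a)
  out <- array(0, d)
  sx <- max(1, 1 - dx):min(d[1], d[1] - dx)
  sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
  sz <- max(1, 1 - dz):min(d[3], d[3] - dz)
  if (length(sx) == 0 || length(sy) == 0 || length(sz) == 0) return(out)
  out[sx + dx, sy + dy, sz + dz] <- a[sx, sy, sz]
  out
}

#' Binary dilation with the 6-connected structuring element
#' @keywords internal
dilate6 <- function(mask, n = 1L) {
  m <- mask != 0
  for (i in seq_len(n)) {
    m <- m |
      shift3(m, 1, 0, 0) | shift3(m, -1, 0, 0) |
      shift3(m, 0, 1, 0) | shift3(m, 0, -1, 0) |
      shift3(m, 0, 0, 1) | shift3(m, 0, 0, -1)
  }
  storage.mode(m) <- "double"
  m
}

#' Central-difference gradient along one axis, one-sided at the edges
#' @keywords internal
central_diff <- function(a, axis, spacing = 1) {
  sh <- function(s) switch(axis, shift3(a, s, 0, 0), shift3(a, 0, s, 0), shift3(a, 0, 0, s))
  g <- (sh(-1) - sh(1)) / (2 * spacing)
  # replace the boundary slabs with one-sided differences
  n <- dim(a)[axis]
  pick <- function(x, i) {
    idx <- list(TRUE, TRUE, TRUE); idx[[axis]] <- i
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  put <- function(x, i, val) {
    idx <- list(TRUE, TRUE, TRUE); idx[[axis]] <- i
    do.call(`[<-`, c(list(x), idx, list(val)))
  }
  g <- put(g, 1L, (pick(a, 2L) - pick(a, 1L)) / spacing)
  put(g, n, (pick(a, n) - pick(a, n - 1L)) / spacing)
}

#' 0-based voxel index grid for a given array dimension
#' @return n x 3 matrix of voxel indices in array (column-major) order
#' @keywords internal
index_grid <- function(d) {
  cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
}

stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
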
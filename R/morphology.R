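# Binary morphology on logical arrays. A Chebyshev ball is a cube, so
# dilation/erosion by radius r separates into r passes of a 3-wide line
# filter per axis.

shift_array <- function(arr, axis, by, fill = FALSE) {
  d <- dim(arr)
  n <- d[axis]
  idx <- seq_len(n) - by
  valid <- idx >= 1L & idx <= n
  args <- rep(list(quote(expr = )), length(d))
  out <- array(fill, dim = d)
  src <- args; dst <- args
  dst[[axis]] <- which(valid)
  src[[axis]] <- idx[valid]
  out <- do.call(`[<-`, c(list(out), dst,
                          list(do.call(`[`, c(list(arr), src,
                                              list(drop = FALSE))))))
  out
}

#' Dilate a boolean mask by a Chebyshev radius
#'
#' Max-filter with a `(2r+1)^d` cube: a voxel is set if any voxel within
#' Chebyshev distance `r` is set. `r = 0` returns the mask unchanged.
#'
#' @param mask logical array (2D or 3D).
#' @param radius non-negative integer radius in voxels.
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, radius) {
  stopifnot(is.logical(mask), radius >= 0)
  radius <- as.integer(radius)
  if (radius == 0L) return(mask)
  out <- mask
  nd <- length(dim(mask))
  for (i in seq_len(radius)) {
    for (ax in seq_len(nd)) {
      out <- out | shift_array(out, ax, 1L) | shift_array(out, ax, -1L)
    }
  }
  out
}

#' Erode a boolean mask by a Chebyshev radius
#'
#' Min-filter with a `(2r+1)^d` cube. Voxels outside the grid count as
#' foreground, so the mask does not erode inward from the field-of-view
#' edge.
#'
#' @inheritParams dilate_mask
#' @return Logical array of the same shape.
#' @export
erode_mask <- function(mask, radius) {
  stopifnot(is.logical(mask), radius >= 0)
  radius <- as.integer(radius)
  if (radius == 0L) return(mask)
  out <- mask
  nd <- length(dim(mask))
  for (i in seq_len(radius)) {
    for (ax in seq_len(nd)) {
      out <- out & shift_array(out, ax, 1L, fill = TRUE) &
        shift_array(out, ax, -1L, fill = TRUE)
    }
  }
  out
}

# Exact Euclidean distance transform (squared-distance lower envelope of
# parabolas, one separable pass per axis), supporting anisotropic spacing.
# Returns distances in physical units to the nearest TRUE voxel; Inf when
# the mask is empty.

dt_1d <- function(f, s) {
  n <- length(f)
  idx <- which(is.finite(f))
  if (length(idx) == 0L) return(rep(Inf, n))
  x <- (idx - 1) * s
  fv <- f[idx]
  m <- length(idx)
  v <- integer(m)
  z <- numeric(m + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  if (m > 1L) {
    for (q in 2L:m) {
      repeat {
        i <- v[k]
        sx <- ((fv[q] + x[q]^2) - (fv[i] + x[i]^2)) / (2 * (x[q] - x[i]))
        if (k > 1L && sx <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- sx
      z[k + 1L] <- Inf
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    xq <- (q - 1) * s
    while (z[k + 1L] < xq) k <- k + 1L
    out[q] <- (xq - x[v[k]])^2 + fv[v[k]]
  }
  out
}

dt_axis <- function(f, axis, s) {
  d <- dim(f)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  x <- aperm(f, perm)
  pd <- dim(x)
  x <- matrix(x, nrow = pd[1])
  x <- apply(x, 2L, dt_1d, s = s)
  dim(x) <- pd
  aperm(x, order(perm))
}

#' Euclidean distance transform of a boolean mask
#'
#' Exact distance (in mm, using per-axis spacing) from every voxel to the
#' nearest `TRUE` voxel.
#'
#' @param mask logical array.
#' @param spacing per-axis voxel size in mm.
#' @return Numeric array of distances; all-`Inf` if the mask is empty.
#' @export
distance_transform <- function(mask, spacing = rep(1, length(dim(mask)))) {
  stopifnot(is.logical(mask))
  f <- array(ifelse(mask, 0, Inf), dim = dim(mask))
  for (ax in seq_along(dim(mask))) {
    f <- dt_axis(f, ax, spacing[ax])
  }
  sqrt(f)
}
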
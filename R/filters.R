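# Separable filtering on 2D/3D grids with half-sample reflect padding.
# Hand-written rather than delegated: the toolkit needs the same boundary
# rule in 2D and 3D under one code path, and reflect padding keeps image
# margins free of spurious gradient response.

reflect_idx <- function(n, r) {
  if (r == 0) return(seq_len(n))
  left <- pmin(pmax(seq(r, 1), 1), n)
  right <- pmin(pmax(seq(n, n - r + 1), 1), n)
  c(left, seq_len(n), right)
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  nd <- length(d)
  r <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(seq_len(nd), axis))
  x <- aperm(arr, perm)
  pd <- dim(x)
  n <- pd[1]
  x <- matrix(x, nrow = n)
  xp <- x[reflect_idx(n, r), , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(x))
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * xp[t:(t + n - 1L), , drop = FALSE]
  }
  dim(out) <- pd
  aperm(out, order(perm))
}

gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with reflect boundary handling (kernel radius
#' `ceiling(4 * sigma)` voxels). `sigma = 0` returns the input unchanged.
#' The mean intensity is preserved to numerical tolerance.
#'
#' @param vol an [image_volume()].
#' @param sigma Gaussian standard deviation in voxels, `>= 0`.
#' @return A smoothed [image_volume()] on the same grid.
#' @export
smooth_volume <- function(vol, sigma) {
  stopifnot(inherits(vol, "us_volume"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("smooth_volume: sigma must be a single value >= 0", call. = FALSE)
  }
  if (sigma == 0) return(vol)
  k <- gaussian_kernel_1d(sigma)
  out <- vol$data
  for (ax in seq_len(n_dims(vol))) out <- convolve_axis(out, k, ax)
  image_volume(out, spacing = vol$spacing, origin = vol$origin)
}

#' Sobel gradient magnitude
#'
#' Per-axis Sobel responses (derivative kernel `(-1, 0, 1)` on the target
#' axis, smoothing kernel `(1, 2, 1)` on the others) combined as the
#' Euclidean norm. In 3D the operator is applied natively per axis; set
#' `mode_2d_slicewise = TRUE` to run the 2D operator on each slice along the
#' first (z) axis instead, which can suit strongly anisotropic sweeps.
#'
#' @param vol an [image_volume()] (2D or 3D).
#' @param normalize rescale the magnitude to `[0, 1]` by its maximum
#'   (no-op for an all-zero gradient).
#' @param mode_2d_slicewise 3D only: apply the 2D operator slice by slice.
#' @return An [image_volume()] of non-negative gradient magnitudes.
#' @export
gradient_magnitude <- function(vol, normalize = FALSE,
                               mode_2d_slicewise = FALSE) {
  stopifnot(inherits(vol, "us_volume"))
  nd <- n_dims(vol)
  deriv <- c(-1, 0, 1)
  smoo <- c(1, 2, 1)
  sq <- array(0, dim = dim(vol$data))
  if (nd == 3L && mode_2d_slicewise) {
    for (ax in 2:3) {
      g <- vol$data
      for (other in setdiff(2:3, ax)) g <- convolve_axis(g, smoo, other)
      g <- convolve_axis(g, deriv, ax)
      sq <- sq + g^2
    }
  } else {
    for (ax in seq_len(nd)) {
      g <- vol$data
      for (other in setdiff(seq_len(nd), ax)) {
        g <- convolve_axis(g, smoo, other)
      }
      g <- convolve_axis(g, deriv, ax)
      sq <- sq + g^2
    }
  }
  mag <- sqrt(sq)
  if (normalize) {
    mx <- max(mag)
    if (mx > 0) mag <- mag / mx
  }
  image_volume(mag, spacing = vol$spacing, origin = vol$origin)
}

#' Edge-detection parameters
#'
#' Bundles the choices behind the edge map used to identify distinct border
#' evidence: the smoothing scale, the thresholding rule applied to the
#' gradient magnitude, and whether the magnitude is normalized to `[0, 1]`
#' first. The default (`sigma = 2` voxels, normalized magnitude, Otsu
#' threshold) is parameter-free across intensity scales: sigma 2 suppresses
#' speckle at ~0.28 mm voxels without erasing tissue interfaces, and Otsu
#' picks the threshold maximizing between-class variance of the gradient
#' histogram.
#'
#' @param smooth_sigma Gaussian sigma in voxels, `>= 0`.
#' @param threshold_method one of `"otsu"`, `"fixed"`, `"percentile"`.
#' @param threshold_value fixed threshold (in `[0, 1]` when `normalize` is
#'   on) or percentile in `(0, 100)` of the nonzero gradient values.
#' @param normalize rescale gradient magnitude to `[0, 1]` by its maximum.
#' @param mode_2d_slicewise apply the 2D Sobel slice-wise on 3D input.
#' @return An object of class `us_edge_params`.
#' @export
edge_params <- function(smooth_sigma = 2, threshold_method = "otsu",
                        threshold_value = NULL, normalize = TRUE,
                        mode_2d_slicewise = FALSE) {
  threshold_method <- match.arg(threshold_method,
                                c("otsu", "fixed", "percentile"))
  if (smooth_sigma < 0) {
    stop("edge_params: smooth_sigma must be >= 0", call. = FALSE)
  }
  if (threshold_method == "fixed") {
    if (is.null(threshold_value)) {
      stop("edge_params: fixed thresholding needs threshold_value",
           call. = FALSE)
    }
    if (normalize && (threshold_value < 0 || threshold_value > 1)) {
      stop("edge_params: fixed threshold_value must lie in [0, 1] when ",
           "normalize is on", call. = FALSE)
    }
  }
  if (threshold_method == "percentile") {
    if (is.null(threshold_value) ||
        threshold_value <= 0 || threshold_value >= 100) {
      stop("edge_params: percentile threshold_value must lie in (0, 100)",
           call. = FALSE)
    }
  }
  structure(
    list(smooth_sigma = smooth_sigma, threshold_method = threshold_method,
         threshold_value = threshold_value, normalize = normalize,
         mode_2d_slicewise = mode_2d_slicewise),
    class = "us_edge_params"
  )
}

#' Otsu threshold of a value vector
#'
#' Histogram-based (256 bins) threshold maximizing the between-class
#' variance `w0 * w1 * (mu0 - mu1)^2` over all bin-edge candidates.
#'
#' @param values numeric vector.
#' @param n_bins number of histogram bins.
#' @return The threshold; values `>= threshold` form the upper class.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cnt <- tabulate(
    pmin(pmax(findInterval(values, breaks, all.inside = TRUE), 1L), n_bins),
    nbins = n_bins
  )
  p <- cnt / sum(cnt)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * w1[valid])
  # the variance curve can plateau across an empty gap between modes;
  # take the middle of the maximizing plateau
  k_set <- which(sigma_b >= max(sigma_b) - 1e-12)
  k <- as.integer(round(mean(range(k_set))))
  breaks[k + 1L]                       # upper class = values >= this edge
}

#' Threshold a gradient-magnitude volume into an edge map
#'
#' Applies the rule in `params` to a non-negative gradient image and records
#' the threshold actually used. The stored mask satisfies
#' `mask == (gradient >= threshold)` exactly (on the normalized scale when
#' `params$normalize` is on). A degenerate (constant) gradient yields an
#' all-false mask with a warning.
#'
#' @param grad an [image_volume()] of non-negative gradient magnitudes.
#' @param params an [edge_params()].
#' @return An object of class `us_edge_map` with fields `mask`, `params`,
#'   `threshold` and `gradient` (the grid the threshold was applied to).
#' @export
threshold_edges <- function(grad, params = edge_params()) {
  stopifnot(inherits(grad, "us_volume"), inherits(params, "us_edge_params"))
  g <- grad$data
  if (min(g) < 0) {
    stop("threshold_edges: gradient must be non-negative", call. = FALSE)
  }
  if (params$normalize) {
    mx <- max(g)
    if (mx > 0) g <- g / mx
  }
  degenerate <- diff(range(g)) == 0
  thr <- switch(params$threshold_method,
    otsu = if (degenerate) NA_real_ else otsu_threshold(as.vector(g)),
    fixed = params$threshold_value,
    percentile = {
      nz <- g[g > 0]
      if (length(nz) == 0) NA_real_
      else unname(stats::quantile(nz, params$threshold_value / 100))
    }
  )
  if (is.na(thr)) {
    warning("threshold_edges: degenerate gradient histogram; ",
            "returning all-false edge mask", call. = FALSE)
    mask <- array(FALSE, dim = dim(g))
    thr <- Inf
  } else {
    mask <- g >= thr
  }
  structure(
    list(mask = mask, params = params, threshold = thr,
         gradient = image_volume(g, spacing = grad$spacing,
                                 origin = grad$origin)),
    class = "us_edge_map"
  )
}

#' Compute the edge map of an image (smoothing, Sobel, threshold)
#'
#' The "distinct evidence" image: a Gaussian-smoothed Sobel gradient
#' magnitude, thresholded into a binary edge mask. Identical to chaining
#' [smooth_volume()], [gradient_magnitude()] and [threshold_edges()].
#'
#' @param vol an [image_volume()].
#' @param params an [edge_params()].
#' @return A `us_edge_map`.
#' @examples
#' img <- image_volume(matrix(rep(c(0, 1), each = 128), 16, 16))
#' em <- compute_edge_map(img, edge_params(smooth_sigma = 1))
#' sum(em$mask)
#' @export
compute_edge_map <- function(vol, params = edge_params()) {
  sm <- smooth_volume(vol, params$smooth_sigma)
  gm <- gradient_magnitude(sm, normalize = FALSE,
                           mode_2d_slicewise = params$mode_2d_slicewise)
  threshold_edges(gm, params)
}

#' @export
print.us_edge_map <- function(x, ...) {
  cat(sprintf("<edge map> %s, %d edge voxels (%.1f%%), threshold %.4g (%s)\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              100 * mean(x$mask), x$threshold,
              x$params$threshold_method))
  invisible(x)
}
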
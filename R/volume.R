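#' Scalar image volume with grid metadata
#'
#' `image_volume()` wraps a numeric array of ultrasound intensities together
#' with its per-axis voxel spacing (mm) and physical origin. Arrays are
#' indexed `(y, x)` in 2D and `(z, y, x)` in 3D; readers reorder on-disk axes
#' into this convention at the boundary, so all morphology and filtering code
#' can assume one layout. The physical position of voxel index `i` (0-based)
#' along an axis is `origin + i * spacing`.
#'
#' @param data numeric array (2D or 3D), finite everywhere.
#' @param spacing numeric vector, one strictly positive entry per axis, in mm.
#' @param origin numeric vector, physical coordinates of voxel `(0, ..., 0)`.
#' @return An object of class `us_volume`.
#' @examples
#' v <- image_volume(matrix(0, 4, 4), spacing = c(1, 1))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = rep(1, length(dim(as.array(data)))),
                         origin = rep(0, length(dim(as.array(data))))) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) {
    stop("image_volume: data must be a 2D or 3D array, got ", nd, " dims",
         call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("image_volume: data contains non-finite values", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != nd || any(spacing <= 0)) {
    stop("image_volume: spacing must have one strictly positive entry per axis",
         call. = FALSE)
  }
  if (length(origin) != nd) {
    stop("image_volume: origin must have one entry per axis", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "us_volume"
  )
}

#' Integer label volume
#'
#' Same grid contract as [image_volume()], but voxel values are non-negative
#' integer class ids; class 0 is reserved for background. When paired with an
#' image, shape and spacing must match.
#'
#' @param data integer array of class ids (non-negative).
#' @param spacing,origin as in [image_volume()].
#' @param class_names optional named character vector mapping class id
#'   (as name) to a human-readable structure name.
#' @return An object of class `us_label` (inherits `us_volume`).
#' @export
label_volume <- function(data, spacing = rep(1, length(dim(as.array(data)))),
                         origin = rep(0, length(dim(as.array(data)))),
                         class_names = NULL) {
  data <- as.array(data)
  if (is.double(data)) {
    rounded <- round(data)
    off <- which(abs(data - rounded) > 0)
    if (length(off) > 0) {
      stop("label_volume: non-integer label value ", data[off[1]],
           " at linear index ", off[1], call. = FALSE)
    }
    data <- array(as.integer(rounded), dim = dim(data))
  }
  if (any(data < 0L)) {
    stop("label_volume: labels must be non-negative integers", call. = FALSE)
  }
  v <- image_volume(data, spacing = spacing, origin = origin)
  v$class_names <- class_names
  class(v) <- c("us_label", class(v))
  v
}

#' @export
print.us_volume <- function(x, ...) {
  kind <- if (inherits(x, "us_label")) "label volume" else "image volume"
  cat(sprintf("<%s> %s, spacing %s mm\n", kind,
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 6), collapse = " x ")))
  if (inherits(x, "us_label")) {
    tab <- table(x$data)
    cat("  classes:", paste(names(tab), collapse = ", "), "\n")
  } else {
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(x$data), max(x$data)))
  }
  invisible(x)
}

n_dims <- function(vol) length(dim(vol$data))

#' Class ids present in a label volume
#'
#' @param labels a `us_label`.
#' @param include_background keep class 0 in the result?
#' @return integer vector of class ids, ascending.
#' @export
label_classes <- function(labels, include_background = FALSE) {
  stopifnot(inherits(labels, "us_label"))
  ids <- sort(unique(as.integer(labels$data)))
  if (!include_background) ids <- ids[ids != 0L]
  ids
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6))
}

check_same_shape <- function(a, b, what = "grids") {
  da <- if (is.array(a)) dim(a) else dim(a$data)
  db <- if (is.array(b)) dim(b) else dim(b$data)
  if (!identical(da, db)) {
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
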
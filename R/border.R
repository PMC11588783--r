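#' Extract the border of one class from a label map
#'
#' The inner morphological boundary: voxels of the class with at least one
#' face-adjacent neighbour (4-connectivity in 2D, 6 in 3D) of a different
#' class or outside the grid. Field-of-view truncation therefore counts as
#' border, since it behaves like an interface for evaluation purposes. The
#' result is one voxel thick and lies inside the class.
#'
#' @param labels a [label_volume()].
#' @param class_id integer class id; if absent from `labels`, an empty mask
#'   is returned with a warning.
#' @return Logical array on the label grid.
#' @examples
#' lab <- label_volume(matrix(1L, 5, 5))
#' sum(extract_border(lab, 1))  # the 16 perimeter pixels
#' @export
extract_border <- function(labels, class_id) {
  stopifnot(inherits(labels, "us_label"))
  m <- labels$data == class_id
  if (!any(m)) {
    warning("extract_border: class ", class_id, " absent from label map",
            call. = FALSE)
    return(array(FALSE, dim = dim(labels$data)))
  }
  interior <- m
  for (ax in seq_along(dim(m))) {
    interior <- interior &
      shift_array(m, ax, 1L, fill = FALSE) &
      shift_array(m, ax, -1L, fill = FALSE)
  }
  m & !interior
}

#' Split a border into distinct and completed parts
#'
#' The distinct part is the border supported by edge evidence: the Hadamard
#' (element-wise) product of the border mask with the binary edge map,
#' optionally after dilating the edge mask by a Chebyshev
#' `tolerance_radius`. The completed part is the exact complement within the
#' border, so `distinct` and `completed` always partition `border`.
#'
#' `tolerance_radius = 0` (the default) is the strict Hadamard product. A
#' radius of 1 is useful in practice because the Sobel response of a bright
#' interface ridge peaks on the ridge flanks, one voxel off the annotated
#' border.
#'
#' @param border logical array (a border mask, e.g. from
#'   [extract_border()]).
#' @param edges a `us_edge_map` from [compute_edge_map()], or a logical
#'   array.
#' @param tolerance_radius non-negative integer, voxels.
#' @param class_id optional class id carried into the result.
#' @return An object of class `us_border_split` with logical fields
#'   `border`, `distinct`, `completed`.
#' @export
split_border <- function(border, edges, tolerance_radius = 0L,
                         class_id = NA_integer_) {
  stopifnot(is.logical(border))
  edge_mask <- if (inherits(edges, "us_edge_map")) edges$mask else edges
  stopifnot(is.logical(edge_mask))
  check_same_shape(border, edge_mask, "border and edge map")
  evidence <- dilate_mask(edge_mask, tolerance_radius)
  distinct <- border & evidence
  structure(
    list(class_id = as.integer(class_id),
         border = border,
         distinct = distinct,
         completed = border & !distinct,
         tolerance_radius = as.integer(tolerance_radius)),
    class = "us_border_split"
  )
}

#' Split the borders of every foreground class
#'
#' Applies [extract_border()] and [split_border()] to each nonzero class of
#' a label map independently; an interface shared by two structures belongs
#' to both structures' borders, matching per-structure reporting.
#'
#' @param labels a [label_volume()].
#' @param edges a `us_edge_map` or logical array on the same grid.
#' @param tolerance_radius as in [split_border()].
#' @return A named list of `us_border_split`, one per nonzero class
#'   (names `"class_<id>"`); empty with a warning if the map is all
#'   background.
#' @export
split_all_classes <- function(labels, edges, tolerance_radius = 0L) {
  stopifnot(inherits(labels, "us_label"))
  ids <- label_classes(labels)
  if (length(ids) == 0) {
    warning("split_all_classes: label map contains only background",
            call. = FALSE)
    return(list())
  }
  out <- lapply(ids, function(cid) {
    split_border(extract_border(labels, cid), edges,
                 tolerance_radius = tolerance_radius, class_id = cid)
  })
  names(out) <- paste0("class_", ids)
  out
}

#' @export
print.us_border_split <- function(x, ...) {
  nb <- sum(x$border)
  cat(sprintf(
    "<border split> class %s: %d border voxels, %d distinct (%.1f%%), %d completed, tolerance %d\n",
    x$class_id, nb, sum(x$distinct),
    if (nb > 0) 100 * sum(x$distinct) / nb else NA_real_,
    sum(x$completed), x$tolerance_radius))
  invisible(x)
}

#' One-row summary of a border split
#'
#' @param x a `us_border_split`.
#' @param ... unused.
#' @return A tibble with voxel counts and the distinct/completed fractions.
#' @export
tidy.us_border_split <- function(x, ...) {
  nb <- sum(x$border)
  tibble::tibble(
    class_id = x$class_id,
    n_border = nb,
    n_distinct = sum(x$distinct),
    n_completed = sum(x$completed),
    distinct_pct = if (nb > 0) 100 * sum(x$distinct) / nb else NA_real_,
    completed_pct = if (nb > 0) 100 * sum(x$completed) / nb else NA_real_,
    tolerance_radius = x$tolerance_radius
  )
}
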
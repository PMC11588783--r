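# Standard boundary metrics plus the distinct/completed decomposition of
# true-positive borders. Surface distances go through the exact Euclidean
# distance transform in morphology.R.

mask_surface <- function(mask) {
  interior <- mask
  for (ax in seq_along(dim(mask))) {
    interior <- interior &
      shift_array(mask, ax, 1L, fill = FALSE) &
      shift_array(mask, ax, -1L, fill = FALSE)
  }
  mask & !interior
}

#' Dice overlap coefficient
#'
#' `2|P intersect G| / (|P| + |G|)`; two empty masks agree perfectly and
#' score 1 by convention.
#'
#' @param pred,gt logical arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  stopifnot(is.logical(pred), is.logical(gt))
  check_same_shape(pred, gt, "prediction and ground truth")
  denom <- sum(pred) + sum(gt)
  if (denom == 0) return(1)
  2 * sum(pred & gt) / denom
}

surface_distance_pool <- function(pred, gt, spacing) {
  sp <- mask_surface(pred)
  sg <- mask_surface(gt)
  if (!any(sp) || !any(sg)) {
    stop("surface metrics undefined for an empty mask", call. = FALSE)
  }
  dt_g <- distance_transform(sg, spacing)
  dt_p <- distance_transform(sp, spacing)
  c(dt_g[sp], dt_p[sg])
}

#' 95th-percentile Hausdorff distance
#'
#' The 95th percentile of the pooled symmetric surface-to-surface distance
#' distribution, in mm. Surfaces are the inner boundaries of the masks.
#' Undefined (error) for empty masks; callers record such cases as missing,
#' never as 0.
#'
#' @inheritParams dice
#' @param spacing per-axis voxel size in mm.
#' @return Scalar distance in mm.
#' @export
hd95 <- function(pred, gt, spacing = rep(1, length(dim(pred)))) {
  stopifnot(is.logical(pred), is.logical(gt))
  check_same_shape(pred, gt, "prediction and ground truth")
  d <- surface_distance_pool(pred, gt, spacing)
  unname(stats::quantile(d, 0.95))
}

#' Normalized surface distance
#'
#' Fraction of surface voxels (both directions, pooled) lying within a
#' tolerance `tau` (mm) of the other surface.
#'
#' @inheritParams hd95
#' @param tau tolerance in mm, `> 0`.
#' @return Scalar in `[0, 1]`.
#' @export
nsd <- function(pred, gt, spacing = rep(1, length(dim(pred))), tau) {
  stopifnot(tau > 0)
  d <- surface_distance_pool(pred, gt, spacing)
  mean(d <= tau)
}

#' Distinct/completed fractions of a reference border
#'
#' The share of a border that is edge-supported (distinct) versus
#' annotator-interpolated (completed), as percentages of the total border.
#' The two entries sum to exactly 100.
#'
#' @param split a `us_border_split` with a nonempty border.
#' @return Named numeric vector `c(distinct_pct, completed_pct)`.
#' @export
reference_border_fractions <- function(split) {
  stopifnot(inherits(split, "us_border_split"))
  nb <- sum(split$border)
  if (nb == 0) {
    stop("reference_border_fractions: empty border", call. = FALSE)
  }
  distinct_pct <- 100 * sum(split$distinct) / nb
  c(distinct_pct = distinct_pct, completed_pct = 100 - distinct_pct)
}

#' True-positive decomposition of a predicted border
#'
#' Scores a predicted border against a reference (ground-truth) border that
#' has been split into distinct and completed parts. A reference-border
#' voxel counts as true positive when a predicted-border voxel exists
#' within `match_tolerance` (Chebyshev radius, voxels). All three
#' percentages use the total reference border as denominator, so
#' `tp_distinct_pct + tp_completed_pct == tp_total_pct` exactly.
#'
#' The default tolerance of 1 voxel matches one-voxel-thick border masks:
#' strict overlap (`match_tolerance = 0`) punishes half-voxel shifts that a
#' clinician would not.
#'
#' @param gt_split a `us_border_split` of the reference border (nonempty).
#' @param pred_border logical array, the predicted border mask.
#' @param match_tolerance non-negative integer, voxels.
#' @return A one-row tibble: `class_id`, `reference_distinct_pct`,
#'   `reference_completed_pct`, `tp_total_pct`, `tp_distinct_pct`,
#'   `tp_completed_pct`, `match_tolerance`.
#' @export
tp_decomposition <- function(gt_split, pred_border, match_tolerance = 1L) {
  stopifnot(inherits(gt_split, "us_border_split"), is.logical(pred_border))
  check_same_shape(gt_split$border, pred_border,
                   "reference and predicted borders")
  nb <- sum(gt_split$border)
  if (nb == 0) {
    stop("tp_decomposition: empty reference border", call. = FALSE)
  }
  ref <- reference_border_fractions(gt_split)
  if (!any(pred_border)) {
    warning("tp_decomposition: empty prediction border; all-zero row",
            call. = FALSE)
    covered <- array(FALSE, dim = dim(pred_border))
  } else {
    covered <- gt_split$border & dilate_mask(pred_border,
                                             as.integer(match_tolerance))
  }
  tp_distinct <- 100 * sum(covered & gt_split$distinct) / nb
  tp_completed <- 100 * sum(covered & gt_split$completed) / nb
  tibble::tibble(
    class_id = gt_split$class_id,
    reference_distinct_pct = ref[["distinct_pct"]],
    reference_completed_pct = ref[["completed_pct"]],
    tp_total_pct = tp_distinct + tp_completed,   # additive by construction
    tp_distinct_pct = tp_distinct,
    tp_completed_pct = tp_completed,
    match_tolerance = as.integer(match_tolerance)
  )
}

#' Per-case segmentation metrics for every foreground class
#'
#' Dice, HD95 (mm) and NSD for each nonzero class of a ground-truth label
#' map against a prediction on the same grid. Classes whose mask is empty
#' in either map get `NA` surface metrics (undefined, recorded as missing).
#'
#' @param pred,gt [label_volume()]s on the same grid.
#' @param nsd_tau NSD tolerance in mm; default 1 voxel (mean spacing).
#' @param case_id identifier copied into the rows.
#' @return A tibble with columns `case_id`, `class_id`, `dice`, `hd95_mm`,
#'   `nsd`.
#' @export
case_metrics <- function(pred, gt, nsd_tau = NULL, case_id = NA_character_) {
  stopifnot(inherits(pred, "us_label"), inherits(gt, "us_label"))
  check_same_shape(pred, gt, "prediction and ground truth")
  if (is.null(nsd_tau)) nsd_tau <- mean(gt$spacing)
  ids <- label_classes(gt)
  purrr::map_dfr(ids, function(cid) {
    pm <- pred$data == cid
    gm <- gt$data == cid
    d <- dice(pm, gm)
    if (any(pm) && any(gm)) {
      pool <- surface_distance_pool(pm, gm, gt$spacing)
      h <- unname(stats::quantile(pool, 0.95))
      s <- mean(pool <= nsd_tau)
    } else {
      h <- NA_real_
      s <- NA_real_
    }
    tibble::tibble(case_id = case_id, class_id = cid,
                   dice = d, hd95_mm = h, nsd = s)
  })
}

#' Mean and sample standard deviation per numeric column
#'
#' Aggregates per-case metric rows the way results tables report them:
#' arithmetic mean and sample (n-1) standard deviation of every numeric
#' column, optionally within groups. A single row yields sd 0.
#'
#' @param rows a tibble of per-case rows (e.g. from [case_metrics()] or
#'   [tp_decomposition()]).
#' @param by optional character vector of grouping columns (e.g.
#'   `"class_id"`).
#' @return A long tibble with columns `<by...>`, `metric`, `mean`, `sd`,
#'   `n`.
#' @export
aggregate_metrics <- function(rows, by = NULL) {
  stopifnot(is.data.frame(rows))
  num_cols <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))], by)
  long <- tidyr::pivot_longer(
    dplyr::select(rows, dplyr::all_of(c(by, num_cols))),
    cols = dplyr::all_of(num_cols),
    names_to = "metric", values_to = "value"
  )
  grouped <- dplyr::group_by(long,
                             dplyr::across(dplyr::all_of(c(by, "metric"))))
  dplyr::ungroup(dplyr::summarise(
    grouped,
    mean = mean(.data$value, na.rm = TRUE),
    sd = if (sum(!is.na(.data$value)) < 2) 0
         else stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  ))
}

#' Inverse-frequency class weights
#'
#' Cross-entropy class weights computed as the inverse of each class's
#' pixel frequency in the pooled training labels, normalized to sum to 1 —
#' the standard recipe against foreground/background imbalance.
#'
#' @param labels a [label_volume()] or list of them (the training set).
#' @param n_classes total number of classes including background.
#' @return A tibble with `class_id`, `frequency`, `weight`
#'   (`sum(weight) == 1`).
#' @export
compute_class_weights <- function(labels, n_classes) {
  if (inherits(labels, "us_label")) labels <- list(labels)
  counts <- rep(0, n_classes)
  for (lab in labels) {
    stopifnot(inherits(lab, "us_label"))
    tab <- tabulate(as.integer(lab$data) + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  if (any(counts == 0)) {
    missing_ids <- which(counts == 0) - 1L
    stop("compute_class_weights: class(es) absent from training labels: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  freq <- counts / sum(counts)
  inv <- 1 / freq
  tibble::tibble(
    class_id = seq_len(n_classes) - 1L,
    frequency = freq,
    weight = inv / sum(inv)
  )
}
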
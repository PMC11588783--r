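#' Pixel-set target for Seg-Grad-CAM
#'
#' A CAM target is a class id plus a nonempty boolean set of output pixels
#' (a distinct border, a completed border, the background, or a whole class
#' mask). The scalar the gradients are taken of is the sum of that class's
#' pre-softmax scores over the set.
#'
#' @param class_id integer class id (0-based, 0 = background).
#' @param pixel_set logical array on the model's output grid, nonempty.
#' @return An object of class `us_cam_target`.
#' @export
cam_target <- function(class_id, pixel_set) {
  stopifnot(is.logical(pixel_set))
  if (!any(pixel_set)) {
    stop("cam_target: pixel_set is empty", call. = FALSE)
  }
  structure(list(class_id = as.integer(class_id), pixel_set = pixel_set),
            class = "us_cam_target")
}

#' Scalar class score of a pixel set
#'
#' Sum of the pre-softmax class-`c` scores over the target's pixel set —
#' the quantity whose gradients drive Seg-Grad-CAM (summing the per-pixel
#' scores is equivalent to summing the per-pixel gradients inside the
#' pooled-gradient weights, by linearity of differentiation).
#'
#' @param scores array `(class, y, x)` of pre-softmax score maps.
#' @param target a [cam_target()].
#' @return Scalar.
#' @export
scalar_target <- function(scores, target) {
  stopifnot(inherits(target, "us_cam_target"))
  sdim <- dim(scores)[-1]
  check_same_shape(array(0, sdim), target$pixel_set,
                   "score grid and target pixel set")
  cls_map <- scores[target$class_id + 1L, , ]
  sum(cls_map[target$pixel_set])
}

target_dscores <- function(scores_dim, target) {
  ds <- array(0, scores_dim)
  m <- array(0, scores_dim[-1])
  m[target$pixel_set] <- 1
  ds[target$class_id + 1L, , ] <- m
  ds
}

#' Seg-Grad-CAM localization map for a pixel-set target
#'
#' Computes the gradient of the summed class score over the target pixel
#' set with respect to the activations `A^f` of a named layer, pools each
#' gradient map to a scalar weight by global average pooling (spatial mean),
#' and combines `ReLU(sum_f weight_f * A^f)`. The map lives at the feature
#' layer's resolution; `upsampled` is its bilinear interpolation to the
#' input grid. Weights, activations and the raw pre-ReLU map are stored so
#' the result is exactly reconstructable.
#'
#' @param model a `us_model` (see [toy_model_fixture()]) or any object
#'   honoring the same forward/backward contract.
#' @param image an [image_volume()] or 2D matrix.
#' @param target a [cam_target()].
#' @param layer name of the layer to explain; defaults to the model's last
#'   convolutional layer before the classification head.
#' @return An object of class `us_cam` with fields `map` (non-negative),
#'   `upsampled`, `weights`, `activations`, `layer`, `target`, `value`
#'   (the scalar target).
#' @export
compute_cam <- function(model, image, target,
                        layer = model$default_layer) {
  stopifnot(inherits(model, "us_model"), inherits(target, "us_cam_target"))
  check_layer(model, layer)
  fwd <- model_forward(model, image)
  sdim <- dim(fwd$scores)
  check_same_shape(array(0, sdim[-1]), target$pixel_set,
                   "model output grid and target pixel set")
  ds <- target_dscores(sdim, target)
  bk <- model_backward(model, fwd, ds)
  dA <- bk$d_acts[[layer]]
  A <- fwd$acts[[layer]]
  weights <- apply(dA, 1L, mean)
  pre <- array(0, dim = dim(A)[-1])
  for (f in seq_along(weights)) pre <- pre + weights[f] * A[f, , ]
  map <- pmax(pre, 0)
  img_dim <- sdim[-1]
  structure(
    list(map = map, pre_map = pre,
         upsampled = bilinear_resize(map, img_dim),
         weights = weights, activations = A, layer = layer,
         target = target,
         value = scalar_target(fwd$scores, target),
         image = if (inherits(image, "us_volume")) image$data
                 else as.array(image)),
    class = "us_cam"
  )
}

#' @export
print.us_cam <- function(x, ...) {
  cat(sprintf(
    "<Seg-Grad-CAM> layer %s, class %d, |pixel set| = %d, map %s, max %.4g\n",
    x$layer, x$target$class_id, sum(x$target$pixel_set),
    paste(dim(x$map), collapse = " x "), max(x$map)))
  invisible(x)
}

#' CAM pair for the distinct and completed parts of a border
#'
#' Runs [compute_cam()] twice on the two parts of a [split_border()]
#' result. An empty part yields a missing (`NULL`) map with a warning, not
#' an error, so degenerate splits do not abort batch runs.
#'
#' @param model,image,layer as in [compute_cam()].
#' @param split a `us_border_split`.
#' @return `list(distinct = , completed = )` of `us_cam` or `NULL`.
#' @export
cam_for_split <- function(model, image, split,
                          layer = model$default_layer) {
  stopifnot(inherits(split, "us_border_split"))
  one <- function(mask, what) {
    if (!any(mask)) {
      warning("cam_for_split: ", what, " border empty; map missing",
              call. = FALSE)
      return(NULL)
    }
    compute_cam(model, image, cam_target(split$class_id, mask), layer)
  }
  list(distinct = one(split$distinct, "distinct"),
       completed = one(split$completed, "completed"))
}

#' CAM robustness under an input perturbation
#'
#' Recomputes the CAM after perturbing the input image and compares it with
#' the baseline: cosine similarity of the (unnormalized) maps, plus the
#' mean CAM value inside the perturbed region before and after. Display
#' normalization never enters these numbers.
#'
#' @param model,image,target,layer as in [compute_cam()].
#' @param perturbation `"zero_patch"` (zero a rectangle), `"gaussian_noise"`
#'   (additive noise) or `"contrast_scale"` (multiply intensities).
#' @param params list: `patch = c(y0, y1, x0, x1)` (1-based, inclusive,
#'   inside the grid) for `zero_patch`; `sd >= 0` for `gaussian_noise`;
#'   `factor > 0` for `contrast_scale`.
#' @param seed seed for the noise draw.
#' @return A one-row tibble: `perturbation`, `similarity`,
#'   `mean_region_baseline`, `mean_region_perturbed`.
#' @export
perturb_and_compare <- function(model, image, target,
                                layer = model$default_layer,
                                perturbation = c("zero_patch",
                                                 "gaussian_noise",
                                                 "contrast_scale"),
                                params = list(), seed = 1L) {
  perturbation <- match.arg(perturbation)
  img <- if (inherits(image, "us_volume")) image else image_volume(image)
  d <- dim(img$data)
  region <- array(TRUE, d)
  pert <- img$data
  if (perturbation == "zero_patch") {
    p <- params$patch
    if (is.null(p) || length(p) != 4 ||
        p[1] < 1 || p[2] > d[1] || p[3] < 1 || p[4] > d[2] ||
        p[1] > p[2] || p[3] > p[4]) {
      stop("perturb_and_compare: patch must be c(y0, y1, x0, x1) inside ",
           "the grid", call. = FALSE)
    }
    pert[p[1]:p[2], p[3]:p[4]] <- 0
    region[] <- FALSE
    region[p[1]:p[2], p[3]:p[4]] <- TRUE
  } else if (perturbation == "gaussian_noise") {
    sd <- params$sd %||% 0
    if (sd < 0) stop("perturb_and_compare: noise sd must be >= 0",
                     call. = FALSE)
    if (sd > 0) {
      pert <- pert + with_seed(seed, array(stats::rnorm(length(pert),
                                                        sd = sd), d))
    }
  } else {
    fac <- params$factor %||% 1
    if (fac <= 0) stop("perturb_and_compare: contrast factor must be > 0",
                       call. = FALSE)
    pert <- pert * fac
  }
  base_cam <- compute_cam(model, img, target, layer)
  pert_cam <- compute_cam(model,
                          image_volume(pert, img$spacing, img$origin),
                          target, layer)
  a <- as.vector(base_cam$map); b <- as.vector(pert_cam$map)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  sim <- if (na == 0 && nb == 0) 1 else if (na == 0 || nb == 0) 0 else
    sum(a * b) / (na * nb)
  tibble::tibble(
    perturbation = perturbation,
    similarity = sim,
    mean_region_baseline = mean(base_cam$upsampled[region]),
    mean_region_perturbed = mean(pert_cam$upsampled[region])
  )
}

# Bilinear interpolation of a 2D map to a target grid (pixel-center
# alignment, clamped at the edges). Identity when shapes already match.
bilinear_resize <- function(m, out_dim) {
  d <- dim(m)
  if (identical(as.integer(d), as.integer(out_dim))) return(m)
  sy <- d[1] / out_dim[1]; sx <- d[2] / out_dim[2]
  yc <- (seq_len(out_dim[1]) - 0.5) * sy + 0.5
  xc <- (seq_len(out_dim[2]) - 0.5) * sx + 0.5
  y0 <- pmin(pmax(floor(yc), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xc), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  wy <- pmin(pmax(yc - y0, 0), 1); wx <- pmin(pmax(xc - x0, 0), 1)
  m00 <- m[y0, x0, drop = FALSE]; m10 <- m[y1, x0, drop = FALSE]
  m01 <- m[y0, x1, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  WY <- matrix(wy, out_dim[1], out_dim[2])
  WX <- matrix(wx, out_dim[1], out_dim[2], byrow = TRUE)
  (1 - WY) * (1 - WX) * m00 + WY * (1 - WX) * m10 +
    (1 - WY) * WX * m01 + WY * WX * m11
}
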
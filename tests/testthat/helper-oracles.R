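# Independent brute-force oracles. These deliberately avoid the package's
# own distance transforms, histogram Otsu and analytic backprop: surfaces
# by explicit neighbour enumeration, distances by all-pairs computation,
# thresholds by exhaustive search, gradients by central finite differences.

bf_surface <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  out <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    on_surf <- FALSE
    for (ax in seq_len(nd)) for (s in c(-1L, 1L)) {
      nb <- v
      nb[ax] <- nb[ax] + s
      if (nb[ax] < 1L || nb[ax] > d[ax]) { on_surf <- TRUE; next }
      if (!mask[matrix(nb, 1L)]) on_surf <- TRUE
    }
    if (on_surf) out[matrix(v, 1L)] <- TRUE
  }
  out
}

bf_surface_pool <- function(pred, gt, spacing) {
  sp <- which(bf_surface(pred), arr.ind = TRUE)
  sg <- which(bf_surface(gt), arr.ind = TRUE)
  ps <- sweep(sp, 2L, spacing, `*`)
  gs <- sweep(sg, 2L, spacing, `*`)
  d2 <- outer(rowSums(ps^2), rowSums(gs^2), `+`) - 2 * ps %*% t(gs)
  d <- sqrt(pmax(d2, 0))
  c(apply(d, 1L, min), apply(d, 2L, min))
}

bf_hd95 <- function(pred, gt, spacing = rep(1, length(dim(pred)))) {
  unname(stats::quantile(bf_surface_pool(pred, gt, spacing), 0.95))
}

bf_nsd <- function(pred, gt, spacing, tau) {
  mean(bf_surface_pool(pred, gt, spacing) <= tau)
}

bf_dice <- function(pred, gt) {
  if (sum(pred) + sum(gt) == 0) return(1)
  2 * sum(pred & gt) / (sum(pred) + sum(gt))
}

# Exhaustive Otsu: every midpoint between adjacent sorted unique values,
# between-class variance computed from the raw split.
bf_otsu <- function(values) {
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; best_t <- NA_real_
  for (t in cand) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

# Finite-difference Seg-Grad-CAM: perturb every activation entry of the
# layer, re-evaluate the scalar target through the model, pool, combine,
# ReLU.
fd_cam <- function(model, image, target, layer, eps = 1e-3) {
  fwd <- model_forward(model, image)
  A <- fwd$acts[[layer]]
  dA <- array(0, dim(A))
  for (i in seq_along(A)) {
    Ap <- A; Ap[i] <- Ap[i] + eps
    Am <- A; Am[i] <- Am[i] - eps
    sp <- scalar_target(model_forward(
      model, image, override = list(layer = layer, value = Ap))$scores,
      target)
    sm <- scalar_target(model_forward(
      model, image, override = list(layer = layer, value = Am))$scores,
      target)
    dA[i] <- (sp - sm) / (2 * eps)
  }
  w <- apply(dA, 1L, mean)
  pre <- array(0, dim(A)[-1])
  for (f in seq_along(w)) pre <- pre + w[f] * A[f, , ]
  pmax(pre, 0)
}

# Random blobby label map for property tests: thresholded smooth noise.
random_labels <- function(shape, n_classes = 3L, seed = 1L) {
  set.seed(seed)
  base <- array(stats::rnorm(prod(shape)), dim = shape)
  sm <- smooth_volume(image_volume(base), 2)$data
  q <- stats::quantile(sm, seq(0.4, 0.95, length.out = n_classes))
  lab <- array(0L, shape)
  for (k in seq_len(n_classes)) lab[sm >= q[k]] <- k
  label_volume(lab)
}

random_mask <- function(shape, p = 0.5, seed = 1L, blur = 1.5) {
  set.seed(seed)
  base <- array(stats::rnorm(prod(shape)), dim = shape)
  sm <- smooth_volume(image_volume(base), blur)$data
  sm >= stats::quantile(sm, p)
}
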
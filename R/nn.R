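# Minimal 2D convnet primitives (im2col convolution, 2x2 max pooling,
# nearest-neighbour upsampling) with explicit backward passes. Enough to
# build the toy segmentation fixtures whose activations and gradients the
# Seg-Grad-CAM module consumes; publication-scale architectures are out of
# scope.

conv2d_forward <- function(X, W, b) {
  co <- dim(W)[1]; ci <- dim(W)[2]; kh <- dim(W)[3]; kw <- dim(W)[4]
  H <- dim(X)[2]; Wd <- dim(X)[3]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Xp <- array(0, c(ci, H + 2L * ph, Wd + 2L * pw))
  Xp[, ph + seq_len(H), pw + seq_len(Wd)] <- X
  M <- matrix(0, H * Wd, ci * kh * kw)
  col <- 0L
  for (dx in seq_len(kw)) for (dy in seq_len(kh)) for (cc in seq_len(ci)) {
    col <- col + 1L
    M[, col] <- Xp[cc, dy:(dy + H - 1L), dx:(dx + Wd - 1L)]
  }
  Wmat <- matrix(W, nrow = co)           # columns ordered (ci, kh, kw)
  out <- M %*% t(Wmat)
  out <- sweep(out, 2L, b, `+`)
  list(out = array(t(out), c(co, H, Wd)), M = M, dims = c(H, Wd))
}

conv2d_backward <- function(cache, W, dOut) {
  co <- dim(W)[1]; ci <- dim(W)[2]; kh <- dim(W)[3]; kw <- dim(W)[4]
  H <- cache$dims[1]; Wd <- cache$dims[2]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  dOut_mat <- t(matrix(dOut, nrow = co))           # (H*W) x co
  dW <- array(t(dOut_mat) %*% cache$M, dim = dim(W))
  db <- colSums(dOut_mat)
  Wmat <- matrix(W, nrow = co)
  dM <- dOut_mat %*% Wmat                          # (H*W) x (ci*kh*kw)
  dXp <- array(0, c(ci, H + 2L * ph, Wd + 2L * pw))
  col <- 0L
  for (dx in seq_len(kw)) for (dy in seq_len(kh)) for (cc in seq_len(ci)) {
    col <- col + 1L
    dXp[cc, dy:(dy + H - 1L), dx:(dx + Wd - 1L)] <-
      dXp[cc, dy:(dy + H - 1L), dx:(dx + Wd - 1L)] +
      matrix(dM[, col], H, Wd)
  }
  list(dX = dXp[, ph + seq_len(H), pw + seq_len(Wd), drop = FALSE],
       dW = dW, db = db)
}

maxpool2_forward <- function(X) {
  d <- dim(X)
  s1 <- seq(1L, d[2], 2L); s2 <- seq(1L, d[3], 2L)
  cand <- list(X[, s1, s2, drop = FALSE], X[, s1 + 1L, s2, drop = FALSE],
               X[, s1, s2 + 1L, drop = FALSE],
               X[, s1 + 1L, s2 + 1L, drop = FALSE])
  out <- pmax(cand[[1]], cand[[2]], cand[[3]], cand[[4]])
  sel <- array(1L, dim = dim(out))
  sel[cand[[2]] > cand[[1]] & cand[[2]] >= pmax(cand[[3]], cand[[4]])] <- 2L
  sel[cand[[3]] > pmax(cand[[1]], cand[[2]]) & cand[[3]] >= cand[[4]]] <- 3L
  sel[cand[[4]] > pmax(cand[[1]], cand[[2]], cand[[3]])] <- 4L
  list(out = out, sel = sel, in_dim = d)
}

maxpool2_backward <- function(cache, dOut) {
  d <- cache$in_dim
  s1 <- seq(1L, d[2], 2L); s2 <- seq(1L, d[3], 2L)
  dX <- array(0, d)
  for (k in 1:4) {
    m <- dOut * (cache$sel == k)
    r <- s1 + (k == 2L | k == 4L)
    cc <- s2 + (k == 3L | k == 4L)
    dX[, r, cc] <- dX[, r, cc] + m
  }
  dX
}

upsample2_forward <- function(X) {
  d <- dim(X)
  X[, ceiling(seq_len(2L * d[2]) / 2), ceiling(seq_len(2L * d[3]) / 2),
    drop = FALSE]
}

upsample2_backward <- function(dOut) {
  d <- dim(dOut)
  s1 <- seq(1L, d[2], 2L); s2 <- seq(1L, d[3], 2L)
  dOut[, s1, s2, drop = FALSE] + dOut[, s1 + 1L, s2, drop = FALSE] +
    dOut[, s1, s2 + 1L, drop = FALSE] + dOut[, s1 + 1L, s2 + 1L, drop = FALSE]
}

relu <- function(x) pmax(x, 0)

# Adam with a step decay schedule on the learning rate.
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Pixel-wise weighted softmax cross-entropy; returns loss and d(loss)/d(scores).
weighted_ce <- function(scores, target, class_weights) {
  C <- dim(scores)[1]
  sm <- matrix(scores, nrow = C)                 # C x pixels
  sm <- sweep(sm, 2L, apply(sm, 2L, max), `-`)
  ex <- exp(sm)
  p <- sweep(ex, 2L, colSums(ex), `/`)
  ty <- as.integer(target) + 1L                  # class ids 0..C-1
  n <- length(ty)
  wpix <- class_weights[ty]
  logp <- log(pmax(p[cbind(ty, seq_len(n))], 1e-12))
  loss <- -sum(wpix * logp) / n
  one_hot <- matrix(0, C, n)
  one_hot[cbind(ty, seq_len(n))] <- 1
  dsm <- sweep(p - one_hot, 2L, wpix, `*`) / n
  list(loss = loss, dscores = array(dsm, dim = dim(scores)))
}
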
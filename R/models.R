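#' Toy segmentation models implementing the adapter contract
#'
#' The Seg-Grad-CAM module talks to any model through a small adapter
#' contract: per-pixel pre-softmax class scores for an image, plus the
#' activations and gradients of a named internal layer. Two fixtures ship
#' with the package:
#'
#' * `fixed_linear` — hand-set weights, features are per-feature affine
#'   transforms of the input and the head is a 1x1 linear map. Fully
#'   deterministic with closed-form gradients; the reference fixture for
#'   CAM oracle tests.
#' * `small_unet` — a miniature two-level encoder-decoder (3x3 convs, 2x2
#'   max-pool, nearest-neighbour upsampling, skip concatenation) trainable
#'   on 2D phantoms in minutes on one CPU. Training uses inverse-frequency
#'   weighted cross-entropy, Adam (lr 1e-3) with a step decay (factor 0.5
#'   every 10 epochs), batch size 2, vertical-axis flip augmentation and
#'   min-max intensity normalization.
#'
#' @param kind `"fixed_linear"` or `"small_unet"`.
#' @param seed integer seed controlling initialization, training data and
#'   augmentation; identical seeds give identical trained weights.
#' @param n_train number of phantom training slices (small_unet).
#' @param steps number of optimizer steps (small_unet).
#' @param grid 2D grid of the training phantoms.
#' @param phantom a [phantom_spec()] used to draw training cases; defaults
#'   to `phantom_spec(shape = grid)`.
#' @return An object of class `us_model`.
#' @export
toy_model_fixture <- function(kind = c("fixed_linear", "small_unet"),
                              seed = 0L, n_train = 32L, steps = 200L,
                              grid = c(64L, 64L), phantom = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed_linear") {
    return(fixed_linear_model())
  }
  small_unet_fixture(seed = seed, n_train = n_train, steps = steps,
                     grid = grid, phantom = phantom)
}

fixed_linear_model <- function() {
  # hand-set, deliberately asymmetric weights
  a <- c(1, -1, 0.5, 2)
  b <- c(0, 0.2, -0.1, 0)
  V <- matrix(c( 0.5, -0.3,  1.0, -0.2,
                -0.4,  0.8, -0.1,  0.3,
                 0.2,  0.1, -0.6,  0.9,
                -0.7,  0.4,  0.3, -0.5), nrow = 4, byrow = TRUE)
  c0 <- c(0.1, -0.1, 0.05, 0)
  structure(
    list(arch = "fixed_linear", n_classes = 4L,
         layers = "features", default_layer = "features",
         normalize = FALSE,
         params = list(a = a, b = b, V = V, c0 = c0),
         meta = list(trained = FALSE)),
    class = "us_model"
  )
}

#' @export
print.us_model <- function(x, ...) {
  cat(sprintf("<us_model> %s: %d classes, layers: %s\n", x$arch,
              x$n_classes, paste(x$layers, collapse = ", ")))
  if (isTRUE(x$meta$trained)) {
    cat(sprintf("  trained %d steps, final loss %.4f\n",
                x$meta$steps, utils::tail(x$meta$loss, 1)))
  }
  invisible(x)
}

model_input <- function(model, image) {
  x <- if (inherits(image, "us_volume")) image$data else as.array(image)
  if (length(dim(x)) != 2L) {
    stop("toy models operate on 2D images", call. = FALSE)
  }
  if (isTRUE(model$normalize)) {
    rng <- range(x)
    if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  }
  if (identical(model$in_channels %||% 1L, 2L)) {
    # depth coordinate channel: attenuation ties appearance to depth, so
    # the net is given the (normalized) depth explicitly
    depth <- matrix(seq_len(nrow(x)) / nrow(x), nrow(x), ncol(x))
    out <- array(0, c(2L, dim(x)))
    out[1L, , ] <- x
    out[2L, , ] <- depth
    return(out)
  }
  array(x, c(1L, dim(x)))
}

#' Forward pass of a toy model
#'
#' Runs the model on an image and returns the pre-softmax class score maps
#' together with the post-activation feature maps of every named layer.
#' `override` substitutes the given array for a layer's activations before
#' the downstream computation, which is what the finite-difference CAM
#' oracle and activation-perturbation checks need.
#'
#' @param model a `us_model`.
#' @param image an [image_volume()] or 2D matrix.
#' @param override optional `list(layer = , value = )`.
#' @return `list(scores, acts, cache)`; `scores` is `(class, y, x)`.
#' @export
model_forward <- function(model, image, override = NULL) {
  x <- model_input(model, image)
  if (model$arch == "fixed_linear") {
    p <- model$params
    K <- length(p$a)
    H <- dim(x)[2]; W <- dim(x)[3]
    A <- array(0, c(K, H, W))
    for (f in seq_len(K)) A[f, , ] <- p$a[f] * x[1, , ] + p$b[f]
    if (!is.null(override) && override$layer == "features") {
      A <- override$value
    }
    C <- model$n_classes
    scores <- array(0, c(C, H, W))
    for (cc in seq_len(C)) {
      s <- matrix(p$c0[cc], H, W)
      for (f in seq_len(K)) s <- s + p$V[cc, f] * A[f, , ]
      scores[cc, , ] <- s
    }
    return(list(scores = scores, acts = list(features = A),
                cache = list(x = x, A = A)))
  }
  unet_forward(model, x, override)
}

unet_forward <- function(model, x, override = NULL) {
  p <- model$params
  ov <- function(name, val) {
    if (!is.null(override) && override$layer == name) override$value else val
  }
  c1 <- conv2d_forward(x, p$W1, p$b1)
  a1 <- ov("enc1", relu(c1$out))
  pl <- maxpool2_forward(a1)
  c2 <- conv2d_forward(pl$out, p$W2, p$b2)
  a2 <- ov("enc2", relu(c2$out))
  u <- upsample2_forward(a2)
  f1 <- dim(a1)[1]; f2 <- dim(a2)[1]
  cat_in <- array(0, c(f2 + f1, dim(a1)[2], dim(a1)[3]))
  cat_in[seq_len(f2), , ] <- u
  cat_in[f2 + seq_len(f1), , ] <- a1
  c3 <- conv2d_forward(cat_in, p$W3, p$b3)
  a3 <- ov("dec1", relu(c3$out))
  c4 <- conv2d_forward(a3, p$W4, p$b4)
  list(scores = c4$out,
       acts = list(enc1 = a1, enc2 = a2, dec1 = a3),
       cache = list(x = x, c1 = c1, a1 = a1, pl = pl, c2 = c2, a2 = a2,
                    cat_in = cat_in, c3 = c3, a3 = a3, c4 = c4,
                    f1 = f1, f2 = f2))
}

# Backward pass: gradients of sum(dscores * scores) w.r.t. each layer's
# post-activation feature maps and (optionally) all parameters.
model_backward <- function(model, fwd, dscores, want_params = FALSE) {
  if (model$arch == "fixed_linear") {
    p <- model$params
    K <- length(p$a)
    dA <- array(0, dim = dim(fwd$acts$features))
    for (f in seq_len(K)) {
      s <- 0
      for (cc in seq_len(model$n_classes)) {
        s <- s + p$V[cc, f] * dscores[cc, , ]
      }
      dA[f, , ] <- s
    }
    return(list(d_acts = list(features = dA), d_params = NULL))
  }
  p <- model$params
  cache <- fwd$cache
  b4 <- conv2d_backward(cache$c4, p$W4, dscores)
  d_a3 <- b4$dX
  dz3 <- d_a3 * (cache$c3$out > 0)
  b3 <- conv2d_backward(cache$c3, p$W3, dz3)
  d_cat <- b3$dX
  du <- d_cat[seq_len(cache$f2), , , drop = FALSE]
  d_a1_skip <- d_cat[cache$f2 + seq_len(cache$f1), , , drop = FALSE]
  d_a2 <- upsample2_backward(du)
  dz2 <- d_a2 * (cache$c2$out > 0)
  b2 <- conv2d_backward(cache$c2, p$W2, dz2)
  d_a1 <- d_a1_skip + maxpool2_backward(cache$pl, b2$dX)
  d_params <- NULL
  if (want_params) {
    dz1 <- d_a1 * (cache$c1$out > 0)
    b1 <- conv2d_backward(cache$c1, p$W1, dz1)
    d_params <- list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
                     W3 = b3$dW, b3 = b3$db, W4 = b4$dW, b4 = b4$db)
  }
  list(d_acts = list(enc1 = d_a1, enc2 = d_a2, dec1 = d_a3),
       d_params = d_params)
}

check_layer <- function(model, layer) {
  if (!layer %in% model$layers) {
    stop("unknown layer '", layer, "'; available layers: ",
         paste(model$layers, collapse = ", "), call. = FALSE)
  }
  invisible(layer)
}

#' Predicted label map of a toy model
#'
#' @param object a `us_model`.
#' @param image an [image_volume()] or 2D matrix.
#' @param ... unused.
#' @return A [label_volume()] of per-pixel argmax classes.
#' @export
predict.us_model <- function(object, image, ...) {
  fwd <- model_forward(object, image)
  C <- dim(fwd$scores)[1]
  sm <- matrix(fwd$scores, nrow = C)
  lab <- array(max.col(t(sm), ties.method = "first") - 1L,
               dim = dim(fwd$scores)[-1])
  sp <- if (inherits(image, "us_volume")) image$spacing else c(1, 1)
  org <- if (inherits(image, "us_volume")) image$origin else c(0, 0)
  label_volume(lab, spacing = sp, origin = org)
}

# ---- small_unet construction and training ----------------------------------

unet_init_params <- function(n_classes, f1 = 8L, f2 = 16L,
                             in_channels = 2L) {
  he <- function(co, ci, kh, kw) {
    array(stats::rnorm(co * ci * kh * kw, sd = sqrt(2 / (ci * kh * kw))),
          c(co, ci, kh, kw))
  }
  list(W1 = he(f1, in_channels, 3L, 3L), b1 = rep(0, f1),
       W2 = he(f2, f1, 3L, 3L), b2 = rep(0, f2),
       W3 = he(f1, f2 + f1, 3L, 3L), b3 = rep(0, f1),
       W4 = he(n_classes, f1, 1L, 1L), b4 = rep(0, n_classes))
}

small_unet_fixture <- function(seed = 0L, n_train = 32L, steps = 200L,
                               grid = c(64L, 64L), phantom = NULL) {
  if (is.null(phantom)) phantom <- phantom_spec(shape = grid)
  cases <- lapply(seq_len(n_train), function(i) {
    generate_phantom(phantom_update(phantom, seed = seed * 10000L + i))
  })
  labels <- lapply(cases, function(cs) cs$labels)
  n_classes <- phantom$n_classes
  cw <- compute_class_weights(labels, n_classes)$weight
  model <- structure(
    list(arch = "small_unet", n_classes = as.integer(n_classes),
         layers = c("enc1", "enc2", "dec1"), default_layer = "dec1",
         normalize = TRUE, in_channels = 2L,
         params = NULL,
         meta = list(trained = FALSE)),
    class = "us_model"
  )
  with_seed(seed, {
    model$params <- unet_init_params(n_classes)
    model <- unet_train(model, cases, cw, steps = steps,
                        batch_size = 2L, lr = 1e-3,
                        decay_epochs = 10L, decay_factor = 0.5)
  })
  model$meta$seed <- seed
  model$meta$class_weights <- cw
  model
}

unet_train <- function(model, cases, class_weights, steps, batch_size = 2L,
                       lr = 1e-3, decay_epochs = 10L, decay_factor = 0.5) {
  n <- length(cases)
  steps_per_epoch <- ceiling(n / batch_size)
  state <- adam_init(model$params)
  losses <- numeric(steps)
  order_pool <- sample.int(n)
  pos <- 1L
  for (st in seq_len(steps)) {
    epoch <- (st - 1L) %/% steps_per_epoch
    lr_t <- lr * decay_factor^(epoch %/% decay_epochs)
    grads <- NULL
    loss_acc <- 0
    for (bi in seq_len(batch_size)) {
      if (pos > n) { order_pool <- sample.int(n); pos <- 1L }
      cs <- cases[[order_pool[pos]]]; pos <- pos + 1L
      img <- cs$image$data
      lab <- cs$labels$data
      if (stats::runif(1) < 0.5) {            # flip across the vertical axis
        img <- img[, rev(seq_len(ncol(img)))]
        lab <- lab[, rev(seq_len(ncol(lab)))]
      }
      fwd <- model_forward(model, img)
      ce <- weighted_ce(fwd$scores, lab, class_weights)
      loss_acc <- loss_acc + ce$loss
      bk <- model_backward(model, fwd, ce$dscores, want_params = TRUE)
      if (is.null(grads)) {
        grads <- bk$d_params
      } else {
        for (i in seq_along(grads)) grads[[i]] <- grads[[i]] + bk$d_params[[i]]
      }
    }
    for (i in seq_along(grads)) grads[[i]] <- grads[[i]] / batch_size
    upd <- adam_step(model$params, grads, state, lr_t)
    model$params <- upd$params
    state <- upd$state
    losses[st] <- loss_acc / batch_size
  }
  model$meta$trained <- TRUE
  model$meta$steps <- steps
  model$meta$loss <- losses
  model
}

#' @export
glance.us_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  tibble::tibble(
    arch = x$arch,
    n_classes = x$n_classes,
    n_parameters = n_par,
    default_layer = x$default_layer,
    trained = isTRUE(x$meta$trained),
    steps = x$meta$steps %||% NA_integer_,
    final_loss = if (isTRUE(x$meta$trained)) utils::tail(x$meta$loss, 1)
                 else NA_real_
  )
}

#' @export
tidy.us_model <- function(x, ...) {
  purrr::map_dfr(names(x$params), function(nm) {
    p <- x$params[[nm]]
    tibble::tibble(parameter = nm, n = length(p),
                   mean = mean(p), sd = stats::sd(as.vector(p)),
                   min = min(p), max = max(p))
  })
}
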
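# Classifier training. The architecture mirrors the transfer-learning recipe:
# a pluggable feature-extracting backbone, a replaced classification head
# (linear -> tanh -> softmax, so pre-softmax activations live in [-1, 1]),
# label-smoothing cross-entropy, a one-epoch warm-up with the backbone frozen,
# Adam, and stochastic augmentations applied with a fixed per-augmentation
# probability. The built-in "tiny_cnn" backbone is a one-layer patch
# convolution (stride = kernel, shared weights, tanh, global average pooling)
# small enough to train on a CPU in seconds; the 100M-parameter pretrained
# transformer of the original deployment plugs into the same slot via
# `backbone = "external"`.

#' Training configuration
#'
#' Defaults follow the tuned recipe of the original pipeline: batch size 64,
#' 5 epochs (plus a one-epoch frozen-backbone warm-up), learning rate 0.003,
#' augmentation probability 0.8, 224 x 224 inputs.
#'
#' @param batch_size minibatch size.
#' @param epochs full-training epochs after the warm-up.
#' @param learning_rate Adam step size.
#' @param warmup_epochs epochs with the backbone frozen (default 1).
#' @param label_smoothing_eps label-smoothing mass (default 0.1).
#' @param augment_prob per-augmentation application probability (default 0.8).
#' @param image_size classifier input side in pixels (default 224; tests use
#'   smaller inputs to keep CPU runtimes in seconds).
#' @param seed integer seed driving shuffling, init and augmentation.
#' @param backbone_name `"tiny_cnn"` or `"external"`.
#' @param n_filters,patch,backbone_input tiny_cnn geometry: number of shared
#'   filters, patch side, and the internal square resolution the grayscale
#'   input is resized to before patching.
#' @param early_stop_patience if positive, stop when validation loss fails to
#'   improve for this many epochs (plateau rule); 0 disables (default).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, epochs = 5L, learning_rate = 0.003,
                         warmup_epochs = 1L, label_smoothing_eps = 0.1,
                         augment_prob = 0.8, image_size = 224L, seed = 1L,
                         backbone_name = c("tiny_cnn", "external"),
                         n_filters = 16L, patch = 4L, backbone_input = 32L,
                         early_stop_patience = 0L) {
  stopifnot(batch_size >= 1L, epochs >= 0L, learning_rate > 0,
            warmup_epochs >= 0L, label_smoothing_eps >= 0,
            augment_prob >= 0, augment_prob <= 1, image_size >= 8L,
            backbone_input %% patch == 0L)
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 warmup_epochs = as.integer(warmup_epochs),
                 label_smoothing_eps = label_smoothing_eps,
                 augment_prob = augment_prob, image_size = as.integer(image_size),
                 seed = as.integer(seed),
                 backbone_name = match.arg(backbone_name),
                 n_filters = as.integer(n_filters), patch = as.integer(patch),
                 backbone_input = as.integer(backbone_input),
                 early_stop_patience = as.integer(early_stop_patience)),
            class = "train_config")
}

# ---- head -------------------------------------------------------------------

#' Build the classification head
#'
#' Linear map from `feature_dim` to `n_classes`, followed by tanh (pre-softmax
#' activations in `[-1, 1]`) and softmax. With zero weights the head outputs
#' the uniform distribution; because the pre-softmax values are bounded, no
#' output probability can reach 0 or 1: every `p_i` lies in
#' `[e^-1 / (e^-1 + (n-1) e), e / (e + (n-1) e^-1)]`.
#'
#' @param feature_dim backbone feature dimension (>= 1).
#' @param n_classes number of classes (>= 2).
#' @param init_sd sd of the Gaussian weight init (default 0: zero init).
#' @param rng optional rng handle for the init.
#' @return A `classifier_head`: list with weight matrix `W` (feature_dim x
#'   n_classes), bias `b`, and `n_params`.
#' @export
build_head <- function(feature_dim, n_classes, init_sd = 0, rng = NULL) {
  stopifnot(feature_dim >= 1L, n_classes >= 2L)
  W <- if (init_sd > 0 && !is.null(rng))
    matrix(rng_norm(rng, feature_dim * n_classes, 0, init_sd), feature_dim, n_classes)
  else matrix(0, feature_dim, n_classes)
  structure(list(W = W, b = rep(0, n_classes),
                 n_params = feature_dim * n_classes + n_classes),
            class = "classifier_head")
}

# forward pass of the head on a feature matrix F (n x feature_dim):
# returns list(P, Z) with Z = tanh(F W + b), P = softmax(Z) row-wise
head_forward <- function(head, F) {
  Z <- tanh(sweep(F %*% head$W, 2L, head$b, `+`))
  E <- exp(Z - apply(Z, 1L, max))
  list(P = E / rowSums(E), Z = Z)
}

#' Label-smoothing cross-entropy loss
#'
#' Cross-entropy against the smoothed target
#' `q_i = (1 - eps) * 1[i = true] + eps / n`. Predicted probabilities are
#' clamped at 1e-12 inside the log for numeric safety (the tanh head cannot
#' produce exact zeros anyway).
#'
#' @param P predicted probability vector, or a matrix with one vector per row.
#' @param true_class integer class index (1-based), vectorized over rows.
#' @param eps smoothing mass in `[0, 1)` (default 0.1).
#' @return Mean loss (scalar).
#' @export
label_smoothing_loss <- function(P, true_class, eps = 0.1) {
  P <- if (is.matrix(P)) P else matrix(P, nrow = 1L)
  n <- ncol(P)
  stopifnot(length(true_class) == nrow(P), eps >= 0, eps < 1)
  Q <- matrix(eps / n, nrow(P), n)
  Q[cbind(seq_len(nrow(P)), true_class)] <- (1 - eps) + eps / n
  -mean(rowSums(Q * log(pmax(P, 1e-12))))
}

# smoothed one-hot target matrix
smooth_targets <- function(true_class, n, eps) {
  Q <- matrix(eps / n, length(true_class), n)
  Q[cbind(seq_along(true_class), true_class)] <- (1 - eps) + eps / n
  Q
}

# ---- augmentations ----------------------------------------------------------

adjust_brightness <- function(img, delta) pmin(pmax(img + delta, 0), 1)

adjust_contrast <- function(img, factor) pmin(pmax(0.5 + (img - 0.5) * factor, 0), 1)

add_noise_patches <- function(img, rng, max_frac = 0.05, n_patches = 2L) {
  h <- dim(img)[1]; w <- dim(img)[2]
  for (k in seq_len(n_patches)) {
    frac <- rng_unif(rng, 1, 0.005, max_frac / n_patches)
    ph <- max(1L, round(sqrt(frac * h * w * rng_unif(rng, 1, 0.5, 2))))
    pw <- max(1L, round(frac * h * w / ph))
    ph <- min(ph, h); pw <- min(pw, w)
    r0 <- rng_int(rng, 1, h - ph + 1L); c0 <- rng_int(rng, 1, w - pw + 1L)
    noise <- rng_unif(rng, ph * pw)
    if (length(dim(img)) == 3L)
      for (ch in seq_len(dim(img)[3]))
        img[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L), ch] <- noise
    else
      img[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L)] <- noise
  }
  img
}

#' Stochastic training augmentation
#'
#' Applies, each independently with probability `cfg$augment_prob`, the
#' augmentation families of the training recipe: rotation (+-15 deg),
#' horizontal/vertical flip, zoom (0.9-1.1), axis scaling (0.9-1.1), shear
#' warp (+-0.1), random crop retaining >= 80% of the area, brightness
#' (+-0.2), contrast (x 0.8-1.25), Gaussian blur (sigma 0-2) and random
#' noise patches (<= 5% of the area). The geometric components compose into a
#' single affine resampling. The result is finally resized to
#' `cfg$image_size`; with `augment_prob = 0` the function is a pixel-exact
#' passthrough (after that resize).
#'
#' @param img H x W or H x W x 3 array in `[0, 1]`.
#' @param rng rng handle (internal `make_rng()`) or integer seed.
#' @param cfg a [train_config()].
#' @return Augmented array of side `cfg$image_size`.
#' @export
augment <- function(img, rng, cfg) {
  if (is.numeric(rng)) rng <- make_rng(rng)
  p <- cfg$augment_prob
  on_ <- function() rng_unif(rng, 1) < p
  # accumulate an affine map acting on centered (row, col) coordinates
  A <- diag(2)
  if (on_()) {                                   # rotation
    th <- rng_unif(rng, 1, -15, 15) * pi / 180
    A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*% A
  }
  if (on_()) A <- diag(c(1, -1)) %*% A           # horizontal flip
  if (on_()) A <- diag(c(-1, 1)) %*% A           # vertical flip
  if (on_()) A <- rng_unif(rng, 1, 0.9, 1.1) * A # zoom
  if (on_()) A <- diag(rng_unif(rng, 2, 0.9, 1.1)) %*% A  # per-axis scaling
  if (on_()) {                                   # shear warp
    s <- rng_unif(rng, 1, -0.1, 0.1)
    A <- matrix(c(1, s, s, 1), 2) %*% A
  }
  crop_shift <- c(0, 0); crop_scale <- 1
  if (on_()) {                                   # random crop, >= 80% area
    retain <- sqrt(rng_unif(rng, 1, 0.8, 1))
    crop_scale <- 1 / retain
    h <- dim(img)[1]; w <- dim(img)[2]
    crop_shift <- c(rng_unif(rng, 1, -1, 1) * (1 - retain) * h / 2,
                    rng_unif(rng, 1, -1, 1) * (1 - retain) * w / 2)
  }
  if (!identical(A, diag(2)) || crop_scale != 1) {
    A <- crop_scale * A
    img <- affine_warp(img, A, b = -crop_shift * crop_scale, fill = 1)
  }
  if (on_()) img <- adjust_brightness(img, rng_unif(rng, 1, -0.2, 0.2))
  if (on_()) img <- adjust_contrast(img, rng_unif(rng, 1, 0.8, 1.25))
  if (on_()) {
    # blur magnitude is defined in pixels at the 224-px reference resolution
    # and scales with the working resolution of the image being augmented
    sigma_ref <- rng_unif(rng, 1, 0, 2)
    img <- gaussian_blur(img, sigma_ref * min(dim(img)[1:2]) / 224)
  }
  if (on_()) img <- add_noise_patches(img, rng)
  resize_image(img, cfg$image_size, cfg$image_size)
}

# ---- tiny_cnn backbone ------------------------------------------------------

# The built-in backbone: grayscale, resize to backbone_input^2, cut into
# non-overlapping patch x patch tiles, apply a shared linear filter bank with
# tanh, and average-pool over tiles. feature_dim = n_filters.

new_tiny_cnn <- function(cfg, rng) {
  pdim <- cfg$patch^2
  K <- matrix(rng_norm(rng, pdim * cfg$n_filters, 0, 1 / sqrt(pdim)),
              pdim, cfg$n_filters)
  list(K = K, bK = rep(0, cfg$n_filters),
       patch = cfg$patch, input = cfg$backbone_input,
       n_patches = (cfg$backbone_input / cfg$patch)^2,
       # fixed per-feature standardization, estimated once at init from the
       # training images (feature whitening); part of initialization, not a
       # trained parameter, so the warm-up freezing contract is unaffected
       feat_mean = rep(0, 2L * cfg$n_filters + 8L),
       feat_sd = rep(1, 2L * cfg$n_filters + 8L))
}

# estimate the whitening constants on (un-augmented) training images
calibrate_tiny_cnn <- function(backbone, images) {
  raw <- backbone_forward(backbone, images_to_patches(images, backbone),
                          length(images), standardize = FALSE)$F
  backbone$feat_mean <- colMeans(raw)
  backbone$feat_sd <- pmax(apply(raw, 2L, stats::sd), 1e-3)
  backbone
}

# closed-form linear-probe initialization of the head: ridge regression from
# the whitened features to signed class targets. The deployment recipe starts
# from a pretrained backbone for which a few fine-tuning epochs suffice; the
# from-scratch tiny backbone gets the analogous head start from this cheap
# deterministic probe, which the warm-up and full epochs then refine by Adam.
init_head_probe <- function(head, F, y, n_classes, scale = 0.6) {
  Y <- matrix(-scale / (n_classes - 1), nrow(F), n_classes)
  Y[cbind(seq_len(nrow(F)), y)] <- scale
  Fc <- cbind(F, 1)
  lambda <- 0.05 * nrow(F)
  G <- crossprod(Fc) + lambda * diag(ncol(Fc))
  B <- solve(G, crossprod(Fc, Y))
  head$W <- B[-nrow(B), , drop = FALSE]
  head$b <- B[nrow(B), ]
  head
}

# images (list of arrays) -> patch-matrix tensor: rows = n_images * n_patches,
# cols = patch^2 pixels. Also returns fixed per-image radial-profile features
# (ring means and standard deviations), a rotation/flip-invariant summary that
# resolves central markings; these carry no trainable parameters.
images_to_patches <- function(images, backbone) {
  s <- backbone$input; p <- backbone$patch; np_side <- s / p
  ring <- ring_index(s)
  n_rings <- max(ring)
  radial <- matrix(0, length(images), 2L * n_rings)
  mats <- lapply(seq_along(images), function(k) {
    im <- images[[k]]
    g <- if (length(dim(im)) == 3L) to_grayscale(im) else as.matrix(im)
    g <- resize_image(g, s, s)
    v <- as.vector(g)
    radial[k, ] <<- c(tapply(v, ring, mean),
                      sqrt(pmax(tapply(v, ring, stats::var), 0)))
    # extract non-overlapping p x p tiles in a fixed order
    do.call(rbind, lapply(seq_len(np_side), function(i) {
      do.call(rbind, lapply(seq_len(np_side), function(j) {
        as.vector(g[((i - 1L) * p + 1L):(i * p), ((j - 1L) * p + 1L):(j * p)])
      }))
    }))
  })
  list(patches = do.call(rbind, mats), radial = radial)
}

# concentric ring labels (1..4) over an s x s grid, by normalized radius
ring_index <- local({
  cache <- list()
  function(s) {
    key <- as.character(s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ctr <- (s + 1) / 2
    r <- sqrt(outer((seq_len(s) - ctr)^2, (seq_len(s) - ctr)^2, `+`))
    r <- r / (s / 2)
    idx <- pmin(floor(r / 0.35) + 1L, 4L)   # rings at radius 0.35/0.7/1.05
    cache[[key]] <<- as.vector(idx)
    cache[[key]]
  }
})

# forward: features are the per-filter mean activation (first moment: overall
# intensity response) concatenated with the mean squared activation (second
# moment: phase-invariant texture energy), each pooled over patches.
# feature_dim = 2 * n_filters.
backbone_forward <- function(backbone, inputs, n_images, standardize = TRUE) {
  patches <- inputs$patches
  Tact <- tanh(sweep(patches %*% backbone$K, 2L, backbone$bK, `+`))
  np <- backbone$n_patches
  nf <- ncol(Tact)
  F <- t(vapply(seq_len(n_images), function(i) {
    block <- Tact[((i - 1L) * np + 1L):(i * np), , drop = FALSE]
    c(colMeans(block), colMeans(block^2))
  }, numeric(2L * nf)))
  F <- cbind(F, inputs$radial)
  if (standardize)
    F <- sweep(sweep(F, 2L, backbone$feat_mean, `-`), 2L, backbone$feat_sd, `/`)
  list(F = F, Tact = Tact)
}

adam_new <- function(shape) list(m = array(0, dim = shape), v = array(0, dim = shape))

adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train the crop classifier
#'
#' Implements the transfer-learning schedule: `cfg$warmup_epochs` epochs in
#' which only the head is updated (the backbone stays bit-identical), then
#' `cfg$epochs` epochs updating everything, with Adam at `cfg$learning_rate`,
#' label-smoothing cross-entropy, and per-image augmentation. Validation loss
#' is tracked per epoch for plateau inspection.
#'
#' @param images list of crop arrays (grayscale or color).
#' @param labels character or factor vector of class labels.
#' @param cfg a [train_config()].
#' @param val_images,val_labels optional held-out data for the validation
#'   curve (a warning is issued when absent).
#' @param backbone optional external backbone: a function mapping a list of
#'   images to a numeric feature matrix (used when
#'   `cfg$backbone_name == "external"`).
#' @return A `beetle_classifier`: list with `backbone`, `head`, `class_names`,
#'   `cfg` and `history` (data.frame: epoch, phase, train_loss, val_loss).
#' @export
train_classifier <- function(images, labels, cfg, val_images = NULL,
                             val_labels = NULL, backbone = NULL) {
  labels <- as.character(labels)
  class_names <- sort(unique(labels))
  if (length(class_names) < 2L)
    stop("training data must contain >= 2 classes", call. = FALSE)
  y <- match(labels, class_names)
  n <- length(images)
  nc <- length(class_names)
  if (is.null(val_images) || length(val_images) == 0L) {
    warning("no validation data supplied; validation curve disabled", call. = FALSE)
    val_images <- NULL
  }
  rng <- make_rng(cfg$seed)
  external <- cfg$backbone_name == "external"
  if (external) {
    stopifnot(is.function(backbone))
    bb <- list(external = backbone)
    feat <- function(imgs) backbone(imgs)
    feature_dim <- ncol(feat(images[1]))
  } else {
    bb <- new_tiny_cnn(cfg, rng)
    bb <- calibrate_tiny_cnn(bb, images)
    feature_dim <- 2L * cfg$n_filters + 8L
  }
  head <- build_head(feature_dim, nc, init_sd = 0.05, rng = rng)
  if (!external) {
    F0 <- backbone_forward(bb, images_to_patches(images, bb), n)$F
    head <- init_head_probe(head, F0, y, nc)
  }
  opt <- list(W = adam_new(dim(head$W)), b = adam_new(length(head$b)),
              K = if (!external) adam_new(dim(bb$K)),
              bK = if (!external) adam_new(length(bb$bK)))
  step <- 0L
  eps <- cfg$label_smoothing_eps
  eval_loss <- function(imgs, yy) {
    if (external) {
      F <- feat(imgs)
    } else {
      F <- backbone_forward(bb, images_to_patches(imgs, bb), length(imgs))$F
    }
    P <- head_forward(head, F)$P
    label_smoothing_loss(P, yy, eps)
  }
  yv <- if (!is.null(val_images)) match(as.character(val_labels), class_names)
  history <- list()
  total_epochs <- cfg$warmup_epochs + cfg$epochs
  best_val <- Inf; stall <- 0L
  for (epoch in seq_len(total_epochs)) {
    warm <- epoch <= cfg$warmup_epochs
    ord <- rng_sample(rng, seq_len(n), n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      bs <- length(idx)
      aug <- lapply(images[idx], augment, rng = rng, cfg = cfg)
      if (external) {
        F <- feat(aug); Tact <- NULL; binput <- NULL
      } else {
        binput <- images_to_patches(aug, bb)
        fwd <- backbone_forward(bb, binput, bs)
        F <- fwd$F; Tact <- fwd$Tact
      }
      hf <- head_forward(head, F)
      Q <- smooth_targets(y[idx], nc, eps)
      batch_losses <- c(batch_losses,
                        -mean(rowSums(Q * log(pmax(hf$P, 1e-12)))))
      step <- step + 1L
      dZ <- (hf$P - Q) / bs
      dA <- dZ * (1 - hf$Z^2)                    # through the output tanh
      gW <- t(F) %*% dA
      gb <- colSums(dA)
      opt$W <- adam_step(opt$W, gW, cfg$learning_rate, step)
      opt$b <- adam_step(opt$b, gb, cfg$learning_rate, step)
      if (!warm && !external) {
        dF <- sweep(dA %*% t(head$W), 2L, bb$feat_sd, `/`)  # undo whitening
        np <- bb$n_patches
        nf <- ncol(Tact)
        d1 <- dF[rep(seq_len(bs), each = np), seq_len(nf), drop = FALSE]
        d2 <- dF[rep(seq_len(bs), each = np), nf + seq_len(nf), drop = FALSE]
        dT <- (d1 + 2 * Tact * d2) / np
        dpre <- dT * (1 - Tact^2)
        gK <- t(binput$patches) %*% dpre
        gbK <- colSums(dpre)
        opt$K <- adam_step(opt$K, gK, cfg$learning_rate, step)
        opt$bK <- adam_step(opt$bK, gbK, cfg$learning_rate, step)
        bb$K <- bb$K - opt$K$delta
        bb$bK <- bb$bK - opt$bK$delta
      }
      head$W <- head$W - opt$W$delta
      head$b <- head$b - opt$b$delta
    }
    val_loss <- if (!is.null(val_images)) eval_loss(val_images, yv) else NA_real_
    history[[epoch]] <- data.frame(
      epoch = epoch, phase = if (warm) "warmup" else "full",
      train_loss = mean(batch_losses), val_loss = val_loss)
    if (cfg$early_stop_patience > 0L && !warm && !is.na(val_loss)) {
      if (val_loss < best_val - 1e-6) { best_val <- val_loss; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= cfg$early_stop_patience) break
    }
  }
  structure(list(backbone = bb, head = head, class_names = class_names,
                 cfg = cfg, history = do.call(rbind, history),
                 external = external),
            class = "beetle_classifier")
}

#' Predict class probabilities for crops
#'
#' @param object a `beetle_classifier` from [train_classifier()].
#' @param images list of crop arrays.
#' @param ... unused.
#' @return Numeric matrix, one probability vector per row (rows sum to 1),
#'   with `colnames = class_names`.
#' @export
predict.beetle_classifier <- function(object, images, ...) {
  if (object$external) {
    F <- object$backbone$external(images)
  } else {
    F <- backbone_forward(object$backbone,
                          images_to_patches(images, object$backbone),
                          length(images))$F
  }
  P <- head_forward(object$head, F)$P
  colnames(P) <- object$class_names
  P
}

#' @export
print.beetle_classifier <- function(x, ...) {
  cat(sprintf("<beetle_classifier %s classes=%d epochs=%d>\n",
              x$cfg$backbone_name, length(x$class_names), nrow(x$history)))
  invisible(x)
}
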
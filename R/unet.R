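#' U-Net architecture configuration
#'
#' Fixes the encoder-decoder geometry for one of the two segmentation
#' models: model 1 predicts 3 classes (background, ganglion cell, normal
#' nerve), model 2 predicts 2 (background, hypertrophic nerve). The
#' network halves resolution `depth - 1` times, so the input size must
#' survive that many poolings.
#'
#' @param model_id `"model1"` or `"model2"` (sets `n_classes`).
#' @param depth Number of encoder levels (default 3).
#' @param base_filters Filters at the top level, doubled per level
#'   (default 16).
#' @param input_size Spatial edge of input tiles; equals the patch size
#'   (256).
#' @param seed Parameter-initialisation seed.
#' @return A `unet_config`.
#' @export
unet_config <- function(model_id = c("model1", "model2"), depth = 3L,
                        base_filters = 16L, input_size = 256L, seed = 1L) {
  model_id <- match.arg(model_id)
  depth <- as.integer(depth); base_filters <- as.integer(base_filters)
  input_size <- as.integer(input_size)
  if (depth < 1L) stopf("depth must be >= 1")
  shrink <- 2L^(depth - 1L)
  if (input_size %% shrink != 0L || input_size %/% shrink < 4L) {
    stopf("depth %d collapses a %dx%d input (bottom level %.1f px); reduce depth",
          depth, input_size, input_size, input_size / shrink)
  }
  structure(list(model_id = model_id,
                 n_classes = if (model_id == "model1") 3L else 2L,
                 depth = depth, base_filters = base_filters,
                 input_size = input_size, seed = as.integer(seed)),
            class = "unet_config")
}

#' Training configuration
#'
#' @param epochs Training epochs (default 120, matching the full-scale
#'   protocol; desk-scale runs use far fewer).
#' @param batch_size Patches per optimiser step (default 8).
#' @param learning_rate Adam step size (default 1e-3).
#' @param class_weights `NULL` for an unweighted loss, `"balanced"` for
#'   inverse-frequency weights estimated from the training split (clipped
#'   to `[0.25, 10]` and normalised to mean 1), or an explicit numeric
#'   vector of length `n_classes`.
#' @param seed Seed controlling shuffling order (and hence the whole run,
#'   together with the architecture seed).
#' @return A `training_config`.
#' @export
training_config <- function(epochs = 120L, batch_size = 8L,
                            learning_rate = 1e-3, class_weights = NULL,
                            seed = 1L) {
  if (epochs < 1) stopf("epochs must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "training_config")
}

# Fixed input standardisation applied before the first convolution.
INPUT_CENTER <- 0.8
INPUT_SCALE <- 0.15

unet_channels <- function(cfg) cfg$base_filters * 2L^(seq_len(cfg$depth) - 1L)

#' Build an untrained U-Net segmenter
#'
#' Initialises an encoder-decoder network with skip connections: two 3x3
#' convolution + ReLU blocks per level, 2x2 max pooling down, nearest-
#' neighbour upsampling with skip concatenation up, and a 1x1 convolution
#' to per-pixel class scores. He initialisation is deterministic for the
#' config seed.
#'
#' @param config A [unet_config()].
#' @return A `unet_segmenter` (untrained).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  f <- unet_channels(config)
  he <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  params <- with_seed(config$seed, {
    p <- list()
    for (l in seq_len(config$depth)) {
      cin <- if (l == 1L) 3L else f[l - 1L]
      p[[sprintf("e%d.W1", l)]] <- he(9L * cin, f[l])
      p[[sprintf("e%d.b1", l)]] <- numeric(f[l])
      p[[sprintf("e%d.W2", l)]] <- he(9L * f[l], f[l])
      p[[sprintf("e%d.b2", l)]] <- numeric(f[l])
    }
    if (config$depth > 1L) {
      for (l in seq_len(config$depth - 1L)) {
        # 1x1 up-projection halves the channels of the upsampled lower
        # level before skip concatenation (the classic up-convolution)
        p[[sprintf("u%d.W", l)]] <- he(f[l + 1L], f[l])
        p[[sprintf("u%d.b", l)]] <- numeric(f[l])
        cin <- 2L * f[l]          # projected lower level + skip
        p[[sprintf("d%d.W1", l)]] <- he(9L * cin, f[l])
        p[[sprintf("d%d.b1", l)]] <- numeric(f[l])
        p[[sprintf("d%d.W2", l)]] <- he(9L * f[l], f[l])
        p[[sprintf("d%d.b2", l)]] <- numeric(f[l])
      }
    }
    p[["out.W"]] <- he(f[1L], config$n_classes)
    p[["out.b"]] <- numeric(config$n_classes)
    p
  })
  structure(list(model_id = config$model_id, config = config,
                 params = params, palette = class_palette(config$model_id),
                 trained = FALSE),
            class = "unet_segmenter")
}

#' @export
print.unet_segmenter <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet_segmenter %s: depth %d, base filters %d, %d classes, %s, %d parameters>\n",
              x$model_id, x$config$depth, x$config$base_filters,
              x$config$n_classes, if (isTRUE(x$trained)) "trained" else "untrained",
              n_par))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

# Layer-by-layer double-precision reference pass. The training loop and
# predict methods use the fused single-precision passes (.unet_step /
# .unet_infer); this path is kept as the readable reference the fused code
# is tested against. With cache = TRUE it also returns every intermediate
# needed by unet_backward.
unet_forward <- function(params, cfg, x, cache = FALSE) {
  xn <- (x - INPUT_CENTER) / INPUT_SCALE
  depth <- cfg$depth
  enc <- vector("list", depth)
  cur <- xn
  for (l in seq_len(depth)) {
    z1 <- .conv3_fwd(cur, params[[sprintf("e%d.W1", l)]], params[[sprintf("e%d.b1", l)]])
    a1 <- relu(z1)
    z2 <- .conv3_fwd(a1, params[[sprintf("e%d.W2", l)]], params[[sprintf("e%d.b2", l)]])
    a2 <- relu(z2)
    enc[[l]] <- list(input = cur, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
    if (l < depth) {
      pl <- .maxpool2_fwd(a2)
      enc[[l]]$pool_idx <- pl$idx
      cur <- pl$y
    } else {
      cur <- a2
    }
  }
  dec <- if (depth > 1L) vector("list", depth - 1L) else list()
  if (depth > 1L) {
    for (l in rev(seq_len(depth - 1L))) {
      up <- .upsample2_fwd(cur)
      uh <- dim(up)[1]; uw <- dim(up)[2]
      upm <- matrix(up, uh * uw, dim(up)[3])
      prm <- sweep(upm %*% params[[sprintf("u%d.W", l)]], 2,
                   params[[sprintf("u%d.b", l)]], "+")
      proj <- array(prm, c(uh, uw, ncol(prm)))
      skip <- enc[[l]]$a2
      cat_in <- array(c(proj, skip), dim = c(uh, uw,
                                             dim(proj)[3] + dim(skip)[3]))
      z1 <- .conv3_fwd(cat_in, params[[sprintf("d%d.W1", l)]], params[[sprintf("d%d.b1", l)]])
      a1 <- relu(z1)
      z2 <- .conv3_fwd(a1, params[[sprintf("d%d.W2", l)]], params[[sprintf("d%d.b2", l)]])
      a2 <- relu(z2)
      dec[[l]] <- list(input = cat_in, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                       up = up, proj_channels = dim(proj)[3])
      cur <- a2
    }
  }
  H <- dim(cur)[1]; W <- dim(cur)[2]; f1 <- dim(cur)[3]
  xm <- matrix(cur, H * W, f1)
  lm <- xm %*% params[["out.W"]]
  lm <- sweep(lm, 2, params[["out.b"]], "+")
  logits <- array(lm, c(H, W, ncol(lm)))
  if (!cache) return(logits)
  list(logits = logits, enc = enc, dec = dec, head_in = xm)
}

# Backward pass: gradient of the loss w.r.t. every parameter, given the
# forward cache and d(loss)/d(logits).
unet_backward <- function(params, cfg, fw, dlogits) {
  depth <- cfg$depth
  grads <- list()
  H <- dim(dlogits)[1]; W <- dim(dlogits)[2]; K <- dim(dlogits)[3]
  dlm <- matrix(dlogits, H * W, K)
  grads[["out.W"]] <- crossprod(fw$head_in, dlm)
  grads[["out.b"]] <- colSums(dlm)
  dcur <- array(dlm %*% t(params[["out.W"]]),
                c(H, W, nrow(params[["out.W"]])))
  dskip <- vector("list", depth)
  if (depth > 1L) {
    for (l in seq_len(depth - 1L)) {     # decoder ran depth-1 .. 1; reverse
      d <- fw$dec[[l]]
      dz2 <- dcur * (d$z2 > 0)
      b2 <- .conv3_bwd(d$a1, params[[sprintf("d%d.W2", l)]], dz2)
      grads[[sprintf("d%d.W2", l)]] <- b2$dW
      grads[[sprintf("d%d.b2", l)]] <- b2$db
      dz1 <- b2$dx * (d$z1 > 0)
      b1 <- .conv3_bwd(d$input, params[[sprintf("d%d.W1", l)]], dz1)
      grads[[sprintf("d%d.W1", l)]] <- b1$dW
      grads[[sprintf("d%d.b1", l)]] <- b1$db
      cp <- d$proj_channels
      dproj <- b1$dx[, , seq_len(cp), drop = FALSE]
      dskip[[l]] <- b1$dx[, , (cp + 1L):dim(b1$dx)[3], drop = FALSE]
      uh <- dim(d$up)[1]; uw <- dim(d$up)[2]
      dprm <- matrix(dproj, uh * uw, cp)
      upm <- matrix(d$up, uh * uw, dim(d$up)[3])
      grads[[sprintf("u%d.W", l)]] <- crossprod(upm, dprm)
      grads[[sprintf("u%d.b", l)]] <- colSums(dprm)
      dup <- array(dprm %*% t(params[[sprintf("u%d.W", l)]]),
                   c(uh, uw, dim(d$up)[3]))
      dcur <- .upsample2_bwd(dup)
    }
  }
  d_from_above <- NULL
  for (l in rev(seq_len(depth))) {
    e <- fw$enc[[l]]
    if (l == depth) {
      d_a2 <- dcur
    } else {
      d_a2 <- .maxpool2_bwd(e$pool_idx, d_from_above) + dskip[[l]]
    }
    dz2 <- d_a2 * (e$z2 > 0)
    b2 <- .conv3_bwd(e$a1, params[[sprintf("e%d.W2", l)]], dz2)
    grads[[sprintf("e%d.W2", l)]] <- b2$dW
    grads[[sprintf("e%d.b2", l)]] <- b2$db
    dz1 <- b2$dx * (e$z1 > 0)
    b1 <- .conv3_bwd(e$input, params[[sprintf("e%d.W1", l)]], dz1)
    grads[[sprintf("e%d.W1", l)]] <- b1$dW
    grads[[sprintf("e%d.b1", l)]] <- b1$db
    d_from_above <- b1$dx
  }
  grads
}

balanced_class_weights <- function(items, n_classes) {
  counts <- numeric(n_classes)
  for (p in items) {
    tab <- tabulate(p$mask$data + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  freq <- counts / sum(counts)
  w <- 1 / pmax(freq, 1e-6)
  w <- pmin(pmax(w / mean(w), 0.25), 10)
  w / mean(w)
}

#' Train a U-Net segmenter
#'
#' Runs seeded mini-batch Adam on the pixel-wise (optionally class-
#' weighted) softmax cross-entropy. Training accuracy is accumulated from
#' the forward passes of each epoch; validation pixel accuracy is measured
#' on the held-out split at the end of every epoch, giving the per-epoch
#' accuracy history. With fixed seeds the run is reproducible on one
#' device.
#'
#' @param segmenter An untrained [build_unet()] segmenter.
#' @param dataset A [build_model_dataset()] result with matching
#'   `model_id`.
#' @param tcfg A [training_config()].
#' @param verbose Print one line per epoch.
#' @return A `trained_segmenter` (also inherits `unet_segmenter`) with a
#'   `history` data.frame (`epoch`, `train_accuracy`,
#'   `validation_accuracy`).
#' @export
train_segmenter <- function(segmenter, dataset, tcfg = training_config(),
                            verbose = FALSE) {
  stopifnot(inherits(segmenter, "unet_segmenter"),
            inherits(dataset, "model_dataset"),
            inherits(tcfg, "training_config"))
  if (!identical(segmenter$model_id, dataset$model_id)) {
    stopf("segmenter is %s but dataset is %s", segmenter$model_id,
          dataset$model_id)
  }
  if (!length(dataset$train)) stopf("training split is empty")
  cfg <- segmenter$config
  k <- cfg$n_classes
  weights <- tcfg$class_weights
  if (is.null(weights)) {
    weights <- rep(1, k)
  } else if (identical(weights, "balanced")) {
    weights <- balanced_class_weights(dataset$train, k)
  } else if (length(weights) != k) {
    stopf("class_weights must have length %d", k)
  }

  params <- segmenter$params
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0L
  lr <- tcfg$learning_rate
  n <- length(dataset$train)
  history <- data.frame(epoch = seq_len(tcfg$epochs),
                        train_accuracy = NA_real_,
                        validation_accuracy = NA_real_)

  for (epoch in seq_len(tcfg$epochs)) {
    ord <- with_seed(derive_seed(tcfg$seed, 1000L + epoch), sample.int(n))
    acc_sum <- 0; acc_n <- 0L
    batch_starts <- seq(1L, n, by = tcfg$batch_size)
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + tcfg$batch_size - 1L, n)]
      gacc <- NULL
      for (i in idx) {
        item <- dataset$train[[i]]
        sx <- .unet_step(params, item$image, item$mask$data, weights,
                         cfg$depth)
        if (!is.finite(sx$loss)) {
          stopf("non-finite loss at epoch %d (item %d); lower the learning rate",
                epoch, i)
        }
        acc_sum <- acc_sum + sx$pixel_accuracy; acc_n <- acc_n + 1L
        g <- sx$grad
        gacc <- if (is.null(gacc)) g[names(params)] else
          mapply(function(a, b) a + b, gacc, g[names(gacc)], SIMPLIFY = FALSE)
      }
      t_step <- t_step + 1L
      scale <- 1 / length(idx)
      for (nm in names(params)) {
        g <- gacc[[nm]] * scale
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
        mhat <- mstate[[nm]] / (1 - b1^t_step)
        vhat <- vstate[[nm]] / (1 - b2^t_step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    history$train_accuracy[epoch] <- acc_sum / max(acc_n, 1L)
    history$validation_accuracy[epoch] <-
      eval_pixel_accuracy(params, cfg, dataset$validation)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  validation %.4f", epoch,
                      history$train_accuracy[epoch],
                      history$validation_accuracy[epoch]))
    }
  }
  out <- segmenter
  out$params <- params
  out$training <- tcfg
  out$class_weights <- weights
  out$history <- history
  out$trained <- TRUE
  class(out) <- c("trained_segmenter", "unet_segmenter")
  out
}

eval_pixel_accuracy <- function(params, cfg, items) {
  if (!length(items)) return(NA_real_)
  accs <- vapply(items, function(item) {
    pred <- .unet_infer(params, item$image, cfg$depth, FALSE)$pred
    mean(pred == item$mask$data)
  }, numeric(1))
  mean(accs)
}

#' Predict the segmentation of a single patch
#'
#' @param segmenter A `unet_segmenter` (usually trained).
#' @param tile RGB array of the configured input size.
#' @param return_probs Attach the per-pixel class probabilities as the
#'   `"probs"` attribute.
#' @return A [multiclass_mask()] of per-pixel argmax classes under the
#'   segmenter's palette.
#' @export
predict_patch <- function(segmenter, tile, return_probs = FALSE) {
  stopifnot(inherits(segmenter, "unet_segmenter"))
  sz <- segmenter$config$input_size
  if (!is_rgb_image(tile) || dim(tile)[1] != sz || dim(tile)[2] != sz) {
    stopf("tile must be %dx%dx3, got [%s]", sz, sz,
          paste(dim(tile), collapse = "x"))
  }
  res <- .unet_infer(segmenter$params, tile, segmenter$config$depth,
                     return_probs)
  mask <- multiclass_mask(res$pred, segmenter$palette)
  if (return_probs) attr(mask, "probs") <- .softmax_probs(res$logits)
  mask
}

#' Predict the segmentation of a whole slide
#'
#' Tiles the slide into patches, predicts each patch, and reassembles the
#' predictions into an original-sized mask; exactly equivalent to
#' `unpatchify` applied to per-patch `predict_patch` calls (the tiling is
#' non-overlapping, so there are no border effects).
#'
#' @param segmenter A `unet_segmenter`.
#' @param image RGB slide array with dimensions divisible by the patch
#'   size.
#' @return A [multiclass_mask()] with the slide's dimensions.
#' @export
predict_slide <- function(segmenter, image) {
  stopifnot(inherits(segmenter, "unet_segmenter"))
  ps <- segmenter$config$input_size
  grid <- patchify(image, patch_size = ps)
  grid$patches <- lapply(grid$patches, function(p) {
    p$mask <- predict_patch(segmenter, p$image)
    p
  })
  unpatchify(grid)$mask
}

#' @export
predict.unet_segmenter <- function(object, newdata, type = c("mask", "probs"), ...) {
  type <- match.arg(type)
  sz <- object$config$input_size
  if (inherits(newdata, "rendered_slide")) newdata <- newdata$image
  if (!is_rgb_image(newdata)) stopf("`newdata` must be an RGB array or rendered_slide")
  if (all(dim(newdata)[1:2] == sz)) {
    predict_patch(object, newdata, return_probs = type == "probs")
  } else {
    if (type == "probs") stopf("probabilities are only returned for single patches")
    predict_slide(object, newdata)
  }
}

#' Pixel accuracy between two masks
#'
#' The fraction of pixels whose predicted class equals the ground-truth
#' class (correct predictions over all predictions). Requires identical
#' dimensions and palettes.
#'
#' @param predicted,truth [multiclass_mask()]s.
#' @return Numeric in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  stopifnot(inherits(predicted, "multiclass_mask"),
            inherits(truth, "multiclass_mask"))
  if (!identical(dim(predicted$data), dim(truth$data))) {
    stopf("mask dimensions differ: [%s] vs [%s]",
          paste(dim(predicted$data), collapse = "x"),
          paste(dim(truth$data), collapse = "x"))
  }
  if (!identical(predicted$palette$model_id, truth$palette$model_id)) {
    stopf("palette mismatch: %s vs %s", predicted$palette$model_id,
          truth$palette$model_id)
  }
  mean(predicted$data == truth$data)
}

#' Detect an accuracy plateau in a training history
#'
#' Finds the earliest epoch from which every length-`window` window of the
#' curve has range (max - min) below `tolerance`; returns `NA` if the
#' curve never settles.
#'
#' @param history A `trained_segmenter` history data.frame or a numeric
#'   accuracy vector.
#' @param window Window length in epochs (>= 2).
#' @param tolerance Maximum within-window range counted as flat.
#' @param metric History column to use when `history` is a data.frame.
#' @return Integer epoch index, or `NA_integer_` if no plateau.
#' @export
detect_plateau <- function(history, window = 10L, tolerance = 0.005,
                           metric = "validation_accuracy") {
  v <- if (is.data.frame(history)) history[[metric]] else as.numeric(history)
  window <- as.integer(window)
  if (window < 2L) stopf("window must be >= 2")
  n <- length(v)
  if (window > n) stopf("window (%d) exceeds history length (%d)", window, n)
  starts <- seq_len(n - window + 1L)
  flat <- vapply(starts, function(k) {
    seg <- v[k:(k + window - 1L)]
    (max(seg) - min(seg)) < tolerance
  }, logical(1))
  if (!all(flat[length(flat)])) return(NA_integer_)
  bad <- which(!flat)
  if (!length(bad)) return(1L)
  k <- max(bad) + 1L
  if (k > length(flat)) NA_integer_ else as.integer(k)
}

#' @export
print.trained_segmenter <- function(x, ...) {
  NextMethod()
  h <- x$history
  cat(sprintf("  %d epochs; final train %.4f, validation %.4f\n",
              nrow(h), h$train_accuracy[nrow(h)],
              h$validation_accuracy[nrow(h)]))
  invisible(x)
}

#' @export
summary.trained_segmenter <- function(object, ...) {
  h <- object$history
  res <- list(model_id = object$model_id, config = object$config,
              epochs = nrow(h),
              final_train_accuracy = h$train_accuracy[nrow(h)],
              final_validation_accuracy = h$validation_accuracy[nrow(h)],
              best_validation_accuracy = max(h$validation_accuracy),
              plateau_epoch = if (nrow(h) >= 5)
                detect_plateau(h, window = min(10L, nrow(h))) else NA_integer_,
              class_weights = object$class_weights)
  class(res) <- "summary.trained_segmenter"
  res
}

#' @export
print.summary.trained_segmenter <- function(x, ...) {
  cat(sprintf("Trained U-Net segmenter (%s)\n", x$model_id))
  cat(sprintf("  depth %d, base filters %d, %d classes\n", x$config$depth,
              x$config$base_filters, x$config$n_classes))
  cat(sprintf("  epochs: %d; final train accuracy %.4f; final validation accuracy %.4f\n",
              x$epochs, x$final_train_accuracy, x$final_validation_accuracy))
  if (!is.na(x$plateau_epoch)) {
    cat(sprintf("  validation accuracy plateau from epoch %d\n", x$plateau_epoch))
  }
  invisible(x)
}

#' @export
coef.unet_segmenter <- function(object, ...) object$params

#' @export
plot.trained_segmenter <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_accuracy, type = "l", col = "red",
       ylim = range(c(h$train_accuracy, h$validation_accuracy), na.rm = TRUE),
       xlab = "epoch", ylab = "pixel accuracy",
       main = sprintf("%s training history", x$model_id), ...)
  lines(h$epoch, h$validation_accuracy, col = "darkgreen")
  legend("bottomright", legend = c("train", "validation"),
         col = c("red", "darkgreen"), lty = 1, bty = "n")
  invisible(x)
}
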
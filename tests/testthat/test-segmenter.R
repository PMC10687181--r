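tiny_cfg <- function(model_id = "model1", input = 64L) {
  unet_config(model_id, depth = 2L, base_filters = 4L, input_size = input,
              seed = 5L)
}

tiny_dataset <- function(model_id = "model1", n_slides = 2, input = 64L) {
  slides <- render_cohort(n_slides, c(transition = 1), seed = 81,
                          canvas_width = 256, canvas_height = 256)
  mask_field <- if (model_id == "model1") "mask_m1" else "mask_m2"
  items <- unlist(lapply(slides, function(s)
    patchify(s$image, s[[mask_field]], patch_size = input)$patches),
    recursive = FALSE)
  split <- split_80_20(items, seed = 2)
  structure(list(model_id = model_id, train = split$train,
                 validation = split$validation,
                 counts = c(total = length(items))),
            class = c("model_dataset"))
}

test_that("the two architectures emit the right number of class planes", {
  s <- render_slide(small_spec(seed = 82))
  tile <- s$image[1:256, 1:256, ]
  for (model_id in c("model1", "model2")) {
    net <- build_unet(unet_config(model_id, depth = 3, base_filters = 4,
                                  seed = 1))
    m <- predict_patch(net, tile, return_probs = TRUE)
    probs <- attr(m, "probs")
    k <- if (model_id == "model1") 3L else 2L
    expect_equal(dim(probs), c(256, 256, k))
    expect_equal(max(abs(apply(probs, c(1, 2), sum) - 1)), 0,
                 tolerance = 1e-6)
    # the returned mask is the per-pixel argmax of the returned scores
    expect_identical(m$data,
                     matrix(apply(probs, c(1, 2), which.max) - 1L, 256, 256))
    expect_equal(sort(unique(as.vector(m$data))),
                 intersect(0:(k - 1), unique(as.vector(m$data))))
  }
})

test_that("excessive depth for the input size is rejected", {
  expect_error(unet_config("model1", depth = 8, input_size = 256),
               "collapses")
  expect_error(predict_patch(build_unet(tiny_cfg()),
                             array(0.5, c(32, 32, 3))), "tile must be")
})

test_that("initialisation is deterministic per seed", {
  a <- build_unet(unet_config("model1", seed = 7))
  b <- build_unet(unet_config("model1", seed = 7))
  c <- build_unet(unet_config("model1", seed = 8))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("fused single-precision passes match the double-precision reference", {
  cfg <- tiny_cfg()
  net <- build_unet(cfg)
  x <- with_test_seed(3, array(runif(64 * 64 * 3), c(64, 64, 3)))
  lab <- with_test_seed(4, matrix(sample(0:2, 64 * 64, TRUE), 64, 64))

  ref_logits <- hirschseg:::unet_forward(net$params, cfg, x)
  fused <- hirschseg:::.unet_infer(net$params, x, cfg$depth, TRUE)
  expect_lt(max(abs(ref_logits - fused$logits)), 1e-4)

  fw <- hirschseg:::unet_forward(net$params, cfg, x, cache = TRUE)
  sx <- hirschseg:::.softmax_xent(fw$logits, lab, rep(1, 3))
  ref_grad <- hirschseg:::unet_backward(net$params, cfg, fw, sx$grad)
  st <- hirschseg:::.unet_step(net$params, x, lab, rep(1, 3), cfg$depth)
  expect_equal(st$loss, sx$loss, tolerance = 1e-5)
  for (nm in names(net$params)) {
    denom <- max(abs(ref_grad[[nm]])) + 1e-8
    expect_lt(max(abs(ref_grad[[nm]] - st$grad[[nm]])) / denom, 1e-4)
  }
})

test_that("backpropagated gradients match finite differences", {
  cfg <- unet_config("model2", depth = 2, base_filters = 2,
                     input_size = 16, seed = 9)
  net <- build_unet(cfg)
  x <- with_test_seed(5, array(runif(16 * 16 * 3), c(16, 16, 3)))
  lab <- with_test_seed(6, matrix(sample(0:1, 256, TRUE), 16, 16))
  w <- c(1, 2)

  loss_at <- function(params) {
    fw <- hirschseg:::unet_forward(params, cfg, x, cache = TRUE)
    hirschseg:::.softmax_xent(fw$logits, lab, w)$loss
  }
  fw <- hirschseg:::unet_forward(net$params, cfg, x, cache = TRUE)
  sx <- hirschseg:::.softmax_xent(fw$logits, lab, w)
  grad <- hirschseg:::unet_backward(net$params, cfg, fw, sx$grad)

  eps <- 1e-5
  for (nm in c("e1.W1", "e2.W2", "u1.W", "d1.W1", "out.W", "out.b")) {
    p <- net$params
    picks <- with_test_seed(10, sample(length(p[[nm]]),
                                       min(4, length(p[[nm]]))))
    for (i in picks) {
      p_hi <- p; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- p; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      fd <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
      # ReLU kinks make central differences only ~2-digit accurate for
      # parameters below an activation; the head (no ReLU above it) is
      # exact and pins the overall scale
      if (nm %in% c("out.W", "out.b")) {
        expect_lt(abs(grad[[nm]][i] - fd), 1e-6 * max(abs(fd), 1e-3))
      } else {
        expect_lt(abs(grad[[nm]][i] - fd), 0.05 * abs(fd) + 2e-3)
      }
    }
  }
})

test_that("training produces a per-epoch history and is reproducible", {
  ds <- tiny_dataset("model2")
  tc <- training_config(epochs = 2, batch_size = 2, learning_rate = 1e-3,
                        seed = 3)
  fit1 <- train_segmenter(build_unet(tiny_cfg("model2")), ds, tc)
  expect_s3_class(fit1, "trained_segmenter")
  expect_equal(nrow(fit1$history), 2L)
  expect_true(all(fit1$history$train_accuracy >= 0 &
                    fit1$history$train_accuracy <= 1))
  expect_true(all(fit1$history$validation_accuracy >= 0 &
                    fit1$history$validation_accuracy <= 1))

  fit2 <- train_segmenter(build_unet(tiny_cfg("model2")), ds, tc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(coef(fit1), coef(fit2))

  one <- train_segmenter(build_unet(tiny_cfg("model2")), ds,
                         training_config(epochs = 1, batch_size = 2, seed = 3))
  expect_equal(nrow(one$history), 1L)

  expect_error(train_segmenter(build_unet(tiny_cfg("model1")), ds, tc),
               "model1")
  empty <- ds; empty$train <- list()
  expect_error(train_segmenter(build_unet(tiny_cfg("model2")), empty, tc),
               "empty")
})

test_that("whole-slide prediction equals reassembled patch predictions", {
  s <- render_slide(small_spec(seed = 83))
  net <- build_unet(unet_config("model1", depth = 2, base_filters = 4,
                                seed = 2))
  slide_mask <- predict_slide(net, s$image)
  expect_equal(dim(slide_mask$data), dim(s$image)[1:2])

  grid <- patchify(s$image, patch_size = 256)
  grid$patches <- lapply(grid$patches, function(p) {
    p$mask <- predict_patch(net, p$image)
    p
  })
  expect_identical(slide_mask$data, unpatchify(grid)$mask$data)

  single <- predict_patch(net, s$image[1:256, 1:256, ])
  expect_identical(slide_mask$data[1:256, 1:256], single$data)

  via_method <- predict(net, s$image)
  expect_identical(via_method$data, slide_mask$data)
})

test_that("pixel accuracy matches an explicit-loop oracle and its invariances", {
  loop_accuracy <- function(a, b) {
    hits <- 0L
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(ncol(a))) if (a[i, j] == b[i, j]) hits <- hits + 1L
    }
    hits / length(a)
  }
  for (seed in 1:4) {
    p <- random_mask("model1", 32, 32, seed = seed)
    t <- random_mask("model1", 32, 32, seed = seed + 50)
    expect_equal(accuracy(p, t), loop_accuracy(p$data, t$data))
    expect_equal(accuracy(p, t), accuracy(t, p))
    # invariance under a fixed label permutation applied to both masks
    perm <- c(2L, 0L, 1L)
    pp <- multiclass_mask(matrix(perm[p$data + 1L], 32, 32), "model1")
    tp <- multiclass_mask(matrix(perm[t$data + 1L], 32, 32), "model1")
    expect_equal(accuracy(pp, tp), accuracy(p, t))
  }

  m <- random_mask("model2", 16, 16, seed = 1)
  expect_equal(accuracy(m, m), 1)
  compl <- multiclass_mask(1L - m$data, "model2")
  expect_equal(accuracy(m, compl), 0)

  half <- multiclass_mask(matrix(rep(c(0L, 1L), each = 32768), 256, 256),
                          "model2")
  full <- multiclass_mask(matrix(0L, 256, 256), "model2")
  expect_equal(accuracy(half, full), 0.5)

  expect_error(accuracy(random_mask("model1", 8, 8),
                        random_mask("model1", 16, 16)), "dimensions")
  expect_error(accuracy(random_mask("model1", 8, 8),
                        random_mask("model2", 8, 8)), "palette")
})

test_that("plateau detection finds the earliest stable epoch", {
  expect_equal(detect_plateau(rep(0.9, 20), window = 5, tolerance = 0.01), 1L)
  expect_true(is.na(detect_plateau(seq(0, 1, length.out = 30), window = 5,
                                   tolerance = 0.01)))
  curve <- c(seq(0.5, 0.9, by = 0.05), rep(0.9, 12))
  k <- detect_plateau(curve, window = 4, tolerance = 0.001)
  # direct-scan oracle
  ranges <- vapply(seq_len(length(curve) - 3), function(i)
    max(curve[i:(i + 3)]) - min(curve[i:(i + 3)]), numeric(1))
  oracle <- max(which(ranges >= 0.001)) + 1L
  expect_equal(k, oracle)
  expect_error(detect_plateau(rep(0.9, 3), window = 5), "exceeds")
  expect_error(detect_plateau(rep(0.9, 3), window = 1), "window")
})
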
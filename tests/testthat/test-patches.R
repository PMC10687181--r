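test_that("the standard slide geometry tiles into 40 patches and back", {
  s <- render_slide(scene_spec(seed = 31))     # 2048 x 1280 default
  grid <- patchify(s$image, s$mask_m1, slide_id = "full")
  expect_equal(grid$n_rows, 5L)
  expect_equal(grid$n_cols, 8L)
  expect_length(grid$patches, 40L)
  back <- unpatchify(grid)
  expect_identical(back$image, s$image)
  expect_identical(back$mask$data, s$mask_m1$data)
})

test_that("degenerate tilings behave as identities", {
  s <- render_slide(small_spec(seed = 32))
  one <- patchify(s$image[1:256, 1:256, ], patch_size = 256)
  expect_length(one$patches, 1L)
  expect_identical(one$patches[[1]]$image, s$image[1:256, 1:256, ])

  four <- patchify(s$image, patch_size = 256)
  expect_length(four$patches, 4L)
  expect_identical(unpatchify(four)$image, s$image)
})

test_that("tiling round-trips over random divisible geometries", {
  for (seed in 1:4) {
    dims <- with_test_seed(seed, c(sample(1:5, 1), sample(1:5, 1)) * 64L)
    img <- with_test_seed(seed + 100,
                          array(runif(dims[1] * dims[2] * 3),
                                c(dims[1], dims[2], 3)))
    grid <- patchify(img, patch_size = 64)
    expect_length(grid$patches, prod(dims %/% 64L))
    expect_identical(unpatchify(grid)$image, img)
  }
})

test_that("non-divisible dimensions error unless padding is requested", {
  img <- array(0.5, c(300, 256, 3))
  expect_error(patchify(img, patch_size = 256), "not divisible")
  expect_message(grid <- patchify(img, patch_size = 256, pad = TRUE),
                 "padding")
  expect_length(grid$patches, 2L)
})

test_that("reconstruction is driven by positions, not list order", {
  s <- render_slide(small_spec(seed = 33))
  grid <- patchify(s$image, s$mask_m1)
  shuffled <- grid
  shuffled$patches <- with_test_seed(1, sample(grid$patches))
  expect_identical(unpatchify(shuffled)$image, unpatchify(grid)$image)

  missing <- grid
  missing$patches <- grid$patches[-2]
  expect_error(unpatchify(missing), "missing patch position")

  dup <- grid
  dup$patches[[2]] <- dup$patches[[1]]
  expect_error(unpatchify(dup), "duplicate patch position")
})

test_that("target filtering partitions patches and matches a pixel-scan oracle", {
  cohort <- render_cohort(4, seed = 51, canvas_width = 512,
                          canvas_height = 512)
  items <- unlist(lapply(seq_along(cohort), function(i)
    patchify(cohort[[i]]$image, cohort[[i]]$mask_m1,
             slide_id = names(cohort)[i])$patches), recursive = FALSE)
  parts <- filter_targetless(items, c("ganglion_cell", "normal_nerve"))
  expect_equal(length(parts$kept) + length(parts$excluded), length(items))

  oracle_kept <- 0L
  for (p in items) {
    hit <- FALSE
    for (v in c(1L, 2L)) if (any(p$mask$data == v)) hit <- TRUE
    if (hit) oracle_kept <- oracle_kept + 1L
  }
  expect_equal(length(parts$kept), oracle_kept)

  expect_error(filter_targetless(items, character(0)), "non-empty")
  expect_error(filter_targetless(items, "nonexistent_class"), "unknown class")
})

test_that("a single target pixel is enough to keep a patch", {
  img <- array(0.5, c(64, 64, 3))
  d <- matrix(0L, 64, 64); d[10, 10] <- 1L
  p_hit <- list(image = img, mask = multiclass_mask(d, "model1"),
                row = 1L, col = 1L, slide_id = "s")
  p_miss <- list(image = img,
                 mask = multiclass_mask(matrix(0L, 64, 64), "model1"),
                 row = 1L, col = 2L, slide_id = "s")
  parts <- filter_targetless(list(p_hit, p_miss),
                             c("ganglion_cell", "normal_nerve"))
  expect_length(parts$kept, 1L)
  expect_identical(parts$kept[[1]]$col, 1L)
})

test_that("background injection reaches the requested fraction exactly", {
  kept <- as.list(seq_len(90))
  pool <- as.list(900 + seq_len(50))
  out <- inject_background(kept, pool, 0.1, seed = 7)
  expect_length(out, 100L)
  expect_identical(out[1:90], kept)

  # brute-force oracle: largest k with k / (n + k) <= f
  for (n in c(10, 90, 137)) {
    for (f in c(0.05, 0.1, 0.25)) {
      k_oracle <- 0L
      while ((k_oracle + 1) / (n + k_oracle + 1) <= f) k_oracle <- k_oracle + 1L
      out <- inject_background(as.list(seq_len(n)),
                               as.list(seq_len(1000)), f, seed = 1)
      expect_length(out, n + k_oracle)
    }
  }

  expect_identical(inject_background(kept, pool, 0, seed = 1), kept)
  expect_identical(inject_background(kept, pool, 0.1, seed = 3),
                   inject_background(kept, pool, 0.1, seed = 3))
  expect_error(inject_background(kept, list(), 0.1), "empty")
  expect_error(inject_background(kept, pool, 1), "background_fraction")
})

test_that("the 80/20 split obeys the floor law and partitions its input", {
  for (n in c(930L, 1015L, 1945L, 5L)) {
    sp <- split_80_20(seq_len(n), seed = 1)
    expect_length(sp$train, floor(0.8 * n))
    expect_length(sp$validation, n - floor(0.8 * n))
    expect_setequal(c(sp$train, sp$validation), seq_len(n))
    expect_length(intersect(sp$train, sp$validation), 0L)
  }
  expect_equal(lengths(split_80_20(seq_len(930), seed = 2)),
               c(train = 744L, validation = 186L))
  expect_equal(lengths(split_80_20(seq_len(1015), seed = 2)),
               c(train = 812L, validation = 203L))
  expect_equal(lengths(split_80_20(seq_len(1945), seed = 2)),
               c(train = 1556L, validation = 389L))

  # size law over the full range
  n_all <- 2:10000
  expect_true(all(vapply(n_all, function(n) {
    ord <- floor(0.8 * n)
    ord >= 1 && (n - ord) >= 1
  }, logical(1))))
  for (n in with_test_seed(1, sample(2:10000, 25))) {
    sp <- split_80_20(seq_len(n), seed = n)
    expect_length(sp$train, floor(0.8 * n))
    expect_setequal(c(sp$train, sp$validation), seq_len(n))
  }

  expect_identical(split_80_20(1:10, seed = 5), split_80_20(1:10, seed = 5))
  expect_error(split_80_20(list(1), seed = 1), "at least 2")
})
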
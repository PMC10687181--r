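mask_with_pixels <- function(model_id, n_pixels, class = 1L, h = 256, w = 256) {
  d <- matrix(0L, h, w)
  if (n_pixels > 0) d[seq_len(n_pixels)] <- class
  multiclass_mask(d, model_id)
}

test_that("the decision table maps all four flag combinations", {
  expect_equal(call_zone(TRUE, FALSE), "ganglionic")
  expect_equal(call_zone(TRUE, TRUE), "transition")
  expect_equal(call_zone(FALSE, TRUE), "aganglionic")
  expect_equal(call_zone(FALSE, FALSE), "no_tissue")
  expect_equal(call_zone(c(TRUE, FALSE), c(TRUE, TRUE)),
               c("transition", "aganglionic"))
})

test_that("presence is an inclusive threshold on target pixels", {
  rule <- presence_rule(min_positive_pixels = 64)
  expect_false(detect_presence(mask_with_pixels("model2", 0), rule)$present)
  expect_true(detect_presence(mask_with_pixels("model2", 64), rule)$present)
  expect_false(detect_presence(mask_with_pixels("model2", 63), rule)$present)

  at <- detect_presence(mask_with_pixels("model1", 40, class = 1L),
                        presence_rule(40))
  expect_true(at$present)
  expect_equal(at$positive_pixels, 40L)
  expect_equal(unname(at$counts["ganglion_cell"]), 40L)
  expect_error(presence_rule(0), "min_positive_pixels")
})

test_that("model 1 presence pools its two positive classes unless restricted", {
  nerve_only <- mask_with_pixels("model1", 500, class = 2L)
  expect_true(detect_presence(nerve_only, presence_rule(64, "pooled"))$present)
  expect_false(detect_presence(nerve_only,
                               presence_rule(64, "ganglion_only"))$present)
})

test_that("presence is monotone non-increasing in the threshold", {
  for (seed in 1:5) {
    n_pix <- with_test_seed(seed, sample(0:300, 1))
    m <- mask_with_pixels("model2", n_pix)
    last <- TRUE
    for (thr in c(1, 32, 64, 128, 256)) {
      cur <- detect_presence(m, presence_rule(thr))$present
      if (!last) expect_false(cur)
      last <- cur
    }
  }
})

test_that("slide-level calls match a per-patch brute-force scan", {
  s <- render_slide(small_spec(c("ganglionic", "aganglionic"), seed = 91))
  rule <- presence_rule(64)
  report <- call_slide(s$mask_m1, s$mask_m2, rule, patch_size = 256,
                       slide_id = "truth-as-prediction")
  expect_equal(nrow(report$calls), 4L)
  expect_equal(sum(report$zone_counts), 4L)

  for (i in seq_len(nrow(report$calls))) {
    r <- report$calls$row[i]; cl <- report$calls$col[i]
    ys <- (r - 1) * 256 + 1:256; xs <- (cl - 1) * 256 + 1:256
    p1 <- sum(s$mask_m1$data[ys, xs] %in% c(1L, 2L))
    p2 <- sum(s$mask_m2$data[ys, xs] == 1L)
    expect_equal(report$calls$zone[i], call_zone(p1 >= 64, p2 >= 64))
    expect_equal(report$calls$review_flag[i],
                 report$calls$zone[i] == "transition")
  }
})

test_that("ideal masks on uniform slides give clean zone calls", {
  g <- render_slide(small_spec("ganglionic", seed = 92))
  rep_g <- call_slide(g$mask_m1, g$mask_m2, slide_id = "g")
  expect_true(all(rep_g$calls$zone == "ganglionic"))
  expect_equal(nrow(rep_g$review_patches), 0L)

  t <- render_slide(small_spec("transition", seed = 92))
  rep_t <- call_slide(t$mask_m1, t$mask_m2, slide_id = "t")
  expect_true(all(rep_t$calls$zone == "transition"))
  expect_true(all(rep_t$calls$review_flag))
  expect_equal(nrow(rep_t$review_patches), 4L)

  empty1 <- multiclass_mask(matrix(0L, 512, 512), "model1")
  empty2 <- multiclass_mask(matrix(0L, 512, 512), "model2")
  rep_e <- call_slide(empty1, empty2, slide_id = "e")
  expect_true(all(rep_e$calls$zone == "no_tissue"))

  expect_error(call_slide(empty1, multiclass_mask(matrix(0L, 256, 256),
                                                  "model2")), "size")
})

test_that("zone accuracy counts matching patches", {
  s <- render_slide(scene_spec(zone_layout = "ganglionic", seed = 93))
  report <- call_slide(s$mask_m1, s$mask_m2, slide_id = "g40")
  expect_equal(zone_accuracy(report, s$zone_truth), 1)

  wrong <- s$zone_truth
  wrong[1, 1:4] <- "aganglionic"   # 4 of 40 disagree
  expect_equal(zone_accuracy(report, wrong), 0.9)

  # loop oracle on an arbitrary report/truth pair
  truth <- matrix(with_test_seed(9, sample(c("ganglionic", "transition",
                                             "aganglionic"), 40, TRUE)),
                  5, 8)
  hits <- 0L
  for (i in 1:5) for (j in 1:8) {
    if (report$zone_grid[i, j] == truth[i, j]) hits <- hits + 1L
  }
  expect_equal(zone_accuracy(report, truth), hits / 40)

  expect_error(zone_accuracy(report, matrix("ganglionic", 2, 2)), "shape")
})

test_that("zone overlays tint called patches only", {
  s <- render_slide(small_spec("aganglionic", seed = 94))
  report <- call_slide(s$mask_m1, s$mask_m2, slide_id = "ov")
  ov <- zone_overlay(report, s$image)
  expect_equal(dim(ov), dim(s$image))
  expect_false(identical(ov, s$image))
})
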
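test_that("an empty scene renders pure background", {
  s <- render_slide(small_spec("ganglionic", n_ganglion_cells = 0,
                               n_normal_nerves = 0,
                               n_hypertrophic_nerves = 0))
  expect_equal(unname(mask_class_counts(s$mask_m1)[1]), 512L * 512L)
  expect_equal(unname(mask_class_counts(s$mask_m2)[1]), 512L * 512L)
})

test_that("requested ganglion cells appear as that many connected components", {
  s <- render_slide(small_spec("ganglionic", n_ganglion_cells = 3,
                               n_normal_nerves = 0,
                               n_hypertrophic_nerves = 0, seed = 11))
  expect_equal(count_components(s$mask_m1$data == 1L), 3)
})

test_that("zone layouts constrain which elements are rendered", {
  s <- render_slide(small_spec("aganglionic", seed = 3))
  counts1 <- mask_class_counts(s$mask_m1)
  counts2 <- mask_class_counts(s$mask_m2)
  expect_equal(unname(counts1["ganglion_cell"]), 0L)
  expect_gt(unname(counts2["hypertrophic_nerve"]), 0L)

  g <- render_slide(small_spec("ganglionic", seed = 3))
  expect_equal(unname(mask_class_counts(g$mask_m2)["hypertrophic_nerve"]), 0L)
  expect_gt(unname(mask_class_counts(g$mask_m1)["ganglion_cell"]), 0L)
})

test_that("inconsistent scene specs are rejected", {
  expect_error(scene_spec(500, 512), "multiple")
  expect_error(small_spec("aganglionic", n_ganglion_cells = 5),
               "ganglion cells requested")
  expect_error(small_spec(hypertrophic_nerve_width_range = c(5, 8)),
               "must exceed")
  expect_error(small_spec(artifact_rate = 1.5), "artifact_rate")
  expect_error(small_spec(zone_layout = c("ganglionic", "weird")),
               "zone_layout")
})

test_that("rendering is deterministic for a fixed spec", {
  a <- render_slide(small_spec(seed = 42))
  b <- render_slide(small_spec(seed = 42))
  expect_identical(a, b)
  c <- render_slide(small_spec(seed = 43))
  expect_false(identical(a$image, c$image))
})

test_that("zone consistency holds per patch across layouts and seeds", {
  layouts <- list("ganglionic", "aganglionic",
                  c("ganglionic", "transition"),
                  c("transition", "aganglionic"))
  for (seed in 1:3) {
    for (lay in layouts) {
      s <- render_slide(small_spec(lay, seed = seed))
      ps <- s$spec$patch_size
      for (r in seq_len(s$spec$n_rows)) {
        for (cl in seq_len(s$spec$n_cols)) {
          ys <- (r - 1L) * ps + seq_len(ps)
          xs <- (cl - 1L) * ps + seq_len(ps)
          zone <- s$zone_truth[r, cl]
          if (zone == "aganglionic") {
            expect_equal(sum(s$mask_m1$data[ys, xs] == 1L), 0L)
          }
          if (zone == "ganglionic") {
            expect_equal(sum(s$mask_m2$data[ys, xs] == 1L), 0L)
          }
        }
      }
    }
  }
})

test_that("hypertrophic nerves are measurably wider than normal nerves", {
  for (seed in c(5, 6)) {
    s <- render_slide(small_spec("transition", seed = seed))
    w_normal <- median_ribbon_width(s$mask_m1$data == 2L)
    w_hyper <- median_ribbon_width(s$mask_m2$data == 1L)
    expect_gt(w_hyper, w_normal)
  }
})

test_that("every labelled pixel is separable from the background colour", {
  s <- render_slide(small_spec("transition", seed = 8))
  labelled <- s$mask_m1$data > 0L | s$mask_m2$data > 0L
  bg_median <- apply(s$image, 3, function(ch) median(ch[!labelled]))
  d2 <- (s$image[, , 1] - bg_median[1])^2 +
    (s$image[, , 2] - bg_median[2])^2 +
    (s$image[, , 3] - bg_median[3])^2
  expect_gt(min(sqrt(d2[labelled])), he_colour_config()$contrast_threshold)
})

test_that("cohorts follow the requested zone mix and are reproducible", {
  counts <- table(attr(render_cohort(108, seed = 1, transform = function(s)
    NULL), "zones"))
  expect_equal(unname(counts[c("ganglionic", "transition", "aganglionic")]),
               c(36L, 36L, 36L), ignore_attr = TRUE)

  one <- render_cohort(1, c(ganglionic = 1), seed = 9,
                       canvas_width = 512, canvas_height = 512)
  direct <- render_slide(scene_spec(512, 512, "ganglionic",
                                    seed = hirschseg:::derive_seed(9, 1)))
  expect_identical(one[[1]], direct)

  a <- render_cohort(3, seed = 4, canvas_width = 512, canvas_height = 512)
  b <- render_cohort(3, seed = 4, canvas_width = 512, canvas_height = 512)
  expect_identical(a, b)

  expect_error(render_cohort(0), "n_slides")
  expect_error(render_cohort(2, c(ganglionic = -0.5, transition = 1.5)),
               "non-negative")
  expect_error(render_cohort(2, c(ganglionic = 0.4)), "sum to 1")
})

test_that("artifacts corrupt the image only, at the requested patch rate", {
  s <- render_slide(small_spec("transition", seed = 12))
  same <- apply_artifact(s, rate = 0, seed = 1)
  expect_identical(same$image, s$image)

  full <- apply_artifact(s, rate = 1, seed = 1)
  expect_equal(length(full$artifact$patches),
               s$spec$n_rows * s$spec$n_cols)
  expect_false(identical(full$image, s$image))
  expect_identical(full$mask_m1, s$mask_m1)
  expect_identical(full$mask_m2, s$mask_m2)

  half <- apply_artifact(s, rate = 0.5, seed = 2)
  expect_equal(length(half$artifact$patches), 2L)  # round(0.5 * 4)
  expect_identical(half, apply_artifact(s, rate = 0.5, seed = 2))
  expect_error(apply_artifact(s, rate = -0.1), "rate")
})
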
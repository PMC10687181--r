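# Shared fixtures. Everything is generated in code; small canvases keep the
# default run fast while exercising the same code paths as full-size slides.

small_spec <- function(zone = "transition", seed = 1L, ...) {
  scene_spec(canvas_width = 512L, canvas_height = 512L, zone_layout = zone,
             seed = seed, ...)
}

# random valid mask for a model palette
random_mask <- function(model_id, h = 64L, w = 64L, seed = 1L) {
  pal <- class_palette(model_id)
  k <- nrow(pal$entries)
  data <- with_test_seed(seed, matrix(sample(0:(k - 1L), h * w, replace = TRUE),
                                      h, w))
  multiclass_mask(data, pal)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# independent connected-component count (flood-fill oracle via EBImage)
count_components <- function(binary_matrix) {
  max(EBImage::bwlabel(EBImage::Image(binary_matrix * 1)))
}

# independent ribbon-width estimate: twice the median distance-to-background
# over the element's pixels (distance-transform oracle)
median_ribbon_width <- function(binary_matrix) {
  d <- EBImage::distmap(EBImage::Image(binary_matrix * 1))
  2 * stats::median(d[binary_matrix])
}

# Desk-scale models shared by the acceptance tests: trained once per session
# on a 24-slide cohort (1024x512 canvases, equal zone mix), cached.
.desk_cache <- new.env(parent = emptyenv())

desk_cohort <- function() {
  if (is.null(.desk_cache$cohort)) {
    .desk_cache$cohort <- render_cohort(
      24, seed = 101L, canvas_width = 1024L, canvas_height = 512L)
  }
  .desk_cache$cohort
}

desk_models <- function() {
  if (is.null(.desk_cache$fits)) {
    t0 <- proc.time()
    fits <- list()
    for (mid in c("model1", "model2")) {
      ds <- build_model_dataset(desk_cohort(), mid,
                                background_fraction = 0.1, seed = 202L)
      fits[[mid]] <- train_segmenter(
        build_unet(unet_config(mid, depth = 3L, base_filters = 16L,
                               seed = 303L)),
        ds,
        training_config(epochs = 3L, batch_size = 4L, learning_rate = 1e-3,
                        class_weights = "balanced", seed = 404L))
    }
    .desk_cache$fits <- fits
    .desk_cache$train_minutes <- (proc.time() - t0)[["elapsed"]] / 60
  }
  .desk_cache$fits
}

desk_train_minutes <- function() {
  desk_models()
  .desk_cache$train_minutes
}
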
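#' Assemble a per-model training dataset from a slide cohort
#'
#' Runs the dataset-curation pipeline for one model: tile every slide into
#' patches, keep patches containing that model's target classes, inject a
#' fraction of targetless (background) patches, and split 80/20 into
#' train/validation. Model 1 patches carry the ganglion-cell/normal-nerve
#' mask; model 2 patches the hypertrophic-nerve mask. All counts are
#' recorded so the accounting of a run can be audited.
#'
#' @param slides List of `rendered_slide`s (e.g. from [render_cohort()] or
#'   [expand_cohort()]).
#' @param model_id `"model1"` or `"model2"`.
#' @param background_fraction Share of background patches injected into
#'   the dataset (default 0.10).
#' @param seed Seed for injection and the split.
#' @param patch_size Patch edge (256).
#' @return A `model_dataset`: list with `model_id`, `train`, `validation`
#'   (patch-item lists), and `counts` (patches, excluded, kept, injected,
#'   total, train, validation).
#' @export
build_model_dataset <- function(slides, model_id = c("model1", "model2"),
                                background_fraction = 0.10, seed = 1L,
                                patch_size = 256L) {
  model_id <- match.arg(model_id)
  mask_field <- if (model_id == "model1") "mask_m1" else "mask_m2"
  targets <- if (model_id == "model1") c("ganglion_cell", "normal_nerve")
             else "hypertrophic_nerve"
  items <- list()
  for (i in seq_along(slides)) {
    s <- slides[[i]]
    sid <- names(slides)[i] %||% sprintf("slide_%03d", i)
    grid <- patchify(s$image, s[[mask_field]], patch_size = patch_size,
                     slide_id = sid)
    items <- c(items, grid$patches)
  }
  n_patches <- length(items)
  parts <- filter_targetless(items, targets)
  dataset <- inject_background(parts$kept, parts$excluded,
                               background_fraction,
                               seed = derive_seed(seed, 1L))
  split <- split_80_20(dataset, seed = derive_seed(seed, 2L))
  structure(list(
    model_id = model_id,
    train = split$train,
    validation = split$validation,
    counts = c(patches = n_patches,
               excluded = length(parts$excluded),
               kept = length(parts$kept),
               injected = length(dataset) - length(parts$kept),
               total = length(dataset),
               train = length(split$train),
               validation = length(split$validation))
  ), class = "model_dataset")
}

#' @export
print.model_dataset <- function(x, ...) {
  cat(sprintf("<model_dataset %s: %d train / %d validation>\n",
              x$model_id, length(x$train), length(x$validation)))
  print(x$counts)
  invisible(x)
}
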
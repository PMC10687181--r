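#' Multiclass segmentation masks
#'
#' A `multiclass_mask` pairs an integer class map (one class index per
#' pixel) with the [class_palette()] that gives those indices meaning.
#' Every pixel value must be a valid index of the palette.
#'
#' @param data Integer matrix (height x width) of class indices.
#' @param palette A [class_palette()] or a model id string.
#' @return A `multiclass_mask` object.
#' @examples
#' m <- multiclass_mask(matrix(0L, 4, 4), "model1")
#' mask_class_counts(m)
#' @export
multiclass_mask <- function(data, palette) {
  if (is.character(palette)) palette <- class_palette(palette)
  if (!inherits(palette, "class_palette")) {
    stopf("`palette` must be a class_palette or model id")
  }
  if (!is.matrix(data)) stopf("mask `data` must be a matrix")
  storage.mode(data) <- "integer"
  validate_mask_values(data, palette)
  structure(list(data = data, palette = palette), class = "multiclass_mask")
}

# internal fast path: trusted callers (the renderer, patch extraction)
# construct masks whose values are valid by construction
new_mask <- function(data, palette) {
  structure(list(data = data, palette = palette), class = "multiclass_mask")
}

validate_mask_values <- function(data, palette) {
  # palette indices are consecutive from 0, so validity is a range check
  # (cheap enough for whole-slide masks)
  hi <- max(palette$entries$index)
  if (min(data) < 0L || max(data) > hi) {
    bad <- setdiff(unique(as.vector(data)), palette$entries$index)
    stopf("mask contains value(s) outside the %s palette (0..%d): %s",
          palette$model_id, hi, paste(sort(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.multiclass_mask <- function(x, ...) {
  cat(sprintf("<multiclass_mask %dx%d, palette %s>\n",
              nrow(x$data), ncol(x$data), format(x$palette)))
  print(mask_class_counts(x))
  invisible(x)
}

#' @export
dim.multiclass_mask <- function(x) dim(x$data)

#' Per-class pixel counts of a mask
#'
#' @param mask A [multiclass_mask()].
#' @return Named integer vector, one entry per palette class.
#' @export
mask_class_counts <- function(mask) {
  stopifnot(inherits(mask, "multiclass_mask"))
  idx <- mask$palette$entries$index
  counts <- vapply(idx, function(i) sum(mask$data == i), integer(1))
  names(counts) <- mask$palette$entries$name
  counts
}

#' One-hot encoding of a mask
#'
#' Expands a class-index map into one binary plane per palette class; the
#' planes partition the pixels, so they sum to exactly 1 everywhere. This
#' is the target representation consumed by the pixel-wise cross-entropy
#' loss during training.
#'
#' @param mask A [multiclass_mask()].
#' @return Numeric array height x width x n_classes of 0/1 values.
#' @export
mask_to_onehot <- function(mask) {
  stopifnot(inherits(mask, "multiclass_mask"))
  k <- n_classes(mask$palette)
  d <- dim(mask$data)
  out <- array(0, dim = c(d[1], d[2], k))
  for (i in seq_len(k)) {
    cls <- mask$palette$entries$index[i]
    plane <- matrix(0, d[1], d[2])
    plane[mask$data == cls] <- 1
    out[, , i] <- plane
  }
  out
}

# Render a mask to RGB display colours (used by plot methods and overlays).
mask_to_rgb <- function(mask) {
  e <- mask$palette$entries
  d <- dim(mask$data)
  out <- array(0, dim = c(d[1], d[2], 3))
  pos <- match(as.vector(mask$data), e$index)
  out[, , 1] <- matrix(e$r[pos] / 255, d[1], d[2])
  out[, , 2] <- matrix(e$g[pos] / 255, d[1], d[2])
  out[, , 3] <- matrix(e$b[pos] / 255, d[1], d[2])
  out
}
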
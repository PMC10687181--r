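#' Read a slide image
#'
#' Reads a PNG or TIFF RGB image into a height x width x 3 numeric array on
#' `[0, 1]`, snapped to 8-bit levels. 16-bit inputs are rescaled to 8 bits
#' with a warning; non-RGB (grayscale or RGBA beyond an opaque alpha
#' channel) inputs are rejected.
#'
#' @param path File path ending in `.png`, `.tif`, or `.tiff`.
#' @return Numeric array height x width x 3.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    info <- attr(img, "info")
    if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8) {
      warning("16-bit PNG rescaled to 8-bit", call. = FALSE)
    }
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)     # always scaled to [0, 1]
    # values off the 8-bit grid reveal a deeper bit depth
    if (max(abs(img * 255 - round(img * 255))) > 1e-6) {
      warning("16-bit TIFF rescaled to 8-bit", call. = FALSE)
    }
  } else {
    stopf("unsupported image format '%s' (PNG/TIFF only)", ext)
  }
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  if (!is_rgb_image(img)) {
    stopf("expected an RGB image, got dimensions [%s]",
          paste(dim(img), collapse = "x"))
  }
  quantize8(img)
}

#' Write a slide image
#'
#' Writes an RGB array on `[0, 1]` as 8-bit PNG or TIFF, chosen by the file
#' extension.
#'
#' @param image Numeric array height x width x 3 on `[0, 1]`.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!is_rgb_image(image)) stopf("`image` must be height x width x 3")
  image <- quantize8(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 8L)
  } else {
    stopf("unsupported image format '%s' (PNG/TIFF only)", ext)
  }
  invisible(path)
}

#' Write / read multiclass masks
#'
#' Masks are stored as single-channel images whose pixel values are the raw
#' class indices, plus a JSON palette sidecar (`<path>.palette.json`). PNG
#' is the default container; a TIFF writer is available via the extension.
#' The round trip is lossless: `read_mask(write_mask(m), palette)` equals
#' `m` element-wise. On read, any pixel value outside the palette raises a
#' validation error naming the offending value.
#'
#' @param mask A [multiclass_mask()].
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param sidecar Write the JSON palette sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, sidecar = TRUE) {
  stopifnot(inherits(mask, "multiclass_mask"))
  ext <- tolower(tools::file_ext(path))
  scaled <- mask$data / 255
  if (ext == "png") {
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
  } else {
    stopf("unsupported mask format '%s' (PNG/TIFF only)", ext)
  }
  if (sidecar) write_palette(mask$palette, paste0(path, ".palette.json"))
  invisible(path)
}

#' @rdname write_mask
#' @param palette A [class_palette()] or model id giving the expected
#'   encoding of the stored mask.
#' @export
read_mask <- function(path, palette) {
  if (is.character(palette)) palette <- class_palette(palette)
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stopf("unsupported mask format '%s' (PNG/TIFF only)", ext)
  }
  if (length(dim(raw)) == 3L) {
    stopf("mask file %s is multi-channel; expected single-channel indices",
          path)
  }
  data <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  multiclass_mask(data, palette)
}

#' @rdname write_mask
#' @export
write_palette <- function(palette, path) {
  stopifnot(inherits(palette, "class_palette"))
  obj <- list(
    model_id = palette$model_id,
    entries = lapply(seq_len(nrow(palette$entries)), function(i) {
      e <- palette$entries[i, ]
      list(index = e$index, name = e$name, rgb = c(e$r, e$g, e$b))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_palette <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pal <- class_palette(obj$model_id)
  stored <- vapply(obj$entries, function(e) e$name, character(1))
  if (!identical(stored, pal$entries$name)) {
    stopf("palette sidecar %s does not match the frozen %s encoding",
          path, obj$model_id)
  }
  pal
}
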
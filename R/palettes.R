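#' Class palettes for the two segmentation models
#'
#' The pipeline uses two fixed class encodings. Model 1 segments ganglion
#' cells and normal nerves against background (three classes); model 2
#' segments hypertrophic nerves against background (two classes). Class
#' index 0 is always background, indices are consecutive, and the display
#' colours (blue background; red ganglion cells; green normal nerves;
#' bordeaux hypertrophic nerves) are presentation metadata only — class
#' semantics live in the indices.
#'
#' @param model_id `"model1"` or `"model2"`.
#' @return A `class_palette`: list with `model_id` and an `entries`
#'   data.frame (`index`, `name`, `r`, `g`, `b`).
#' @examples
#' class_palette("model1")$entries$name
#' @export
class_palette <- function(model_id = c("model1", "model2")) {
  model_id <- match.arg(model_id)
  entries <- if (model_id == "model1") {
    data.frame(
      index = 0:2,
      name = c("background", "ganglion_cell", "normal_nerve"),
      r = c(0L, 255L, 0L), g = c(0L, 0L, 200L), b = c(255L, 0L, 0L),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      index = 0:1,
      name = c("background", "hypertrophic_nerve"),
      r = c(0L, 109L), g = c(0L, 7L), b = c(255L, 26L),
      stringsAsFactors = FALSE
    )
  }
  structure(list(model_id = model_id, entries = entries),
            class = "class_palette")
}

n_classes <- function(palette) nrow(palette$entries)

#' @export
print.class_palette <- function(x, ...) {
  cat(sprintf("<class_palette %s: %d classes>\n", x$model_id,
              nrow(x$entries)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' @export
format.class_palette <- function(x, ...) {
  paste0(x$model_id, "[", paste(x$entries$name, collapse = ","), "]")
}

palette_class_index <- function(palette, names) {
  idx <- match(names, palette$entries$name)
  if (anyNA(idx)) {
    stopf("unknown class name(s) for %s: %s", palette$model_id,
          paste(names[is.na(idx)], collapse = ", "))
  }
  palette$entries$index[idx]
}
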
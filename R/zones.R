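#' Presence rule: when does a patch count as "segmented"?
#'
#' A patch is called positive under a model when its predicted mask holds
#' at least `min_positive_pixels` pixels of the model's target classes.
#' The default threshold of 64 pixels (about 0.1% of a 256x256 patch)
#' keeps single-pixel noise from flipping zone calls. For model 1 the two
#' positive classes are pooled by default (`m1_mode = "pooled"`: either
#' ganglion cells or normal nerves trigger presence); `m1_mode =
#' "ganglion_only"` restricts presence to ganglion cells, the stricter
#' reading under which transition patches show ganglion cells
#' specifically.
#'
#' @param min_positive_pixels Pixel threshold (>= 1).
#' @param m1_mode `"pooled"` or `"ganglion_only"`.
#' @return A `presence_rule`.
#' @export
presence_rule <- function(min_positive_pixels = 64L,
                          m1_mode = c("pooled", "ganglion_only")) {
  m1_mode <- match.arg(m1_mode)
  min_positive_pixels <- as.integer(min_positive_pixels)
  if (min_positive_pixels < 1L) stopf("min_positive_pixels must be >= 1")
  structure(list(
    min_positive_pixels = min_positive_pixels,
    m1_mode = m1_mode,
    targets = list(
      model1 = if (m1_mode == "pooled") c("ganglion_cell", "normal_nerve")
               else "ganglion_cell",
      model2 = "hypertrophic_nerve")
  ), class = "presence_rule")
}

#' Detect target presence in a predicted patch mask
#'
#' @param mask A [multiclass_mask()] (model 1 or model 2 palette).
#' @param rule A [presence_rule()].
#' @return List with `present` (logical), `positive_pixels` (total target
#'   pixels), and `counts` (per-class pixel counts).
#' @export
detect_presence <- function(mask, rule = presence_rule()) {
  stopifnot(inherits(mask, "multiclass_mask"), inherits(rule, "presence_rule"))
  model_id <- mask$palette$model_id
  targets <- rule$targets[[model_id]]
  if (is.null(targets)) stopf("no presence targets for palette %s", model_id)
  counts <- mask_class_counts(mask)
  pos <- sum(counts[targets])
  list(present = pos >= rule$min_positive_pixels,
       positive_pixels = as.integer(pos),
       counts = counts)
}

#' The two-model zone decision table
#'
#' Combines per-patch presence flags from the two models into a zone call:
#' model 1 positive alone is ganglionic tissue, model 2 positive alone is
#' aganglionic tissue, both positive is the transition zone (flagged for
#' pathologist review), and neither positive is background with no tissue
#' elements. Vectorised over its arguments.
#'
#' @param m1_present,m2_present Logical flags (recycled to a common
#'   length).
#' @return Character vector of zone calls in
#'   `c("ganglionic", "transition", "aganglionic", "no_tissue")`.
#' @export
call_zone <- function(m1_present, m2_present) {
  n <- max(length(m1_present), length(m2_present))
  m1 <- rep_len(as.logical(m1_present), n)
  m2 <- rep_len(as.logical(m2_present), n)
  ifelse(m1 & m2, "transition",
         ifelse(m1, "ganglionic",
                ifelse(m2, "aganglionic", "no_tissue")))
}

#' Call zones for every patch of a slide
#'
#' Tiles the two model predictions into the patch grid, applies the
#' presence rule per patch, and combines the flags through [call_zone()].
#' Transition patches carry `review_flag = TRUE` — these are the patches a
#' pathologist must scrutinise.
#'
#' @param m1_mask,m2_mask Whole-slide [multiclass_mask()]s from model 1
#'   and model 2, of identical dimensions divisible by `patch_size`.
#' @param rule A [presence_rule()].
#' @param patch_size Patch edge (256).
#' @param slide_id Identifier recorded in the report.
#' @return A `slide_zone_report`: list with `slide_id`, `calls` (one row
#'   per patch: `row`, `col`, per-model positive-pixel counts and flags,
#'   `zone`, `review_flag`), `zone_grid` (n_rows x n_cols character
#'   matrix), `zone_counts`, and `review_patches`.
#' @export
call_slide <- function(m1_mask, m2_mask, rule = presence_rule(),
                       patch_size = 256L, slide_id = "slide") {
  stopifnot(inherits(m1_mask, "multiclass_mask"),
            inherits(m2_mask, "multiclass_mask"))
  if (!identical(dim(m1_mask$data), dim(m2_mask$data))) {
    stopf("model masks differ in size: [%s] vs [%s]",
          paste(dim(m1_mask$data), collapse = "x"),
          paste(dim(m2_mask$data), collapse = "x"))
  }
  ps <- as.integer(patch_size)
  H <- nrow(m1_mask$data); W <- ncol(m1_mask$data)
  if (H %% ps != 0L || W %% ps != 0L) {
    stopf("slide %dx%d is not divisible by patch size %d", H, W, ps)
  }
  n_rows <- H %/% ps; n_cols <- W %/% ps
  t1 <- palette_class_index(m1_mask$palette, rule$targets$model1)
  t2 <- palette_class_index(m2_mask$palette, rule$targets$model2)
  calls <- vector("list", n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows)) {
    for (cl in seq_len(n_cols)) {
      ys <- (r - 1L) * ps + seq_len(ps)
      xs <- (cl - 1L) * ps + seq_len(ps)
      p1 <- sum(m1_mask$data[ys, xs] %in% t1)
      p2 <- sum(m2_mask$data[ys, xs] %in% t2)
      m1p <- p1 >= rule$min_positive_pixels
      m2p <- p2 >= rule$min_positive_pixels
      zone <- call_zone(m1p, m2p)
      k <- k + 1L
      calls[[k]] <- data.frame(slide_id = slide_id, row = r, col = cl,
                               m1_positive_pixels = p1,
                               m2_positive_pixels = p2,
                               m1_present = m1p, m2_present = m2p,
                               zone = zone,
                               review_flag = zone == "transition",
                               stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, calls)
  zone_grid <- matrix(NA_character_, n_rows, n_cols)
  zone_grid[cbind(calls$row, calls$col)] <- calls$zone
  zone_counts <- vapply(ZONES_CALL, function(z) sum(calls$zone == z),
                        integer(1))
  structure(list(slide_id = slide_id, calls = calls, zone_grid = zone_grid,
                 zone_counts = zone_counts,
                 review_patches = calls[calls$review_flag,
                                        c("row", "col"), drop = FALSE],
                 rule = rule),
            class = "slide_zone_report")
}

#' @export
print.slide_zone_report <- function(x, ...) {
  cat(sprintf("<slide_zone_report '%s': %d patches>\n", x$slide_id,
              nrow(x$calls)))
  print(x$zone_counts)
  if (nrow(x$review_patches)) {
    cat(sprintf("  %d transition patch(es) flagged for pathologist review\n",
                nrow(x$review_patches)))
  }
  invisible(x)
}

#' Fraction of patches whose zone call matches the truth
#'
#' @param report A [call_slide()] report.
#' @param zone_truth Character matrix of true per-patch zones with the
#'   report's grid shape.
#' @param exclude_no_tissue Drop patches called `no_tissue` before
#'   scoring (useful when the truth grid has no background-only label).
#' @return Numeric fraction in `[0, 1]`.
#' @export
zone_accuracy <- function(report, zone_truth, exclude_no_tissue = FALSE) {
  stopifnot(inherits(report, "slide_zone_report"))
  if (!identical(dim(report$zone_grid), dim(zone_truth))) {
    stopf("zone grids differ in shape: [%s] vs [%s]",
          paste(dim(report$zone_grid), collapse = "x"),
          paste(dim(zone_truth), collapse = "x"))
  }
  called <- as.vector(report$zone_grid)
  truth <- as.vector(zone_truth)
  if (exclude_no_tissue) {
    keep <- called != "no_tissue"
    called <- called[keep]; truth <- truth[keep]
    if (!length(called)) return(NA_real_)
  }
  mean(called == truth)
}

#' Colour overlay of zone calls on a slide image
#'
#' @param report A [call_slide()] report.
#' @param image The slide RGB array the report was computed from.
#' @param alpha Blend weight of the zone tint.
#' @return RGB array with each patch tinted by its zone call (ganglionic
#'   green, transition amber, aganglionic red, no_tissue untinted).
#' @export
zone_overlay <- function(report, image, alpha = 0.3) {
  stopifnot(inherits(report, "slide_zone_report"), is_rgb_image(image))
  tint <- list(ganglionic = c(0.1, 0.7, 0.2),
               transition = c(0.95, 0.7, 0.1),
               aganglionic = c(0.85, 0.15, 0.15))
  ps <- nrow(image) %/% nrow(report$zone_grid)
  out <- image
  for (i in seq_len(nrow(report$calls))) {
    z <- report$calls$zone[i]
    if (z == "no_tissue") next
    ys <- (report$calls$row[i] - 1L) * ps + seq_len(ps)
    xs <- (report$calls$col[i] - 1L) * ps + seq_len(ps)
    for (ch in 1:3) {
      out[ys, xs, ch] <- (1 - alpha) * out[ys, xs, ch] + alpha * tint[[z]][ch]
    }
  }
  quantize8(out)
}
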
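#' Reference colour moments for colour normalisation
#'
#' Per-channel target means and standard deviations used by the
#' `colour_norm` augmentation op. The defaults are the moments of the
#' synthetic H&E background model; any reference can be supplied.
#'
#' @return List with numeric `mean` and `sd`, each length 3 (R, G, B).
#' @export
he_reference_moments <- function() {
  list(mean = c(0.89, 0.72, 0.80), sd = c(0.06, 0.08, 0.07))
}

AUGMENT_OPS <- c("hflip", "vflip", "rot90", "rot180", "rot270", "colour_norm")

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

apply_geom_matrix <- function(m, op) {
  switch(op,
    hflip = m[, ncol(m):1, drop = FALSE],
    vflip = m[nrow(m):1, , drop = FALSE],
    rot90 = rot90cw(m),
    rot180 = m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270 = rot90cw(rot90cw(rot90cw(m))),
    stopf("unknown geometric op '%s'", op)
  )
}

apply_geom_image <- function(image, op) {
  planes <- lapply(1:3, function(ch) apply_geom_matrix(image[, , ch], op))
  array(unlist(planes), c(dim(planes[[1]]), 3))
}

colour_norm_image <- function(image, reference) {
  out <- image
  for (ch in 1:3) {
    v <- image[, , ch]
    mu <- mean(v)
    sig <- sqrt(mean((v - mu)^2))      # population sd
    if (sig < 1e-12) sig <- 1e-12
    out[, , ch] <- (v - mu) / sig * reference$sd[ch] + reference$mean[ch]
  }
  out
}

#' Augment an image/mask pair
#'
#' Applies the listed ops in order. Geometric ops (`hflip`, `vflip`,
#' `rot90`, `rot180`, `rot270`) are applied identically to image and mask,
#' so the pair stays pixel-aligned and the mask class histogram is
#' preserved; rotations are restricted to 90-degree multiples precisely so
#' masks never need interpolation. `colour_norm` matches the image's
#' per-channel mean/sd to `reference` and leaves the mask untouched. With
#' `ops = NULL` a random non-empty op combination is drawn from `seed`
#' (random flip/rotation plus colour normalisation).
#'
#' @param image RGB array.
#' @param mask Optional [multiclass_mask()] of matching size.
#' @param ops Character vector of ops, a subset of
#'   `c("hflip","vflip","rot90","rot180","rot270","colour_norm")`, or
#'   `NULL` for a seeded random choice.
#' @param seed Used only when `ops = NULL`.
#' @param reference Colour target, see [he_reference_moments()].
#' @return List with `image`, `mask`, and `ops` (the ops applied).
#' @export
augment <- function(image, mask = NULL, ops = NULL, seed = 1L,
                    reference = he_reference_moments()) {
  if (!is_rgb_image(image)) stopf("`image` must be height x width x 3")
  if (is.null(ops)) ops <- with_seed(seed, sample_augment_ops(square = dim(image)[1] == dim(image)[2]))
  bad <- setdiff(ops, AUGMENT_OPS)
  if (length(bad)) stopf("unknown augmentation op(s): %s", paste(bad, collapse = ", "))
  if (dim(image)[1] != dim(image)[2] && any(ops %in% c("rot90", "rot270"))) {
    stopf("rot90/rot270 require square inputs; use rot180 or flips for %dx%d",
          dim(image)[1], dim(image)[2])
  }
  for (op in ops) {
    if (op == "colour_norm") {
      image <- colour_norm_image(image, reference)
    } else {
      image <- apply_geom_image(image, op)
      if (!is.null(mask)) {
        mask <- multiclass_mask(apply_geom_matrix(mask$data, op), mask$palette)
      }
    }
  }
  list(image = image, mask = mask, ops = ops)
}

# Non-empty random op combo; geometric part from the shape-preserving set
# unless the input is square.
sample_augment_ops <- function(square) {
  geom_pool <- if (square) c("hflip", "vflip", "rot90", "rot180", "rot270")
               else c("hflip", "vflip", "rot180")
  geom <- sample(c(geom_pool, NA_character_), 1)
  colour <- runif(1) < 0.5
  ops <- c(if (!is.na(geom)) geom, if (colour) "colour_norm")
  if (!length(ops)) ops <- sample(geom_pool, 1)   # never the identity
  ops
}

augment_slide <- function(slide, ops, reference = he_reference_moments()) {
  img <- slide$image
  m1 <- slide$mask_m1$data
  m2 <- slide$mask_m2$data
  zones <- slide$zone_truth
  for (op in ops) {
    if (op == "colour_norm") {
      img <- colour_norm_image(img, reference)
    } else {
      img <- apply_geom_image(img, op)
      m1 <- apply_geom_matrix(m1, op)
      m2 <- apply_geom_matrix(m2, op)
      zones <- apply_geom_matrix(zones, op)
    }
  }
  out <- slide
  out$image <- quantize8(img)
  out$mask_m1 <- multiclass_mask(m1, "model1")
  out$mask_m2 <- multiclass_mask(m2, "model2")
  out$zone_truth <- zones
  attr(out, "augmented_with") <- ops
  out
}

#' Expand a slide cohort by augmentation
#'
#' Each input slide yields itself plus `factor - 1` augmented variants
#' (seeded random combinations of flips, 180-degree rotation, and colour
#' normalisation — the shape-preserving subset, since slides are not
#' square). With the default factor of 5 this reproduces the 108 -> 540
#' slide expansion.
#'
#' @param slides List of `rendered_slide`s.
#' @param factor Expansion factor (>= 1).
#' @param seed Seed for the per-variant op draws.
#' @return List of `factor * length(slides)` slides, originals first
#'   within each slide's block; `zones` attribute expanded to match.
#' @export
expand_cohort <- function(slides, factor = 5L, seed = 1L) {
  if (factor < 1) stopf("expansion factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(slides)
  out <- vector("list", length(slides) * factor)
  out_names <- character(length(out))
  in_names <- names(slides) %||% sprintf("slide_%03d", seq_along(slides))
  zones <- character(length(out))
  combos <- list("hflip", "vflip", "rot180",
                 c("hflip", "colour_norm"), c("vflip", "colour_norm"),
                 c("rot180", "colour_norm"), "colour_norm")
  k <- 0L
  for (i in seq_along(slides)) {
    slide <- slides[[i]]
    zone <- (attr(slides, "zones") %||% rep(NA_character_, length(slides)))[i]
    k <- k + 1L
    out[[k]] <- slide
    out_names[k] <- in_names[i]
    zones[k] <- zone
    picks <- with_seed(derive_seed(seed, i), {
      n_var <- factor - 1L
      sample(seq_along(combos), n_var, replace = n_var > length(combos))
    })
    for (j in seq_along(picks)) {
      k <- k + 1L
      out[[k]] <- augment_slide(slide, combos[[picks[j]]])
      out_names[k] <- sprintf("%s_aug%d", in_names[i], j)
      zones[k] <- zone
    }
  }
  names(out) <- out_names
  attr(out, "zones") <- zones
  out
}
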
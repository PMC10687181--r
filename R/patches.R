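#' Tile a slide into fixed-size patches
#'
#' Partitions an image (and optionally its mask) into a non-overlapping
#' row-major grid of square patches. For the standard 2048 x 1280 slide at
#' patch size 256 this yields the 8 x 5 = 40 patch grid. Dimensions that
#' do not divide the patch size are an error unless `pad = TRUE`, which
#' pads to the next multiple with background (and reports the padding).
#'
#' @param image RGB array height x width x 3.
#' @param mask Optional [multiclass_mask()] of identical dimensions.
#' @param patch_size Patch edge in pixels (default 256).
#' @param slide_id Identifier carried into every patch.
#' @param pad Pad to the next multiple instead of erroring.
#' @return A `patch_grid`: list with `slide_id`, `patch_size`, `n_rows`,
#'   `n_cols`, and `patches`, a row-major list of items each holding
#'   `image`, `mask` (or `NULL`), `row`, `col`, `slide_id`.
#' @export
patchify <- function(image, mask = NULL, patch_size = 256L,
                     slide_id = "slide", pad = FALSE) {
  if (!is_rgb_image(image)) stopf("`image` must be height x width x 3")
  ps <- as.integer(patch_size)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "multiclass_mask"))
    if (!identical(dim(mask$data), dim(image)[1:2])) {
      stopf("mask dimensions [%s] do not match image [%s]",
            paste(dim(mask$data), collapse = "x"), paste(H, W, sep = "x"))
    }
  }
  if (H %% ps != 0L || W %% ps != 0L) {
    if (!pad) {
      stopf("image %dx%d is not divisible by patch size %d (use pad = TRUE to pad)",
            H, W, ps)
    }
    H2 <- as.integer(ceiling(H / ps) * ps); W2 <- as.integer(ceiling(W / ps) * ps)
    message(sprintf("padding %dx%d to %dx%d", H, W, H2, W2))
    img2 <- array(0, c(H2, W2, 3))
    img2[seq_len(H), seq_len(W), ] <- image
    image <- img2
    if (!is.null(mask)) {
      d2 <- matrix(0L, H2, W2)
      d2[seq_len(H), seq_len(W)] <- mask$data
      mask <- multiclass_mask(d2, mask$palette)
    }
    H <- H2; W <- W2
  }
  n_rows <- H %/% ps; n_cols <- W %/% ps
  tiles <- .extract_tiles3(image, H, W, ps)
  mtiles <- if (is.null(mask)) NULL else .extract_tiles2(mask$data, ps)
  patches <- vector("list", n_rows * n_cols)
  k <- 0L
  for (r in seq_len(n_rows)) {
    for (cl in seq_len(n_cols)) {
      k <- k + 1L
      patches[[k]] <- list(
        image = tiles[[k]],
        mask = if (is.null(mask)) NULL else
          new_mask(mtiles[[k]], mask$palette),
        row = r, col = cl, slide_id = slide_id
      )
    }
  }
  structure(list(slide_id = slide_id, patch_size = ps,
                 n_rows = n_rows, n_cols = n_cols, patches = patches),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid '%s': %dx%d patches of %d px (%d total)>\n",
              x$slide_id, x$n_cols, x$n_rows, x$patch_size,
              length(x$patches)))
  invisible(x)
}

#' Reassemble a slide from its patch grid
#'
#' Exact inverse of [patchify()]: placement is driven by each patch's
#' `(row, col)` origin, not list order, so a shuffled patch list
#' reconstructs identically. Missing or duplicated grid positions are an
#' error naming the offending positions.
#'
#' @param grid A `patch_grid` (its `patches` may be reordered).
#' @return List with `image` and `mask` (`NULL` if patches carry none).
#' @export
unpatchify <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  ps <- grid$patch_size
  key <- vapply(grid$patches, function(p) paste(p$row, p$col), character(1))
  want <- as.vector(outer(seq_len(grid$n_rows), seq_len(grid$n_cols), paste))
  dup <- unique(key[duplicated(key)])
  miss <- setdiff(want, key)
  if (length(dup)) stopf("duplicate patch position(s): (%s)",
                         paste(dup, collapse = "), ("))
  if (length(miss)) stopf("missing patch position(s): (%s)",
                          paste(miss, collapse = "), ("))
  H <- grid$n_rows * ps; W <- grid$n_cols * ps
  image <- array(0, c(H, W, 3))
  has_mask <- !is.null(grid$patches[[1]]$mask)
  mdat <- if (has_mask) matrix(0L, H, W) else NULL
  palette <- if (has_mask) grid$patches[[1]]$mask$palette else NULL
  for (p in grid$patches) {
    ys <- (p$row - 1L) * ps + seq_len(ps)
    xs <- (p$col - 1L) * ps + seq_len(ps)
    image[ys, xs, ] <- p$image
    if (has_mask) mdat[ys, xs] <- p$mask$data
  }
  list(image = image,
       mask = if (has_mask) multiclass_mask(mdat, palette) else NULL)
}

#' Partition patches by target-class content
#'
#' Splits patches into those containing at least one pixel of any target
#' class (`kept`) and the rest (`excluded`). This mirrors the dataset
#' curation step in which patches without target elements are set aside;
#' the excluded pool is later the source for background injection.
#'
#' @param patches A `patch_grid` or a plain list of patch items carrying
#'   masks.
#' @param target_classes Class names or indices of the patches' palette;
#'   must be non-empty.
#' @return List with `kept` and `excluded` patch lists
#'   (`kept` + `excluded` = input).
#' @export
filter_targetless <- function(patches, target_classes) {
  items <- as_patch_items(patches)
  if (!length(target_classes)) stopf("target_classes must be non-empty")
  if (!length(items)) return(list(kept = list(), excluded = list()))
  pal <- items[[1]]$mask$palette
  if (is.character(target_classes)) {
    target_classes <- palette_class_index(pal, target_classes)
  }
  has_target <- vapply(items, function(p) {
    if (is.null(p$mask)) stopf("filter_targetless requires patches with masks")
    any(p$mask$data %in% target_classes)
  }, logical(1))
  list(kept = items[has_target], excluded = items[!has_target])
}

as_patch_items <- function(patches) {
  if (inherits(patches, "patch_grid")) patches$patches else patches
}

#' Inject background-only patches into a dataset
#'
#' Appends randomly chosen patches from the excluded (targetless) pool so
#' that they form `background_fraction` of the result, rounded down: for
#' `n` kept patches the number appended is the largest `k` with
#' `k / (n + k) <= background_fraction`. Selection is deterministic per
#' seed. If the pool is smaller than `k`, patches are reused (sampled with
#' replacement); an empty pool with a positive fraction is an error.
#'
#' @param kept,excluded Patch lists as returned by [filter_targetless()].
#' @param background_fraction Desired background share of the result, in
#'   `[0, 1)`.
#' @param seed Selection seed.
#' @return Combined patch list (`kept` then injected background patches).
#' @export
inject_background <- function(kept, excluded, background_fraction, seed = 1L) {
  if (background_fraction < 0 || background_fraction >= 1) {
    stopf("background_fraction must be in [0, 1)")
  }
  if (background_fraction == 0) return(kept)
  if (!length(excluded)) {
    stopf("background injection requested but the excluded pool is empty")
  }
  n <- length(kept)
  k <- floor(background_fraction * n / (1 - background_fraction))
  if (k == 0) return(kept)
  sel <- with_seed(seed, sample.int(length(excluded), k,
                                    replace = k > length(excluded)))
  c(kept, excluded[sel])
}

#' Deterministic 80/20 train/validation split
#'
#' Shuffles items with a seeded generator and assigns the first
#' `floor(0.8 * n)` to training, the remainder to validation. The two sets
#' are disjoint and together exhaust the input.
#'
#' @param items List (or vector) of at least 2 items.
#' @param seed Shuffle seed.
#' @return List with `train` and `validation`.
#' @export
split_80_20 <- function(items, seed = 1L) {
  n <- length(items)
  if (n < 2) stopf("need at least 2 items to split, got %d", n)
  ord <- with_seed(seed, sample.int(n))
  n_train <- floor(0.8 * n)
  list(train = items[ord[seq_len(n_train)]],
       validation = items[ord[(n_train + 1L):n]])
}
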
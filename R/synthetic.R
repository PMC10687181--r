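#' Colour configuration of the synthetic H&E scene
#'
#' All colours and texture parameters used by [render_slide()] live here
#' rather than being hard-coded, so alternative stain appearances can be
#' injected via `scene_spec(colours = ...)`. Values are RGB on `[0, 1]`:
#' an eosin-pink background with stationary noise texture, haematoxylin
#' purple ganglion cell bodies with a darker nucleus, lighter eosinophilic
#' normal nerve fibres, and a deeper tone for hypertrophic nerve trunks.
#' `contrast_threshold` is the minimum Euclidean RGB distance guaranteed
#' between any labelled element pixel and the median background colour.
#'
#' @return Named list of colour/texture parameters.
#' @export
he_colour_config <- function() {
  list(
    background = c(0.906, 0.745, 0.816),
    background_noise_sd = 0.015,
    texture_tile = 320L,
    ganglion_body = c(0.52, 0.33, 0.62),
    ganglion_nucleus = c(0.29, 0.15, 0.38),
    normal_nerve = c(0.83, 0.60, 0.69),
    hypertrophic_nerve = c(0.66, 0.42, 0.54),
    element_noise_sd = 0.01,
    artifact = c(0.45, 0.33, 0.20),
    contrast_threshold = 0.08
  )
}

#' Specify a synthetic slide scene
#'
#' A `scene_spec` fixes everything [render_slide()] needs: canvas geometry
#' (multiples of the patch size), a per-patch-column zone layout, element
#' counts and sizes, the submucosal band where ganglion cells may sit, and
#' a seed. Element counts default to densities proportional to the number
#' of zone-compatible patch columns so that rendered patches of a zone
#' reliably contain that zone's elements.
#'
#' Zone/element consistency is enforced: ganglion cells and normal nerves
#' are only placed in ganglionic or transition columns, hypertrophic
#' nerves only in aganglionic or transition columns. Requesting elements a
#' layout cannot host is a validation error.
#'
#' @param canvas_width,canvas_height Canvas size in pixels; must be
#'   positive multiples of `patch_size`. Defaults 2048 x 1280 (a x10 slide
#'   scan), giving an 8 x 5 patch grid.
#' @param zone_layout Single zone label or one per patch column, each in
#'   `c("ganglionic", "transition", "aganglionic")`.
#' @param n_ganglion_cells,n_normal_nerves,n_hypertrophic_nerves Element
#'   counts; `NULL` picks layout-scaled defaults.
#' @param ganglion_radius_range Ellipse semi-axis range in px.
#' @param normal_nerve_width_range,hypertrophic_nerve_width_range Ribbon
#'   widths in px; the hypertrophic minimum must strictly exceed the
#'   normal maximum.
#' @param submucosa_band Vertical pixel interval `c(y0, y1)` where
#'   ganglion cells may be placed; default the middle 70% of the canvas.
#' @param artifact_rate Fraction of patches receiving a brown-like overlap
#'   artifact (image only; masks are never altered).
#' @param patch_size Patch edge in px (256).
#' @param colours See [he_colour_config()].
#' @param seed Integer seed; rendering is fully deterministic given the
#'   spec.
#' @return A validated `scene_spec`.
#' @export
scene_spec <- function(canvas_width = 2048L, canvas_height = 1280L,
                       zone_layout = "ganglionic",
                       n_ganglion_cells = NULL,
                       n_normal_nerves = NULL,
                       n_hypertrophic_nerves = NULL,
                       ganglion_radius_range = c(8, 16),
                       normal_nerve_width_range = c(3, 6),
                       hypertrophic_nerve_width_range = c(10, 20),
                       submucosa_band = NULL,
                       artifact_rate = 0,
                       patch_size = 256L,
                       colours = he_colour_config(),
                       seed = 1L) {
  ps <- as.integer(patch_size)
  W <- as.integer(canvas_width); H <- as.integer(canvas_height)
  if (ps < 1L || W < ps || H < ps || W %% ps != 0L || H %% ps != 0L) {
    stopf("canvas %dx%d is not a positive multiple of patch size %d",
          W, H, ps)
  }
  n_cols <- W %/% ps; n_rows <- H %/% ps
  if (length(zone_layout) == 1L) zone_layout <- rep(zone_layout, n_cols)
  if (length(zone_layout) != n_cols || !all(zone_layout %in% ZONES)) {
    stopf("zone_layout must be one label or %d labels from {%s}",
          n_cols, paste(ZONES, collapse = ", "))
  }
  if (hypertrophic_nerve_width_range[1] <= normal_nerve_width_range[2]) {
    stopf("hypertrophic nerve width minimum (%g) must exceed normal nerve width maximum (%g)",
          hypertrophic_nerve_width_range[1], normal_nerve_width_range[2])
  }
  if (artifact_rate < 0 || artifact_rate > 1) {
    stopf("artifact_rate must be in [0, 1]")
  }
  if (is.null(submucosa_band)) {
    submucosa_band <- c(ceiling(0.15 * H), floor(0.85 * H))
  }
  submucosa_band <- as.numeric(submucosa_band)
  if (length(submucosa_band) != 2L || submucosa_band[1] >= submucosa_band[2] ||
      submucosa_band[1] < 1 || submucosa_band[2] > H) {
    stopf("submucosa_band must be an increasing pixel interval inside [1, %d]", H)
  }
  g_cols <- sum(zone_layout %in% c("ganglionic", "transition"))
  h_cols <- sum(zone_layout %in% c("aganglionic", "transition"))
  if (is.null(n_ganglion_cells)) n_ganglion_cells <- 2L * n_rows * g_cols
  if (is.null(n_normal_nerves)) n_normal_nerves <- 4L * g_cols
  if (is.null(n_hypertrophic_nerves)) n_hypertrophic_nerves <- 4L * h_cols
  if (n_ganglion_cells > 0 && g_cols == 0) {
    stopf("ganglion cells requested but no ganglionic/transition column in the layout")
  }
  if (n_normal_nerves > 0 && g_cols == 0) {
    stopf("normal nerves requested but no ganglionic/transition column in the layout")
  }
  if (n_hypertrophic_nerves > 0 && h_cols == 0) {
    stopf("hypertrophic nerves requested but no aganglionic/transition column in the layout")
  }
  structure(list(
    canvas_width = W, canvas_height = H, patch_size = ps,
    n_rows = n_rows, n_cols = n_cols, zone_layout = zone_layout,
    n_ganglion_cells = as.integer(n_ganglion_cells),
    n_normal_nerves = as.integer(n_normal_nerves),
    n_hypertrophic_nerves = as.integer(n_hypertrophic_nerves),
    ganglion_radius_range = as.numeric(ganglion_radius_range),
    normal_nerve_width_range = as.numeric(normal_nerve_width_range),
    hypertrophic_nerve_width_range = as.numeric(hypertrophic_nerve_width_range),
    submucosa_band = submucosa_band,
    artifact_rate = artifact_rate,
    colours = colours,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec %dx%d (%dx%d patches of %d), seed %d>\n",
              x$canvas_width, x$canvas_height, x$n_cols, x$n_rows,
              x$patch_size, x$seed))
  cat(" zones:", paste(x$zone_layout, collapse = " "), "\n")
  cat(sprintf(" elements: %d ganglion cells, %d normal nerves, %d hypertrophic nerves\n",
              x$n_ganglion_cells, x$n_normal_nerves, x$n_hypertrophic_nerves))
  invisible(x)
}

# ---- rasterisation helpers (linear indices into an H x W matrix) ---------

ellipse_pixels <- function(cx, cy, rx, ry, H, W) {
  ys <- max(1L, floor(cy - ry)):min(H, ceiling(cy + ry))
  xs <- max(1L, floor(cx - rx)):min(W, ceiling(cx + rx))
  dy <- (ys - cy) / ry
  dx <- (xs - cx) / rx
  inside <- outer(dy^2, dx^2, "+") <= 1
  idx <- which(inside)
  if (!length(idx)) return(integer(0))
  r <- ((idx - 1L) %% length(ys)) + 1L
  c <- ((idx - 1L) %/% length(ys)) + 1L
  (xs[c] - 1L) * H + ys[r]
}

# A near-vertical wavy ribbon of width `w` centred on x(y) = cx + A sin(.),
# rasterised row by row so its footprint stays inside [cx - A - w, cx + A + w].
ribbon_pixels <- function(cx, amp, wavelength, phase, w, H, W) {
  stopifnot(is.finite(cx), is.finite(amp), w >= 1)
  y <- seq_len(H)
  xc <- cx + amp * sin(2 * pi * y / wavelength + phase)
  x0 <- round(xc - (w - 1) / 2)
  cols <- outer(x0, 0:(w - 1L), "+")
  cols[cols < 1L] <- 1L
  cols[cols > W] <- W
  idx <- (cols - 1L) * H + y      # recycles y down each column of `cols`
  as.integer(idx)                 # duplicates at clamped edges are harmless
}

# Deferred painter: elements are queued and written with one indexed
# assignment per channel/mask at the end (per-element writes would copy
# the multi-megabyte canvas once per element). Queue order is draw order;
# R's "last write wins" for duplicated indices preserves overpainting.
element_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$items <- list()
  q
}

queue_element <- function(q, idx, colour, noise_sd, m1val, m2val) {
  if (!length(idx)) return(invisible(q))
  q$items[[length(q$items) + 1L]] <-
    list(idx = idx, colour = colour, noise_sd = noise_sd,
         m1val = m1val, m2val = m2val)
  invisible(q)
}

flush_queue <- function(q, image, m1, m2) {
  if (!length(q$items)) return(list(image = image, m1 = m1, m2 = m2))
  idx <- unlist(lapply(q$items, `[[`, "idx"), use.names = FALSE)
  # element texture comes from a recycled noise pool (one draw per slide,
  # scaled per element) rather than per-pixel draws
  pool <- rnorm(65536L)
  offsets <- cumsum(c(0L, vapply(q$items, function(e) length(e$idx),
                                 integer(1))))
  vals <- unlist(lapply(1:3, function(ch) {
    unlist(lapply(seq_along(q$items), function(k) {
      e <- q$items[[k]]
      n <- length(e$idx)
      at <- ((offsets[k] + (ch - 1L) * 21871L + seq_len(n) - 1L) %% 65536L) + 1L
      e$colour[ch] + e$noise_sd * pool[at]
    }), use.names = FALSE)
  }), use.names = FALSE)
  image <- .scatter_paint(image, as.integer(idx), vals,
                          dim(image)[1] * dim(image)[2])
  m1[idx] <- unlist(lapply(q$items, function(e)
    rep(e$m1val, length(e$idx))), use.names = FALSE)
  m2[idx] <- unlist(lapply(q$items, function(e)
    rep(e$m2val, length(e$idx))), use.names = FALSE)
  list(image = image, m1 = m1, m2 = m2)
}

# Evenly spaced, jittered lane centres for `n` ribbons sharing one patch
# column, with amplitudes capped so footprints never leave the column.
plan_lanes <- function(n, x0, x1, max_halfwidth) {
  margin <- max_halfwidth + 3
  lo <- x0 + margin; hi <- x1 - margin
  spacing <- (hi - lo) / n
  centres <- lo + (seq_len(n) - 0.5) * spacing +
    runif(n, -0.15 * spacing, 0.15 * spacing)
  amp <- rep(max(0, min(10, spacing / 2 - max_halfwidth - 2)), n)
  list(centres = centres, amp = amp)
}

#' Render a synthetic H&E slide with ground truth
#'
#' Deterministically (per spec seed) draws an H&E-like scene: textured
#' eosin background, full-height wavy nerve ribbons (thin = normal, thick
#' = hypertrophic) confined to zone-compatible patch columns, and ganglion
#' cells as filled ellipses with a darker nucleus inside the submucosal
#' band. Alongside the RGB image it returns pixel-exact ground truth for
#' both models and the per-patch zone label grid.
#'
#' @param spec A [scene_spec()].
#' @return A `rendered_slide`: list with `image` (H x W x 3 on `[0, 1]`),
#'   `mask_m1` / `mask_m2` ([multiclass_mask()]s), `zone_truth`
#'   (n_rows x n_cols character matrix), and the originating `spec`.
#' @examples
#' s <- render_slide(scene_spec(512, 512, "transition", seed = 7))
#' mask_class_counts(s$mask_m1)
#' @export
render_slide <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, render_slide_impl(spec))
}

render_slide_impl <- function(spec) {
  H <- spec$canvas_height; W <- spec$canvas_width; ps <- spec$patch_size
  col_x0 <- (seq_len(spec$n_cols) - 1L) * ps + 1L
  col_x1 <- col_x0 + ps - 1L
  cc <- spec$colours

  # background: base colour + a modulo-tiled noise block (stationary texture)
  t <- cc$texture_tile
  tile <- array(rnorm(t * t * 3, 0, cc$background_noise_sd), c(t, t, 3))
  image <- .tiled_canvas(H, W, tile, t, cc$background)
  m1 <- matrix(0L, H, W)
  m2 <- matrix(0L, H, W)

  g_cols <- which(spec$zone_layout %in% c("ganglionic", "transition"))
  h_cols <- which(spec$zone_layout %in% c("aganglionic", "transition"))

  # plan nerve ribbons: round-robin over compatible columns, then one lane
  # per ribbon within each column so ribbons never cross
  ribbons <- list()
  if (spec$n_normal_nerves > 0) {
    for (i in seq_len(spec$n_normal_nerves)) {
      ribbons[[length(ribbons) + 1L]] <- list(
        type = "normal", col = g_cols[((i - 1L) %% length(g_cols)) + 1L],
        w = round(runif(1, spec$normal_nerve_width_range[1],
                        spec$normal_nerve_width_range[2])))
    }
  }
  if (spec$n_hypertrophic_nerves > 0) {
    for (i in seq_len(spec$n_hypertrophic_nerves)) {
      ribbons[[length(ribbons) + 1L]] <- list(
        type = "hyper", col = h_cols[((i - 1L) %% length(h_cols)) + 1L],
        w = round(runif(1, spec$hypertrophic_nerve_width_range[1],
                        spec$hypertrophic_nerve_width_range[2])))
    }
  }
  queue <- element_queue()
  by_col <- split(seq_along(ribbons),
                  vapply(ribbons, function(r) r$col, numeric(1)))
  for (colname in names(by_col)) {
    ids <- by_col[[colname]]
    cidx <- as.integer(colname)
    lanes <- plan_lanes(length(ids), col_x0[cidx], col_x1[cidx],
                        max_halfwidth = max(vapply(ribbons[ids],
                                                   function(r) r$w, numeric(1))) / 2)
    ord <- sample(length(ids))     # random lane assignment
    for (j in seq_along(ids)) {
      r <- ribbons[[ids[j]]]
      idx <- ribbon_pixels(lanes$centres[ord[j]], lanes$amp[ord[j]],
                           wavelength = runif(1, 200, 600),
                           phase = runif(1, 0, 2 * pi),
                           w = r$w, H = H, W = W)
      if (r$type == "normal") {
        queue_element(queue, idx, cc$normal_nerve, cc$element_noise_sd,
                      m1val = 2L, m2val = 0L)
      } else {
        queue_element(queue, idx, cc$hypertrophic_nerve, cc$element_noise_sd,
                      m1val = 0L, m2val = 1L)
      }
    }
  }

  # ganglion cells: non-overlapping ellipses inside the submucosal band,
  # stratified over compatible columns; drawn last so bodies sit on top
  if (spec$n_ganglion_cells > 0) {
    rr <- spec$ganglion_radius_range
    band <- spec$submucosa_band
    placed <- matrix(numeric(0), ncol = 3)   # cx, cy, r
    for (i in seq_len(spec$n_ganglion_cells)) {
      cidx <- g_cols[((i - 1L) %% length(g_cols)) + 1L]
      ok <- FALSE
      for (try in 1:200) {
        rx <- runif(1, rr[1], rr[2]); ry <- runif(1, rr[1], rr[2])
        rmax <- max(rx, ry)
        cx <- runif(1, col_x0[cidx] + rmax + 2, col_x1[cidx] - rmax - 2)
        ylo <- max(band[1] + ry, ry + 1); yhi <- min(band[2] - ry, H - ry)
        if (ylo >= yhi) stopf("submucosa band too narrow for ganglion radius %g", ry)
        cy <- runif(1, ylo, yhi)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                placed[, 3] + rmax + 2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("could not place ganglion cell %d without overlap; reduce n_ganglion_cells", i)
      placed <- rbind(placed, c(cx, cy, rmax))
      body <- ellipse_pixels(cx, cy, rx, ry, H, W)
      queue_element(queue, body, cc$ganglion_body, cc$element_noise_sd,
                    m1val = 1L, m2val = 0L)
      nuc <- ellipse_pixels(cx + runif(1, -0.2, 0.2) * rx,
                            cy + runif(1, -0.2, 0.2) * ry,
                            0.45 * rx, 0.45 * ry, H, W)
      queue_element(queue, nuc, cc$ganglion_nucleus, cc$element_noise_sd / 2,
                    m1val = 1L, m2val = 0L)
    }
  }

  # canvas and painted values are already quantized to 8-bit levels
  drawn <- flush_queue(queue, image, m1, m2)
  image <- drawn$image; m1 <- drawn$m1; m2 <- drawn$m2

  zone_truth <- matrix(rep(spec$zone_layout, each = spec$n_rows),
                       spec$n_rows, spec$n_cols)
  slide <- structure(list(
    image = image,
    mask_m1 = new_mask(m1, class_palette("model1")),
    mask_m2 = new_mask(m2, class_palette("model2")),
    zone_truth = zone_truth,
    spec = spec
  ), class = "rendered_slide")
  if (spec$artifact_rate > 0) {
    slide <- apply_artifact(slide, spec$artifact_rate,
                            seed = derive_seed(spec$seed, 9901L))
  }
  slide
}

#' @export
print.rendered_slide <- function(x, ...) {
  cat(sprintf("<rendered_slide %dx%d, %dx%d patch grid>\n",
              x$spec$canvas_width, x$spec$canvas_height,
              x$spec$n_cols, x$spec$n_rows))
  cat(" zone columns:", paste(x$spec$zone_layout, collapse = " "), "\n")
  cat(" model 1 pixels:", paste(names(mask_class_counts(x$mask_m1)),
                                mask_class_counts(x$mask_m1), collapse = ", "), "\n")
  cat(" model 2 pixels:", paste(names(mask_class_counts(x$mask_m2)),
                                mask_class_counts(x$mask_m2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.rendered_slide <- function(x, what = c("image", "mask_m1", "mask_m2"), ...) {
  what <- match.arg(what)
  arr <- if (what == "image") x$image else mask_to_rgb(x[[what]])
  plot.new()
  plot.window(c(0, 1), c(0, 1), asp = dim(arr)[1] / dim(arr)[2])
  rasterImage(arr, 0, 0, 1, 1)
  title(main = what)
  invisible(x)
}

#' Render a reproducible cohort of synthetic slides
#'
#' Draws `n_slides` uniform-zone slides whose zone composition follows
#' `zone_mix` by largest-remainder allocation (realised counts are within
#' one slide of the requested proportions). Per-slide seeds are derived
#' deterministically from the cohort seed, so the same call yields a
#' byte-identical cohort.
#'
#' @param n_slides Number of slides (>= 1).
#' @param zone_mix Named non-negative proportions over
#'   `c("ganglionic", "transition", "aganglionic")` summing to 1.
#' @param seed Cohort seed.
#' @param transform Optional function applied to each slide as it is
#'   rendered; when supplied, the list holds `transform(slide)` instead of
#'   the slide itself. Use this to stream large cohorts (e.g. reduce each
#'   slide to patch counts) without materialising every canvas in memory.
#' @param ... Further arguments to [scene_spec()] (canvas size, element
#'   counts, ...).
#' @return List of length `n_slides` (slides, or transformed values), with
#'   a `zones` attribute recording each slide's zone.
#' @export
render_cohort <- function(n_slides, zone_mix = c(ganglionic = 1 / 3,
                                                 transition = 1 / 3,
                                                 aganglionic = 1 / 3),
                          seed = 1L, transform = NULL, ...) {
  if (n_slides < 1) stopf("n_slides must be >= 1")
  if (!length(zone_mix) || is.null(names(zone_mix)) ||
      !all(names(zone_mix) %in% ZONES)) {
    stopf("zone_mix must be a named vector over {%s}", paste(ZONES, collapse = ", "))
  }
  if (any(zone_mix < 0)) stopf("zone_mix proportions must be non-negative")
  if (abs(sum(zone_mix) - 1) > 1e-8) stopf("zone_mix must sum to 1")

  base <- floor(zone_mix * n_slides)
  rem <- n_slides - sum(base)
  if (rem > 0) {
    frac <- zone_mix * n_slides - base
    bump <- order(-frac)[seq_len(rem)]
    base[bump] <- base[bump] + 1
  }
  zones <- rep(names(zone_mix), base)

  out <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    spec <- scene_spec(zone_layout = zones[i],
                       seed = derive_seed(seed, i), ...)
    slide <- render_slide(spec)
    # out[i] <- list(...): transform() may return NULL, which `[[<-` would
    # silently delete from the list
    out[i] <- list(if (is.null(transform)) slide else transform(slide))
  }
  names(out) <- sprintf("slide_%03d", seq_len(n_slides))
  attr(out, "zones") <- zones
  out
}

#' Overlay brown-like artifacts on a slide image
#'
#' Emulates the staining artifact in which overlapping tissue layers
#' create a brown-like colouration that can be mistaken for ganglion
#' cells. A fraction of patch positions receives a soft brown blob blended
#' into the image only; ground-truth masks are never modified, because
#' artifacts are not true tissue elements.
#'
#' @param slide A `rendered_slide`.
#' @param rate Fraction of patches to corrupt, in `[0, 1]`.
#' @param seed Seed for patch selection and blob geometry.
#' @return The slide with a corrupted image and an `artifact` record
#'   (`rate`, `seed`, affected patch indices).
#' @export
apply_artifact <- function(slide, rate, seed = 1L) {
  stopifnot(inherits(slide, "rendered_slide"))
  if (rate < 0 || rate > 1) stopf("artifact rate must be in [0, 1]")
  spec <- slide$spec
  n_patch <- spec$n_rows * spec$n_cols
  n_sel <- round(rate * n_patch)
  if (n_sel == 0) {
    slide$artifact <- list(rate = rate, seed = seed, patches = integer(0))
    return(slide)
  }
  ps <- spec$patch_size
  brown <- spec$colours$artifact
  with_seed(seed, {
    sel <- sort(sample.int(n_patch, n_sel))
    img <- slide$image
    for (p in sel) {
      row <- ((p - 1L) %% spec$n_rows) + 1L
      col <- ((p - 1L) %/% spec$n_rows) + 1L
      y0 <- (row - 1L) * ps; x0 <- (col - 1L) * ps
      cy <- runif(1, 0.3, 0.7) * ps; cx <- runif(1, 0.3, 0.7) * ps
      r <- runif(1, 0.25, 0.4) * ps
      d2 <- outer((seq_len(ps) - cy)^2, (seq_len(ps) - cx)^2, "+")
      alpha <- 0.6 * exp(-d2 / r^2)
      for (ch in 1:3) {
        block <- img[y0 + seq_len(ps), x0 + seq_len(ps), ch]
        img[y0 + seq_len(ps), x0 + seq_len(ps), ch] <-
          (1 - alpha) * block + alpha * brown[ch]
      }
    }
    slide$image <- quantize8(img)
  })
  slide$artifact <- list(rate = rate, seed = seed, patches = sel)
  slide
}
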
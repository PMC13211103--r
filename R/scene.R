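# Synthetic field scenes: curved capsule "fruits" of controlled aspect
# ratio on cluttered backgrounds, partially covered by leaf-like occluder
# blobs, with tight pre-occlusion bounding-box annotations.

#' Specification of a synthetic field scene
#'
#' Controls everything the generator randomizes.  Identical specs (including
#' `seed`) yield bit-identical scenes and datasets.
#'
#' @param image_size image side in pixels (square images).
#' @param n_objects integer range `c(lo, hi)` of objects per scene.
#' @param n_classes number of fruit classes (colors drawn from
#'   [default_classes()]).
#' @param ar_range range of target aspect ratios (long side / short side of
#'   the rendered capsule's tight box); lower bound must be >= 1.  The
#'   default spans round through very elongated fruit so all four
#'   aspect-ratio buckets G1-G4 are populated.
#' @param curvature_range range of bend angles in degrees; the capsule
#'   midline is bent along a circular arc subtending this angle.
#' @param occlusion_fraction_range range in `[0, 1]` of the fraction of each
#'   object's area to cover with occluder blobs.
#' @param clutter_level background texture intensity in `[0, 1]`.
#' @param length_frac_range object long extent as a fraction of the image
#'   side.
#' @param seed integer seed; the sole source of randomness.
#' @return A `scene_spec` list.
#' @export
#' @examples
#' spec <- scene_spec(image_size = 128, n_objects = c(2, 3), seed = 1)
#' sc <- generate_scene(spec)
#' nrow(sc$boxes)
scene_spec <- function(image_size = 640L,
                       n_objects = c(3L, 6L),
                       n_classes = 3L,
                       ar_range = c(1, 12),
                       curvature_range = c(0, 35),
                       occlusion_fraction_range = c(0, 0.5),
                       clutter_level = 0.5,
                       length_frac_range = c(0.15, 0.45),
                       seed = 1L) {
  if (length(n_objects) == 1L) n_objects <- c(n_objects, n_objects)
  if (ar_range[1] < 1) stopf("stripedet_spec_error", "ar_range lower bound must be >= 1")
  if (any(occlusion_fraction_range < 0) || any(occlusion_fraction_range > 1))
    stopf("stripedet_spec_error", "occlusion fractions must lie in [0, 1]")
  if (clutter_level < 0 || clutter_level > 1)
    stopf("stripedet_spec_error", "clutter_level must lie in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 n_objects = as.integer(n_objects),
                 n_classes = as.integer(n_classes),
                 ar_range = as.numeric(ar_range),
                 curvature_range = as.numeric(curvature_range),
                 occlusion_fraction_range = as.numeric(occlusion_fraction_range),
                 clutter_level = as.numeric(clutter_level),
                 length_frac_range = as.numeric(length_frac_range),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Distance from grid points to a capsule midline (straight segment or
# circular arc), in the capsule's local frame: long axis along x, midline
# through the origin.  px/py are vectors of local coordinates.
capsule_dist <- function(px, py, arc_len, theta) {
  if (theta < 1e-6) {
    hx <- arc_len / 2
    cx <- pmin(pmax(px, -hx), hx)
    return(sqrt((px - cx)^2 + py^2))
  }
  R <- arc_len / theta
  # arc: P(phi) = (R sin phi, R - R cos phi), phi in [-theta/2, theta/2]
  vx <- px
  vy <- py - R
  phi <- atan2(vx, -vy)
  d_arc <- abs(sqrt(vx^2 + vy^2) - R)
  inside <- abs(phi) <= theta / 2
  ex <- R * sin(theta / 2)
  ey <- R - R * cos(theta / 2)
  d_end <- pmin(sqrt((px - ex)^2 + (py - ey)^2),
                sqrt((px + ex)^2 + (py - ey)^2))
  ifelse(inside, d_arc, d_end)
}

# Rasterize one capsule; returns the logical mask (H x W) of covered pixels.
# length_px is the total long extent (midline chord + caps), width_px the
# short extent; orientation "h" or "v"; bend_sign flips the arc side.
rasterize_capsule <- function(H, W, cx, cy, length_px, width_px,
                              theta_deg, orientation, bend_sign) {
  theta <- theta_deg * pi / 180
  arc_len <- max(length_px - width_px, 1)
  xs <- seq_len(W) - 0.5
  ys <- seq_len(H) - 0.5
  gx <- matrix(xs, H, W, byrow = TRUE) - cx
  gy <- matrix(ys, H, W) - cy
  if (orientation == "v") { tmp <- gx; gx <- gy; gy <- tmp }
  gy <- gy * bend_sign
  d <- capsule_dist(as.vector(gx), as.vector(gy), arc_len, theta)
  matrix(d <= width_px / 2, H, W)
}

mask_bbox <- function(mask) {
  # tight 0-based half-open box of TRUE pixels; mask[y, x]
  w <- which(mask, arr.ind = TRUE)
  c(x1 = min(w[, 2]) - 1, y1 = min(w[, 1]) - 1,
    x2 = max(w[, 2]), y2 = max(w[, 1]))
}

class_palette <- function(n_classes) {
  base <- rbind(c(0.20, 0.55, 0.20),   # deep green
                c(0.48, 0.62, 0.20),   # yellow-green
                c(0.72, 0.15, 0.12))   # red
  if (n_classes <= 3L) return(base[seq_len(n_classes), , drop = FALSE])
  extra <- matrix(runif(3 * (n_classes - 3L), 0.1, 0.8), ncol = 3)
  rbind(base, extra)
}

paint_mask <- function(img, mask, col) {
  for (k in 1:3) {
    ch <- img[, , k]
    ch[mask] <- col[k]
    img[, , k] <- ch
  }
  img
}

draw_ellipse_mask <- function(H, W, cx, cy, rx, ry, angle) {
  xs <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE) - cx
  ys <- matrix(seq_len(H) - 0.5, H, W) - cy
  ca <- cos(angle); sa <- sin(angle)
  u <- xs * ca + ys * sa
  v <- -xs * sa + ys * ca
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate one annotated synthetic scene
#'
#' Renders capsule-shaped fruits (rectangles with semicircular caps,
#' optionally bent along a circular arc) on a cluttered background, then
#' covers each with leaf-like occluder blobs up to a drawn coverage
#' fraction.  Bounding boxes annotate the full pre-occlusion extent of each
#' object; `visibility` records the fraction left uncovered.
#'
#' @param spec a [scene_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return An `annotated_scene` list: `image` (H x W x 3 array in `[0, 1]`,
#'   quantized to 8 bits), `boxes` (n x 4 matrix, 0-based half-open pixel
#'   coords), `labels` (1-based class ids), `visibility`, `width`, `height`.
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    S <- spec$image_size
    img <- render_background(S, spec$clutter_level)
    pal <- class_palette(spec$n_classes)
    n_obj <- if (spec$n_objects[1] == spec$n_objects[2]) spec$n_objects[1] else
      sample(spec$n_objects[1]:spec$n_objects[2], 1L)
    boxes <- NULL
    labels <- integer(0)
    masks <- list()
    budget <- 40L * n_obj
    placed <- 0L
    while (placed < n_obj) {
      if (budget <= 0L)
        stopf("stripedet_place_error",
              "could not place %d objects in a %dpx scene; spec too dense",
              n_obj, S)
      budget <- budget - 1L
      ar <- runif(1, spec$ar_range[1], spec$ar_range[2])
      len <- runif(1, spec$length_frac_range[1], spec$length_frac_range[2]) * S
      wid <- max(len / ar, 3)
      len <- wid * ar
      theta <- runif(1, spec$curvature_range[1], spec$curvature_range[2])
      orient <- sample(c("h", "v"), 1L)
      bend <- sample(c(-1, 1), 1L)
      half <- len / 2 + 2
      if (2 * half >= S) next
      cx <- runif(1, half, S - half)
      cy <- runif(1, half, S - half)
      mask <- rasterize_capsule(S, S, cx, cy, len, wid, theta, orient, bend)
      if (!any(mask)) next
      bb <- mask_bbox(mask)
      if (bb[1] < 0 || bb[2] < 0 || bb[3] > S || bb[4] > S) next
      if (!is.null(boxes) && nrow(boxes) > 0) {
        ious <- iou_matrix(matrix(bb, 1), boxes)
        if (any(ious > 0.25)) next
      }
      cls <- sample.int(spec$n_classes, 1L)
      col <- pmin(pmax(pal[cls, ] + runif(3, -0.08, 0.08), 0), 1)
      img <- paint_mask(img, mask, col)
      boxes <- rbind(boxes, bb)
      labels <- c(labels, cls)
      masks[[length(masks) + 1L]] <- mask
      placed <- placed + 1L
    }
    # occluders: leaf-green ellipse unions drawn over each object
    occ_total <- matrix(FALSE, S, S)
    for (i in seq_len(placed)) {
      f_target <- runif(1, spec$occlusion_fraction_range[1],
                        spec$occlusion_fraction_range[2])
      if (f_target <= 0) next
      obj <- masks[[i]]
      obj_px <- sum(obj)
      tries <- 0L
      while (sum(obj & occ_total) / obj_px < f_target && tries < 25L) {
        tries <- tries + 1L
        pts <- which(obj, arr.ind = TRUE)
        p <- pts[sample.int(nrow(pts), 1L), ]
        L <- boxes[i, 3] - boxes[i, 1]
        rx <- runif(1, 0.08, 0.25) * max(L, 20)
        ry <- rx * runif(1, 0.5, 1.2)
        ang <- runif(1, 0, pi)
        leaf <- draw_ellipse_mask(S, S, p[2] - 0.5 + runif(1, -3, 3),
                                  p[1] - 0.5 + runif(1, -3, 3), rx, ry, ang)
        col <- c(0.10, 0.38, 0.12) + runif(3, -0.05, 0.05)
        img <- paint_mask(img, leaf, pmin(pmax(col, 0), 1))
        occ_total <- occ_total | leaf
      }
    }
    visibility <- vapply(seq_len(placed), function(i) {
      obj <- masks[[i]]
      1 - sum(obj & occ_total) / sum(obj)
    }, numeric(1))
    img <- img + array(rnorm(length(img), 0, 0.015 * spec$clutter_level),
                       dim = dim(img))
    img <- round(pmin(pmax(img, 0), 1) * 255) / 255
    if (is.null(boxes)) boxes <- matrix(numeric(0), 0, 4)
    rownames(boxes) <- NULL
    structure(list(image = img,
                   boxes = box_matrix(boxes[, 1], boxes[, 2],
                                      boxes[, 3], boxes[, 4]),
                   labels = labels,
                   visibility = visibility,
                   width = S, height = S),
              class = "annotated_scene")
  })
}

render_background <- function(S, clutter) {
  base <- c(0.32, 0.28, 0.18)  # soil
  img <- array(rep(base, each = S * S), dim = c(S, S, 3))
  n_blob <- round(clutter * 30)
  for (i in seq_len(n_blob)) {
    m <- draw_ellipse_mask(S, S, runif(1, 0, S), runif(1, 0, S),
                           runif(1, 0.03, 0.12) * S, runif(1, 0.03, 0.12) * S,
                           runif(1, 0, pi))
    hue <- sample(1:2, 1)
    col <- if (hue == 1) c(0.15, 0.35, 0.12) else c(0.40, 0.34, 0.20)
    img <- paint_mask(img, m, pmin(pmax(col + runif(3, -0.08, 0.08), 0), 1))
  }
  img + array(rnorm(S * S * 3, 0, 0.02 * clutter), dim = c(S, S, 3))
}

#' Generate a VOC-format synthetic dataset
#'
#' Writes `n_images` scenes as PNG plus one VOC XML each, under the usual
#' `JPEGImages/`, `Annotations/`, `ImageSets/Main/` layout, splitting 80/20
#' into train/val lists.  Fully determined by `(spec, n_images)`.
#'
#' @param spec a [scene_spec()].
#' @param n_images number of scenes to write.
#' @param out_dir output directory (created if missing).
#' @return A `dataset_summary` list with tibbles `per_class` and
#'   `per_bucket` (instance counts), plus `n_images`.
#' @export
generate_dataset <- function(spec, n_images, out_dir) {
  dir.create(file.path(out_dir, "JPEGImages"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "Annotations"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "ImageSets", "Main"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "Annotations")))
    stopf("stripedet_io_error", "cannot create dataset tree under %s", out_dir)
  classes <- default_classes(spec$n_classes)
  labs <- integer(0)
  buckets <- character(0)
  ids <- character(0)
  for (i in seq_len(n_images)) {
    sd_i <- as.integer((as.numeric(spec$seed) + 7919 * i) %% 2147483647)
    sc <- generate_scene(spec, seed = sd_i)
    id <- sprintf("scene_%05d", i)
    ids <- c(ids, id)
    png::writePNG(sc$image,
                  file.path(out_dir, "JPEGImages", paste0(id, ".png")))
    write_voc(sc, file.path(out_dir, "Annotations", paste0(id, ".xml")),
              classes = classes, filename = paste0(id, ".png"))
    labs <- c(labs, sc$labels)
    buckets <- c(buckets, apply(sc$boxes, 1, function(b)
      ar_bucket(b[3] - b[1], b[4] - b[2])))
  }
  n_train <- ceiling(0.8 * n_images)
  writeLines(ids[seq_len(n_train)],
             file.path(out_dir, "ImageSets", "Main", "train.txt"))
  writeLines(if (n_train < n_images) ids[(n_train + 1L):n_images] else character(0),
             file.path(out_dir, "ImageSets", "Main", "val.txt"))
  per_class <- tibble::tibble(
    class = classes,
    count = vapply(seq_along(classes), function(k) sum(labs == k), integer(1)))
  bl <- c("G1", "G2", "G3", "G4")
  per_bucket <- tibble::tibble(
    bucket = bl,
    count = vapply(bl, function(b) sum(buckets == b), integer(1)))
  structure(list(n_images = n_images, per_class = per_class,
                 per_bucket = per_bucket), class = "dataset_summary")
}
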
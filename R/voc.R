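# Pascal VOC annotation I/O and the paired-view augmentation pipeline.
#
# Internal box convention is 0-based half-open pixel coordinates
# [x1, x2) x [y1, y2), so widths are simply x2 - x1.  VOC's 1-based closed
# convention is translated only at the XML boundary:
#   read:  x1 <- xmin - 1, x2 <- xmax      write: xmin <- x1 + 1, xmax <- x2

#' Read a Pascal VOC annotation file
#'
#' @param xml_path path to a VOC XML file.
#' @param classes class-name table; labels are 1-based indices into it.
#' @return An `annotated_scene` (without pixel data): `width`, `height`,
#'   `boxes` (0-based half-open pixel coords), `labels`, `filename`.
#' @export
read_voc <- function(xml_path, classes = default_classes()) {
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e)
    stopf("stripedet_xml_error", "malformed VOC XML '%s': %s",
          xml_path, conditionMessage(e)))
  size <- xml2::xml_find_first(doc, "./size")
  if (inherits(size, "xml_missing"))
    stopf("stripedet_xml_error", "VOC XML '%s' has no <size> entry", xml_path)
  W <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  H <- as.numeric(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  objs <- xml2::xml_find_all(doc, "./object")
  n <- length(objs)
  boxes <- matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  labels <- integer(0)
  for (o in objs) {
    nm <- xml2::xml_text(xml2::xml_find_first(o, "./name"))
    lab <- match(nm, classes)
    if (is.na(lab))
      stopf("stripedet_class_error", "unknown class name '%s' in %s", nm, xml_path)
    bb <- xml2::xml_find_first(o, "./bndbox")
    xmin <- as.numeric(xml2::xml_text(xml2::xml_find_first(bb, "./xmin")))
    ymin <- as.numeric(xml2::xml_text(xml2::xml_find_first(bb, "./ymin")))
    xmax <- as.numeric(xml2::xml_text(xml2::xml_find_first(bb, "./xmax")))
    ymax <- as.numeric(xml2::xml_text(xml2::xml_find_first(bb, "./ymax")))
    boxes <- rbind(boxes, c(xmin - 1, ymin - 1, xmax, ymax))
    labels <- c(labels, lab)
  }
  check_boxes(boxes, W, H)
  fn <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  structure(list(image = NULL, boxes = boxes, labels = labels,
                 visibility = rep(1, n), width = W, height = H,
                 filename = fn),
            class = "annotated_scene")
}

#' Write a Pascal VOC annotation file
#'
#' Inverse of [read_voc()]: internal 0-based half-open boxes become VOC
#' 1-based closed `xmin/ymin/xmax/ymax`.
#'
#' @param scene an `annotated_scene`.
#' @param xml_path output path.
#' @param classes class-name table (ASCII names only).
#' @param filename image filename stored in the XML.
#' @export
write_voc <- function(scene, xml_path, classes = default_classes(),
                      filename = scene$filename %||% "image.png") {
  if (any(grepl("[^ -~]", classes)))
    stopf("stripedet_class_error", "class names must be ASCII")
  if (length(scene$labels) && any(scene$labels > length(classes)))
    stopf("stripedet_class_error", "label id outside the class table")
  check_boxes(scene$boxes, scene$width, scene$height)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "JPEGImages")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(as.integer(scene$width)))
  xml2::xml_add_child(size, "height", as.character(as.integer(scene$height)))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_along(scene$labels)) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", classes[scene$labels[i]])
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    b <- scene$boxes[i, ]
    xml2::xml_add_child(bb, "xmin", format(b[1] + 1, scientific = FALSE))
    xml2::xml_add_child(bb, "ymin", format(b[2] + 1, scientific = FALSE))
    xml2::xml_add_child(bb, "xmax", format(b[3], scientific = FALSE))
    xml2::xml_add_child(bb, "ymax", format(b[4], scientific = FALSE))
  }
  ok <- tryCatch({ xml2::write_xml(doc, xml_path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stopf("stripedet_io_error", "cannot write '%s'", xml_path)
  invisible(xml_path)
}

#' Augmentation configuration for paired views
#'
#' The pipeline applies exactly three augmentation families: random
#' horizontal flipping, color jittering, and region masking.  Geometric
#' transforms move the boxes consistently; color jitter and region masking
#' never touch the annotations (a fully erased object keeps its box — the
#' reconstruction loss, not the labels, handles invisibility).
#'
#' @param flip_prob probability of a horizontal flip.
#' @param brightness,contrast,saturation multiplicative jitter amplitudes;
#'   factors are drawn from `[1 - a, 1 + a]`.
#' @param hue additive hue rotation amplitude (fraction of the hue circle).
#' @param mask_count integer range of erased rectangles per view.
#' @param mask_size range of erased-rectangle side length as a fraction of
#'   the image side.
#' @return An `augment_config` list.
#' @export
augment_config <- function(flip_prob = 0.5,
                           brightness = 0.2, contrast = 0.2,
                           saturation = 0.2, hue = 0.05,
                           mask_count = c(0L, 2L),
                           mask_size = c(0.05, 0.15)) {
  stopifnot(flip_prob >= 0, flip_prob <= 1,
            brightness >= 0, contrast >= 0, saturation >= 0, hue >= 0)
  structure(list(flip_prob = flip_prob, brightness = brightness,
                 contrast = contrast, saturation = saturation, hue = hue,
                 mask_count = as.integer(mask_count),
                 mask_size = as.numeric(mask_size)),
            class = "augment_config")
}

jitter_image <- function(img, fb, fc, fs, dh) {
  if (fb != 1) img <- img * fb
  if (fc != 1) {
    m <- mean(img)
    img <- (img - m) * fc + m
  }
  if (fs != 1) {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (k in 1:3) img[, , k] <- gray + (img[, , k] - gray) * fs
  }
  img <- pmin(pmax(img, 0), 1)
  if (abs(dh) > 1e-9) {
    d <- dim(img)
    rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                 as.vector(img[, , 3]))
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
    hsv[1, ] <- (hsv[1, ] + dh) %% 1
    out <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
    cr <- grDevices::col2rgb(out) / 255
    img <- array(c(cr[1, ], cr[2, ], cr[3, ]), dim = d)
  }
  pmin(pmax(img, 0), 1)
}

augment_once <- function(scene, cfg) {
  img <- scene$image
  W <- scene$width; H <- scene$height
  nb <- scene$boxes
  if (nrow(nb) > 0) {
    nb <- cbind(nb[, 1] / W, nb[, 2] / H, nb[, 3] / W, nb[, 4] / H)
  } else nb <- matrix(numeric(0), 0, 4)
  flipped <- runif(1) < cfg$flip_prob
  if (flipped) {
    img <- img[, W:1, , drop = FALSE]
    if (nrow(nb) > 0) nb <- cbind(1 - nb[, 3], nb[, 2], 1 - nb[, 1], nb[, 4])
  }
  fb <- runif(1, 1 - cfg$brightness, 1 + cfg$brightness)
  fc <- runif(1, 1 - cfg$contrast, 1 + cfg$contrast)
  fs <- runif(1, 1 - cfg$saturation, 1 + cfg$saturation)
  dh <- runif(1, -cfg$hue, cfg$hue)
  img <- jitter_image(img, fb, fc, fs, dh)
  k <- if (cfg$mask_count[1] == cfg$mask_count[2]) cfg$mask_count[1] else
    sample(cfg$mask_count[1]:cfg$mask_count[2], 1L)
  for (j in seq_len(k)) {
    mw <- max(2L, round(runif(1, cfg$mask_size[1], cfg$mask_size[2]) * W))
    mh <- max(2L, round(runif(1, cfg$mask_size[1], cfg$mask_size[2]) * H))
    x0 <- sample.int(W - mw + 1L, 1L)
    y0 <- sample.int(H - mh + 1L, 1L)
    img[y0:(y0 + mh - 1L), x0:(x0 + mw - 1L), ] <- 0.5
  }
  colnames(nb) <- c("x1", "y1", "x2", "y2")
  list(image = img, boxes = nb, flipped = flipped)
}

#' Build two independently augmented views of a scene
#'
#' Both views of each object share an `instance_id`, which is what makes
#' the instance-level contrastive branch pair them as positives.
#'
#' @param scene an `annotated_scene` with pixel data.
#' @param cfg an [augment_config()].
#' @param seed integer seed; the two pipelines draw independent parameters
#'   from this one stream.
#' @return List with `view1` and `view2`, each holding `image` and a tibble
#'   `boxes` with normalized coordinates (`x1, y1, x2, y2` in `[0, 1]`),
#'   `label`, and `instance_id`.
#' @export
make_paired_views <- function(scene, cfg = augment_config(), seed = 1L) {
  stopifnot(inherits(scene, "annotated_scene"), !is.null(scene$image))
  with_seed(seed, {
    v1 <- augment_once(scene, cfg)
    v2 <- augment_once(scene, cfg)
    as_view <- function(v) {
      b <- v$boxes
      list(image = v$image,
           boxes = tibble::tibble(
             x1 = b[, 1], y1 = b[, 2], x2 = b[, 3], y2 = b[, 4],
             label = scene$labels,
             instance_id = seq_along(scene$labels)),
           flipped = v$flipped)
    }
    list(view1 = as_view(v1), view2 = as_view(v2))
  })
}
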
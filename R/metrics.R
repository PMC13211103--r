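# Evaluation suite: COCO-style AP with IoU / size / aspect-ratio
# breakdowns, and the Edge Concentration Score (ECS) for attention maps.
#
# Detections and ground truths are tibbles with one row per box:
#   dets: image, class, x1, y1, x2, y2, score
#   gts:  image, class, x1, y1, x2, y2

# Greedy matching + 101-point interpolated AP for one class.
# gt_ignore marks ground truths excluded from a restricted evaluation:
# detections matching only an ignored GT are dropped (neither TP nor FP).
ap_one_class <- function(dets, gts, iou_thr, gt_ignore = NULL) {
  n_gt_all <- nrow(gts)
  if (is.null(gt_ignore)) gt_ignore <- rep(FALSE, n_gt_all)
  n_gt <- sum(!gt_ignore)
  if (n_gt == 0L) return(NA_real_)
  if (nrow(dets) == 0L) return(0)
  ord <- order(-dets$score)
  dets <- dets[ord, ]
  gt_used <- rep(FALSE, n_gt_all)
  state <- integer(nrow(dets))  # 1 TP, 0 FP, -1 ignored
  for (i in seq_len(nrow(dets))) {
    in_img <- which(gts$image == dets$image[i])
    if (length(in_img) == 0L) next
    db <- as.numeric(dets[i, c("x1", "y1", "x2", "y2")])
    ious <- vapply(in_img, function(j)
      iou(db, as.numeric(gts[j, c("x1", "y1", "x2", "y2")])), numeric(1))
    cand <- in_img[ious >= iou_thr & !gt_used[in_img] & !gt_ignore[in_img]]
    if (length(cand) > 0L) {
      best <- cand[which.max(ious[match(cand, in_img)])]
      gt_used[best] <- TRUE
      state[i] <- 1L
    } else if (any(ious >= iou_thr & gt_ignore[in_img])) {
      state[i] <- -1L
    }
  }
  keep <- state >= 0L
  tp <- cumsum(state[keep] == 1L)
  fp <- cumsum(state[keep] == 0L)
  if (length(tp) == 0L) return(0)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  rs <- seq(0, 1, by = 0.01)
  p_interp <- vapply(rs, function(r) {
    sel <- recall >= r - 1e-12
    if (!any(sel)) 0 else max(precision[sel])
  }, numeric(1))
  mean(p_interp)
}

#' Average precision at one IoU threshold
#'
#' Greedy highest-score-first matching (each ground truth matched at most
#' once, a match requires IoU at or above the threshold), followed by the
#' COCO-convention 101-point interpolated area under the precision-recall
#' curve.
#'
#' @param dets tibble with columns `image, x1, y1, x2, y2, score`.
#' @param gts tibble with columns `image, x1, y1, x2, y2`.
#' @param iou_thr IoU threshold for a match.
#' @return AP in `[0, 1]`; `NA` when there are no ground truths.
#' @export
average_precision <- function(dets, gts, iou_thr = 0.5) {
  ap_one_class(dets, gts, iou_thr)
}

size_ignore <- function(gts, lo, hi) {
  area <- (gts$x2 - gts$x1) * (gts$y2 - gts$y1)
  !(area >= lo & area < hi)
}

#' Full COCO-style evaluation report
#'
#' `mAP` averages AP over the classes present in the ground truth and over
#' IoU thresholds 0.50:0.05:0.95; `AP@50`/`AP@75` fix the threshold.
#' `AP@S/M/L` restrict the ground truths (and their matched detections) to
#' areas below 32^2, between 32^2 and 96^2, and above 96^2 pixels.
#'
#' @param dets detections tibble (`image, class, x1, y1, x2, y2, score`).
#' @param gts ground-truth tibble (`image, class, x1, y1, x2, y2`).
#' @param iou_thrs IoU thresholds averaged into mAP.
#' @return An `eval_report` list: `map, ap50, ap75, ap_s, ap_m, ap_l` and a
#'   `per_class` tibble.
#' @export
map_suite <- function(dets, gts, iou_thrs = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(gts$class))
  per <- lapply(classes, function(cl) {
    d <- dets[dets$class == cl, , drop = FALSE]
    g <- gts[gts$class == cl, , drop = FALSE]
    aps <- vapply(iou_thrs, function(t) ap_one_class(d, g, t), numeric(1))
    sizes <- list(s = c(0, 32^2), m = c(32^2, 96^2), l = c(96^2, Inf))
    size_ap <- vapply(sizes, function(rng) {
      ig <- size_ignore(g, rng[1], rng[2])
      mean(vapply(iou_thrs, function(t) ap_one_class(d, g, t, ig), numeric(1)))
    }, numeric(1))
    c(map = mean(aps), ap50 = aps[which.min(abs(iou_thrs - 0.5))],
      ap75 = aps[which.min(abs(iou_thrs - 0.75))],
      ap_s = size_ap[["s"]], ap_m = size_ap[["m"]], ap_l = size_ap[["l"]])
  })
  m <- do.call(rbind, per)
  agg <- colMeans(m, na.rm = TRUE)
  agg[is.nan(agg)] <- NA_real_
  structure(list(map = agg[["map"]], ap50 = agg[["ap50"]],
                 ap75 = agg[["ap75"]], ap_s = agg[["ap_s"]],
                 ap_m = agg[["ap_m"]], ap_l = agg[["ap_l"]],
                 per_class = tibble::tibble(class = classes,
                                            map = m[, "map"],
                                            ap50 = m[, "ap50"],
                                            ap75 = m[, "ap75"])),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("mAP %.3f | AP@50 %.3f | AP@75 %.3f | S/M/L %.3f/%.3f/%.3f\n",
              x$map, x$ap50, x$ap75, x$ap_s, x$ap_m, x$ap_l))
  invisible(x)
}

#' Aspect-ratio bucket of a box
#'
#' AR is the long side over the short side; buckets are `G1: AR < 2.5`,
#' `G2: 2.5 <= AR < 5`, `G3: 5 <= AR < 8`, `G4: AR >= 8` (half-open
#' boundaries).
#' @param w box width, or a length-4 box `c(x1, y1, x2, y2)` when `h` is
#'   missing.
#' @param h box height.
#' @return `"G1"`, `"G2"`, `"G3"` or `"G4"`.
#' @export
#' @examples
#' ar_bucket(10, 100)           # G4
#' ar_bucket(c(0, 0, 50, 10))   # AR 5 -> G3
ar_bucket <- function(w, h = NULL) {
  if (is.null(h)) { b <- w; w <- b[3] - b[1]; h <- b[4] - b[2] }
  ar <- max(w, h) / min(w, h)
  if (ar < 2.5) "G1" else if (ar < 5) "G2" else if (ar < 8) "G3" else "G4"
}

ecs_strip_set <- function(bp, H, W, strip_width = 3L) {
  # pixels inside the projected box within strip_width of any box edge
  xs <- (bp[1] + 1L):bp[3]
  ys <- (bp[2] + 1L):bp[4]
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  d_edge <- pmin(gx - bp[1] - 1L, bp[3] - gx,
                 gy - bp[2] - 1L, bp[4] - gy)
  edge <- d_edge < strip_width
  cbind(y = gy[edge], x = gx[edge])
}

#' Edge Concentration Score of an attention map
#'
#' For each ground-truth box, projected onto the map's grid, ECS is the
#' mean attention over the 3-pixel-wide strip just inside the box edges
#' divided by the mean over the whole map.  Values above 1 indicate
#' boundary-concentrated attention; any constant map scores exactly 1.
#'
#' @param attention `H x W` matrix of non-negative intensities.
#' @param boxes pixel boxes (n x 4 matrix, 0-based half-open).
#' @param stride image-to-map downsampling factor.
#' @param strip_width strip width in map pixels.
#' @return List with `per_box` (NA for boxes whose strip is empty after
#'   clipping) and `mean` over scored boxes.
#' @export
ecs <- function(attention, boxes, stride = 1L, strip_width = 3L) {
  H <- nrow(attention); W <- ncol(attention)
  mu_g <- mean(attention)
  if (mu_g <= 0) stopf("stripedet_cfg_error",
                       "attention map has no positive values")
  per <- vapply(seq_len(nrow(boxes)), function(i) {
    bp <- project_box(as.numeric(boxes[i, 1:4]), stride, fw = W, fh = H)
    if (is.null(bp)) {
      warning("box ", i, " empty after projection; skipped")
      return(NA_real_)
    }
    px <- ecs_strip_set(bp, H, W, strip_width)
    mean(attention[px]) / mu_g
  }, numeric(1))
  list(per_box = per, mean = mean(per, na.rm = TRUE))
}

#' Per-aspect-ratio-bucket evaluation
#'
#' Restricts the AP evaluation to ground truths in each bucket (other
#' ground truths and their matches are ignored) and scores each ground
#' truth's ECS on the spatial attention gate of its assigned pyramid
#' level.
#'
#' @param dets detections tibble.
#' @param gts ground-truth tibble.
#' @param gates named list (by image id) of per-level attention matrices.
#' @param strides pyramid strides, aligned with `gates[[img]]`.
#' @param iou_thrs IoU thresholds averaged into the bucket mAP.
#' @return Tibble with one row per non-empty bucket: `bucket, n_gt, map,
#'   mean_ecs`.
#' @export
bucketed_report <- function(dets, gts, gates, strides = c(8L, 16L, 32L, 64L),
                            iou_thrs = seq(0.5, 0.95, by = 0.05)) {
  buck <- vapply(seq_len(nrow(gts)), function(i)
    ar_bucket(as.numeric(gts[i, c("x1", "y1", "x2", "y2")])), character(1))
  classes <- sort(unique(gts$class))
  rows <- list()
  for (b in c("G1", "G2", "G3", "G4")) {
    sel <- buck == b
    if (!any(sel)) next
    aps <- vapply(classes, function(cl) {
      d <- dets[dets$class == cl, , drop = FALSE]
      g <- gts[gts$class == cl, , drop = FALSE]
      ig <- !(buck[gts$class == cl] == b)
      if (all(ig)) return(NA_real_)
      mean(vapply(iou_thrs, function(t) ap_one_class(d, g, t, ig), numeric(1)))
    }, numeric(1))
    ecs_vals <- vapply(which(sel), function(i) {
      img <- as.character(gts$image[i])
      box <- matrix(as.numeric(gts[i, c("x1", "y1", "x2", "y2")]), 1)
      lev <- assign_level(box[1, ], strides)
      ecs(gates[[img]][[lev]], box, stride = strides[lev])$mean
    }, numeric(1))
    rows[[b]] <- tibble::tibble(bucket = b, n_gt = sum(sel),
                                map = mean(aps, na.rm = TRUE),
                                mean_ecs = mean(ecs_vals, na.rm = TRUE))
  }
  dplyr::bind_rows(rows)
}
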
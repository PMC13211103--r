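# Topology reconstruction loss on the strip-response stacks.
#
# Each ground-truth box is assigned to the pyramid level whose stride best
# matches its scale, projected onto that level's grid, and the 3-channel
# strip responses inside it are cropped.  A rectangular mask (25% of the
# crop per side, minimum 2 px, uniformly placed, shared across channels)
# is filled with the channel-wise mean of the visible positions, and the
# loss is the mean squared deviation of the filled crop from the original,
# averaged over accepted RoIs.

#' Configuration for the reconstruction loss
#'
#' @param mask_ratio masked fraction of each crop dimension.
#' @param min_mask_px minimum mask side in feature pixels.
#' @param min_roi_px minimum feature-space box size: a RoI is accepted when
#'   either its height or its width reaches this many feature pixels.
#' @param w_tr weight of the loss in the total objective.
#' @param detach_target treat the original crop as a constant
#'   reconstruction target (stop-gradient); by default gradients flow
#'   through both the crop and the mean fill, treating masking as a
#'   training-time perturbation.
#' @return A `tr_config` list.
#' @export
tr_config <- function(mask_ratio = 0.25, min_mask_px = 2L,
                      min_roi_px = 4L, w_tr = 0.1,
                      detach_target = FALSE) {
  if (mask_ratio <= 0 || mask_ratio >= 1)
    stopf("stripedet_cfg_error", "mask_ratio must lie in (0, 1)")
  if (min_mask_px < 1) stopf("stripedet_cfg_error", "min_mask_px must be >= 1")
  structure(list(mask_ratio = mask_ratio,
                 min_mask_px = as.integer(min_mask_px),
                 min_roi_px = as.integer(min_roi_px),
                 w_tr = w_tr, detach_target = detach_target),
            class = "tr_config")
}

#' Project a pixel box onto a feature grid
#'
#' Divides by the stride, floors the top-left corner, ceils the
#' bottom-right, and clips to the level extent.
#' @param b pixel box `c(x1, y1, x2, y2)` (0-based half-open).
#' @param stride level stride.
#' @param fw,fh feature-grid width and height for clipping (optional).
#' @return Integer feature box `c(x1, y1, x2, y2)`, or `NULL` when empty
#'   after clipping.
#' @export
project_box <- function(b, stride, fw = Inf, fh = Inf) {
  out <- c(floor(b[1] / stride), floor(b[2] / stride),
           ceiling(b[3] / stride), ceiling(b[4] / stride))
  out <- c(max(out[1], 0), max(out[2], 0), min(out[3], fw), min(out[4], fh))
  if (out[3] <= out[1] || out[4] <= out[2]) return(NULL)
  as.integer(out)
}

#' Assign a box to a pyramid level by scale
#'
#' Picks the level minimizing `|log2(sqrt(area) / (8 * stride))|`, i.e. the
#' level where the box spans about 8 feature pixels; ties go to the finer
#' stride.
#' @param b pixel box `c(x1, y1, x2, y2)`.
#' @param strides ascending stride vector.
#' @return 1-based level index.
#' @export
assign_level <- function(b, strides = c(8L, 16L, 32L, 64L)) {
  scale <- sqrt(max((b[3] - b[1]) * (b[4] - b[2]), 1e-9))
  which.min(abs(log2(scale / (8 * strides))))
}

#' Sample a rectangular mask inside a crop
#'
#' Mask sides are `mask_ratio` of the crop sides, rounded half-up, clamped
#' to `[min_mask_px, side]`; the position is uniform over valid placements.
#' One rectangle, shared across the three strip channels.
#' @param h,w crop height and width (feature pixels).
#' @param cfg a [tr_config()].
#' @return `h x w` logical matrix.
#' @export
sample_mask <- function(h, w, cfg = tr_config()) {
  mh <- min(h, max(cfg$min_mask_px, floor(cfg$mask_ratio * h + 0.5)))
  mw <- min(w, max(cfg$min_mask_px, floor(cfg$mask_ratio * w + 0.5)))
  y0 <- if (h - mh > 0) sample.int(h - mh + 1L, 1L) else 1L
  x0 <- if (w - mw > 0) sample.int(w - mw + 1L, 1L) else 1L
  m <- matrix(FALSE, h, w)
  m[y0:(y0 + mh - 1L), x0:(x0 + mw - 1L)] <- TRUE
  m
}

#' Mean-fill reconstruction of a masked crop
#'
#' Masked positions receive the channel-wise mean over visible positions;
#' visible positions are copied unchanged.
#' @param s_roi `3 x h x w` array cropped from a strip stack.
#' @param mask `h x w` logical matrix.
#' @return The reconstructed array, or `NULL` when no position is visible
#'   (the RoI is then excluded from the loss).
#' @export
reconstruct <- function(s_roi, mask) {
  if (all(mask)) return(NULL)
  out <- s_roi
  for (c in 1:3) {
    ch <- s_roi[c, , ]
    out[c, , ][mask] <- mean(ch[!mask])
  }
  out
}

# Precompute accepted RoIs for one image: level assignment, projection,
# and a sampled mask each.  level_sizes: list of c(h, w) per level.
tr_prepare_rois <- function(boxes, cfg, level_sizes,
                            strides = c(8L, 16L, 32L, 64L)) {
  rois <- list()
  for (i in seq_len(nrow(boxes))) {
    b <- as.numeric(boxes[i, 1:4])
    lev <- assign_level(b, strides)
    fs <- level_sizes[[lev]]
    bp <- project_box(b, strides[lev], fw = fs[2], fh = fs[1])
    if (is.null(bp)) next
    h <- bp[4] - bp[2]; w <- bp[3] - bp[1]
    if (max(h, w) < cfg$min_roi_px) next
    mask <- sample_mask(h, w, cfg)
    if (all(mask)) next
    rois[[length(rois) + 1L]] <- list(level = lev, box = bp, mask = mask)
  }
  rois
}

tr_roi_value <- function(stack, roi) {
  bp <- roi$box
  crop <- stack[1, , bp[2]:(bp[4] - 1L) + 1L, bp[1]:(bp[3] - 1L) + 1L,
                drop = FALSE]
  dim(crop) <- dim(crop)[2:4]
  rec <- reconstruct(crop, roi$mask)
  h <- nrow(roi$mask); w <- ncol(roi$mask)
  val <- sum((rec - crop)^2) / (3 * h * w)
  list(value = val, crop = crop, rec = rec)
}

#' Topology reconstruction loss
#'
#' Mean over accepted RoIs of the per-RoI mean squared reconstruction
#' error `(1 / 3hw) * sum (S_recon - S_RoI)^2`; 0 when no RoI is accepted.
#' Training-only: the inference path never evaluates it.
#'
#' @param stacks list of strip-stack nodes/arrays, one per pyramid level,
#'   dim `(1, 3, H_l, W_l)`.
#' @param boxes ground-truth pixel boxes (n x 4 matrix, 0-based half-open).
#' @param cfg a [tr_config()].
#' @param strides level strides.
#' @param seed seed for mask placement.
#' @param tape optional `ad_tape`; gradients flow through both the crop and
#'   the mean fill unless `cfg$detach_target`.
#' @return Scalar (or scalar node) loss.
#' @export
tr_loss <- function(stacks, boxes, cfg = tr_config(),
                    strides = c(8L, 16L, 32L, 64L), seed = 1L, tape = NULL) {
  level_sizes <- lapply(stacks, function(s) dim(nv(s))[3:4])
  rois <- with_seed(seed, tr_prepare_rois(boxes, cfg, level_sizes, strides))
  tr_loss_rois(stacks, rois, cfg, tape)
}

# Core evaluation given prepared RoIs; shared by the numeric and training
# paths.
tr_loss_rois <- function(stacks, rois, cfg = tr_config(), tape = NULL) {
  any_node <- any(vapply(stacks, is_node, logical(1)))
  if (length(rois) == 0L) {
    return(if (any_node || !is.null(tape)) ad_node(0) else 0)
  }
  vals <- lapply(rois, function(r) tr_roi_value(nv(stacks[[r$level]]), r))
  total <- mean(vapply(vals, `[[`, numeric(1), "value"))
  if (!any_node && is.null(tape)) return(total)
  n <- length(rois)
  ad_op(tape, total, stacks, function(g) {
    gs <- lapply(stacks, function(s) array(0, dim = dim(nv(s))))
    for (j in seq_along(rois)) {
      r <- rois[[j]]
      v <- vals[[j]]
      mask <- r$mask
      h <- nrow(mask); w <- ncol(mask)
      diff <- v$rec - v$crop             # zero on visible cells
      # The fill depends on the visible cells, so every visible cell of a
      # channel receives +2 sum(diff)/(3hw |V|).  Masked cells appear only
      # in the target crop, contributing -2 diff/(3hw) unless the target
      # is treated as a stop-gradient constant.
      gcrop <- if (cfg$detach_target) diff * 0 else -2 * diff / (3 * h * w)
      nvis <- sum(!mask)
      for (c in 1:3) {
        add <- sum(diff[c, , ][mask]) * 2 / (3 * h * w * nvis)
        gcrop[c, , ][!mask] <- gcrop[c, , ][!mask] + add
      }
      bp <- r$box
      ys <- bp[2]:(bp[4] - 1L) + 1L
      xs <- bp[1]:(bp[3] - 1L) + 1L
      slice <- gs[[r$level]][1, , ys, xs, drop = FALSE]
      dim(gcrop) <- dim(slice)
      gs[[r$level]][1, , ys, xs] <- slice + gcrop / n
    }
    lapply(gs, function(gi) gi * as.numeric(g))
  })
}
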
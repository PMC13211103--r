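# Detector assembly: tiny backbone -> 4-level 96-channel pyramid (strides
# 8/16/32/64) -> per-level MS-LSAM -> shared anchor-free head, plus the
# training loop composing L_total = L_cls + L_loc + 0.35 L_ICC + 0.1 L_TR.

#' Detector configuration
#'
#' @param num_classes number of object classes.
#' @param pyramid_channels channels of every pyramid level (contract: 96).
#' @param strides pyramid strides (contract: 8, 16, 32, 64).
#' @param gate_type spatial attention branch: `"stripe"` (multi-scale strip
#'   convolutions, the default), `"square"` (3x3 ablation), or `"uniform"`
#'   (constant-gate control).
#' @param kernel_lengths strip kernel lengths.
#' @param reduction channel-attention reduction ratio.
#' @param w_icc,w_tr weights of the contrastive and reconstruction losses
#'   in the total objective.
#' @param icc an [icc_config()].
#' @param tr a [tr_config()].
#' @param lr,momentum,weight_decay,min_lr_ratio SGD settings; the learning
#'   rate follows a cosine schedule down to `lr * min_lr_ratio`.
#' @param focal_alpha,focal_gamma focal classification loss parameters.
#' @param score_thr,nms_iou prediction-time score threshold and NMS IoU.
#' @return A `model_config` list.
#' @export
model_config <- function(num_classes = 3L, pyramid_channels = 96L,
                         strides = c(8L, 16L, 32L, 64L),
                         gate_type = c("stripe", "square", "uniform"),
                         kernel_lengths = c(7L, 11L, 21L), reduction = 16L,
                         w_icc = 0.35, w_tr = 0.1,
                         icc = icc_config(), tr = tr_config(),
                         lr = 0.005, momentum = 0.937, weight_decay = 5e-4,
                         min_lr_ratio = 0.01,
                         focal_alpha = 0.25, focal_gamma = 2,
                         score_thr = 0.3, nms_iou = 0.5) {
  gate_type <- match.arg(gate_type)
  if (!identical(as.integer(strides), c(8L, 16L, 32L, 64L)))
    stopf("stripedet_cfg_error",
          "the pyramid contract requires strides 8/16/32/64")
  structure(list(num_classes = as.integer(num_classes),
                 pyramid_channels = as.integer(pyramid_channels),
                 strides = as.integer(strides), gate_type = gate_type,
                 kernel_lengths = as.integer(kernel_lengths),
                 reduction = as.integer(reduction),
                 w_icc = w_icc, w_tr = w_tr, icc = icc, tr = tr,
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 min_lr_ratio = min_lr_ratio,
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 score_thr = score_thr, nms_iou = nms_iou),
            class = "model_config")
}

conv_init <- function(co, ci, kh, kw) {
  list(W = he_init(c(co, ci, kh, kw), ci * kh * kw), b = numeric(co))
}

#' Build a detector model
#'
#' The tiny backbone is a stack of stride-2 3x3 convolutions whose last
#' four stages feed 1x1 lateral projections into a top-down pyramid; all
#' pyramid levels carry `pyramid_channels` channels at strides 8/16/32/64,
#' so a `640^2` input yields `80^2, 40^2, 20^2, 10^2` maps.  Each level is
#' refined by its own MS-LSAM instance; a shared head emits classification
#' logits and log-scale box distances.
#'
#' @param cfg a [model_config()].
#' @param seed seed for deterministic parameter initialization.
#' @return A `stripedet_model` list with `cfg` and the flat named parameter
#'   list `params`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  C <- cfg$pyramid_channels
  with_seed(seed, {
    p <- list()
    add <- function(prefix, l) {
      for (nm in names(l)) p[[paste0(prefix, ".", nm)]] <<- l[[nm]]
    }
    widths <- c(16L, 32L, 64L, 96L, 96L, 96L)
    ins <- c(3L, widths[-6])
    for (i in 1:6) add(paste0("bb", i), conv_init(widths[i], ins[i], 3L, 3L))
    lat_in <- widths[3:6]
    for (l in 1:4) add(paste0("lat", l), conv_init(C, lat_in[l], 1L, 1L))
    for (l in 1:4) add(paste0("smooth", l), conv_init(C, C, 3L, 3L))
    add("head.conv", conv_init(C, C, 3L, 3L))
    add("head.cls", conv_init(cfg$num_classes, C, 1L, 1L))
    add("head.reg", conv_init(4L, C, 1L, 1L))
    # bias the classification output towards background (focal-loss prior)
    p[["head.cls.b"]] <- rep(-3, cfg$num_classes)
    iccp <- icc_init(cfg$icc, seed = sample.int(2^31 - 1, 1))
    for (nm in names(iccp)) p[[paste0("icchead.", nm)]] <- iccp[[nm]]
    att_cfgs <- list()
    for (l in 1:4) {
      ap <- mslsam_init(C, cfg$reduction, cfg$kernel_lengths,
                        gate_type = cfg$gate_type,
                        seed = sample.int(2^31 - 1, 1))
      att_cfgs[[l]] <- attr(ap, "config")
      for (nm in names(ap)) p[[paste0("att", l, ".", nm)]] <- ap[[nm]]
    }
    structure(list(cfg = cfg, params = p, att_cfgs = att_cfgs),
              class = "stripedet_model")
  })
}

subset_params <- function(params, prefix, config = NULL) {
  sel <- startsWith(names(params), prefix)
  out <- params[sel]
  names(out) <- substring(names(out), nchar(prefix) + 1L)
  if (!is.null(config)) attr(out, "config") <- config
  out
}

#' Convert an H x W x 3 image array to a feature tensor
#' @param image array in `[0, 1]`.
#' @return Array of dim `(1, 3, H, W)`.
#' @export
img_to_tensor <- function(image) {
  d <- dim(image)
  x <- aperm(image, c(3, 1, 2))
  dim(x) <- c(1L, 3L, d[1], d[2])
  x
}

#' Detector forward pass
#'
#' @param model a `stripedet_model`.
#' @param x input node/array of dim `(B, 3, H, W)` with H, W divisible
#'   by 64.
#' @param tape optional `ad_tape`.
#' @return List with per-level lists `levels` (refined features), `stacks`
#'   (pre-sigmoid strip stacks), `gates` (spatial gates), `cls` and `reg`
#'   (head outputs).
#' @export
model_forward <- function(model, x, tape = NULL) {
  p <- model$params
  d <- dim(nv(x))
  if (d[3] %% 64 != 0 || d[4] %% 64 != 0)
    stopf("stripedet_cfg_error", "input size must be divisible by 64")
  conv <- function(h, prefix, stride = 1L, pad = 1L) {
    t_conv2d(h, p[[paste0(prefix, ".W")]], p[[paste0(prefix, ".b")]],
             stride = stride, padh = pad, padw = pad, tape = tape)
  }
  h <- x
  feats <- list()
  for (i in 1:6) {
    h <- t_relu(conv(h, paste0("bb", i), stride = 2L), tape)
    if (i >= 3) feats[[i - 2L]] <- h
  }
  lat <- lapply(1:4, function(l)
    conv(feats[[l]], paste0("lat", l), stride = 1L, pad = 0L))
  pyr <- vector("list", 4)
  pyr[[4]] <- lat[[4]]
  for (l in 3:1)
    pyr[[l]] <- t_add(lat[[l]], t_upsample2(pyr[[l + 1]], tape), tape)
  pyr <- lapply(1:4, function(l) conv(pyr[[l]], paste0("smooth", l)))
  levels <- vector("list", 4)
  stacks <- vector("list", 4)
  gates <- vector("list", 4)
  for (l in 1:4) {
    ap <- subset_params(p, paste0("att", l, "."), model$att_cfgs[[l]])
    ms <- mslsam_forward(pyr[[l]], ap, tape)
    levels[[l]] <- ms$refined
    stacks[[l]] <- ms$strip_stack
    gates[[l]] <- ms$spatial_gate
  }
  cls <- vector("list", 4)
  reg <- vector("list", 4)
  for (l in 1:4) {
    hh <- t_relu(conv(levels[[l]], "head.conv"), tape)
    cls[[l]] <- conv(hh, "head.cls", pad = 0L)
    reg[[l]] <- conv(hh, "head.reg", pad = 0L)
  }
  list(levels = levels, stacks = stacks, gates = gates, cls = cls, reg = reg)
}

# --- head losses ---------------------------------------------------------

# focal classification loss on sigmoid logits; normalized by the number of
# positive locations (at least 1)
t_focal <- function(logits, targets, alpha, gamma, npos, tape = NULL) {
  x <- nv(logits)
  pr <- 1 / (1 + exp(-x))
  pt <- targets * pr + (1 - targets) * (1 - pr)
  at <- targets * alpha + (1 - targets) * (1 - alpha)
  eps <- 1e-12
  fl <- -at * (1 - pt)^gamma * log(pmax(pt, eps))
  norm <- max(npos, 1)
  val <- sum(fl) / norm
  ad_op(tape, val, list(logits), function(g) {
    gx <- -at * (2 * targets - 1) * pr * (1 - pr) *
      ((1 - pt)^gamma / pmax(pt, eps) -
       gamma * (1 - pt)^(gamma - 1) * log(pmax(pt, eps)))
    list(shaped(gx / norm * as.numeric(g), x))
  })
}

# IoU box regression loss: pred and target are (N, 4) positive l/t/r/b
# distances in stride units; loss is mean(1 - IoU).
t_iouloss <- function(pred, target, tape = NULL) {
  q <- nv(pred); g <- target
  n <- nrow(q)
  wi <- pmin(q[, 1], g[, 1]) + pmin(q[, 3], g[, 3])
  hi <- pmin(q[, 2], g[, 2]) + pmin(q[, 4], g[, 4])
  I <- wi * hi
  Ap <- (q[, 1] + q[, 3]) * (q[, 2] + q[, 4])
  Ag <- (g[, 1] + g[, 3]) * (g[, 2] + g[, 4])
  U <- Ap + Ag - I
  iou_v <- I / U
  val <- mean(1 - iou_v)
  ad_op(tape, val, list(pred), function(gr) {
    gq <- matrix(0, n, 4)
    for (k in 1:4) {
      horiz <- k %in% c(1, 3)
      dI <- (q[, k] < g[, k]) * (if (horiz) hi else wi)
      dAp <- if (horiz) q[, 2] + q[, 4] else q[, 1] + q[, 3]
      dU <- dAp - dI
      diou <- (dI * U - I * dU) / U^2
      gq[, k] <- -diou / n
    }
    list(gq * as.numeric(gr))
  })
}

# Assign ground-truth boxes to head locations.  Returns, per level, the
# one-hot classification target matrix plus positive rows and their l/t/r/b
# targets (in stride units).
assign_targets <- function(boxes, labels, cfg, level_sizes) {
  strides <- cfg$strides
  K <- cfg$num_classes
  out <- lapply(seq_along(strides), function(l) {
    hw <- level_sizes[[l]]
    list(cls = matrix(0, hw[1] * hw[2], K),
         pos_idx = integer(0), pos_ltrb = NULL,
         area = rep(Inf, hw[1] * hw[2]))
  })
  if (length(labels) == 0L) return(out)
  for (i in seq_len(nrow(boxes))) {
    b <- as.numeric(boxes[i, 1:4])
    lev <- assign_level(b, strides)
    s <- strides[lev]
    hw <- level_sizes[[lev]]
    area <- (b[3] - b[1]) * (b[4] - b[2])
    bcx <- (b[1] + b[3]) / 2; bcy <- (b[2] + b[4]) / 2
    # candidate rows/cols: centres inside the box and near its centre
    jj <- which((seq_len(hw[2]) - 0.5) * s >= b[1] &
                (seq_len(hw[2]) - 0.5) * s < b[3] &
                abs((seq_len(hw[2]) - 0.5) * s - bcx) <= 1.5 * s)
    ii <- which((seq_len(hw[1]) - 0.5) * s >= b[2] &
                (seq_len(hw[1]) - 0.5) * s < b[4] &
                abs((seq_len(hw[1]) - 0.5) * s - bcy) <= 1.5 * s)
    if (length(jj) == 0L)
      jj <- max(1L, min(hw[2], round(bcx / s + 0.5)))
    if (length(ii) == 0L)
      ii <- max(1L, min(hw[1], round(bcy / s + 0.5)))
    for (jx in jj) for (iy in ii) {
      # row index in the (b, h, w) flattening used by t_bhwc_matrix (B = 1)
      ridx <- iy + (jx - 1L) * hw[1]
      if (out[[lev]]$area[ridx] <= area) next
      px <- (jx - 0.5) * s; py <- (iy - 0.5) * s
      ltrb <- pmax(c(px - b[1], py - b[2], b[3] - px, b[4] - py) / s, 0.05)
      out[[lev]]$area[ridx] <- area
      out[[lev]]$cls[ridx, ] <- 0
      out[[lev]]$cls[ridx, labels[i]] <- 1
      keep <- out[[lev]]$pos_idx != ridx
      out[[lev]]$pos_idx <- c(out[[lev]]$pos_idx[keep], ridx)
      out[[lev]]$pos_ltrb <- rbind(out[[lev]]$pos_ltrb[keep, , drop = FALSE],
                                   ltrb)
    }
  }
  out
}

# detection (head) loss for a single image forward pass
detection_loss <- function(fw, boxes, labels, cfg, tape = NULL) {
  level_sizes <- lapply(fw$cls, function(x) dim(nv(x))[3:4])
  tg <- assign_targets(boxes, labels, cfg, level_sizes)
  cls_mats <- lapply(fw$cls, function(x) t_bhwc_matrix(x, tape))
  logits <- Reduce(function(a, b) rbind_nodes(a, b, tape), cls_mats)
  targets <- do.call(rbind, lapply(tg, `[[`, "cls"))
  npos <- sum(vapply(tg, function(t) length(t$pos_idx), integer(1)))
  l_cls <- t_focal(logits, targets, cfg$focal_alpha, cfg$focal_gamma,
                   npos, tape)
  if (npos == 0L) return(list(l_cls = l_cls, l_loc = ad_node(0), npos = 0L))
  preds <- list(); gts <- list()
  for (l in seq_along(tg)) {
    if (length(tg[[l]]$pos_idx) == 0L) next
    rm_ <- t_bhwc_matrix(fw$reg[[l]], tape)
    sel <- t_select_rows(rm_, tg[[l]]$pos_idx, tape)
    preds[[length(preds) + 1L]] <- t_exp(sel, tape)
    gts[[length(gts) + 1L]] <- tg[[l]]$pos_ltrb
  }
  pred <- Reduce(function(a, b) rbind_nodes(a, b, tape), preds)
  l_loc <- t_iouloss(pred, do.call(rbind, gts), tape)
  list(l_cls = l_cls, l_loc = l_loc, npos = npos)
}

#' Total training objective
#'
#' `L_total = L_cls + L_loc + w_icc * L_ICC + w_tr * L_TR`.
#' @param l_cls,l_loc,l_icc,l_tr scalar loss components (numbers or nodes).
#' @param cfg a [model_config()] supplying the weights.
#' @param tape optional `ad_tape`.
#' @return Scalar (or scalar node).
#' @export
total_loss <- function(l_cls, l_loc, l_icc, l_tr, cfg = model_config(),
                       tape = NULL) {
  comps <- c(as.numeric(nv(l_cls)), as.numeric(nv(l_loc)),
             as.numeric(nv(l_icc)), as.numeric(nv(l_tr)))
  if (any(!is.finite(comps)))
    stopf("stripedet_nan_error",
          "non-finite loss component: cls=%g loc=%g icc=%g tr=%g",
          comps[1], comps[2], comps[3], comps[4])
  if (is.null(tape) && !any(vapply(list(l_cls, l_loc, l_icc, l_tr),
                                   is_node, logical(1))))
    return(comps[1] + comps[2] + cfg$w_icc * comps[3] + cfg$w_tr * comps[4])
  t_wsum(list(l_cls, l_loc, l_icc, l_tr), c(1, 1, cfg$w_icc, cfg$w_tr), tape)
}

# --- training ------------------------------------------------------------

load_voc_dir <- function(data_dir, classes, split = "train") {
  list_file <- file.path(data_dir, "ImageSets", "Main",
                         paste0(split, ".txt"))
  ids <- if (file.exists(list_file)) readLines(list_file) else
    sub("\\.xml$", "", list.files(file.path(data_dir, "Annotations"),
                                  pattern = "\\.xml$"))
  if (length(ids) == 0L)
    stopf("stripedet_io_error", "no annotations found under %s", data_dir)
  lapply(ids, function(id) {
    sc <- read_voc(file.path(data_dir, "Annotations", paste0(id, ".xml")),
                   classes)
    img <- png::readPNG(file.path(data_dir, "JPEGImages",
                                  sc$filename %||% paste0(id, ".png")))
    sc$image <- img[, , 1:3, drop = FALSE]
    sc
  })
}

#' Train the detector
#'
#' SGD with momentum, weight decay and a cosine learning-rate schedule.
#' Each step draws two augmented views of one scene: the detection loss
#' (focal classification + IoU box regression) is computed on the first
#' view, the contrastive loss across both views, and the reconstruction
#' loss on the first view's strip stacks.  Deterministic given `seed`.
#'
#' @param data list of `annotated_scene`s with pixel data, or a VOC dataset
#'   directory (as written by [generate_dataset()]).
#' @param cfg a [model_config()].
#' @param steps number of optimizer steps (one image per step).
#' @param seed integer seed for initialization, augmentation, and masking.
#' @param model optionally continue training an existing model.
#' @param aug an [augment_config()]; set `flip_prob = 0` etc. for weaker
#'   augmentation.
#' @param classes class table used when `data` is a directory.
#' @param verbose print a line every 25 steps.
#' @return The trained `stripedet_model`, with a per-step loss `log`
#'   tibble (`step, lr, l_cls, l_loc, l_inst, l_ccls, l_tr, total`)
#'   attached.
#' @export
train_detector <- function(data, cfg = model_config(), steps = 100L,
                           seed = 1L, model = NULL,
                           aug = augment_config(),
                           classes = default_classes(cfg$num_classes),
                           verbose = FALSE) {
  scenes <- if (is.character(data)) load_voc_dir(data, classes) else data
  if (length(scenes) == 0L) stopf("stripedet_io_error", "empty dataset")
  if (is.null(model)) model <- build_model(cfg, seed)
  cfg <- model$cfg
  params <- model$params
  vel <- lapply(params, function(a) a * 0)
  use_icc <- cfg$w_icc > 0
  use_tr <- cfg$w_tr > 0
  log <- vector("list", steps)
  with_seed(seed + 1L, {
    order_idx <- integer(0)
    for (step in seq_len(steps)) {
      if (length(order_idx) == 0L) order_idx <- sample(seq_along(scenes))
      si <- order_idx[1]
      order_idx <- order_idx[-1]
      sc <- scenes[[si]]
      pair_seed <- sample.int(2^31 - 1, 1)
      views <- make_paired_views(sc, aug, seed = pair_seed)
      tape <- ad_tape()
      pn <- lapply(params, function(a) ad_node(a, tape))
      W <- sc$width; H <- sc$height
      v1 <- views$view1
      fw1 <- model_forward(list(cfg = cfg, params = pn,
                                att_cfgs = model$att_cfgs),
                           img_to_tensor(v1$image), tape)
      b1px <- cbind(v1$boxes$x1 * W, v1$boxes$y1 * H,
                    v1$boxes$x2 * W, v1$boxes$y2 * H)
      det <- detection_loss(fw1, b1px, v1$boxes$label, cfg, tape)
      l_icc <- ad_node(0); l_inst <- ad_node(0); l_ccls <- ad_node(0)
      if (use_icc && nrow(v1$boxes) > 0) {
        v2 <- views$view2
        fw2 <- model_forward(list(cfg = cfg, params = pn,
                                  att_cfgs = model$att_cfgs),
                             img_to_tensor(v2$image), tape)
        ic <- icc_loss(list(fw1$levels[[2]], fw1$levels[[3]]),
                       list(fw2$levels[[2]], fw2$levels[[3]]),
                       v1$boxes, v2$boxes,
                       subset_params(pn, "icchead."), cfg$icc, tape)
        l_icc <- ic$l_icc; l_inst <- ic$l_inst; l_ccls <- ic$l_cls
      }
      l_tr <- ad_node(0)
      if (use_tr && nrow(v1$boxes) > 0) {
        l_tr <- tr_loss(fw1$stacks, b1px, cfg$tr, cfg$strides,
                        seed = sample.int(2^31 - 1, 1), tape = tape)
      }
      total <- total_loss(det$l_cls, det$l_loc, l_icc, l_tr, cfg, tape)
      ad_backward(total, tape)
      lr_t <- cfg$lr * (cfg$min_lr_ratio +
        0.5 * (1 - cfg$min_lr_ratio) * (1 + cos(pi * (step - 1) / steps)))
      for (nm in names(params)) {
        g <- pn[[nm]]$grad
        if (is.null(g)) next
        g <- g + cfg$weight_decay * params[[nm]]
        vel[[nm]] <- cfg$momentum * vel[[nm]] + g
        params[[nm]] <- params[[nm]] - lr_t * shaped(vel[[nm]], params[[nm]])
      }
      log[[step]] <- tibble::tibble(
        step = step, lr = lr_t,
        l_cls = as.numeric(nv(det$l_cls)), l_loc = as.numeric(nv(det$l_loc)),
        l_inst = as.numeric(nv(l_inst)), l_ccls = as.numeric(nv(l_ccls)),
        l_tr = as.numeric(nv(l_tr)), total = as.numeric(nv(total)))
      if (verbose && step %% 25 == 0)
        message(sprintf("step %d: total %.4f", step, as.numeric(nv(total))))
    }
  })
  model$params <- params
  model$log <- dplyr::bind_rows(log)
  model
}

# --- prediction ----------------------------------------------------------

#' Greedy non-maximum suppression
#' @param boxes n x 4 matrix, `scores` numeric vector.
#' @param iou_thr suppression threshold.
#' @return Indices of kept boxes, highest score first.
#' @export
nms <- function(boxes, scores, iou_thr = 0.5) {
  ord <- order(-scores)
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) == 0L) break
    ious <- iou_matrix(matrix(boxes[i, ], 1), boxes[ord, , drop = FALSE])
    ord <- ord[ious[1, ] <= iou_thr]
  }
  keep
}

#' Run the detector on one image
#'
#' Forward pass (auxiliary losses are training-only and never evaluated
#' here), sigmoid score decoding, per-class greedy NMS.
#'
#' @param model a trained `stripedet_model`.
#' @param image H x W x 3 array in `[0, 1]`, sides divisible by 64.
#' @param score_thr minimum class score.
#' @param nms_iou NMS IoU threshold.
#' @return Tibble `x1, y1, x2, y2, score, class` (pixel coords, clipped to
#'   the image).
#' @export
predict_boxes <- function(model, image, score_thr = model$cfg$score_thr,
                          nms_iou = model$cfg$nms_iou) {
  fw <- model_forward(model, img_to_tensor(image))
  decode_detections(fw, model$cfg, dim(image)[1:2], score_thr, nms_iou)
}

decode_detections <- function(fw, cfg, hw_img, score_thr, nms_iou) {
  out <- list()
  for (l in seq_along(cfg$strides)) {
    s <- cfg$strides[l]
    cl <- nv(fw$cls[[l]])
    rg <- nv(fw$reg[[l]])
    d <- dim(cl)
    for (iy in seq_len(d[3])) for (jx in seq_len(d[4])) {
      sc <- 1 / (1 + exp(-cl[1, , iy, jx]))
      k <- which.max(sc)
      if (sc[k] < score_thr) next
      px <- (jx - 0.5) * s; py <- (iy - 0.5) * s
      ltrb <- exp(rg[1, , iy, jx]) * s
      out[[length(out) + 1L]] <- c(px - ltrb[1], py - ltrb[2],
                                   px + ltrb[3], py + ltrb[4], sc[k], k)
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                          y2 = numeric(0), score = numeric(0),
                          class = integer(0)))
  m <- do.call(rbind, out)
  m[, 1] <- pmax(m[, 1], 0); m[, 2] <- pmax(m[, 2], 0)
  m[, 3] <- pmin(m[, 3], hw_img[2]); m[, 4] <- pmin(m[, 4], hw_img[1])
  keep <- integer(0)
  for (k in unique(m[, 6])) {
    idx <- which(m[, 6] == k)
    keep <- c(keep, idx[nms(m[idx, 1:4, drop = FALSE], m[idx, 5], nms_iou)])
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(-m[, 5]), , drop = FALSE]
  tibble::tibble(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4],
                 score = m[, 5], class = as.integer(m[, 6]))
}

#' Evaluate a model on a set of scenes
#'
#' Runs detection on every scene and returns the detection and ground
#' truth tibbles together with the per-level spatial attention gates
#' (for ECS analysis).
#'
#' @param model a `stripedet_model`.
#' @param scenes list of `annotated_scene`s with pixel data.
#' @param score_thr score threshold (kept low so the PR curve is filled).
#' @return List with `dets`, `gts`, `gates` ready for [map_suite()] and
#'   [bucketed_report()].
#' @export
evaluate_model <- function(model, scenes, score_thr = 0.05) {
  dets <- list(); gts <- list(); gates <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    img_id <- as.character(i)
    fw <- model_forward(model, img_to_tensor(sc$image))
    d <- decode_detections(fw, model$cfg, c(sc$height, sc$width),
                           score_thr, model$cfg$nms_iou)
    if (nrow(d) > 0) dets[[i]] <- tibble::tibble(image = img_id, class = d$class,
                                                 x1 = d$x1, y1 = d$y1,
                                                 x2 = d$x2, y2 = d$y2,
                                                 score = d$score)
    if (nrow(sc$boxes) > 0)
      gts[[i]] <- tibble::tibble(image = img_id, class = sc$labels,
                                 x1 = sc$boxes[, 1], y1 = sc$boxes[, 2],
                                 x2 = sc$boxes[, 3], y2 = sc$boxes[, 4])
    gates[[img_id]] <- lapply(fw$gates, function(g) {
      v <- nv(g)
      matrix(v[1, 1, , ], dim(v)[3], dim(v)[4])
    })
  }
  list(dets = dplyr::bind_rows(dets), gts = dplyr::bind_rows(gts),
       gates = gates)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: the configuration travels with the
#' weights.
#' @param model a `stripedet_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
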
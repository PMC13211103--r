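# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written with plain loops / base matrix algebra and
# never calls into the package's computational-graph ops.

sigm <- function(x) 1 / (1 + exp(-x))

# Brute-force MS-LSAM forward on a (B, C, H, W) array with "stripe" params.
oracle_mslsam <- function(x, params) {
  cfg <- attr(params, "config")
  d <- dim(x)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  # channel gate
  gate_c <- matrix(0, B, C)
  for (b in seq_len(B)) {
    favg <- vapply(seq_len(C), function(c) mean(x[b, c, , ]), numeric(1))
    fmax <- vapply(seq_len(C), function(c) max(x[b, c, , ]), numeric(1))
    mlp <- function(v)
      drop(pmax(drop(v %*% params$mlp.W1) + params$mlp.b1, 0) %*%
             params$mlp.W2) + params$mlp.b2
    gate_c[b, ] <- sigm(mlp(favg) + mlp(fmax))
  }
  xp <- x
  for (b in seq_len(B)) for (c in seq_len(C))
    xp[b, c, , ] <- x[b, c, , ] * gate_c[b, c]
  # spatial descriptor
  fs <- array(0, dim = c(B, 2, H, W))
  for (b in seq_len(B)) for (i in seq_len(H)) for (j in seq_len(W)) {
    fs[b, 1, i, j] <- mean(xp[b, , i, j])
    fs[b, 2, i, j] <- max(xp[b, , i, j])
  }
  # strip responses
  strip_conv <- function(b, Wt, bias, horizontal, k) {
    out <- matrix(0, H, W)
    r <- k %/% 2
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- bias
      for (t in -r:r) {
        ii <- if (horizontal) i else i + t
        jj <- if (horizontal) j + t else j
        if (ii < 1 || ii > H || jj < 1 || jj > W) next
        for (c in 1:2) {
          wv <- if (horizontal) Wt[1, c, 1, t + r + 1] else Wt[1, c, t + r + 1, 1]
          acc <- acc + fs[b, c, ii, jj] * wv
        }
      }
      out[i, j] <- acc
    }
    out
  }
  S <- array(0, dim = c(B, 3, H, W))
  for (b in seq_len(B)) {
    for (ki in seq_along(cfg$kernel_lengths)) {
      k <- cfg$kernel_lengths[ki]
      ah <- strip_conv(b, params[[sprintf("strip.h%d.W", k)]],
                       params[[sprintf("strip.h%d.b", k)]], TRUE, k)
      av <- strip_conv(b, params[[sprintf("strip.v%d.W", k)]],
                       params[[sprintf("strip.v%d.b", k)]], FALSE, k)
      S[b, ki, , ] <- pmax(ah, av)
    }
  }
  gate_s <- array(0, dim = c(B, 1, H, W))
  refined <- xp
  for (b in seq_len(B)) {
    fused <- (S[b, 1, , ] + S[b, 2, , ] + S[b, 3, , ]) / 3
    gate_s[b, 1, , ] <- sigm(fused)
    for (c in seq_len(C)) refined[b, c, , ] <- xp[b, c, , ] * sigm(fused)
  }
  list(refined = refined, channel_gate = gate_c, spatial_gate = gate_s,
       strip_stack = S)
}

# Brute-force bilinear RoI align + pooled fusion of two levels.
# feat: (1, C, H, W); box: normalized c(x1, y1, x2, y2); out: C-vector.
oracle_roi_pool <- function(feat, box, n_bins = 7) {
  d <- dim(feat)
  C <- d[2]; H <- d[3]; W <- d[4]
  sample_at <- function(c, cy, cx) {
    fy <- min(max(cy - 0.5, 0), H - 1)
    fx <- min(max(cx - 0.5, 0), W - 1)
    y0 <- min(max(floor(fy), 0), H - 2 + (H == 1)); y1 <- min(y0 + 1, H - 1)
    x0 <- min(max(floor(fx), 0), W - 2 + (W == 1)); x1 <- min(x0 + 1, W - 1)
    wy <- fy - y0; wx <- fx - x0
    if (H == 1) { y0 <- 0; y1 <- 0; wy <- 0 }
    if (W == 1) { x0 <- 0; x1 <- 0; wx <- 0 }
    (1 - wy) * ((1 - wx) * feat[1, c, y0 + 1, x0 + 1] +
                wx * feat[1, c, y0 + 1, x1 + 1]) +
      wy * ((1 - wx) * feat[1, c, y1 + 1, x0 + 1] +
            wx * feat[1, c, y1 + 1, x1 + 1])
  }
  out <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
      cy <- (box[2] + (i - 0.5) * (box[4] - box[2]) / n_bins) * H
      cx <- (box[1] + (j - 0.5) * (box[3] - box[1]) / n_bins) * W
      acc <- acc + sample_at(c, cy, cx)
    }
    out[c] <- acc / n_bins^2
  }
  out
}

oracle_roi_fuse <- function(f3, f4, box, n_bins = 7) {
  (oracle_roi_pool(f3, box, n_bins) + oracle_roi_pool(f4, box, n_bins)) / 2
}

# Reference brute-force detection evaluator.  dets/gts: data frames with
# image, class, x1..y2(, score).  Implements greedy highest-score-first
# matching and 101-point interpolated AP with its own IoU code.
ref_iou <- function(a, b) {
  ia <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ib <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ia * ib
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / ua
}

ref_ap <- function(dets, gts, thr, gt_ignore = rep(FALSE, nrow(gts))) {
  n_gt <- sum(!gt_ignore)
  if (n_gt == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  dets <- dets[order(dets$score, decreasing = TRUE), , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  flags <- character(0)
  for (i in seq_len(nrow(dets))) {
    best <- 0; best_j <- 0; ign_hit <- FALSE
    for (j in seq_len(nrow(gts))) {
      if (gts$image[j] != dets$image[i]) next
      v <- ref_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                   as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v < thr) next
      if (gt_ignore[j]) { ign_hit <- TRUE; next }
      if (used[j]) next
      if (v > best) { best <- v; best_j <- j }
    }
    if (best_j > 0) { used[best_j] <- TRUE; flags <- c(flags, "tp") }
    else if (ign_hit) flags <- c(flags, "ign")
    else flags <- c(flags, "fp")
  }
  flags <- flags[flags != "ign"]
  if (length(flags) == 0) return(0)
  tp <- cumsum(flags == "tp"); fp <- cumsum(flags == "fp")
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    sel <- rec >= r - 1e-12
    total <- total + if (any(sel)) max(prec[sel]) else 0
  }
  total / 101
}

ref_map_suite <- function(dets, gts, thrs = seq(0.5, 0.95, by = 0.05)) {
  classes <- sort(unique(gts$class))
  per <- sapply(classes, function(cl) {
    d <- dets[dets$class == cl, , drop = FALSE]
    g <- gts[gts$class == cl, , drop = FALSE]
    area <- (g$x2 - g$x1) * (g$y2 - g$y1)
    aps <- sapply(thrs, function(t) ref_ap(d, g, t))
    c(map = mean(aps), ap50 = aps[1], ap75 = aps[6],
      ap_s = mean(sapply(thrs, function(t) ref_ap(d, g, t, !(area < 32^2)))),
      ap_m = mean(sapply(thrs, function(t)
        ref_ap(d, g, t, !(area >= 32^2 & area < 96^2)))),
      ap_l = mean(sapply(thrs, function(t) ref_ap(d, g, t, !(area >= 96^2)))))
  })
  rowMeans(per, na.rm = TRUE)
}

# Random evaluation fixtures: a few images, 2 classes, ground truths with
# perturbed/decoy detections.
random_eval_fixture <- function(n_img = 3, n_cls = 2) {
  gts <- list(); dets <- list()
  for (im in seq_len(n_img)) {
    n <- sample(1:4, 1)
    for (q in seq_len(n)) {
      w <- runif(1, 10, 120); h <- runif(1, 10, 120)
      x1 <- runif(1, 0, 500); y1 <- runif(1, 0, 500)
      cl <- sample(n_cls, 1)
      gts[[length(gts) + 1]] <- data.frame(image = im, class = cl,
                                           x1 = x1, y1 = y1,
                                           x2 = x1 + w, y2 = y1 + h)
      if (runif(1) < 0.8) {  # jittered detection
        j <- runif(4, -8, 8)
        dets[[length(dets) + 1]] <- data.frame(
          image = im, class = if (runif(1) < 0.9) cl else sample(n_cls, 1),
          x1 = x1 + j[1], y1 = y1 + j[2], x2 = x1 + w + j[3],
          y2 = y1 + h + j[4], score = runif(1))
      }
      if (runif(1) < 0.4) {  # decoy false positive
        dets[[length(dets) + 1]] <- data.frame(
          image = im, class = sample(n_cls, 1),
          x1 = runif(1, 0, 500), y1 = runif(1, 0, 500),
          x2 = runif(1, 510, 620), y2 = runif(1, 510, 620),
          score = runif(1))
      }
    }
  }
  list(dets = do.call(rbind, dets), gts = do.call(rbind, gts))
}

# Small random scene with pixel data for round-trip / augmentation tests.
random_scene <- function(seed, size = 64, n = 2) {
  spec <- stripedet::scene_spec(image_size = size, n_objects = c(n, n),
                                length_frac_range = c(0.2, 0.5),
                                occlusion_fraction_range = c(0, 0.3),
                                seed = seed)
  stripedet::generate_scene(spec)
}
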
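# Dual-level RoI contrastive regularization (instance + class branches).
#
# Ground-truth boxes from the two augmented views are RoI-aligned on the
# stride-16 and stride-32 pyramid levels, pooled and averaged into one
# 96-vector per RoI, projected by two separate MLP heads into unit-norm
# 128-d embeddings, and optimized with a supervised contrastive loss: the
# instance branch pairs the two views of the same object (temperature
# 0.07), the class branch pulls same-class objects together (temperature
# 0.15).

#' Configuration for the contrastive regulariser
#'
#' @param roi_output spatial size of RoI alignment patches.
#' @param feature_dim pyramid channel count (96).
#' @param hidden_dim,embed_dim projection head dimensions (96 -> 256 -> 128).
#' @param tau_inst,tau_cls temperatures of the instance and class branches.
#' @param w_inst,w_cls branch weights in the combined loss.
#' @param include_self include the anchor itself in the contrastive
#'   denominator (the literal printed form); default excludes it, the
#'   standard supervised-contrastive reading.
#' @return An `icc_config` list.
#' @export
icc_config <- function(roi_output = 7L, feature_dim = 96L,
                       hidden_dim = 256L, embed_dim = 128L,
                       tau_inst = 0.07, tau_cls = 0.15,
                       w_inst = 0.05, w_cls = 0.3,
                       include_self = FALSE) {
  if (tau_inst <= 0 || tau_cls <= 0)
    stopf("stripedet_cfg_error", "temperatures must be positive")
  if (w_inst < 0 || w_cls < 0)
    stopf("stripedet_cfg_error", "branch weights must be non-negative")
  structure(list(roi_output = as.integer(roi_output),
                 feature_dim = as.integer(feature_dim),
                 hidden_dim = as.integer(hidden_dim),
                 embed_dim = as.integer(embed_dim),
                 tau_inst = tau_inst, tau_cls = tau_cls,
                 w_inst = w_inst, w_cls = w_cls,
                 include_self = include_self),
            class = "icc_config")
}

#' Initialize the two projection heads
#'
#' Identical architecture, separate weights.
#' @param cfg an [icc_config()].
#' @param seed seed for weight initialization.
#' @export
icc_init <- function(cfg = icc_config(), seed = 1L) {
  with_seed(seed, {
    head <- function() list(
      W1 = he_init(c(cfg$feature_dim, cfg$hidden_dim), cfg$feature_dim),
      b1 = numeric(cfg$hidden_dim),
      W2 = he_init(c(cfg$hidden_dim, cfg$embed_dim), cfg$hidden_dim),
      b2 = numeric(cfg$embed_dim))
    h1 <- head(); h2 <- head()
    p <- list()
    for (nm in names(h1)) p[[paste0("inst.", nm)]] <- h1[[nm]]
    for (nm in names(h2)) p[[paste0("cls.", nm)]] <- h2[[nm]]
    p
  })
}

boxes_to_rois <- function(boxes, batch_idx = 0L) {
  # boxes: tibble or matrix with normalized x1,y1,x2,y2
  b <- as.matrix(boxes[, c("x1", "y1", "x2", "y2")])
  if (any(b[, 3] - b[, 1] <= 0) || any(b[, 4] - b[, 2] <= 0))
    stopf("stripedet_box_error", "degenerate RoI box (zero area)")
  cbind(rep(batch_idx, nrow(b)), b)
}

#' Fuse RoI features from the two intermediate pyramid levels
#'
#' RoI-aligns a patch per box from each of the stride-16 and stride-32
#' levels, average-pools each patch to a vector, and returns the mean of
#' the two per-level vectors.
#'
#' @param f3,f4 feature nodes/arrays, dim `(B, 96, H, W)` at strides 16 and
#'   32.
#' @param boxes normalized boxes (tibble or matrix with columns x1..y2).
#' @param cfg an [icc_config()].
#' @param tape optional `ad_tape`.
#' @param batch_idx 0-based image index within the batch.
#' @return `(n_boxes, feature_dim)` matrix node.
#' @export
roi_fuse <- function(f3, f4, boxes, cfg = icc_config(), tape = NULL,
                     batch_idx = 0L) {
  rois <- boxes_to_rois(boxes, batch_idx)
  v3 <- t_roi_mean(t_roi_align(f3, rois, cfg$roi_output, cfg$roi_output, tape), tape)
  v4 <- t_roi_mean(t_roi_align(f4, rois, cfg$roi_output, cfg$roi_output, tape), tape)
  t_scale(t_add(v3, v4, tape), 0.5, tape)
}

#' Project RoI vectors into the contrastive embedding space
#'
#' `z = l2norm(FC2(relu(FC1(v))))`; rows of the result are unit vectors.
#' @param v `(n, feature_dim)` matrix node/array.
#' @param head `"inst"` or `"cls"`.
#' @param params from [icc_init()].
#' @param tape optional `ad_tape`.
#' @return `(n, embed_dim)` matrix node with unit-norm rows.
#' @export
icc_project <- function(v, head = c("inst", "cls"), params, tape = NULL) {
  head <- match.arg(head)
  g <- function(nm) params[[paste0(head, ".", nm)]]
  h <- t_relu(t_linear(v, g("W1"), g("b1"), tape), tape)
  t_l2norm_rows(t_linear(h, g("W2"), g("b2"), tape), tape)
}

# numeric supervised contrastive loss; Z rows unit-norm
supcon_value <- function(Z, labels, tau, include_self = FALSE) {
  n <- nrow(Z)
  sims <- Z %*% t(Z) / tau
  total <- 0
  n_anchor <- 0L
  grad <- matrix(0, n, ncol(Z))
  for (i in seq_len(n)) {
    pos <- which(labels == labels[i] & seq_len(n) != i)
    if (length(pos) == 0L) next
    den_idx <- if (include_self) seq_len(n) else setdiff(seq_len(n), i)
    e <- exp(sims[i, den_idx] - max(sims[i, den_idx]))
    pn <- match(pos, den_idx)
    total <- total + (-log(sum(e[pn]) / sum(e)))
    n_anchor <- n_anchor + 1L
    # gradient wrt rows of Z (softmax over denominator minus softmax over
    # positives, mapped back through the dot products)
    sm_d <- e / sum(e)
    sm_p <- numeric(length(den_idx))
    sm_p[pn] <- e[pn] / sum(e[pn])
    coef <- (sm_d - sm_p) / tau
    grad[i, ] <- grad[i, ] + drop(coef %*% Z[den_idx, , drop = FALSE])
    grad[den_idx, ] <- grad[den_idx, ] + outer(coef, Z[i, ])
  }
  if (n_anchor == 0L) return(list(value = 0, grad = grad * 0))
  list(value = total / n_anchor, grad = grad / n_anchor)
}

#' Supervised contrastive loss
#'
#' Per anchor with at least one same-label partner, the loss is
#' `-log( sum_pos exp(z_i.z_j / tau) / sum_others exp(z_i.z_k / tau) )`;
#' anchors without positives are skipped and the mean over contributing
#' anchors is returned.  Non-negative whenever the denominator set contains
#' the positives.
#'
#' @param Z `(n, d)` matrix (or node) of unit-norm embeddings.
#' @param labels integer labels defining the positive sets.
#' @param tau positive temperature.
#' @param include_self include the anchor in the denominator.
#' @param tape optional `ad_tape` (returns a scalar node when given).
#' @return Scalar (or scalar node): the loss value.
#' @export
supcon_loss <- function(Z, labels, tau, include_self = FALSE, tape = NULL) {
  if (tau <= 0) stopf("stripedet_cfg_error", "tau must be positive")
  Zv <- nv(Z)
  if (nrow(Zv) < 2L)
    stopf("stripedet_cfg_error", "supcon_loss needs at least 2 embeddings")
  res <- supcon_value(Zv, labels, tau, include_self)
  if (is.null(tape) && !is_node(Z)) return(res$value)
  ad_op(tape, res$value, list(Z),
        function(g) list(res$grad * as.numeric(g)))
}

#' Combined dual-level contrastive loss
#'
#' Embeds the fused RoI vectors of both views through the instance head
#' (labels = instance ids, so the two views of one object are mutual
#' positives) and the class head (labels = class ids), and combines the two
#' supervised contrastive losses as `w_inst * L_inst + w_cls * L_cls`.
#'
#' @param feats1,feats2 lists `list(f3, f4)` of pyramid feature nodes for
#'   the two views.
#' @param boxes1,boxes2 tibbles from [make_paired_views()] sharing
#'   `instance_id`.
#' @param params from [icc_init()].
#' @param cfg an [icc_config()].
#' @param tape optional `ad_tape`.
#' @return List with scalar (nodes) `l_icc`, `l_inst`, `l_cls`.
#' @export
icc_loss <- function(feats1, feats2, boxes1, boxes2, params,
                     cfg = icc_config(), tape = NULL) {
  if (nrow(boxes1) == 0L || nrow(boxes2) == 0L) {
    z <- ad_node(0)
    return(list(l_icc = z, l_inst = z, l_cls = z))
  }
  v1 <- roi_fuse(feats1[[1]], feats1[[2]], boxes1, cfg, tape)
  v2 <- roi_fuse(feats2[[1]], feats2[[2]], boxes2, cfg, tape)
  inst_labels <- c(boxes1$instance_id, boxes2$instance_id)
  cls_labels <- c(boxes1$label, boxes2$label)
  z_inst <- rbind_nodes(icc_project(v1, "inst", params, tape),
                        icc_project(v2, "inst", params, tape), tape)
  z_cls <- rbind_nodes(icc_project(v1, "cls", params, tape),
                       icc_project(v2, "cls", params, tape), tape)
  l_inst <- supcon_loss(z_inst, inst_labels, cfg$tau_inst, cfg$include_self, tape)
  l_cls <- supcon_loss(z_cls, cls_labels, cfg$tau_cls, cfg$include_self, tape)
  l_icc <- t_wsum(list(l_inst, l_cls), c(cfg$w_inst, cfg$w_cls), tape)
  list(l_icc = l_icc, l_inst = l_inst, l_cls = l_cls)
}

# stack two matrix nodes row-wise
rbind_nodes <- function(a, b, tape = NULL) {
  av <- nv(a); bv <- nv(b)
  na <- nrow(av)
  ad_op(tape, rbind(av, bv), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE],
         g[na + seq_len(nrow(bv)), , drop = FALSE])
  })
}
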
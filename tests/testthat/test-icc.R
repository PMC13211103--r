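# Contrastive module: RoI fusion, projection, supervised contrastive loss
# properties, and the combined dual-level objective.

test_that("roi_fuse averages the two levels and matches the bilinear oracle", {
  set.seed(5)
  f3 <- array(rnorm(1 * 6 * 16 * 16), c(1, 6, 16, 16))
  f4 <- array(rnorm(1 * 6 * 8 * 8), c(1, 6, 8, 8))
  cfg <- icc_config(feature_dim = 6L)
  boxes <- data.frame(x1 = c(0.1, 0.4), y1 = c(0.2, 0.1),
                      x2 = c(0.6, 0.9), y2 = c(0.5, 0.7))
  got <- nrow(boxes)
  fused <- roi_fuse(f3, f4, boxes, cfg)$value
  for (i in seq_len(nrow(boxes))) {
    want <- oracle_roi_fuse(f3, f4, as.numeric(boxes[i, ]))
    expect_lt(max(abs(fused[i, ] - want)), 1e-10)
  }
  # identical levels: fusion equals either level's pooled vector
  same <- roi_fuse(f3, array(f3[, , seq(1, 16, 2), seq(1, 16, 2)],
                             c(1, 6, 8, 8)), boxes, cfg)$value
  const3 <- array(2.5, c(1, 6, 16, 16)); const4 <- array(2.5, c(1, 6, 8, 8))
  cf <- roi_fuse(const3, const4, boxes, cfg)$value
  expect_equal(as.vector(cf), rep(2.5, length(cf)))
  expect_error(roi_fuse(f3, f4, data.frame(x1 = 0.5, y1 = 0.1,
                                           x2 = 0.5, y2 = 0.4), cfg),
               class = "stripedet_box_error")
})

test_that("projection heads emit unit-norm embeddings", {
  cfg <- icc_config(feature_dim = 8L, hidden_dim = 12L, embed_dim = 6L)
  params <- icc_init(cfg, seed = 3)
  set.seed(6)
  v <- matrix(rnorm(5 * 8), 5, 8)
  z <- icc_project(v, "inst", params)$value
  expect_equal(rowSums(z^2), rep(1, 5), tolerance = 1e-10)
  # explicit two-matrix computation as oracle
  h <- pmax(v %*% params$inst.W1 + matrix(params$inst.b1, 5, 12, TRUE), 0)
  raw <- h %*% params$inst.W2 + matrix(params$inst.b2, 5, 6, TRUE)
  expect_equal(z, raw / sqrt(rowSums(raw^2)), tolerance = 1e-12)
  # constant map: zero weights, nonzero bias -> embedding independent of v
  pz <- params
  pz$cls.W1[] <- 0; pz$cls.W2[] <- 0; pz$cls.b1[] <- 0
  pz$cls.b2 <- seq_len(6)
  zc <- icc_project(v, "cls", pz)$value
  expect_equal(zc, matrix(rep(seq_len(6) / sqrt(sum((1:6)^2)), each = 5), 5, 6),
               tolerance = 1e-12)
})

test_that("supcon_loss reproduces closed-form fixtures", {
  e1 <- c(1, rep(0, 7)); e2 <- c(0, 1, rep(0, 6))
  Z <- rbind(e1, e1, e2)
  expect_equal(supcon_loss(Z, c(0, 0, 1), tau = 1),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-9)
  Zs <- rbind(e1, e1, e1)
  expect_equal(supcon_loss(Zs, c(0, 0, 1), tau = 1), log(2), tolerance = 1e-9)
  expect_equal(supcon_loss(Z, c(1, 2, 3), tau = 0.5), 0)   # no positives
  expect_error(supcon_loss(Z, c(0, 0, 1), tau = -1),
               class = "stripedet_cfg_error")
  expect_error(supcon_loss(Z[1, , drop = FALSE], 0, tau = 1),
               class = "stripedet_cfg_error")
})

test_that("supcon_loss is non-negative, invariant to rotation and permutation,
           and monotone in positive-pair similarity", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    Z <- matrix(rnorm(n * 16), n, 16)
    Z <- Z / sqrt(rowSums(Z^2))
    labels <- sample(1:3, n, replace = TRUE)
    tau <- runif(1, 0.05, 1)
    l <- supcon_loss(Z, labels, tau)
    expect_gte(l, 0)
    # rotation invariance
    Q <- qr.Q(qr(matrix(rnorm(256), 16, 16)))
    expect_equal(supcon_loss(Z %*% Q, labels, tau), l, tolerance = 1e-6)
    # permutation invariance
    p <- sample(n)
    expect_equal(supcon_loss(Z[p, ], labels[p], tau), l, tolerance = 1e-9)
  }
  # monotonicity: raising one positive pair's similarity cannot raise the loss
  base <- diag(4)[c(1, 2, 3, 4), ]
  labels <- c(1, 1, 2, 2)
  l0 <- supcon_loss(base, labels, 0.3)
  closer <- base
  closer[2, ] <- c(sqrt(0.5), sqrt(0.5), 0, 0)  # row 2 moves toward row 1
  expect_lt(supcon_loss(closer, labels, 0.3), l0)
})

test_that("icc_loss combines branches with the configured weights", {
  cfg <- icc_config(feature_dim = 6L, hidden_dim = 8L, embed_dim = 4L)
  params <- icc_init(cfg, seed = 4)
  set.seed(9)
  f3a <- array(rnorm(6 * 256), c(1, 6, 16, 16))
  f4a <- array(rnorm(6 * 64), c(1, 6, 8, 8))
  f3b <- array(rnorm(6 * 256), c(1, 6, 16, 16))
  f4b <- array(rnorm(6 * 64), c(1, 6, 8, 8))
  boxes <- tibble::tibble(x1 = c(0.1, 0.5, 0.2), y1 = c(0.1, 0.5, 0.6),
                          x2 = c(0.4, 0.9, 0.55), y2 = c(0.3, 0.8, 0.95),
                          label = c(1L, 1L, 2L), instance_id = 1:3)
  out <- icc_loss(list(f3a, f4a), list(f3b, f4b), boxes, boxes, params, cfg)
  expect_equal(as.numeric(out$l_icc$value),
               0.05 * as.numeric(out$l_inst$value) +
                 0.3 * as.numeric(out$l_cls$value), tolerance = 1e-12)
  # fully enumerated reference for both branches
  fuse_o <- function(f3, f4) t(sapply(seq_len(nrow(boxes)), function(i)
    oracle_roi_fuse(f3, f4, as.numeric(boxes[i, 1:4]))))
  proj_o <- function(v, pre) {
    h <- pmax(v %*% params[[paste0(pre, ".W1")]] +
                matrix(params[[paste0(pre, ".b1")]], nrow(v), 8, TRUE), 0)
    r <- h %*% params[[paste0(pre, ".W2")]] +
      matrix(params[[paste0(pre, ".b2")]], nrow(v), 4, TRUE)
    r / sqrt(rowSums(r^2))
  }
  supcon_o <- function(Z, labels, tau) {
    n <- nrow(Z); tot <- 0; m <- 0
    for (i in seq_len(n)) {
      P <- setdiff(which(labels == labels[i]), i)
      if (!length(P)) next
      den <- setdiff(seq_len(n), i)
      s <- drop(Z %*% Z[i, ]) / tau
      tot <- tot + (-log(sum(exp(s[P])) / sum(exp(s[den]))))
      m <- m + 1
    }
    tot / m
  }
  v1 <- fuse_o(f3a, f4a); v2 <- fuse_o(f3b, f4b)
  zi <- rbind(proj_o(v1, "inst"), proj_o(v2, "inst"))
  zc <- rbind(proj_o(v1, "cls"), proj_o(v2, "cls"))
  expect_equal(as.numeric(out$l_inst$value),
               supcon_o(zi, rep(1:3, 2), cfg$tau_inst), tolerance = 1e-8)
  expect_equal(as.numeric(out$l_cls$value),
               supcon_o(zc, rep(c(1, 1, 2), 2), cfg$tau_cls), tolerance = 1e-8)
  # empty boxes -> all zeros
  eb <- boxes[0, ]
  z <- icc_loss(list(f3a, f4a), list(f3b, f4b), eb, eb, params, cfg)
  expect_equal(as.numeric(z$l_icc$value), 0)
})

test_that("optimizing the heads on a fixed batch reduces the combined loss", {
  ns <- asNamespace("stripedet")
  cfg <- icc_config(feature_dim = 6L, hidden_dim = 8L, embed_dim = 4L)
  params <- icc_init(cfg, seed = 10)
  set.seed(11)
  v1 <- matrix(rnorm(4 * 6), 4, 6)
  v2 <- v1 + matrix(rnorm(24, 0, 0.1), 4, 6)
  inst <- rep(1:4, 2); cls <- rep(c(1, 1, 2, 2), 2)
  eval_loss <- function(p, tape = NULL) {
    zi <- rbind_nodes <- NULL
    z1 <- icc_project(if (is.null(tape)) v1 else ns$ad_node(v1), "inst", p, tape)
    z2 <- icc_project(if (is.null(tape)) v2 else ns$ad_node(v2), "inst", p, tape)
    zi <- ns$rbind_nodes(z1, z2, tape)
    c1 <- icc_project(if (is.null(tape)) v1 else ns$ad_node(v1), "cls", p, tape)
    c2 <- icc_project(if (is.null(tape)) v2 else ns$ad_node(v2), "cls", p, tape)
    zc <- ns$rbind_nodes(c1, c2, tape)
    ns$t_wsum(list(supcon_loss(zi, inst, cfg$tau_inst, tape = tape),
                   supcon_loss(zc, cls, cfg$tau_cls, tape = tape)),
              c(cfg$w_inst, cfg$w_cls), tape)
  }
  l0 <- as.numeric(ns$nv(eval_loss(params)))
  for (step in 1:200) {
    tape <- ns$ad_tape()
    pn <- lapply(params, function(a) ns$ad_node(a, tape))
    loss <- eval_loss(pn, tape)
    ns$ad_backward(loss, tape)
    for (nm in names(params))
      if (!is.null(pn[[nm]]$grad))
        params[[nm]] <- params[[nm]] - 0.5 * ns$shaped(pn[[nm]]$grad,
                                                       params[[nm]])
  }
  l1 <- as.numeric(ns$nv(eval_loss(params)))
  expect_lt(l1, l0)
})
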
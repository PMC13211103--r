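# Detector assembly: pyramid contract, determinism, loss composition,
# decoding/NMS, and a short training smoke run.

test_that("the pyramid contract holds and initialization is deterministic", {
  cfg <- model_config()
  m1 <- build_model(cfg, seed = 3)
  m2 <- build_model(cfg, seed = 3)
  expect_identical(m1$params, m2$params)
  x <- array(runif(3 * 128 * 128), c(1, 3, 128, 128))
  fw <- model_forward(m1, x)
  sizes <- t(vapply(fw$levels, function(l) dim(l$value)[3:4], integer(2)))
  expect_equal(sizes, cbind(c(16L, 8L, 4L, 2L), c(16L, 8L, 4L, 2L)),
               ignore_attr = TRUE)
  expect_true(all(vapply(fw$levels, function(l) dim(l$value)[2], integer(1)) ==
                    96L))
  expect_true(all(vapply(fw$stacks, function(s) dim(s$value)[2], integer(1)) ==
                    3L))
  # stride arithmetic on another divisible size
  x2 <- array(runif(3 * 192 * 192), c(1, 3, 192, 192))
  fw2 <- model_forward(m1, x2)
  expect_equal(dim(fw2$levels[[1]]$value)[3:4], c(24L, 24L))
  expect_error(model_forward(m1, array(0, c(1, 3, 100, 100))),
               class = "stripedet_cfg_error")
})

test_that("total_loss composes components with the stated weights", {
  cfg <- model_config()
  expect_identical(total_loss(1, 1, 1, 1, cfg), 2.45)
  expect_equal(total_loss(0.5, 0.8, 0.2, 4.0, cfg), 1.77, tolerance = 1e-12)
  expect_equal(total_loss(0.3, 0.6, 0, 0, cfg), 0.9, tolerance = 1e-12)
  expect_error(total_loss(NaN, 1, 1, 1, cfg), class = "stripedet_nan_error")
})

test_that("NMS keeps the best box and suppresses duplicates", {
  boxes <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(50, 50, 60, 60))
  keep <- nms(boxes, c(0.9, 0.8, 0.7), iou_thr = 0.99)
  expect_equal(keep, c(1, 3))
  # disjoint boxes survive any threshold
  disj <- rbind(c(0, 0, 10, 10), c(100, 100, 120, 140))
  expect_length(nms(disj, c(0.5, 0.6), iou_thr = 0.01), 2)
})

test_that("decoding respects the score threshold and the head geometry", {
  cfg <- model_config(num_classes = 2L)
  m <- build_model(cfg, seed = 5)
  img <- array(runif(128 * 128 * 3), c(128, 128, 3))
  expect_equal(nrow(predict_boxes(m, img, score_thr = 1.0)), 0)
  # hand-built head outputs encoding two disjoint boxes
  ns <- asNamespace("stripedet")
  fake <- list(cls = list(), reg = list())
  sizes <- c(16L, 8L, 4L, 2L)
  for (l in 1:4) {
    fake$cls[[l]] <- array(-20, c(1, 2, sizes[l], sizes[l]))
    fake$reg[[l]] <- array(0, c(1, 4, sizes[l], sizes[l]))
  }
  # two objects at stride-8 positions (3,3) and (13,13), classes 1 and 2
  fake$cls[[1]][1, 1, 3, 3] <- 20
  fake$cls[[1]][1, 2, 13, 13] <- 20
  fake$reg[[1]][1, , 3, 3] <- log(c(1, 1, 1, 1))       # 8 px half-extents
  fake$reg[[1]][1, , 13, 13] <- log(c(0.5, 0.5, 0.5, 0.5))
  for (thr in c(0.3, 0.9)) {
    d <- ns$decode_detections(fake, cfg, c(128, 128), thr, 0.1)
    expect_equal(nrow(d), 2)
    expect_setequal(d$class, c(1L, 2L))
    b1 <- as.numeric(d[d$class == 1L, 1:4])
    expect_equal(b1, c(20 - 8, 20 - 8, 20 + 8, 20 + 8))
  }
})

test_that("detection targets place positives inside their boxes", {
  ns <- asNamespace("stripedet")
  cfg <- model_config()
  sizes <- list(c(16L, 16L), c(8L, 8L), c(4L, 4L), c(2L, 2L))
  boxes <- rbind(c(16, 40, 80, 56), c(8, 8, 120, 120))
  tg <- ns$assign_targets(boxes, c(1L, 2L), cfg, sizes)
  npos <- sum(vapply(tg, function(t) length(t$pos_idx), integer(1)))
  expect_gt(npos, 0)
  for (l in seq_along(tg)) {
    if (length(tg[[l]]$pos_idx) == 0) next
    expect_true(all(tg[[l]]$pos_ltrb > 0))
    expect_equal(nrow(tg[[l]]$pos_ltrb), length(tg[[l]]$pos_idx))
    expect_true(all(rowSums(tg[[l]]$cls) <= 1))
  }
})

test_that("a short training run logs finite components and updates weights", {
  spec <- scene_spec(image_size = 128, n_objects = c(1, 2), seed = 11,
                     length_frac_range = c(0.25, 0.5))
  scenes <- lapply(1:2, function(i) generate_scene(spec, seed = 300 + i))
  cfg <- model_config()
  m <- train_detector(scenes, cfg, steps = 4, seed = 2)
  expect_equal(nrow(m$log), 4)
  expect_true(all(is.finite(unlist(m$log[, c("l_cls", "l_loc", "l_inst",
                                             "l_ccls", "l_tr", "total")]))))
  m0 <- build_model(cfg, seed = 2)
  expect_false(identical(m0$params$head.cls.W, m$params$head.cls.W))
  # disabling the auxiliary losses logs them as zero
  cfg0 <- model_config(w_icc = 0, w_tr = 0)
  m2 <- train_detector(scenes, cfg0, steps = 2, seed = 2)
  expect_equal(unlist(m2$log[, c("l_inst", "l_ccls", "l_tr")]),
               rep(0, 6), ignore_attr = TRUE)
})

test_that("auxiliary losses leave inference untouched", {
  spec <- scene_spec(image_size = 128, n_objects = c(1, 2), seed = 11)
  sc <- generate_scene(spec, seed = 501)
  cfg <- model_config()
  m <- build_model(cfg, seed = 9)
  d1 <- predict_boxes(m, sc$image, score_thr = 0.01)
  # predictions only depend on the weights, not on the auxiliary loss
  # configuration
  m_noaux <- m
  m_noaux$cfg <- model_config(w_icc = 0, w_tr = 0)
  d2 <- predict_boxes(m_noaux, sc$image, score_thr = 0.01)
  expect_equal(d1, d2)
})

test_that("checkpoints round-trip through save/load", {
  cfg <- model_config()
  m <- build_model(cfg, seed = 4)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$cfg$strides, m2$cfg$strides)
})
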
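# Evaluation suite: IoU, AP fixtures, suite equivalence with the
# brute-force reference evaluator, bucketing, ECS.

test_that("iou follows the half-open area convention", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(iou(c(0, 0, 10, 10), c(5, 0, 15, 10)), 50 / 150)
  expect_warning(v <- iou(c(0, 0, 0, 10), c(0, 0, 10, 10)))
  expect_equal(v, 0)
})

test_that("average precision reproduces hand-computed fixtures", {
  one_gt <- tibble::tibble(image = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  perfect <- tibble::tibble(image = 1, x1 = 0, y1 = 0, x2 = 10, y2 = 10,
                            score = 0.9)
  expect_equal(average_precision(perfect, one_gt, 0.5), 1)
  expect_equal(average_precision(perfect[0, ], one_gt, 0.5), 0)
  # two GTs; a non-matching det outranks one perfect match:
  # PR points (r=0, p=0) then (r=0.5, p=0.5) -> 51 * 0.5 / 101
  two_gt <- tibble::tibble(image = 1, x1 = c(0, 100), y1 = 0,
                           x2 = c(10, 110), y2 = 10)
  dets <- tibble::tibble(image = 1,
                         x1 = c(300, 0), y1 = c(300, 0),
                         x2 = c(310, 10), y2 = c(310, 10),
                         score = c(0.9, 0.8))
  expect_equal(average_precision(dets, two_gt, 0.5), 51 * 0.5 / 101,
               tolerance = 1e-12)
  # no ground truth -> excluded, not zero
  expect_true(is.na(average_precision(dets, two_gt[0, ], 0.5)))
})

test_that("average precision is invariant to monotone score rescaling and
           never rises when a trailing false positive is added", {
  set.seed(3)
  fx <- random_eval_fixture()
  d <- tibble::as_tibble(fx$dets); g <- tibble::as_tibble(fx$gts)
  base <- average_precision(d, g, 0.5)
  d2 <- d; d2$score <- 0.1 + 0.8 * d$score^3
  expect_equal(average_precision(d2, g, 0.5), base, tolerance = 1e-12)
  worse <- dplyr::bind_rows(d, tibble::tibble(image = g$image[1],
                                              x1 = 600, y1 = 600, x2 = 610,
                                              y2 = 610,
                                              score = min(d$score) / 2))
  expect_lte(average_precision(worse, g, 0.5), base)
})

test_that("map_suite matches trivial closed forms", {
  g <- tibble::tibble(image = rep(1:2, each = 2), class = rep(1:2, 2),
                      x1 = c(0, 50, 0, 50), y1 = 0,
                      x2 = c(40, 90, 40, 90), y2 = 40)
  d <- dplyr::mutate(g, score = 0.9)
  rep <- map_suite(d, g)
  expect_equal(rep$map, 1)
  expect_equal(rep$ap50, 1)
  expect_equal(rep$ap75, 1)
  expect_gte(rep$ap50, rep$ap75)
  expect_equal(rep$per_class$map, c(1, 1))
})

test_that("map_suite agrees with the brute-force reference evaluator", {
  set.seed(11)
  for (rep_i in 1:25) {
    fx <- random_eval_fixture()
    d <- tibble::as_tibble(fx$dets); g <- tibble::as_tibble(fx$gts)
    got <- map_suite(d, g)
    want <- ref_map_suite(fx$dets, fx$gts)
    for (f in c("map", "ap50", "ap75", "ap_s", "ap_m", "ap_l")) {
      gv <- got[[f]]; wv <- want[[f]]
      if (is.na(wv) || is.nan(wv)) expect_true(is.na(gv))
      else expect_equal(gv, wv, tolerance = 1e-9)
    }
  }
})

test_that("aspect-ratio buckets use the stated half-open boundaries", {
  expect_equal(ar_bucket(100, 100), "G1")
  expect_equal(ar_bucket(10, 100), "G4")
  expect_equal(ar_bucket(c(0, 0, 50, 10)), "G3")   # AR exactly 5
  expect_equal(ar_bucket(c(0, 0, 10, 80)), "G4")   # AR exactly 8
  expect_equal(ar_bucket(25, 10), "G2")
})

test_that("ECS is 1 on uniform maps, scale-invariant, and matches the
           strip-set enumeration", {
  u <- matrix(4.2, 16, 16)
  boxes <- rbind(c(8, 8, 96, 40), c(40, 16, 120, 120))
  e <- ecs(u, boxes, stride = 8)
  expect_equal(e$per_box, c(1, 1))
  set.seed(13)
  a <- matrix(runif(256, 0.1, 2), 16, 16)
  e1 <- ecs(a, boxes, stride = 8)
  e2 <- ecs(a * 37.5, boxes, stride = 8)
  expect_equal(e1$per_box, e2$per_box, tolerance = 1e-12)
  # explicit enumeration oracle: intensity 2 on the strip set, 1 elsewhere
  bp <- project_box(boxes[1, ], 8, 16, 16)
  strip <- matrix(FALSE, 16, 16)
  for (y in (bp[2] + 1):bp[4]) for (x in (bp[1] + 1):bp[3]) {
    d_in <- min(x - 1 - bp[1], bp[3] - x, y - 1 - bp[2], bp[4] - y)
    if (d_in < 3) strip[y, x] <- TRUE
  }
  m <- matrix(1, 16, 16); m[strip] <- 2
  expect_equal(ecs(m, boxes[1, , drop = FALSE], stride = 8)$mean,
               2 / mean(m), tolerance = 1e-12)
  expect_error(ecs(matrix(0, 8, 8), boxes, stride = 8),
               class = "stripedet_cfg_error")
})

test_that("bucketed_report restricts AP and averages ECS per bucket", {
  g <- tibble::tibble(image = "1", class = 1L,
                      x1 = c(10, 10), y1 = c(10, 60),
                      x2 = c(30, 105), y2 = c(30, 72))   # G1 and G3
  d <- dplyr::mutate(g, score = c(0.9, 0.8))
  gates <- list("1" = lapply(c(16, 8, 4, 2), function(s) matrix(1, s, s)))
  rep <- bucketed_report(d, g, gates)
  expect_setequal(rep$bucket, c("G1", "G3"))     # empty buckets absent
  expect_equal(rep$mean_ecs, c(1, 1))            # uniform gates
  expect_equal(rep$map, c(1, 1))
  # per-box oracle aggregation with non-uniform hand-set gates
  gate1 <- matrix(1, 16, 16); gate1[2:3, 2:3] <- 3
  gates2 <- list("1" = list(gate1, matrix(1, 8, 8), matrix(1, 4, 4),
                            matrix(1, 2, 2)))
  rep2 <- bucketed_report(d, g, gates2)
  lev1 <- assign_level(as.numeric(g[1, c("x1", "y1", "x2", "y2")]))
  want1 <- ecs(gates2[["1"]][[lev1]],
               matrix(as.numeric(g[1, c("x1", "y1", "x2", "y2")]), 1),
               stride = c(8, 16, 32, 64)[lev1])$mean
  expect_equal(rep2$mean_ecs[rep2$bucket == "G1"], want1, tolerance = 1e-12)
})
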
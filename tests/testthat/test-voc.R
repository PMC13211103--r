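# VOC I/O: coordinate convention, round trips, error classes, and the
# paired-view augmentation contract.

test_that("VOC 1-based closed coordinates convert to 0-based half-open", {
  sc <- structure(list(image = NULL, boxes = cbind(0, 0, 100, 50),
                       labels = 1L, visibility = 1,
                       width = 640, height = 640),
                  class = "annotated_scene")
  path <- tempfile(fileext = ".xml")
  write_voc(sc, path)
  txt <- readLines(path)
  expect_true(any(grepl("<xmin>1</xmin>", txt)))
  expect_true(any(grepl("<xmax>100</xmax>", txt)))
  back <- read_voc(path)
  expect_equal(unname(back$boxes[1, ]), c(0, 0, 100, 50))
})

test_that("write/read round trip is lossless over random scenes", {
  for (seed in 1:5) {
    sc <- random_scene(seed)
    path <- tempfile(fileext = ".xml")
    write_voc(sc, path)
    back <- read_voc(path)
    expect_equal(unname(back$boxes), unname(sc$boxes))
    expect_equal(back$labels, sc$labels)
    expect_equal(back$width, sc$width)
  }
})

test_that("malformed input raises distinct error classes", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<annotation><object>", bad)
  expect_error(read_voc(bad), class = "stripedet_xml_error")

  nosize <- tempfile(fileext = ".xml")
  writeLines("<annotation><filename>x</filename></annotation>", nosize)
  expect_error(read_voc(nosize), class = "stripedet_xml_error")

  unk <- tempfile(fileext = ".xml")
  writeLines(paste0("<annotation><size><width>64</width><height>64</height>",
                    "</size><object><name>martian</name><bndbox>",
                    "<xmin>1</xmin><ymin>1</ymin><xmax>10</xmax>",
                    "<ymax>10</ymax></bndbox></object></annotation>"), unk)
  expect_error(read_voc(unk), class = "stripedet_class_error")

  oob <- tempfile(fileext = ".xml")
  writeLines(paste0("<annotation><size><width>64</width><height>64</height>",
                    "</size><object><name>red</name><bndbox>",
                    "<xmin>1</xmin><ymin>1</ymin><xmax>99</xmax>",
                    "<ymax>10</ymax></bndbox></object></annotation>"), oob)
  expect_error(read_voc(oob), class = "stripedet_box_error")

  sc <- random_scene(1)
  expect_error(write_voc(sc, tempfile(), classes = c("réd", "b", "c")),
               class = "stripedet_class_error")
})

test_that("an annotation without objects reads as an empty scene", {
  empty <- tempfile(fileext = ".xml")
  writeLines(paste0("<annotation><size><width>64</width>",
                    "<height>64</height></size></annotation>"), empty)
  sc <- read_voc(empty)
  expect_equal(nrow(sc$boxes), 0)
  expect_length(sc$labels, 0)
})

test_that("paired views transform boxes consistently with the geometry", {
  sc <- random_scene(3)
  # forced flip mirrors the x-extent
  cfg <- augment_config(flip_prob = 1, brightness = 0, contrast = 0,
                        saturation = 0, hue = 0, mask_count = c(0, 0))
  v <- make_paired_views(sc, cfg, seed = 1)
  orig <- cbind(sc$boxes[, 1] / sc$width, sc$boxes[, 2] / sc$height,
                sc$boxes[, 3] / sc$width, sc$boxes[, 4] / sc$height)
  expect_equal(v$view1$boxes$x1, 1 - orig[, 3], tolerance = 1e-9)
  expect_equal(v$view1$boxes$x2, 1 - orig[, 1], tolerance = 1e-9)
  expect_equal(v$view1$boxes$y1, orig[, 2], tolerance = 1e-9)
  # identity pipeline reproduces the input exactly
  idc <- augment_config(flip_prob = 0, brightness = 0, contrast = 0,
                        saturation = 0, hue = 0, mask_count = c(0, 0))
  vi <- make_paired_views(sc, idc, seed = 1)
  expect_identical(vi$view1$image, sc$image)
  expect_identical(vi$view2$image, sc$image)
  expect_equal(as.matrix(vi$view1$boxes[, 1:4]), orig,
               ignore_attr = TRUE, tolerance = 1e-12)
  # instance ids pair the two views; photometric ops never move boxes
  cj <- augment_config(flip_prob = 0, mask_count = c(1, 2))
  vj <- make_paired_views(sc, cj, seed = 5)
  expect_identical(vj$view1$boxes$instance_id, vj$view2$boxes$instance_id)
  expect_equal(as.matrix(vj$view1$boxes[, 1:4]), orig, ignore_attr = TRUE,
               tolerance = 1e-12)
  # determinism
  va <- make_paired_views(sc, augment_config(), seed = 11)
  vb <- make_paired_views(sc, augment_config(), seed = 11)
  expect_identical(va$view1$image, vb$view1$image)
  expect_identical(va$view2$image, vb$view2$image)
  expect_equal(va$view2$boxes, vb$view2$boxes)
})

test_that("normalized view boxes always satisfy the box invariants", {
  for (seed in 1:10) {
    sc <- random_scene(seed %% 3 + 1)
    v <- make_paired_views(sc, augment_config(), seed = seed)
    for (b in list(v$view1$boxes, v$view2$boxes)) {
      expect_true(all(b$x1 >= 0 & b$x1 < b$x2 & b$x2 <= 1))
      expect_true(all(b$y1 >= 0 & b$y1 < b$y2 & b$y2 <= 1))
    }
  }
})
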
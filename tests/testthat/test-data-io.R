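# Dataset plumbing: class map, LabelMe conversion, YOLO label files,
# deterministic splits, letterbox geometry.

test_that("the class map is a fixed four-class bijection", {
  cm <- classMap()
  expect_equal(names(cm), c("abdomen", "four_chamber", "vot", "three_vessels"))
  expect_equal(unname(cm), 0:3)
  for (nm in names(cm)) expect_equal(className(classId(nm)), nm)
  expect_equal(classId("vot"), 2L)
  expect_error(classId("aorta"), "aorta")
})

test_that("LabelMe rectangles and polygons convert to normalised boxes", {
  rec <- list(imageHeight = 640, imageWidth = 640, shapes = list(
    list(label = "abdomen", shape_type = "rectangle",
         points = list(c(160, 160), c(480, 480)))))
  b <- convertLabelme(rec)
  expect_equal(as.numeric(b[1, ]), c(0, 0.5, 0.5, 0.5, 0.5))
  # polygon reduces to its bounding rectangle
  poly <- list(imageHeight = 200, imageWidth = 100, shapes = list(
    list(label = "vot", shape_type = "polygon",
         points = list(c(10, 20), c(50, 40), c(30, 120)))))
  b2 <- convertLabelme(poly)
  expect_equal(b2$class, 2L)
  expect_equal(b2$w, 40 / 100)
  expect_equal(b2$h, 100 / 200)
  expect_equal(nrow(convertLabelme(list(shapes = list()),
                                   imageDims = c(64, 64))), 0L)
  bad <- list(imageHeight = 10, imageWidth = 10, shapes = list(
    list(label = "unknown_view", points = list(c(1, 1), c(5, 5)))))
  expect_error(convertLabelme(bad), "unknown_view")
  # conversion -> write -> read -> write is byte-stable
  f1 <- tempfile(); f2 <- tempfile()
  writeYoloLabels(f1, b)
  writeYoloLabels(f2, readYoloLabels(f1))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("YOLO label files round-trip and validate line by line", {
  boxes <- data.frame(class = c(0L, 3L), cx = c(0.5, 0.123456),
                      cy = c(0.5, 0.654321), w = c(0.25, 0.2),
                      h = c(0.25, 0.1))
  f <- tempfile()
  writeYoloLabels(f, boxes)
  back <- readYoloLabels(f)
  expect_equal(back, boxes, tolerance = 1e-6)
  expect_equal(nrow(readYoloLabels(tempfile())), 0L)  # missing file = empty
  writeLines(c("0 0.5 0.5 0.25 0.25", "1 0.5 0.5 0.1"), f)
  expect_error(readYoloLabels(f), ":2")
  writeLines("7 0.5 0.5 0.2 0.2", f)
  expect_error(readYoloLabels(f), "class id")
})

test_that("splits are deterministic, exhaustive and follow the ratios", {
  items <- list(a = sprintf("a%02d", 1:10), b = sprintf("b%02d", 1:23))
  s1 <- splitDataset(items, ratios = c(7, 2, 1), seed = 4)
  s2 <- splitDataset(items, ratios = c(7, 2, 1), seed = 4)
  expect_identical(s1, s2)
  expect_equal(lengths(s1$train)[["a"]], 7L)
  expect_equal(lengths(s1$val)[["a"]], 2L)
  expect_equal(lengths(s1$test)[["a"]], 1L)
  all_a <- c(s1$train$a, s1$val$a, s1$test$a)
  expect_setequal(all_a, items$a)
  expect_equal(anyDuplicated(all_a), 0L)
  # different seed: same sizes, different assignment
  s3 <- splitDataset(items, ratios = c(7, 2, 1), seed = 5)
  expect_equal(lengths(s3$train), lengths(s1$train))
  expect_false(identical(s3$train$b, s1$train$b))
  # largest-remainder arithmetic at the published 6:2:2 override
  s4 <- splitDataset(list(tv = sprintf("t%03d", 1:113)),
                     ratios = c(6, 2, 2), seed = 1)
  expect_equal(c(length(s4$train$tv), length(s4$val$tv),
                 length(s4$test$tv)), c(68L, 22L, 23L))
  expect_error(splitDataset(list(a = character()), c(7, 2, 1), 1), "item")
})

test_that("letterboxing preserves aspect, pads symmetrically, inverts", {
  sq <- matrix(runif(64 * 64), 64, 64)
  lb <- letterbox(sq, 64)
  expect_equal(lb$transform$scale, 1)
  expect_equal(lb$transform$padX + lb$transform$padY, 0)
  expect_equal(lb$image, sq, tolerance = 1e-6)
  # 320x640 -> scale 1, 160 px left+right padding in total
  wide <- matrix(runif(320 * 640), 320, 640)
  lb2 <- letterbox(wide, 640)
  expect_equal(lb2$transform$scale, 1)
  expect_equal(lb2$transform$padY, 160)
  expect_equal(lb2$transform$padX, 0)
  # boxes survive the round trip to within half a pixel
  boxes <- data.frame(class = 0L, cx = c(0.3, 0.8), cy = c(0.25, 0.6),
                      w = c(0.2, 0.1), h = c(0.3, 0.15))
  tall <- matrix(runif(300 * 130), 300, 130)
  lb3 <- letterbox(tall, 96)
  back <- boxesFromLetterbox(boxesToLetterbox(boxes, lb3$transform),
                             lb3$transform)
  expect_lt(max(abs(as.matrix(back[, 2:5] - boxes[, 2:5])) * 300), 0.5)
  expect_error(letterbox(sq, 100), "divisible")
})

test_that("images round-trip through PNG files", {
  img <- matrix(runif(40 * 60), 40, 60)
  f <- tempfile(fileext = ".png")
  writeImageArray(img, f)
  back <- readImageArray(f)
  expect_equal(dim(back), c(40L, 60L))
  expect_lt(max(abs(back - img)), 1 / 255)
})
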
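# The declarative graph, the variant registry, pruning, parameter and
# module accounting, width calibration and shape inference.

test_that("the full graph wires heads to the published concat layers", {
  g <- fullGraph(4)
  expect_equal(headLayers(g), c(`1` = 15L, `2` = 19L, `3` = 22L, `4` = 25L))
  expect_equal(g@strides, c(`1` = 16L, `2` = 8L, `3` = 16L, `4` = 32L))
  kinds <- setNames(vapply(g@layers, function(l) l@kind, character(1)),
                    layerIndices(g))
  expect_equal(unname(kinds["12"]), "sppf")
  expect_true(all(kinds[as.character(headLayers(g))] == "concat"))
  expect_equal(sum(kinds == "bneck"), 11L)
  # layer 12 survives every variant; 10-11 are the prunable bnecks
  for (v in variantRegistry()) {
    expect_true(12L %in% v@keptLayers)
  }
  removed_backbone <- setdiff(0:12, variantRegistry()$emnm@keptLayers)
  expect_equal(removed_backbone, c(10L, 11L))
  expect_true(all(kinds[as.character(removed_backbone)] == "bneck"))
})

test_that("variant registry matches the published pruning table", {
  reg <- variantRegistry()
  expect_equal(reg$emnxx@keptLayers, 0:25)
  expect_equal(reg$emnxx@keptHeads, c(2L, 3L, 4L))
  expect_equal(reg$emnx@keptLayers, 0:22)
  expect_equal(reg$emnx@keptHeads, c(2L, 3L))
  expect_equal(reg$emnl@keptLayers, 0:19)
  expect_equal(reg$emnl@keptHeads, c(1L, 2L))
  expect_equal(reg$emnm@keptLayers, c(0:9, 12:22))
  expect_equal(reg$emns@keptLayers, c(0:9, 12:19))
  expect_equal(reg$emns@keptHeads, c(1L, 2L))
})

test_that("pruning keeps registered layers, reroutes and drops heads", {
  g <- buildVariant("emnxx", 4)
  expect_equal(layerIndices(g), 0:25)
  expect_equal(names(headLayers(g)), c("2", "3", "4"))
  s <- buildVariant("emns", 4)
  expect_equal(layerIndices(s), c(0:9, 12:19))
  expect_equal(names(headLayers(s)), c("1", "2"))
  # the SPPF's source is rerouted to the nearest kept ancestor (bneck 9)
  sppf <- s@layers[[which(layerIndices(s) == 12L)]]
  expect_equal(sppf@from, 9L)
  # emnm vs emnx: identical neck, backbone differs by exactly layers 10-11
  m <- buildVariant("emnm", 4); x <- buildVariant("emnx", 4)
  expect_equal(setdiff(layerIndices(x), layerIndices(m)), c(10L, 11L))
  neck_m <- m@layers[layerIndices(m) >= 13]
  neck_x <- x@layers[layerIndices(x) >= 13 & layerIndices(x) <= 22]
  expect_equal(lapply(neck_m, function(l) l@hyper),
               lapply(neck_x, function(l) l@hyper))
  expect_error(buildVariant("emnz", 4), "emns")
})

test_that("parameter counting matches hand arithmetic and enumeration", {
  # single conv layer, 3 -> 16 channels, 3x3, bias-free + BN
  expect_equal(sectornet:::count_conv(3, 16, 3), 464)
  # closed form equals brute-force weight enumeration on a real variant
  for (v in c("emns", "emnxx")) {
    g <- buildVariant(v, 4)
    net <- initNetwork(g, seed = 1)
    expect_equal(countParameters(g), networkParameterCount(net))
  }
  # per-layer counts of shared layers agree between variant and full graph
  g_full <- fullGraph(4)
  pl_full <- countParameters(g_full, perLayer = TRUE)
  for (v in c("emns", "emnm")) {
    pl_v <- countParameters(buildVariant(v, 4), perLayer = TRUE)
    shared <- intersect(names(pl_v), names(pl_full))
    expect_equal(pl_v[shared], pl_full[shared])
  }
})

test_that("variant parameters and module counts increase strictly", {
  order_v <- c("emns", "emnm", "emnl", "emnx", "emnxx")
  params <- vapply(order_v, function(v) countParameters(buildVariant(v, 4)),
                   numeric(1))
  expect_true(all(diff(params) > 0))
  mods <- vapply(order_v, function(v) countLayers(buildVariant(v, 4)),
                 integer(1))
  expect_true(all(diff(mods) > 0))
  # the stock small-model baseline dwarfs the whole series
  expect_gt(yolov5sParameterCount(4), max(params))
})

test_that("width calibration reproduces the published parameter table", {
  cal <- calibrateWidths()
  expect_true(all(abs(cal$residuals) <= 0.01))
  # the shipped canonical widths are the calibration's fixed point
  expect_equal(cal$widths, emnWidths())
  target <- c(emns = 0.33, emnm = 0.44, emnl = 0.81, emnx = 0.92,
              emnxx = 1.28)
  achieved <- vapply(names(target), function(v) {
    round(countParameters(buildVariant(v, 4, cal$widths)) / 1e6, 2)
  }, numeric(1))
  expect_equal(achieved, target)
  # pruning-model delta identities implied by the table arithmetic
  p <- vapply(names(target), function(v)
    countParameters(buildVariant(v, 4)), numeric(1))
  expect_equal(p[["emnx"]] - p[["emnm"]], p[["emnl"]] - p[["emns"]])
  expect_equal(p[["emnx"]] - p[["emnl"]], p[["emnm"]] - p[["emns"]])
  expect_equal(round((p[["emnx"]] - p[["emnm"]]) / 1e6, 2), 0.48)
  expect_equal(round((p[["emnx"]] - p[["emnl"]]) / 1e6, 2), 0.11)
})

test_that("forward shapes follow the head strides", {
  g <- buildVariant("emnxx", 4)
  expect_equal(forwardShapes(g, 640),
               list(`2` = c(80, 80), `3` = c(40, 40), `4` = c(20, 20)))
  expect_equal(forwardShapes(buildVariant("emnl", 4), 640),
               list(`1` = c(40, 40), `2` = c(80, 80)))
  half <- forwardShapes(g, 320)
  expect_equal(half, lapply(forwardShapes(g, 640), `/`, 2))
  expect_error(forwardShapes(g, 100), "multiple of 32")
})

test_that("every variant's forward pass emits one grid per kept head", {
  set.seed(5)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  for (v in names(variantRegistry())) {
    g <- buildVariant(v, 4)
    net <- initNetwork(g, seed = 2)
    fwd <- networkForward(net, x)
    expect_named(fwd$heads, names(headLayers(g)))
    for (h in names(fwd$heads)) {
      expect_equal(dim(fwd$heads[[h]]),
                   c(64 / g@strides[[h]], 64 / g@strides[[h]], 27, 1))
      expect_true(all(is.finite(fwd$heads[[h]])))
    }
  }
})

test_that("the shipped canonical config matches the built full graph", {
  p <- system.file("extdata", "emn_full_4class.yaml", package = "sectornet")
  expect_true(nzchar(p))
  g <- readModelConfig(p)
  ref <- fullGraph(4)
  expect_equal(headLayers(g), headLayers(ref))
  expect_equal(countParameters(g, perLayer = TRUE),
               countParameters(ref, perLayer = TRUE))
  tmp <- tempfile(fileext = ".yaml")
  writeModelConfig(g, tmp)
  expect_identical(readLines(tmp), readLines(p))
})

test_that("model configs round-trip through YAML bit-exactly", {
  g <- buildVariant("emnm", 4)
  p1 <- tempfile(fileext = ".yaml"); p2 <- tempfile(fileext = ".yaml")
  writeModelConfig(g, p1)
  g2 <- readModelConfig(p1)
  writeModelConfig(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(countParameters(g2), countParameters(g))
  expect_equal(headLayers(g2), headLayers(g))
})
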
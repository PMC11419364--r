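# Synthetic ultrasound-like scenes: a dark background, a bright sector
# (fan) field, one class-specific hypoechoic structure per image, and
# multiplicative Rayleigh speckle. The four classes are designed to be
# indistinguishable by intensity histograms (their hypoechoic areas are
# matched) but trivially separable by shape: the number of hypoechoic
# connected components is 2 (abdomen: body ellipse + stomach bubble),
# 4 (four-chamber: ellipse quartered by bright septa), 1 (outflow tract:
# one curved vessel) and 3 (three collinear vessels).

#' Synthetic scene specification
#'
#' @slot classId integer 0-3 (see [classMap()]).
#' @slot imageSize square image side in pixels.
#' @slot speckleScale Rayleigh scale of the multiplicative speckle; the
#'   default `sqrt(2/pi)` gives a unit-mean speckle field.
#' @slot sectorAngle full opening angle of the scan sector, degrees.
#' @slot structure named list of class-specific geometry overrides.
#' @slot seed integer; the same spec yields a byte-identical scene.
#' @export
setClass("SyntheticSceneSpec",
  representation(classId = "integer", imageSize = "integer",
                 speckleScale = "numeric", sectorAngle = "numeric",
                 structure = "list", seed = "integer"))

setValidity("SyntheticSceneSpec", function(object) {
  if (!object@classId %in% 0:3) return("classId must be 0-3")
  if (object@imageSize < 64) return("imageSize must be >= 64")
  if (object@speckleScale < 0) return("speckleScale must be >= 0")
  if (object@sectorAngle <= 10 || object@sectorAngle > 180) {
    return("sectorAngle must be in (10, 180] degrees")
  }
  TRUE
})

#' @rdname SyntheticSceneSpec-class
#' @param classId,imageSize,speckleScale,sectorAngle,structure,seed see slots.
#' @export
sceneSpec <- function(classId, imageSize = 640L, speckleScale = sqrt(2 / pi),
                      sectorAngle = 70, structure = list(), seed = 1L) {
  new("SyntheticSceneSpec", classId = as.integer(classId),
      imageSize = as.integer(imageSize), speckleScale = speckleScale,
      sectorAngle = sectorAngle, structure = structure,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSceneSpec", function(object) {
  cat(sprintf("SyntheticSceneSpec: class %s, %dpx, speckle %.3f, seed %d\n",
              className(object@classId), object@imageSize,
              object@speckleScale, object@seed))
  invisible(NULL)
})

# pixel-centre coordinate grids (y = row, x = column), 0-based centres
scene_grid <- function(S) {
  list(x = matrix(rep(seq_len(S) - 0.5, each = S), S, S),
       y = matrix(rep(seq_len(S) - 0.5, times = S), S, S))
}

ellipse_mask <- function(g, cx, cy, a, b, theta = 0) {
  xr <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
  yr <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

#' Generate one synthetic labelled scan
#'
#' @param spec a [SyntheticSceneSpec-class].
#' @return list with `image` (`(S, S)` matrix in `[0, 1]`), `box` (one-row
#'   ground-truth data.frame, the tight bounding box of the structure
#'   mask), `mask` (logical structure mask) and `sector` (logical sector
#'   mask).
#' @examples
#' scan <- generateScan(sceneSpec(0, imageSize = 128, seed = 7))
#' scan$box
#' @export
generateScan <- function(spec) {
  validObject(spec)
  S <- spec@imageSize
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec@seed)

  g <- scene_grid(S)
  apex <- c(x = S / 2, y = 0.04 * S)
  R <- 0.92 * S
  dx <- g$x - apex["x"]; dy <- g$y - apex["y"]
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(dx, dy)                       # 0 = straight down
  half <- spec@sectorAngle / 2 * pi / 180
  sector <- r >= 0.06 * S & r <= R & abs(ang) < half

  # structure centre: along the beam axis with bounded jitter
  rc <- R * stats::runif(1, 0.48, 0.60)
  ac <- stats::runif(1, -0.22, 0.22) * half
  theta <- stats::runif(1, -pi / 6, pi / 6)

  # hypoechoic area budget shared by all classes so intensity histograms
  # do not separate them
  Tarea <- 0.018 * S^2
  st <- spec@structure
  pick <- function(name, default) if (!is.null(st[[name]])) st[[name]] else default

  build_structure <- function(cx, cy) {
    mask <- matrix(FALSE, S, S)       # hypoechoic structure pixels
    bright <- matrix(FALSE, S, S)     # bright internal walls (septa)
    if (spec@classId == 0L) {                      # abdomen
      r_st <- pick("stomachRadius", 0.045 * S)
      ab_area <- Tarea - pi * r_st^2
      b <- pick("ellipseMinor", sqrt(ab_area / pi / 1.35))
      a <- ab_area / pi / b
      body <- ellipse_mask(g, cx, cy, a, b, theta)
      # stomach bubble sits beside the body section, separated by a wall
      sx <- cx + (a + r_st + 0.035 * S) * cos(theta)
      sy <- cy + (a + r_st + 0.035 * S) * sin(theta)
      mask <- body | ellipse_mask(g, sx, sy, r_st, r_st)
    } else if (spec@classId == 1L) {               # four-chamber view
      b <- pick("ellipseMinor", sqrt(Tarea / pi / 1.35))
      a <- Tarea / pi / b
      heart <- ellipse_mask(g, cx, cy, a, b, theta)
      wall <- pick("septumWidth", 0.020 * S)
      xr <- (g$x - cx) * cos(theta) + (g$y - cy) * sin(theta)
      yr <- -(g$x - cx) * sin(theta) + (g$y - cy) * cos(theta)
      septa <- heart & (abs(xr) < wall / 2 | abs(yr) < wall / 2)
      mask <- heart & !septa
      bright <- septa
    } else if (spec@classId == 2L) {               # outflow tract
      rv <- pick("vesselRadius", 0.13 * S)
      span <- pick("arcSpan", 2.2)                 # radians
      th <- pick("thickness", Tarea / (rv * span))
      vx <- cx - rv * cos(theta); vy <- cy - rv * sin(theta)
      rr <- sqrt((g$x - vx)^2 + (g$y - vy)^2)
      aa <- atan2(g$y - vy, g$x - vx)
      da <- (aa - theta + pi) %% (2 * pi) - pi
      mask <- abs(rr - rv) < th / 2 & abs(da) < span / 2
    } else {                                       # three vessels
      r3 <- pick("vesselRadius", sqrt(Tarea / (3 * pi)))
      gap <- pick("gap", 2.6 * r3)
      for (k in -1:1) {
        mask <- mask | ellipse_mask(g, cx + k * gap * cos(theta),
                                    cy + k * gap * sin(theta), r3, r3)
      }
    }
    list(mask = mask, bright = bright)
  }

  # if the jittered placement spills out of the sector, pull the centre
  # toward the reference point on the beam axis (deterministic; no RNG)
  ref <- c(apex["x"] + 0.54 * R * sin(0), apex["y"] + 0.54 * R * cos(0))
  cx <- apex["x"] + rc * sin(ac)
  cy <- apex["y"] + rc * cos(ac)
  stx <- NULL
  for (i in 0:20) {
    stx <- build_structure(cx, cy)
    if (!any((stx$mask | stx$bright) & !sector)) break
    if (i == 20) {
      stop("structure exceeds the sector; reduce the structure parameters")
    }
    cx <- cx + 0.25 * (ref[1] - cx)
    cy <- cy + 0.25 * (ref[2] - cy)
  }
  mask <- stx$mask; bright <- stx$bright

  # per-image acquisition gain jitter, as scanner gain settings vary
  gain <- stats::runif(1, 0.85, 1.15)
  clean <- matrix(0.03, S, S)
  clean[sector] <- 0.60 * (1 - 0.25 * (r[sector] / R))
  clean[mask] <- 0.10
  clean[bright] <- 0.80
  clean <- clean * gain
  # multiplicative Rayleigh speckle, then clip to the displayable range
  u <- matrix(stats::runif(S * S), S, S)
  speck <- spec@speckleScale * sqrt(-2 * log(pmax(u, 1e-12)))
  img <- pmin(pmax(clean * speck, 0), 1)

  struct_all <- mask | bright
  rows <- which(rowSums(struct_all) > 0)
  cols <- which(colSums(struct_all) > 0)
  box <- data.frame(class = spec@classId,
                    cx = (min(cols) - 1 + max(cols)) / 2 / S,
                    cy = (min(rows) - 1 + max(rows)) / 2 / S,
                    w = (max(cols) - min(cols) + 1) / S,
                    h = (max(rows) - min(rows) + 1) / S)
  list(image = img, box = box, mask = struct_all, sector = sector)
}

#' Generate a labelled synthetic dataset in YOLO layout
#'
#' Writes `images/{train,val,test}/*.png`, matching
#' `labels/{train,val,test}/*.txt` and a `manifest.yaml` (class names,
#' ratios, seed) under `outDir`, using [splitDataset()] for the
#' per-class partition. Class balance is exact: `nPerClass` scenes per
#' class.
#'
#' @param nPerClass scenes per class (>= 1).
#' @param ratios train/val/test ratios.
#' @param seed integer seed; two runs with the same seed produce
#'   byte-identical trees.
#' @param outDir output directory.
#' @param imageSize square image size in pixels.
#' @param speckleScale Rayleigh speckle scale.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a data.frame manifest of the written items.
#' @export
generateDataset <- function(nPerClass, ratios = c(7, 2, 1), seed = 0L,
                            outDir, imageSize = 640L,
                            speckleScale = sqrt(2 / pi), overwrite = FALSE) {
  if (nPerClass < 1) stop("`nPerClass` must be >= 1")
  if (dir.exists(outDir) && length(list.files(outDir)) && !overwrite) {
    stop("`outDir` exists and is not empty; pass overwrite = TRUE")
  }
  cm <- classMap()
  items <- lapply(setNames(nm = names(cm)), function(cls) {
    sprintf("%s_%03d", cls, seq_len(nPerClass))
  })
  split <- splitDataset(items, ratios = ratios, seed = seed)
  for (p in c("train", "val", "test")) {
    dir.create(file.path(outDir, "images", p), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outDir, "labels", p), recursive = TRUE,
               showWarnings = FALSE)
  }
  rows <- list()
  for (cls in names(cm)) {
    for (i in seq_len(nPerClass)) {
      id <- sprintf("%s_%03d", cls, i)
      part <- if (id %in% split$train[[cls]]) "train"
              else if (id %in% split$val[[cls]]) "val" else "test"
      spec <- sceneSpec(cm[[cls]], imageSize = imageSize,
                        speckleScale = speckleScale,
                        seed = seed + 13L * cm[[cls]] + 101L * i)
      scan <- generateScan(spec)
      writeImageArray(scan$image,
                      file.path(outDir, "images", part, paste0(id, ".png")))
      writeYoloLabels(file.path(outDir, "labels", part, paste0(id, ".txt")),
                      scan$box)
      rows[[length(rows) + 1L]] <- data.frame(id = id, class = cls,
                                              split = part)
    }
  }
  manifest <- list(classes = names(cm), nPerClass = nPerClass,
                   ratios = as.numeric(ratios / sum(ratios)), seed = seed,
                   imageSize = imageSize, speckleScale = speckleScale)
  writeLines(yaml::as.yaml(manifest), file.path(outDir, "manifest.yaml"))
  invisible(do.call(rbind, rows))
}
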
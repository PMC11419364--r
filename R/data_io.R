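# Dataset plumbing: the four-class map, LabelMe JSON -> YOLO txt
# conversion, deterministic splitting, letterbox resizing and image IO.
#
# Ground-truth boxes are rows of a data.frame with columns
# class (integer 0-3), cx, cy, w, h -- YOLO convention: box centre and
# size normalised to [0, 1] relative to the image dimensions.

#' The four fetal-section classes
#'
#' Fixed, ordered class map: `abdomen` (abdominal transverse section),
#' `four_chamber` (four-chamber view), `vot` (outflow tract section),
#' `three_vessels` (three-vessel view) with ids 0-3.
#'
#' @return named integer vector, name -> id.
#' @export
classMap <- function() {
  c(abdomen = 0L, four_chamber = 1L, vot = 2L, three_vessels = 3L)
}

#' @rdname classMap
#' @param id integer class id(s).
#' @export
className <- function(id) {
  cm <- classMap()
  out <- names(cm)[match(id, cm)]
  if (anyNA(out)) stop("unknown class id: ", paste(id[is.na(out)], collapse = ", "))
  out
}

#' @rdname classMap
#' @param name character class name(s).
#' @export
classId <- function(name) {
  cm <- classMap()
  out <- unname(cm[name])
  if (anyNA(out)) {
    stop("unknown class label: ", paste(name[is.na(out)], collapse = ", "))
  }
  out
}

empty_boxes <- function() {
  data.frame(class = integer(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric())
}

validate_boxes <- function(boxes) {
  stopifnot(is.data.frame(boxes),
            all(c("class", "cx", "cy", "w", "h") %in% names(boxes)))
  if (nrow(boxes) == 0) return(boxes)
  if (any(boxes$w <= 0 | boxes$h <= 0)) stop("boxes must have positive size")
  if (any(boxes$cx < 0 | boxes$cx > 1 | boxes$cy < 0 | boxes$cy > 1)) {
    stop("box centres must lie in [0, 1]")
  }
  boxes
}

#' Convert LabelMe annotations to normalised ground-truth boxes
#'
#' Rectangle shapes use their two corner points; polygon shapes are
#' reduced to their axis-aligned bounding rectangle. Coordinates are
#' normalised by the image dimensions, clipped to the image, and boxes
#' with zero area after clipping are dropped with a warning. Labels must
#' belong to the four-class map.
#'
#' @param json a LabelMe record: a file path, a JSON string, or an
#'   already-parsed list with `shapes` (and optionally `imageHeight`,
#'   `imageWidth`).
#' @param imageDims `c(height, width)` in pixels; taken from the record
#'   when omitted.
#' @return data.frame of boxes (`class`, `cx`, `cy`, `w`, `h`).
#' @export
convertLabelme <- function(json, imageDims = NULL) {
  if (is.character(json)) {
    rec <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  } else {
    rec <- json
  }
  if (is.null(imageDims)) {
    if (is.null(rec$imageHeight) || is.null(rec$imageWidth)) {
      stop("`imageDims` missing and the record carries no image size")
    }
    imageDims <- c(rec$imageHeight, rec$imageWidth)
  }
  H <- imageDims[1]; W <- imageDims[2]
  if (length(rec$shapes) == 0) return(empty_boxes())
  rows <- lapply(rec$shapes, function(sh) {
    id <- classId(sh$label)
    pts <- do.call(rbind, lapply(sh$points, as.numeric))
    x1 <- max(0, min(pts[, 1])); x2 <- min(W, max(pts[, 1]))
    y1 <- max(0, min(pts[, 2])); y2 <- min(H, max(pts[, 2]))
    if (x2 <= x1 || y2 <= y1) {
      warning(sprintf("dropping zero-area box for label '%s'", sh$label))
      return(NULL)
    }
    data.frame(class = id, cx = (x1 + x2) / 2 / W, cy = (y1 + y2) / 2 / H,
               w = (x2 - x1) / W, h = (y2 - y1) / H)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) empty_boxes() else validate_boxes(out)
}

#' Read and write YOLO txt label files
#'
#' One whitespace-delimited line per box: `class cx cy w h` with
#' normalised floats. Writing rounds to 6 decimal places, and a write/read
#' round trip is lossless at that precision. A missing label file is
#' equivalent to an image with zero boxes.
#'
#' @param path label file path.
#' @param nClasses number of valid classes (ids `0:(nClasses - 1)`).
#' @return `readYoloLabels()` returns a box data.frame;
#'   `writeYoloLabels()` returns `path` invisibly.
#' @export
readYoloLabels <- function(path, nClasses = 4L) {
  if (!file.exists(path)) return(empty_boxes())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 5L) {
      stop(sprintf("%s:%d: expected 5 fields, found %d", path, i, length(tok)))
    }
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) stop(sprintf("%s:%d: non-numeric field", path, i))
    if (v[1] != as.integer(v[1]) || v[1] < 0 || v[1] >= nClasses) {
      stop(sprintf("%s:%d: class id %s out of range", path, i, tok[1]))
    }
    if (any(v[2:5] < 0) || any(v[2:3] > 1) || any(v[4:5] > 1) ||
        any(v[4:5] == 0)) {
      stop(sprintf("%s:%d: coordinates out of range", path, i))
    }
    data.frame(class = as.integer(v[1]), cx = v[2], cy = v[3],
               w = v[4], h = v[5])
  })
  do.call(rbind, rows)
}

#' @rdname readYoloLabels
#' @param boxes box data.frame (`class`, `cx`, `cy`, `w`, `h`).
#' @export
writeYoloLabels <- function(path, boxes) {
  boxes <- validate_boxes(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class, boxes$cx,
                   boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic per-class dataset split
#'
#' Shuffles each class with a seeded generator and assigns items to the
#' train/validation/test partitions by floor-then-largest-remainder
#' apportionment, so the partition is disjoint, exhaustive and exactly
#' reproducible from the seed. Per-class ratio overrides support the
#' published 6:2:2 treatment of the under-represented three-vessel class.
#'
#' @param itemsByClass named list: class name -> character vector of item
#'   identifiers.
#' @param ratios numeric length 3 (train, val, test); normalised to sum 1.
#' @param seed integer seed.
#' @param perClassRatios optional named list of per-class ratio overrides.
#' @return list with `train`, `val`, `test` (named lists per class) and
#'   the `seed` and `ratios` used.
#' @examples
#' splitDataset(list(abdomen = sprintf("img%02d", 1:10)),
#'              ratios = c(7, 2, 1), seed = 1)
#' @export
splitDataset <- function(itemsByClass, ratios = c(7, 2, 1), seed = 0L,
                         perClassRatios = NULL) {
  stopifnot(is.list(itemsByClass), length(itemsByClass) > 0)
  if (any(!vapply(itemsByClass, length, integer(1)))) {
    stop("every class must contribute at least one item")
  }
  if (any(ratios < 0) || sum(ratios) <= 0) stop("ratios must be positive")
  parts <- c("train", "val", "test")
  out <- setNames(vector("list", 3), parts)
  for (p in parts) out[[p]] <- list()
  for (cls in names(itemsByClass)) {
    r <- if (!is.null(perClassRatios[[cls]])) perClassRatios[[cls]] else ratios
    r <- r / sum(r)
    items <- itemsByClass[[cls]]
    n <- length(items)
    old <- .Random.seed_save()
    set.seed(seed + sum(utf8ToInt(cls)))
    items <- sample(items)
    .Random.seed_restore(old)
    exact <- n * r
    sizes <- floor(exact)
    rem <- exact - sizes
    short <- n - sum(sizes)
    if (short > 0) {
      # largest remainder; ties favour the later partition so the test
      # set is never short-changed
      take <- order(-rem, -seq_along(rem))[seq_len(short)]
      sizes[take] <- sizes[take] + 1
    }
    at <- 0
    for (i in seq_along(parts)) {
      out[[parts[i]]][[cls]] <-
        if (sizes[i] > 0) items[at + seq_len(sizes[i])] else character()
      at <- at + sizes[i]
    }
  }
  out$seed <- seed
  out$ratios <- ratios
  out
}

# --- images ---------------------------------------------------------------

#' Read an image as a numeric array
#'
#' Returns an `(H, W)` matrix for grayscale or an `(H, W, 3)` array for
#' colour, values in `[0, 1]`.
#'
#' @param path PNG or JPEG file.
#' @return numeric matrix or array.
#' @export
readImageArray <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    e <- EBImage::readImage(path)
    a <- as.array(e)
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  }
  if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]
  if (length(dim(a)) == 3L && dim(a)[3] == 2L) a <- a[, , 1]
  if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
  a
}

#' @rdname readImageArray
#' @param image `(H, W)` or `(H, W, 3)` array in `[0, 1]`.
#' @export
writeImageArray <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

resize_gray <- function(mat, newH, newW) {
  e <- EBImage::resize(EBImage::Image(t(mat)), w = newW, h = newH)
  t(as.array(e))
}

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear rescale followed by symmetric gray padding
#' (value 114/255) to `target x target`. The returned transform maps box
#' coordinates both ways, so labels survive a round trip to within half a
#' pixel.
#'
#' @param image `(H, W)` matrix or `(H, W, 3)` array in `[0, 1]`.
#' @param target square output size, divisible by 32.
#' @return list with `image` and `transform` (`scale`, `padX`, `padY`,
#'   `origH`, `origW`, `target`).
#' @seealso [boxesToLetterbox()], [boxesFromLetterbox()]
#' @export
letterbox <- function(image, target = 640L) {
  if (target %% 32 != 0) stop("`target` must be divisible by 32")
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (is.null(d) || H < 1 || W < 1) stop("image dimensions must be positive")
  s <- min(target / H, target / W)
  newH <- max(1L, round(H * s)); newW <- max(1L, round(W * s))
  pad_fill <- 114 / 255
  padY <- (target - newH) %/% 2L
  padX <- (target - newW) %/% 2L
  place <- function(mat) {
    rs <- resize_gray(mat, newH, newW)
    out <- matrix(pad_fill, target, target)
    out[padY + seq_len(newH), padX + seq_len(newW)] <- rs
    out
  }
  out <- if (length(d) == 2L) {
    place(image)
  } else {
    arr <- array(pad_fill, c(target, target, d[3]))
    for (k in seq_len(d[3])) arr[, , k] <- place(image[, , k])
    arr
  }
  list(image = out,
       transform = list(scale = s, padX = padX, padY = padY,
                        origH = H, origW = W, target = target))
}

#' Map normalised boxes into / out of a letterboxed frame
#'
#' @param boxes box data.frame normalised to the original image
#'   (`boxesToLetterbox`) or to the letterboxed square
#'   (`boxesFromLetterbox`).
#' @param transform transform list returned by [letterbox()].
#' @return box data.frame in the other frame.
#' @export
boxesToLetterbox <- function(boxes, transform) {
  t <- transform
  within(boxes, {
    cx <- (cx * t$origW * t$scale + t$padX) / t$target
    cy <- (cy * t$origH * t$scale + t$padY) / t$target
    w <- w * t$origW * t$scale / t$target
    h <- h * t$origH * t$scale / t$target
  })
}

#' @rdname boxesToLetterbox
#' @export
boxesFromLetterbox <- function(boxes, transform) {
  t <- transform
  within(boxes, {
    cx <- (cx * t$target - t$padX) / t$scale / t$origW
    cy <- (cy * t$target - t$padY) / t$scale / t$origH
    w <- w * t$target / t$scale / t$origW
    h <- h * t$target / t$scale / t$origH
  })
}
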
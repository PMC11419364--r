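#' Trainable-parameter count of the reference small one-stage detector
#'
#' Parameter accounting for the publicly specified small YOLOv5 model
#' (v6.0 layout: 6x6 stem, C3 blocks, SPPF, three heads with three anchors
#' each; depth multiple 0.33, width multiple 0.50), used as the baseline
#' the pruned series is compared against. Only the count is implemented;
#' the series itself is the forward-capable architecture in this package.
#'
#' With 80 classes this reproduces the well-known reference value
#' 7,235,389; the 4-class fetal-section configuration gives 7.03 million.
#'
#' @param nClasses number of object classes.
#' @param depthMultiple,widthMultiple scaling factors of the small model.
#' @return total number of trainable scalars (numeric).
#' @examples
#' yolov5sParameterCount(80)
#' yolov5sParameterCount(4) / 1e6
#' @export
yolov5sParameterCount <- function(nClasses = 4L, depthMultiple = 0.33,
                                  widthMultiple = 0.50) {
  ch <- function(c) as.integer(8 * ceiling(c * widthMultiple / 8))
  rep_n <- function(n) max(1L, round(n * depthMultiple))
  c3 <- function(cin, cout, n) {
    h <- cout %/% 2L
    count_conv(cin, h, 1) + count_conv(cin, h, 1) +
      count_conv(2 * h, cout, 1) +
      n * (count_conv(h, h, 1) + count_conv(h, h, 3))
  }
  p <- count_conv(3, ch(64), 6) +                       # stem
    count_conv(ch(64), ch(128), 3) + c3(ch(128), ch(128), rep_n(3)) +
    count_conv(ch(128), ch(256), 3) + c3(ch(256), ch(256), rep_n(6)) +
    count_conv(ch(256), ch(512), 3) + c3(ch(512), ch(512), rep_n(9)) +
    count_conv(ch(512), ch(1024), 3) + c3(ch(1024), ch(1024), rep_n(3)) +
    count_conv(ch(1024), ch(512), 1) +                  # SPPF reduce
    count_conv(4 * ch(512), ch(1024), 1)                # SPPF fuse
  # feature-fusion head: two upsample stages, two downsample stages
  p <- p + count_conv(ch(1024), ch(512), 1) + c3(ch(1024), ch(512), rep_n(3)) +
    count_conv(ch(512), ch(256), 1) + c3(ch(512), ch(256), rep_n(3)) +
    count_conv(ch(256), ch(256), 3) + c3(ch(512), ch(512), rep_n(3)) +
    count_conv(ch(512), ch(512), 3) + c3(ch(1024), ch(1024), rep_n(3))
  no <- 3 * (5 + nClasses)
  p + sum(c(ch(256), ch(512), ch(1024)) * no + no)
}
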
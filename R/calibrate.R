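#' Calibrate free channel widths against published parameter counts
#'
#' The published tables fix each variant's total trainable parameters but
#' not the per-layer channel widths. `calibrateWidths()` resolves the free
#' widths (neck convolution widths and the expansion of backbone blocks
#' 10-11) so that [countParameters()] reproduces all five targets to
#' within `tol` million. The search is exact and deterministic: the five
#' targets decompose into independent integer subproblems because the
#' variants differ by disjoint layer groups (blocks 10-11; neck layers
#' 20-21 with head 3 versus head 1; neck layers 23-24 with head 4), and
#' each subproblem is solved by exhaustive search over multiples of 8.
#'
#' @param targets named numeric, millions of parameters per variant;
#'   defaults to the published series values.
#' @param nClasses number of object classes the targets refer to.
#' @param tol acceptable absolute residual per variant, in millions.
#' @return list with `widths` (see [emnWidths()]), `achieved` (millions per
#'   variant from re-running [countParameters()] on the built variants),
#'   and `residuals`. Errors with the per-variant residual report if the
#'   target system cannot be met within `tol`.
#' @examples
#' cal <- calibrateWidths()
#' cal$residuals
#' @export
calibrateWidths <- function(targets = c(emns = 0.33, emnm = 0.44, emnl = 0.81,
                                        emnx = 0.92, emnxx = 1.28),
                            nClasses = 4L, tol = 0.01) {
  need <- c("emns", "emnm", "emnl", "emnx", "emnxx")
  if (!all(need %in% names(targets))) {
    stop("`targets` must name all five variants")
  }
  t_abs <- targets[need] * 1e6
  grid <- function(lo, hi) seq.int(lo, hi, by = 8L)

  # fixed masses: stem + backbone blocks 1-9, and the SPPF at its
  # conventional half-width reduction
  sppf_hidden <- 48L
  base_sched <- mnv3_small_schedule(list(bneck10_exp = 1L, bneck11_exp = 1L))
  cin <- 16L
  b9 <- 0
  for (i in 1:9) {
    b9 <- b9 + count_bneck(cin, base_sched[[i]])
    cin <- base_sched[[i]]$cout
  }
  fixed <- count_conv(3, 16, 3) + b9 +
    count_sppf(96, list(hidden = sppf_hidden, cout = 96))
  hp <- function(cin) count_head(cin, nClasses)

  # subproblem 1: expansion of blocks 10-11 carries the emnl - emns mass
  mass_b <- ((t_abs["emnl"] - t_abs["emns"]) +
             (t_abs["emnx"] - t_abs["emnm"])) / 2
  bmass <- function(e) 2 * count_bneck(96, list(kernel = 5L, exp = e,
                                                cout = 96L, se = TRUE))
  es <- grid(8L, 1024L)
  e <- es[which.min(abs(vapply(es, bmass, numeric(1)) - mass_b))]

  # subproblem 2: upsampling neck + heads 1-2 close the emns total
  best <- NULL; bestr <- Inf
  for (c13 in grid(16L, 160L)) for (c16 in grid(16L, 160L)) {
    for (c18 in grid(16L, 160L)) {
      v <- fixed + count_conv(96, c13, 1) + count_conv(c13 + 48, c16, 1) +
        count_conv(c16, c18, 1) + hp(c13 + 48) + hp(c18 + 24)
      r <- abs(v - t_abs["emns"])
      if (r < bestr) { bestr <- r; best <- c(c13, c16, c18) }
    }
  }
  c13 <- best[1]; c16 <- best[2]; c18 <- best[3]

  # subproblem 3: layers 20-21 plus head 3 minus head 1 give emnm - emns
  d_m <- t_abs["emnm"] - t_abs["emns"]
  best <- NULL; bestr <- Inf
  for (c20 in grid(32L, 256L)) for (c21 in grid(32L, 512L)) {
    v <- count_conv(c18 + 24, c20, 3) + count_conv(c20, c21, 1) +
      hp(c21 + c16) - hp(c13 + 48)
    r <- abs(v - d_m)
    if (r < bestr) { bestr <- r; best <- c(c20, c21) }
  }
  c20 <- best[1]; c21 <- best[2]

  # subproblem 4: layers 23-24 plus head 4 give emnxx - emnx
  d_xx <- t_abs["emnxx"] - t_abs["emnx"]
  best <- NULL; bestr <- Inf
  for (c23 in grid(32L, 256L)) for (c24 in grid(64L, 768L)) {
    v <- count_conv(c21 + c16, c23, 3) + count_conv(c23, c24, 1) +
      hp(c24 + c13)
    r <- abs(v - d_xx)
    if (r < bestr) { bestr <- r; best <- c(c23, c24) }
  }

  widths <- list(bneck10_exp = e, bneck11_exp = e, sppf_hidden = sppf_hidden,
                 c13 = c13, c16 = c16, c18 = c18, c20 = c20, c21 = c21,
                 c23 = best[1], c24 = best[2])

  achieved <- vapply(need, function(nm) {
    countParameters(buildVariant(nm, nClasses, widths)) / 1e6
  }, numeric(1))
  residuals <- achieved - targets[need]
  if (any(abs(residuals) > tol)) {
    stop(paste0("width calibration infeasible; per-variant residuals (M): ",
                paste(sprintf("%s %+0.4f", need, residuals), collapse = ", ")))
  }
  list(widths = widths, achieved = achieved, residuals = residuals)
}
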
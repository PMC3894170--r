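#' Copy number of a target region from depth of coverage
#'
#' Per-base copy number is `2 * smoothed depth / control diploid mean`,
#' where the control mean comes from known-diploid (copy 2) regions of
#' the same sample and the smoothing is a sliding mean (window shrinks at
#' the track edges). The region estimate is the mean per-base copy over
#' the target interval, and the discrete call rounds it half-up, so
#' fractional estimates (e.g. "three to four copies") remain first-class
#' alongside the integer call.
#'
#' @param track A `depth_track` (see [simulate_depth_track()]) or a list
#'   with `depth` (per-base reads) and `control$mean` (mean depth of
#'   diploid control regions).
#' @param region Integer length-2, 0-based half-open `(start, end)`
#'   interval within the track.
#' @param smoothing_window Sliding-mean width in bp (default 1000).
#' @return An object of class `copy_call`: `per_base` copy estimates over
#'   the region, `mean_copy`, `call` and the region.
#' @examples
#' tr <- simulate_depth_track(rep(c(2L, 29L, 2L), c(2000, 7000, 2000)),
#'                            15, seed = 1)
#' # score the interior of the expansion, clear of the smoothing window
#' copy_number_from_depth(tr, c(3000, 8000))$call  # 29
#' @export
copy_number_from_depth <- function(track, region,
                                   smoothing_window = 1000) {
  depth <- track$depth
  ctrl <- track$control$mean
  if (is.null(ctrl) || !is.finite(ctrl) || ctrl <= 0)
    stop("control diploid mean depth is zero; cannot normalize",
         call. = FALSE)
  L <- length(depth)
  if (length(region) != 2L || region[1] < 0 || region[2] > L ||
      region[2] <= region[1])
    stop("'region' must be a non-empty 0-based half-open interval ",
         "within the track", call. = FALSE)
  sm <- running_mean(depth, smoothing_window)
  per_base <- 2 * sm / ctrl
  idx <- (region[1] + 1L):region[2]
  mean_copy <- mean(per_base[idx])
  structure(list(per_base = per_base[idx],
                 mean_copy = mean_copy,
                 call = floor(mean_copy + 0.5),   # round half-up
                 region = c(start = region[1], end = region[2])),
            class = "copy_call")
}

#' @export
print.copy_call <- function(x, ...) {
  cat(sprintf(
    "Copy number over [%d, %d): mean %.2f, discrete call %d\n",
    x$region["start"], x$region["end"], x$mean_copy, x$call))
  invisible(x)
}

# centered sliding mean; edge windows shrink
running_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Copy number from qPCR delta-delta-Ct
#'
#' Standard relative quantification: the target's copy number equals the
#' calibrator's copy number scaled by
#' `efficiency^(-delta_delta_ct)`, where the amplification efficiency is
#' the per-cycle amplification factor (2 for perfect doubling) and the
#' calibrator is a sample of known copy number (a diploid two-copy
#' individual by default).
#'
#' @param delta_delta_ct Cycle-threshold difference of differences
#'   (target vs reference gene, sample vs calibrator).
#' @param efficiency Amplification factor per cycle, in `(1, 2]`.
#' @param calibrator_copies Copy number of the calibrator sample (> 0).
#' @return Estimated copy number.
#' @examples
#' qpcr_copy_number(-1)  # 4 copies
#' @export
qpcr_copy_number <- function(delta_delta_ct, efficiency = 2,
                             calibrator_copies = 2) {
  if (efficiency <= 1 || efficiency > 2)
    stop("'efficiency' must be in (1, 2]", call. = FALSE)
  if (calibrator_copies <= 0)
    stop("'calibrator_copies' must be > 0", call. = FALSE)
  calibrator_copies * efficiency^(-delta_delta_ct)
}
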
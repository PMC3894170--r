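#' Windowed heterozygosity of one diploid sample
#'
#' Counts heterozygous sites per window and divides by the called sites
#' per window. For a [locus_set()] the windows are runs of consecutive
#' loci covering `window_bp` of concatenated sequence. Windows with no
#' called sites get a missing (`NA`) rate, not zero. Summary quartiles
#' for box-plot style reporting exclude windows with under half of their
#' sites called.
#'
#' @param data A [locus_set()].
#' @param sample Sample name.
#' @param window_bp Window size in bp (converted to whole loci).
#' @return An object of class `het_track`: a data.frame of windows
#'   (`start`, `end` in bp on the concatenated coordinate system,
#'   `het`, `called`, `rate`) with attributes `genome_rate` (total het /
#'   total called) and `quartiles`.
#' @examples
#' m <- canid_model("fig5a")
#' ls <- simulate_dataset(m, n_loci = 200, mu = 1e-8, seed = 1,
#'                        samples = c(CRW = 2))
#' attr(windowed_heterozygosity(ls, "CRW"), "genome_rate")
#' @export
windowed_heterozygosity <- function(data, sample, window_bp = 1e5) {
  stopifnot(inherits(data, "locus_set"))
  g <- sample_geno(data, sample)[, 1L]
  loci_per_win <- max(1L, round(window_bp / data$locus_length))
  n_win <- max(1L, (data$n_loci - 1L) %/% loci_per_win + 1L)
  win_of_locus <- (seq_len(data$n_loci) - 1L) %/% loci_per_win + 1L
  het_site <- !is.na(g) & g == 1L
  wf <- factor(win_of_locus[data$site$locus], levels = seq_len(n_win))
  het <- as.integer(tabulate(wf[het_site], nbins = n_win))
  called_locus <- data$called[, sample]
  # missing genotypes reduce the called count
  miss <- tabulate(factor(data$site$locus[is.na(g)],
                          levels = seq_len(data$n_loci)),
                   nbins = data$n_loci)
  called <- as.numeric(tapply(called_locus - miss,
                              factor(win_of_locus,
                                     levels = seq_len(n_win)), sum))
  rate <- ifelse(called > 0, het / called, NA_real_)
  w_start <- (seq_len(n_win) - 1L) * loci_per_win * data$locus_length
  w_end <- pmin(seq_len(n_win) * loci_per_win, data$n_loci) *
    data$locus_length
  full <- w_end - w_start
  tr <- data.frame(start = w_start, end = w_end,
                   het = het, called = called, rate = rate)
  attr(tr, "genome_rate") <- sum(het) / sum(called)
  ok <- !is.na(rate) & called >= 0.5 * full
  attr(tr, "quartiles") <- stats::quantile(rate[ok], c(.25, .5, .75),
                                           na.rm = TRUE)
  attr(tr, "sample") <- sample
  attr(tr, "window_bp") <- loci_per_win * data$locus_length
  class(tr) <- c("het_track", "data.frame")
  tr
}

#' Classify variant sites by sharing between two groups
#'
#' For every biallelic variant site with no missing genotype in either
#' group: a site segregating (both alleles present) within both groups is
#' `shared`; segregating in exactly one group while the other is
#' monomorphic is `private` to the segregating group; monomorphic for
#' opposite alleles in the two groups is a `fixed` difference. Sites
#' monomorphic for the same allele in both groups are not variant within
#' the comparison and are left unclassified.
#'
#' @param data A [locus_set()].
#' @param dogs,wolves Character vectors of sample names for the two
#'   groups (names kept for the canid application; any two groups work).
#' @return An object of class `sharing_summary`: counts and percentages
#'   for shared / private-to-wolves / private-to-dogs / fixed, plus the
#'   number of sites excluded for missingness.
#' @export
classify_variant_sites <- function(data, dogs, wolves) {
  stopifnot(inherits(data, "locus_set"))
  if (!length(dogs) || !length(wolves))
    stop("both groups must be non-empty", call. = FALSE)
  gd <- sample_geno(data, dogs)
  gw <- sample_geno(data, wolves)
  ok <- rowSums(is.na(gd)) == 0L & rowSums(is.na(gw)) == 0L
  gd <- gd[ok, , drop = FALSE]; gw <- gw[ok, , drop = FALSE]
  cd <- rowSums(gd); cw <- rowSums(gw)
  md <- 2L * ncol(gd); mw <- 2L * ncol(gw)
  seg_d <- cd > 0L & cd < md
  seg_w <- cw > 0L & cw < mw
  mono_d <- !seg_d; mono_w <- !seg_w
  shared <- seg_d & seg_w
  priv_d <- seg_d & mono_w
  priv_w <- seg_w & mono_d
  fixed <- mono_d & mono_w & ((cd == 0L) != (cw == 0L))
  counts <- c(shared = sum(shared), private_wolves = sum(priv_w),
              private_dogs = sum(priv_d), fixed = sum(fixed))
  structure(list(counts = counts,
                 percent = 100 * counts / sum(counts),
                 n_classified = sum(counts),
                 n_excluded_missing = sum(!ok)),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat("Variant-site sharing between groups:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-15s %8d  (%.1f%%)\n", nm, x$counts[nm],
                x$percent[nm]))
  if (x$n_excluded_missing)
    cat(sprintf("  (%d sites excluded for missing genotypes)\n",
                x$n_excluded_missing))
  invisible(x)
}

#' Mask runs of homozygosity from a heterozygosity track
#'
#' Flags maximal runs of consecutive windows whose heterozygosity falls
#' below `rate_threshold` times the genome-wide mean and whose total
#' length reaches `min_length`. Recent inbreeding produces such runs;
#' masking them tests whether depressed-diversity segments drive
#' long-term effective-size estimates.
#'
#' @param het_track A [windowed_heterozygosity()] track.
#' @param rate_threshold Fraction of the genome-wide mean rate below
#'   which a window is a candidate (default 0.1).
#' @param min_length Minimum run length in bp (default 1 Mb).
#' @return A list with `intervals` (data.frame of 0-based half-open
#'   `start`/`end`) and `masked_rate` (genome heterozygosity excluding
#'   masked windows).
#' @export
roh_mask <- function(het_track, rate_threshold = 0.1, min_length = 1e6) {
  stopifnot(inherits(het_track, "het_track"))
  gm <- attr(het_track, "genome_rate")
  if (!is.finite(gm) || gm <= 0)
    stop("genome-wide mean heterozygosity is zero; threshold undefined",
         call. = FALSE)
  low <- !is.na(het_track$rate) & het_track$rate < rate_threshold * gm
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = numeric(0), end = numeric(0))
  keep_mask <- rep(FALSE, nrow(het_track))
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    len <- het_track$end[i1] - het_track$start[i0]
    if (len >= min_length) {
      iv <- rbind(iv, data.frame(start = het_track$start[i0],
                                 end = het_track$end[i1]))
      keep_mask[i0:i1] <- TRUE
    }
  }
  un <- !keep_mask
  masked_rate <- sum(het_track$het[un]) / sum(het_track$called[un])
  list(intervals = iv, masked_rate = masked_rate)
}
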
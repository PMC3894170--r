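#' Specify an ordered quartet for site-pattern analysis
#'
#' Site patterns are read in the order (P1, P2, P3, O). In the admixture
#' test P3 is the putative source lineage and P1/P2 the two receiving
#' lineages, with O a fixed outgroup.
#'
#' @param p1,p2,p3 Ingroup sample names.
#' @param outgroup Outgroup sample name.
#' @return An object of class `quartet_spec`.
#' @export
quartet_spec <- function(p1, p2, p3, outgroup) {
  s <- c(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup)
  if (anyDuplicated(s)) stop("quartet samples must be distinct",
                             call. = FALSE)
  structure(as.list(s), class = "quartet_spec")
}

#' @export
print.quartet_spec <- function(x, ...) {
  cat(sprintf("Quartet: P1=%s P2=%s P3=%s O=%s\n",
              x$p1, x$p2, x$p3, x$outgroup))
  invisible(x)
}

#' Classify sites into ABBA / BABA / BBAA presence patterns
#'
#' An allele is "present" in a diploid iff it carries at least one copy.
#' A site qualifies only when the two alleles partition the four
#' individuals 2/2 with no individual carrying both alleles (i.e. all
#' four are homozygous, two for each allele). Writing A for the allele
#' carried by the outgroup: `BBAA` pairs P1 with P2, `ABBA` pairs P2 with
#' P3, `BABA` pairs P1 with P3. Heterozygous, monomorphic and missing
#' sites are classified `other`.
#'
#' @param geno Integer matrix or vector: derived-allele dosages for
#'   (P1, P2, P3, O), one row per site.
#' @return Character vector of labels in
#'   `{"ABBA", "BABA", "BBAA", "other"}`.
#' @examples
#' presence_partition(rbind(c(2, 2, 0, 0), c(0, 2, 2, 0), c(1, 0, 2, 0)))
#' @export
presence_partition <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
  stopifnot(ncol(geno) == 4L)
  lab <- rep("other", nrow(geno))
  ok <- rowSums(is.na(geno)) == 0L & rowSums(geno == 1L) == 0L
  x <- geno[ok, , drop = FALSE] / 2L              # 0/1 per individual
  flip <- x[, 4L] == 1L                           # recode so O carries A
  x[flip, ] <- 1L - x[flip, ]
  two <- rowSums(x[, 1:3, drop = FALSE]) == 2L    # 2/2 partition
  cls <- rep("other", nrow(x))
  cls[two & x[, 1L] == 0L] <- "ABBA"
  cls[two & x[, 2L] == 0L] <- "BABA"
  cls[two & x[, 3L] == 0L] <- "BBAA"
  lab[ok] <- cls
  lab
}

#' Tally quartet site patterns over a locus set
#'
#' Applies [presence_partition()] to every variant site (strict mode) and
#' additionally accumulates frequency-weighted pattern sums in which each
#' diploid contributes its derived-allele frequency in `{0, 1/2, 1}`
#' (ABBA weight `(1-p1) p2 p3 (1-p4)`, BABA weight `p1 (1-p2) p3 (1-p4)`,
#' BBAA weight `p1 p2 (1-p3) (1-p4)`), so heterozygous sites contribute
#' fractionally instead of being discarded. Sites with a missing genotype
#' in any quartet member are excluded from this quartet only. Contiguous
#' runs of whole loci form the jackknife blocks.
#'
#' @param quartet A [quartet_spec()].
#' @param data A [locus_set()].
#' @param block_size Number of consecutive loci per jackknife block.
#' @return An object of class `site_pattern_table`: strict counts
#'   `n_abba`, `n_baba`, `n_bbaa`, frequencies conditional on qualifying
#'   sites, weighted sums `w_abba`/`w_baba`/`w_bbaa`, and a `blocks`
#'   data.frame with per-block tallies.
#' @export
count_patterns <- function(quartet, data, block_size = 200) {
  stopifnot(inherits(quartet, "quartet_spec"), inherits(data, "locus_set"))
  g <- sample_geno(data, c(quartet$p1, quartet$p2, quartet$p3,
                           quartet$outgroup))
  keep <- rowSums(is.na(g)) == 0L
  g <- g[keep, , drop = FALSE]
  blk <- (data$site$locus[keep] - 1L) %/% as.integer(block_size) + 1L
  n_blocks <- max(1L, (data$n_loci - 1L) %/% as.integer(block_size) + 1L)

  lab <- presence_partition(g)
  p <- g / 2
  wa <- (1 - p[, 1L]) * p[, 2L] * p[, 3L] * (1 - p[, 4L])
  wb <- p[, 1L] * (1 - p[, 2L]) * p[, 3L] * (1 - p[, 4L])
  wc <- p[, 1L] * p[, 2L] * (1 - p[, 3L]) * (1 - p[, 4L])

  blocks <- data.frame(block = seq_len(n_blocks))
  f <- factor(blk, levels = seq_len(n_blocks))
  blocks$n_abba <- as.integer(tabulate(f[lab == "ABBA"], n_blocks))
  blocks$n_baba <- as.integer(tabulate(f[lab == "BABA"], n_blocks))
  blocks$n_bbaa <- as.integer(tabulate(f[lab == "BBAA"], n_blocks))
  sum_by <- function(w) {
    z <- tapply(w, f, sum, default = 0)
    as.numeric(ifelse(is.na(z), 0, z))
  }
  blocks$w_abba <- sum_by(wa)
  blocks$w_baba <- sum_by(wb)
  blocks$w_bbaa <- sum_by(wc)

  n <- c(abba = sum(blocks$n_abba), baba = sum(blocks$n_baba),
         bbaa = sum(blocks$n_bbaa))
  tot <- sum(n)
  structure(list(
    quartet = quartet,
    n_abba = unname(n["abba"]), n_baba = unname(n["baba"]),
    n_bbaa = unname(n["bbaa"]),
    freq = if (tot > 0) unname(n / tot) else rep(NA_real_, 3L),
    w_abba = sum(blocks$w_abba), w_baba = sum(blocks$w_baba),
    w_bbaa = sum(blocks$w_bbaa),
    blocks = blocks, n_excluded_missing = sum(!keep)),
    class = "site_pattern_table")
}

#' @export
print.site_pattern_table <- function(x, ...) {
  cat(sprintf("Site patterns (P1=%s P2=%s P3=%s O=%s):\n",
              x$quartet$p1, x$quartet$p2, x$quartet$p3,
              x$quartet$outgroup))
  cat(sprintf("  ABBA=%d BABA=%d BBAA=%d (%d blocks)\n",
              x$n_abba, x$n_baba, x$n_bbaa, nrow(x$blocks)))
  invisible(x)
}

#' D statistic from a site-pattern table
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`, in `[-1, 1]`. The default uses
#' the frequency-weighted sums, which use heterozygous sites instead of
#' discarding them; `mode = "strict"` uses the homozygous 2/2 counts.
#'
#' @param table A `site_pattern_table`.
#' @param mode `"weighted"` (default) or `"strict"`.
#' @return The D statistic.
#' @export
d_statistic <- function(table, mode = c("weighted", "strict")) {
  stopifnot(inherits(table, "site_pattern_table"))
  mode <- match.arg(mode)
  ab <- pattern_ab(table, mode)
  if (ab$a + ab$b <= 0)
    stop("D undefined: no ABBA or BABA signal at any site", call. = FALSE)
  (ab$a - ab$b) / (ab$a + ab$b)
}

pattern_ab <- function(table, mode) {
  if (mode == "strict")
    list(a = table$n_abba, b = table$n_baba,
         ba = table$blocks$n_abba, bb = table$blocks$n_baba)
  else
    list(a = table$w_abba, b = table$w_baba,
         ba = table$blocks$w_abba, bb = table$blocks$w_baba)
}

#' Block-jackknife Z-score for the D statistic
#'
#' Delete-one-block jackknife over contiguous blocks of loci: the D
#' statistic is recomputed with each block removed, the jackknife
#' standard error is derived from the spread of the leave-one-out
#' estimates, and `Z = D / SE`. Following the usual convention, `|Z| >= 3`
#' is flagged significant.
#'
#' @inheritParams d_statistic
#' @param min_blocks Minimum number of non-empty blocks required.
#' @return A list with `D`, `SE`, `Z`, `significant` and `n_blocks`.
#' @export
jackknife_z <- function(table, mode = c("weighted", "strict"),
                        min_blocks = 20) {
  stopifnot(inherits(table, "site_pattern_table"))
  mode <- match.arg(mode)
  ab <- pattern_ab(table, mode)
  use <- (ab$ba + ab$bb) > 0
  g <- sum(use)
  if (g < min_blocks)
    stop(sprintf("only %d non-empty blocks; need at least %d", g,
                 min_blocks), call. = FALSE)
  A <- sum(ab$ba); B <- sum(ab$bb)
  if (A + B <= 0) stop("D undefined: no ABBA/BABA signal", call. = FALSE)
  D <- (A - B) / (A + B)
  Aj <- A - ab$ba[use]; Bj <- B - ab$bb[use]
  Dj <- (Aj - Bj) / (Aj + Bj)
  se <- sqrt((g - 1) / g * sum((Dj - mean(Dj))^2))
  if (se == 0)
    stop("jackknife variance is zero; Z undefined (identical blocks)",
         call. = FALSE)
  z <- D / se
  list(D = D, SE = se, Z = z, significant = abs(z) >= 3, n_blocks = g)
}

#' Enumerate quartets for site-pattern analysis
#'
#' With `mode = "all"`, every 3-subset of the ingroup is combined with the
#' outgroup (in deterministic, sorted-combination order), giving
#' `choose(n, 3)` quartets: the configuration-frequency layout. With
#' `mode = "dog_wolf_test"`, only quartets where P3 belongs to one group
#' and (P1, P2) to the other are returned, the layout of the directed
#' admixture scan between two labeled groups.
#'
#' @param ingroup Character vector of ingroup sample names (>= 3).
#' @param outgroup Outgroup sample name.
#' @param mode `"all"` or `"dog_wolf_test"`.
#' @param groups Named character vector mapping each ingroup sample to
#'   `"dog"` or `"wolf"` (required for `dog_wolf_test`).
#' @return A list of [quartet_spec()] objects.
#' @examples
#' length(enumerate_quartets(letters[1:6], "o"))  # 20
#' @export
enumerate_quartets <- function(ingroup, outgroup,
                               mode = c("all", "dog_wolf_test"),
                               groups = NULL) {
  mode <- match.arg(mode)
  if (length(ingroup) < 3L) stop("need at least 3 ingroup samples",
                                 call. = FALSE)
  if (mode == "all") {
    cmb <- utils::combn(ingroup, 3L)
    return(lapply(seq_len(ncol(cmb)), function(j)
      quartet_spec(cmb[1L, j], cmb[2L, j], cmb[3L, j], outgroup)))
  }
  if (is.null(groups) || !all(ingroup %in% names(groups)) ||
      !all(groups[ingroup] %in% c("dog", "wolf")))
    stop("'dog_wolf_test' mode requires dog/wolf labels for all ingroup ",
         "samples", call. = FALSE)
  dogs <- ingroup[groups[ingroup] == "dog"]
  wolves <- ingroup[groups[ingroup] == "wolf"]
  out <- list()
  add <- function(p3s, pair_pool) {
    for (p3 in p3s) {
      if (length(pair_pool) < 2L) next
      pr <- utils::combn(pair_pool, 2L)
      for (j in seq_len(ncol(pr)))
        out[[length(out) + 1L]] <<- quartet_spec(pr[1L, j], pr[2L, j],
                                                 p3, outgroup)
    }
  }
  add(dogs, wolves)   # dog source, wolf receivers
  add(wolves, dogs)   # wolf source, dog receivers
  out
}

#' Configuration-frequency table over many quartets
#'
#' Convenience wrapper running [count_patterns()] over a list of quartets
#' and returning one row per quartet with strict counts, conditional
#' frequencies, and (when at least `min_blocks` blocks are available) the
#' weighted D statistic with its jackknife Z-score.
#'
#' @param data A [locus_set()].
#' @param quartets List of [quartet_spec()] objects.
#' @param block_size Loci per jackknife block.
#' @param jackknife If `TRUE`, attach D/SE/Z columns.
#' @return A data.frame, one row per quartet.
#' @export
pattern_frequency_table <- function(data, quartets, block_size = 200,
                                    jackknife = FALSE) {
  rows <- lapply(quartets, function(q) {
    tab <- count_patterns(q, data, block_size = block_size)
    row <- data.frame(p1 = q$p1, p2 = q$p2, p3 = q$p3,
                      outgroup = q$outgroup,
                      n_abba = tab$n_abba, n_baba = tab$n_baba,
                      n_bbaa = tab$n_bbaa,
                      f_abba = tab$freq[1], f_baba = tab$freq[2],
                      f_bbaa = tab$freq[3], stringsAsFactors = FALSE)
    if (jackknife) {
      jz <- jackknife_z(tab)
      row$D <- jz$D; row$SE <- jz$SE; row$Z <- jz$Z
      row$significant <- jz$significant
    }
    row
  })
  do.call(rbind, rows)
}

#' Absolute-error fit score between observed and simulated configurations
#'
#' Sums, over quartets and over the three configurations
#' {ABBA, BABA, BBAA}, the absolute difference between simulated and
#' observed conditional frequencies. Cells whose absolute difference
#' exceeds `flag_threshold` (default 0.015, i.e. 1.5 percentage points)
#' are flagged.
#'
#' @param observed,simulated Data.frames as returned by
#'   [pattern_frequency_table()] (columns `p1`, `p2`, `p3`, `outgroup`,
#'   `f_abba`, `f_baba`, `f_bbaa`), covering the same quartets.
#' @param flag_threshold Absolute frequency difference above which a cell
#'   is flagged.
#' @return A list with `score` (the summed absolute error) and `flags`
#'   (data.frame of flagged quartet/configuration cells).
#' @export
model_fit_error <- function(observed, simulated, flag_threshold = 0.015) {
  key <- function(d) paste(d$p1, d$p2, d$p3, d$outgroup, sep = "|")
  ko <- key(observed); ks <- key(simulated)
  if (!setequal(ko, ks) || anyDuplicated(ko) || anyDuplicated(ks))
    stop("observed and simulated tables must cover the same quartets",
         call. = FALSE)
  simulated <- simulated[match(ko, ks), ]
  cols <- c("f_abba", "f_baba", "f_bbaa")
  diff <- as.matrix(simulated[cols]) - as.matrix(observed[cols])
  score <- sum(abs(diff))
  hit <- which(abs(diff) > flag_threshold, arr.ind = TRUE)
  flags <- data.frame(quartet = ko[hit[, 1L]],
                      configuration = c("ABBA", "BABA", "BBAA")[hit[, 2L]],
                      difference = diff[hit], stringsAsFactors = FALSE)
  list(score = score, flags = flags)
}
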
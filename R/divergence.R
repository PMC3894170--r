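#' Pairwise sequence divergence between two diploids
#'
#' Two estimators of per-site divergence between diploid genotype tracks
#' aligned on the same called-site set. In `allpairs` mode every site
#' contributes the mean of the four inter-individual allele comparisons,
#' i.e. `p(1-q) + (1-p)q` with `p`, `q` the two derived-allele dosages
#' divided by 2. In `conservative` mode a site contributes 1 only when the
#' two genotypes share no allele (one is homozygous reference where the
#' other is homozygous alternate); all sites involving a heterozygote
#' contribute 0. The conservative estimator therefore never exceeds the
#' all-pairs estimator.
#'
#' @param a,b Integer vectors of derived-allele dosages at the variant
#'   sites (`NA` allowed; such sites are dropped pairwise).
#' @param called Total number of called sites shared by the pair
#'   (variant + monomorphic).
#' @param mode `"conservative"` or `"allpairs"`.
#' @return Mean per-site divergence.
#' @examples
#' pairwise_divergence(c(0L, 0L, 0L), c(0L, 1L, 2L), called = 1000)
#' @export
pairwise_divergence <- function(a, b, called,
                                mode = c("conservative", "allpairs")) {
  mode <- match.arg(mode)
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (called <= 0) stop("no overlapping called sites", call. = FALSE)
  mm <- pair_mismatch(a[ok], b[ok], mode)
  sum(mm) / called
}

pair_mismatch <- function(a, b, mode) {
  if (mode == "conservative") as.numeric(abs(a - b) == 2L)
  else { p <- a / 2; q <- b / 2; p * (1 - q) + (1 - p) * q }
}

#' Pairwise divergence matrix with per-window partial sums
#'
#' Computes all pairwise divergences over a [locus_set()] and retains
#' per-window mismatch and called-site partial sums (windows are runs of
#' `window_loci` consecutive loci), the inputs for
#' [window_bootstrap_support()]. Missing genotypes are dropped per pair;
#' the corresponding called-site counts are reduced accordingly.
#'
#' @param data A [locus_set()] with at least 3 samples.
#' @param mode `"conservative"` (default) or `"allpairs"`, see
#'   [pairwise_divergence()].
#' @param window_loci Number of consecutive loci per window.
#' @return An object of class `divergence_matrix`: the symmetric matrix
#'   `d`, sample names, and per-window partials `window_mismatch` /
#'   `window_called` (windows x pairs).
#' @export
distance_matrix <- function(data, mode = c("conservative", "allpairs"),
                            window_loci = 10) {
  stopifnot(inherits(data, "locus_set"))
  mode <- match.arg(mode)
  s <- data$samples
  if (length(s) < 3L) stop("need at least 3 samples", call. = FALSE)
  n_win <- max(1L, (data$n_loci - 1L) %/% as.integer(window_loci) + 1L)
  win_of_locus <- (seq_len(data$n_loci) - 1L) %/%
    as.integer(window_loci) + 1L
  wf <- factor(win_of_locus[data$site$locus], levels = seq_len(n_win))
  pairs <- utils::combn(s, 2L)
  np <- ncol(pairs)
  mm <- matrix(0, n_win, np)
  cl <- matrix(0, n_win, np)
  pair_names <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  colnames(mm) <- colnames(cl) <- pair_names
  lf <- factor(data$site$locus, levels = seq_len(data$n_loci))
  for (j in seq_len(np)) {
    a <- data$geno[, pairs[1L, j]]
    b <- data$geno[, pairs[2L, j]]
    ok <- !is.na(a) & !is.na(b)
    v <- pair_mismatch(a[ok], b[ok], mode)
    z <- tapply(v, wf[ok], sum, default = 0)
    mm[, j] <- ifelse(is.na(z), 0, as.numeric(z))
    # called sites: min of the pair's per-locus calls, minus pairwise-missing
    called_locus <- pmin(data$called[, pairs[1L, j]],
                         data$called[, pairs[2L, j]])
    miss <- tabulate(lf[!ok], nbins = data$n_loci)
    cl[, j] <- as.numeric(tapply(
      called_locus - miss,
      factor(win_of_locus, levels = seq_len(n_win)), sum))
  }
  tot_mm <- colSums(mm); tot_cl <- colSums(cl)
  if (any(tot_cl <= 0)) stop("no overlapping called sites for some pair",
                             call. = FALSE)
  d <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (j in seq_len(np))
    d[pairs[1L, j], pairs[2L, j]] <- d[pairs[2L, j], pairs[1L, j]] <-
      tot_mm[j] / tot_cl[j]
  structure(list(d = d, samples = s, mode = mode,
                 window_mismatch = mm, window_called = cl,
                 pairs = pairs),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("Divergence matrix (%s mode), %d samples, %d windows\n",
              x$mode, length(x$samples), nrow(x$window_mismatch)))
  print(signif(x$d, 3))
  invisible(x)
}

#' Neighbor-joining tree from a divergence matrix
#'
#' Canonical neighbor joining (via [ape::nj()]) on the pairwise
#' divergence matrix. Negative branch-length estimates, which NJ can
#' produce by sampling noise, are clamped to zero; the tree carries an
#' attribute `clamped` saying whether that happened.
#'
#' @param x A `divergence_matrix` or a plain symmetric numeric matrix
#'   with dimnames.
#' @return An [ape::phylo] tree (unrooted, branch lengths in per-site
#'   divergence units).
#' @export
nj_tree <- function(x) {
  d <- if (inherits(x, "divergence_matrix")) x$d else as.matrix(x)
  if (!all(is.finite(d))) stop("divergence matrix has non-finite entries",
                               call. = FALSE)
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- any(neg)
  tr
}

#' Bootstrap support from resampled windows
#'
#' Nonparametric bootstrap over genomic windows: each replicate draws
#' windows with replacement until the resampled genome contains at least
#' as many called sites as the original, rebuilds each pairwise
#' divergence as (sum of mismatches) / (sum of called sites) over the
#' drawn windows, and re-runs neighbor joining. Windows are resampled
#' globally (one window sequence per replicate applied to every pair) so
#' each replicate's matrix is internally consistent. Support for each
#' internal edge of the original tree is the percentage of replicates
#' containing the same bipartition.
#'
#' @param x A `divergence_matrix` with window partials.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param outgroup Optional sample name used to root trees before clade
#'   comparison (the natural choice is the outgroup taxon); if `NULL`,
#'   unrooted bipartitions are compared.
#' @return An [ape::phylo] tree with internal-node labels giving percent
#'   bootstrap support.
#' @export
window_bootstrap_support <- function(x, n_reps = 100, seed = 1,
                                     outgroup = NULL) {
  stopifnot(inherits(x, "divergence_matrix"))
  n_win <- nrow(x$window_mismatch)
  if (n_win < 2L) {
    warning("single window: all supports are 100 by construction")
  }
  set.seed(as.integer(seed))
  target <- sum(x$window_called) / ncol(x$window_called)  # per-genome mean
  win_tot <- rowMeans(x$window_called)
  orig <- nj_tree(x)
  root_at <- function(tr) {
    if (is.null(outgroup)) tr
    else ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  boot <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    idx <- integer(0); got <- 0
    while (got < target) {
      draw <- sample.int(n_win, max(16L, n_win), replace = TRUE)
      cum <- got + cumsum(win_tot[draw])
      need <- which(cum >= target)
      if (length(need)) {
        idx <- c(idx, draw[seq_len(need[1L])])
        got <- cum[need[1L]]
      } else {
        idx <- c(idx, draw)
        got <- cum[length(cum)]
      }
    }
    mm <- colSums(x$window_mismatch[idx, , drop = FALSE])
    cl <- colSums(x$window_called[idx, , drop = FALSE])
    d <- x$d
    d[] <- 0
    for (j in seq_len(ncol(x$pairs)))
      d[x$pairs[1L, j], x$pairs[2L, j]] <-
        d[x$pairs[2L, j], x$pairs[1L, j]] <- mm[j] / max(cl[j], 1)
    boot[[r]] <- root_at(nj_tree(d))
  }
  orig_r <- root_at(orig)
  counts <- ape::prop.clades(orig_r, boot,
                             rooted = !is.null(outgroup))
  counts[is.na(counts)] <- n_reps  # trivial/root partitions
  orig_r$node.label <- round(100 * counts / n_reps)
  orig_r
}

#' Moment estimator of a split time from net divergence
#'
#' Subtracts the within-population diversity (mean of the two
#' heterozygosities, an estimate of the ancestral coalescent
#' contribution) from the between-population divergence, and converts the
#' remainder to years: `T = (dxy - (het_a + het_b)/2) / (2 mu) *
#' gen_time`. Negative estimates are clamped to zero and flagged.
#'
#' @param dxy Mean pairwise divergence between the populations.
#' @param het_a,het_b Genome-wide heterozygosity of a sample from each
#'   population.
#' @param mu Mutation rate per site per generation (> 0).
#' @param gen_time Years per generation.
#' @return A list with `years` and `clamped`.
#' @examples
#' split_time_moment_estimator(5e-4, 4e-4, 4e-4, 1e-8, 3)  # 15,000 years
#' @export
split_time_moment_estimator <- function(dxy, het_a, het_b, mu,
                                        gen_time = 3) {
  if (dxy < 0) stop("'dxy' must be >= 0", call. = FALSE)
  if (mu <= 0) stop("'mu' must be > 0", call. = FALSE)
  t_gen <- (dxy - (het_a + het_b) / 2) / (2 * mu)
  clamped <- t_gen < 0
  list(years = max(t_gen, 0) * gen_time, clamped = clamped)
}

#' Read or write a distance matrix in PHYLIP square format
#'
#' @param x A `divergence_matrix` or symmetric matrix with dimnames.
#' @param path Output (or input) file path.
#' @return `write_phylip()` returns `path` invisibly; `read_phylip()`
#'   returns a named symmetric matrix.
#' @export
write_phylip <- function(x, path) {
  d <- if (inherits(x, "divergence_matrix")) x$d else as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.8f", d[i, ]), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  d <- matrix(0, n, n)
  nm <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    nm[i] <- parts[1L]
    d[i, ] <- as.numeric(parts[-1L])
  }
  dimnames(d) <- list(nm, nm)
  d
}
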
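#' Construct a set of unlinked biallelic loci
#'
#' The central data container: variant sites from many unlinked loci, one
#' diploid genotype per sample per site, coded as the number of derived
#' alleles (0, 1 or 2; `NA` for missing). All sites within a locus share
#' one genealogy; loci are independent. Monomorphic called sites are not
#' stored; they are accounted for through the per-locus called-site
#' counts.
#'
#' @param geno Integer matrix, variant sites x samples, entries in
#'   `{0, 1, 2, NA}` (derived-allele dosage).
#' @param site Data.frame with columns `locus` (1-based locus index) and
#'   `pos` (0-based position within the locus).
#' @param n_loci Number of loci in the set (variant-free loci included).
#' @param locus_length Locus length in bp.
#' @param called Optional matrix (`n_loci` x samples) of called-site
#'   counts per locus; defaults to fully called loci.
#' @return An object of class `locus_set`.
#' @export
locus_set <- function(geno, site, n_loci, locus_length, called = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) stop("'geno' needs sample column names",
                                    call. = FALSE)
  stopifnot(is.data.frame(site), all(c("locus", "pos") %in% names(site)),
            nrow(site) == nrow(geno))
  if (any(geno < 0 | geno > 2, na.rm = TRUE))
    stop("genotypes must be derived-allele dosages in {0, 1, 2}",
         call. = FALSE)
  if (nrow(site) && (any(site$locus < 1 | site$locus > n_loci) ||
                     any(site$pos < 0 | site$pos >= locus_length)))
    stop("site coordinates outside locus bounds", call. = FALSE)
  if (is.null(called)) {
    called <- matrix(as.numeric(locus_length), nrow = n_loci,
                     ncol = ncol(geno), dimnames = list(NULL, colnames(geno)))
  }
  structure(list(geno = geno,
                 site = data.frame(locus = as.integer(site$locus),
                                   pos = as.integer(site$pos)),
                 samples = colnames(geno),
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 called = called),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf(
    "Locus set: %d loci x %d bp, %d samples, %d variant sites\n",
    x$n_loci, x$locus_length, length(x$samples), nrow(x$geno)))
  cat("  samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.locus_set` <- function(x, loci) {
  loci <- sort(unique(as.integer(loci)))
  keep <- x$site$locus %in% loci
  new_idx <- match(x$site$locus[keep], loci)
  locus_set(x$geno[keep, , drop = FALSE],
            data.frame(locus = new_idx, pos = x$site$pos[keep]),
            n_loci = length(loci), locus_length = x$locus_length,
            called = x$called[loci, , drop = FALSE])
}

# total called sites per sample
called_sites <- function(x) colSums(x$called)

# genotype columns for a subset of samples, with checks
sample_geno <- function(x, samples) {
  miss <- setdiff(samples, x$samples)
  if (length(miss))
    stop(sprintf("sample(s) not in locus set: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  x$geno[, samples, drop = FALSE]
}
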
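#' Write a locus set as a minimal VCF
#'
#' One pseudo-contig per locus (`locus_1`, `locus_2`, ...), 1-based VCF
#' positions (internal positions are 0-based), REF = A for the ancestral
#' allele and ALT = T for the derived allele, diploid GT fields. The
#' ancestral allele is recorded in the INFO field (`AA=A`).
#'
#' @param data A [locus_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(data, path) {
  stopifnot(inherits(data, "locus_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=canidemog",
    sprintf("##contig=<ID=locus_%d,length=%d>", seq_len(data$n_loci),
            data$locus_length),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", data$samples), collapse = "\t")), con)
  if (nrow(data$geno)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[data$geno + 1L],
                 nrow = nrow(data$geno))
    gt[is.na(data$geno)] <- "./."
    lines <- paste(
      sprintf("locus_%d", data$site$locus), data$site$pos + 1L, ".",
      "A", "T", ".", "PASS", "AA=A", "GT",
      apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Reads biallelic SNVs from a VCF (via the vcfR parser). Multi-allelic
#' and indel records are skipped and counted. 1-based VCF positions are
#' converted to the 0-based internal convention; missing genotypes are
#' preserved as `NA`. Contigs are treated as loci in order of first
#' appearance; genotype dosages count ALT alleles, so for files written
#' by [write_vcf()] the round trip is exact (ALT = derived).
#'
#' @param path VCF file path.
#' @param locus_length Locus length to assume when the header does not
#'   declare contig lengths.
#' @return A [locus_set()]; the number of skipped records is attached as
#'   attribute `skipped`.
#' @export
read_vcf <- function(path, locus_length = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    warning("empty VCF: no variant records")
    samples <- colnames(v@gt)[-1L]
    if (is.null(samples)) samples <- "sample"
    geno <- matrix(integer(0), 0, length(samples),
                   dimnames = list(NULL, samples))
    return(locus_set(geno, data.frame(locus = integer(0),
                                      pos = integer(0)),
                     n_loci = 1L,
                     locus_length = if (is.null(locus_length)) 1000L
                     else locus_length))
  }
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  skipped <- sum(!snv)
  gt <- vcfR::extract.gt(v)[snv, , drop = FALSE]
  fix <- fix[snv, , drop = FALSE]
  contigs <- unique(fix$CHROM)
  hdr_len <- grep("^##contig", v@meta, value = TRUE)
  if (is.null(locus_length)) {
    len <- regmatches(hdr_len, regexpr("length=\\d+", hdr_len))
    locus_length <- if (length(len))
      max(as.integer(sub("length=", "", len))) else
        max(as.integer(fix$POS))
  }
  dose <- function(x) {
    a <- substr(x, 1L, 1L); b <- substr(x, 3L, 3L)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
  }
  geno <- apply(gt, 2L, dose)
  geno <- matrix(as.integer(geno), nrow = nrow(fix),
                 dimnames = list(NULL, colnames(gt)))
  site <- data.frame(locus = match(fix$CHROM, contigs),
                     pos = as.integer(fix$POS) - 1L)
  ls <- locus_set(geno, site, n_loci = length(contigs),
                  locus_length = locus_length)
  attr(ls, "skipped") <- skipped
  ls
}

#' Read or write a locus set as a plain site table
#'
#' Tab-separated text: columns `locus`, `pos` (0-based) and one
#' derived-allele dosage column per sample; a `# n_loci=.. locus_length=..`
#' header line carries the set dimensions.
#'
#' @param data A [locus_set()].
#' @param path File path.
#' @return `write_site_table()` returns `path` invisibly;
#'   `read_site_table()` returns a [locus_set()].
#' @export
write_site_table <- function(data, path) {
  stopifnot(inherits(data, "locus_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_loci=%d locus_length=%d", data$n_loci,
                     data$locus_length), con)
  df <- cbind(data$site, as.data.frame(data$geno))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  n_loci <- as.integer(sub(".*n_loci=(\\d+).*", "\\1", hdr))
  locus_length <- as.integer(sub(".*locus_length=(\\d+).*", "\\1", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          check.names = FALSE)
  geno <- as.matrix(df[, -(1:2), drop = FALSE])
  locus_set(geno, df[, 1:2], n_loci = n_loci,
            locus_length = locus_length)
}

#' Write a heterozygosity track or depth windows as BED
#'
#' 0-based half-open intervals with the track's value columns, suitable
#' for genome browsers and interval tools.
#'
#' @param x A `het_track`, or the `windows` data.frame of a
#'   `depth_track`.
#' @param path Output path.
#' @param chrom Chromosome/contig name for the intervals.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, chrom = "genome") {
  df <- as.data.frame(x)
  stopifnot(all(c("start", "end") %in% names(df)))
  out <- cbind(chrom = chrom, df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED-graph style depth file
#'
#' Expects tab-separated `chrom`, `start`, `end`, `depth` (one row per
#' base or per window) with or without a header, 0-based half-open. If
#' per-base rows are given, returns a `depth_track`-compatible list;
#' the control mean must be supplied separately or via control intervals.
#'
#' @param path Input path.
#' @param control_mean Mean depth of known-diploid regions (for
#'   normalization in [copy_number_from_depth()]).
#' @return A list with `contig`, `depth` and `control`.
#' @export
read_depth_bedgraph <- function(path, control_mean = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("start", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t")
  names(df)[1:4] <- c("chrom", "start", "end", "depth")
  n <- max(df$end)
  depth <- numeric(n)
  for (i in seq_len(nrow(df)))
    depth[(df$start[i] + 1L):df$end[i]] <- df$depth[i]
  list(contig = df$chrom[1L], depth = depth,
       control = list(mean = control_mean))
}

#' Write a quartet results table as delimited text
#'
#' One row per quartet with pattern counts, conditional frequencies and,
#' when present, D, Z and the significance flag.
#'
#' @param table Data.frame from [pattern_frequency_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pattern_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tree with bootstrap supports as Newick
#'
#' @param tree An [ape::phylo] tree (internal node labels carry percent
#'   supports when produced by [window_bootstrap_support()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
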
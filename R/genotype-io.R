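#' Read a haploid genotype matrix from tab-separated text
#'
#' Dialect: tab-separated, UTF-8, LF line endings. The first header cell is
#' literally `site` and the remaining header cells are strain names. Each data
#' row starts with a `CHROM:POS` key followed by one single-character
#' nucleotide state per strain, with `.` denoting a missing call. This mirrors
#' the sites-by-strains layout of published SNP inheritance tables while
#' pinning down the delimiters they leave unstated.
#'
#' Internally each site is recoded to `{0, 1}` with allele 0 the
#' lexicographically smaller of the two observed states, so minor/major
#' orientation is always recomputed from counts and never inherited from the
#' file.
#'
#' @param path file to read.
#' @param lenient if `TRUE`, cells that are not a single nucleotide character
#'   (or `.`) are demoted to missing; if `FALSE` (default) they are an error.
#'   More than two distinct valid states at a site is always an error.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty genotype file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (header[[1]] != "site")
    stop("genotype TSV must start with a 'site' header cell, got '",
         header[[1]], "'")
  strains <- header[-1]
  ncell <- length(header)
  m <- length(lines) - 1L

  chrom <- character(m); pos <- integer(m)
  allele0 <- character(m); allele1 <- character(m)
  calls <- matrix(NA_integer_, nrow = m, ncol = length(strains))

  for (i in seq_len(m)) {
    fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != ncell)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, ncell, length(fields)))
    key <- strsplit(fields[[1]], ":", fixed = TRUE)[[1]]
    if (length(key) != 2L || is.na(suppressWarnings(as.integer(key[[2]]))))
      stop(sprintf("line %d: malformed site key '%s' (want CHROM:POS)",
                   i + 1L, fields[[1]]))
    chrom[i] <- key[[1]]
    pos[i] <- as.integer(key[[2]])
    cells <- fields[-1]
    valid <- cells %in% c("A", "C", "G", "T", ".")
    if (!all(valid)) {
      if (!lenient)
        stop(sprintf("line %d: malformed call(s) '%s' (use --lenient to mask)",
                     i + 1L, paste(unique(cells[!valid]), collapse = "','")))
      cells[!valid] <- "."
    }
    states <- sort(unique(cells[cells != "."]))
    if (length(states) > 2L)
      stop(sprintf("site %s:%d has %d observed allele states (%s); only biallelic sites are supported",
                   chrom[i], pos[i], length(states),
                   paste(states, collapse = ",")))
    ab <- fill_allele_pair(states)
    allele0[i] <- ab[[1]]; allele1[i] <- ab[[2]]
    calls[i, ] <- ifelse(cells == ".", NA_integer_,
                         ifelse(cells == ab[[1]], 0L, 1L))
  }

  genotype_matrix(
    sites = data.frame(chrom = chrom, pos = pos,
                       allele0 = allele0, allele1 = allele1),
    strains = strains, calls = calls
  )
}

# A site needs two distinct allele labels even when only one (or zero) state
# is observed; pad deterministically so round-trips stay stable.
fill_allele_pair <- function(states) {
  nucs <- c("A", "C", "G", "T")
  while (length(states) < 2L) states <- c(states, setdiff(nucs, states)[[1]])
  sort(states)
}

#' Write a genotype matrix in the TSV dialect of [read_genotype_tsv()]
#'
#' Exact inverse of the reader on valid matrices: writing then reading
#' reproduces the object field by field, including missing cells.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  validate_genotype_matrix(gm)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("site", gm$strains), collapse = "\t"), con, sep = "\n")
  if (nrow(gm$sites)) {
    chars <- matrix(".", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
    chars[which(gm$calls == 0L)] <- gm$sites$allele0[row(gm$calls)[which(gm$calls == 0L)]]
    chars[which(gm$calls == 1L)] <- gm$sites$allele1[row(gm$calls)[which(gm$calls == 1L)]]
    keys <- paste(gm$sites$chrom, gm$sites$pos, sep = ":")
    rows <- apply(cbind(keys, chars), 1L, paste, collapse = "\t")
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

#' Read a haploid VCF into a genotype matrix
#'
#' Interoperability convenience for variant matrices stored as VCF 4.x.
#' Only haploid single-allele GT fields are accepted (`0`, `1`, `.`);
#' encountering a diploid genotype is an error because the whole pipeline
#' treats strains as phased haplotypes. Records that are not biallelic
#' single-nucleotide variants are skipped and counted.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [genotype_matrix()] with attribute `skipped` giving the number
#'   of non-biallelic-SNV records dropped.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_genotype_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  if (any(grepl("[/|]", gt)))
    stop("diploid GT encountered; this pipeline is haploid-only")
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    ref %in% c("A", "C", "G", "T") & alt1 %in% c("A", "C", "G", "T") &
    ref != alt1
  skipped <- sum(!keep)
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  gt <- gt[keep, , drop = FALSE]
  ref <- ref[keep]; alt1 <- alt1[keep]

  raw <- suppressWarnings(matrix(as.integer(gt), nrow = nrow(gt)))
  if (length(raw) && any(!is.na(raw) & raw > 1L))
    stop("GT codes > 1 in a biallelic record; malformed VCF")
  # allele 0 is the lexicographically smaller state, so flip where REF > ALT
  flip <- ref > alt1
  if (any(flip)) raw[flip, ] <- 1L - raw[flip, , drop = FALSE]
  a0 <- pmin(ref, alt1); a1 <- pmax(ref, alt1)

  gm <- genotype_matrix(
    sites = data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                       pos = GenomicRanges::start(rr),
                       allele0 = a0, allele1 = a1),
    strains = colnames(gt),
    calls = raw
  )
  attr(gm, "skipped") <- skipped
  gm
}
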
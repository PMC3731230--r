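#' Construct a haploid genotype matrix
#'
#' The central genotype container: biallelic calls for `S` haploid strains at
#' `M` sites, plus per-site metadata. Calls are coded per site as `0L` (the
#' lexicographically smaller allele state), `1L` (the larger), or `NA`
#' (missing). Minor/major orientation is never stored; it is recomputed from
#' counts wherever it is needed, so file column order carries no meaning.
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (1-based integer), `allele0`, `allele1` (distinct single-character
#'   states, `allele0 < allele1`).
#' @param strains character vector of unique strain identifiers.
#' @param calls integer matrix, `nrow(sites)` x `length(strains)`, values in
#'   `{0L, 1L, NA}`.
#' @param chrom_levels optional ordered chromosome labels. If omitted,
#'   Roman numerals I..VII are used when all labels fall in that set,
#'   otherwise order of first appearance.
#' @param validate check invariants (set `FALSE` only on trusted internals).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, strains, calls, chrom_levels = NULL,
                            validate = TRUE) {
  sites <- as.data.frame(sites)
  strains <- as.character(strains)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(NULL, strains)
  if (is.null(chrom_levels)) chrom_levels <- infer_chrom_levels(sites$chrom)
  gm <- structure(
    list(sites = sites, strains = strains, calls = calls,
         chrom_levels = chrom_levels),
    class = "genotype_matrix"
  )
  gm <- sort_sites(gm)
  if (validate) validate_genotype_matrix(gm)
  gm
}

ROMAN7 <- c("I", "II", "III", "IV", "V", "VI", "VII")

infer_chrom_levels <- function(chrom) {
  u <- unique(as.character(chrom))
  if (length(u) && all(u %in% ROMAN7)) ROMAN7[ROMAN7 %in% u] else u
}

sort_sites <- function(gm) {
  ord <- order(match(gm$sites$chrom, gm$chrom_levels), gm$sites$pos)
  if (!identical(ord, seq_len(nrow(gm$sites)))) {
    gm$sites <- gm$sites[ord, , drop = FALSE]
    rownames(gm$sites) <- NULL
    gm$calls <- gm$calls[ord, , drop = FALSE]
  }
  gm
}

validate_genotype_matrix <- function(gm) {
  s <- gm$sites
  needed <- c("chrom", "pos", "allele0", "allele1")
  if (!all(needed %in% names(s)))
    stop("sites must have columns ", paste(needed, collapse = ", "))
  if (nrow(s) != nrow(gm$calls) || length(gm$strains) != ncol(gm$calls))
    stop("calls dimensions do not match sites x strains")
  if (anyDuplicated(gm$strains))
    stop("duplicate strain identifiers: ",
         paste(unique(gm$strains[duplicated(gm$strains)]), collapse = ", "))
  if (nrow(s)) {
    if (any(s$pos < 1)) stop("site positions must be >= 1")
    key <- paste(s$chrom, s$pos, sep = ":")
    if (anyDuplicated(key))
      stop("duplicate (chromosome, position): ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    if (any(s$allele0 == s$allele1))
      stop("allele states must differ at every site")
  }
  bad <- gm$calls[!is.na(gm$calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("calls must be 0, 1 or NA")
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d strains\n",
              nrow(x$sites), length(x$strains)))
  if (nrow(x$sites)) {
    tab <- table(factor(x$sites$chrom, levels = x$chrom_levels))
    cat("  sites per chromosome:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat(sprintf("  missing calls: %d (%.2f%%)\n", sum(is.na(x$calls)),
                100 * mean(is.na(x$calls))))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$strains))

#' Number of sites / strains
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_strains <- function(gm) length(gm$strains)

#' Subset a genotype matrix by site index and/or strain
#'
#' @param gm a `genotype_matrix`.
#' @param sites integer or logical index into sites.
#' @param strains character, integer or logical index into strains.
#' @return a `genotype_matrix`.
#' @export
subset_gm <- function(gm, sites = NULL, strains = NULL) {
  if (!is.null(sites)) {
    gm$sites <- gm$sites[sites, , drop = FALSE]
    rownames(gm$sites) <- NULL
    gm$calls <- gm$calls[sites, , drop = FALSE]
  }
  if (!is.null(strains)) {
    if (is.character(strains)) {
      miss <- setdiff(strains, gm$strains)
      if (length(miss))
        stop("unknown strains: ", paste(miss, collapse = ", "))
      strains <- match(strains, gm$strains)
    }
    gm$strains <- gm$strains[strains]
    gm$calls <- gm$calls[, strains, drop = FALSE]
  }
  gm
}

#' Compare two genotype matrices field by field
#' @param a,b `genotype_matrix` objects.
#' @return `TRUE` or `FALSE`.
#' @export
identical_gm <- function(a, b) {
  isTRUE(all.equal(a$sites, b$sites, check.attributes = FALSE)) &&
    identical(a$strains, b$strains) &&
    identical(unname(a$calls), unname(b$calls))
}
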
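# Orientation and count machinery shared by the real-data scan and the
# permutation null. For a fixed site the minor/major orientation is
# recomputed from the non-missing calls among the *tested* strains; ties in
# allele counts break toward allele 0 as "minor". Orientation does not
# depend on the class labels, so it is permutation-invariant and computed
# once per site.
site_count_parts <- function(gm, strains) {
  x <- gm$calls[, strains, drop = FALSE]
  nonmiss <- !is.na(x)
  ones <- x == 1L & nonmiss
  n1 <- rowSums(ones)
  n_obs <- rowSums(nonmiss)
  minor_is_1 <- n1 < n_obs - n1            # tie -> allele 0 is minor
  minor_mat <- ones
  if (any(!minor_is_1)) {
    flip <- which(!minor_is_1)
    minor_mat[flip, ] <- (x[flip, , drop = FALSE] == 0L) &
      nonmiss[flip, , drop = FALSE]
  }
  list(minor_mat = minor_mat * 1, nonmiss = nonmiss * 1,
       n_minor = pmin(n1, n_obs - n1), n_obs = n_obs,
       minor_is_1 = minor_is_1)
}

tested_strains <- function(gm, bp) {
  strains <- names(bp$classes)
  missing <- setdiff(strains, gm$strains)
  if (length(missing) == length(strains))
    stop("no overlap between phenotyped and genotyped strains")
  if (length(missing))
    warning("dropping ", length(missing),
            " phenotyped strain(s) absent from the genotype matrix: ",
            paste(missing, collapse = ", "))
  intersect(strains, gm$strains)
}

#' Build the 2x2 allele-by-class table for one site
#'
#' Counts the phenotyped strains by (communication class, allele) at one
#' site. Strains with a missing call at the site are excluded. Cells:
#' `a` low/minor, `b` low/major, `c` high/minor, `d` high/major.
#'
#' @param gm a [genotype_matrix()].
#' @param site_index 1-based site index.
#' @param bp a [binarize()] result (strains must be a subset of `gm`'s).
#' @return a `contingency_table`: list `a`, `b`, `c`, `d`, `degenerate`
#'   (TRUE when the site is monomorphic among the tested strains),
#'   `minor_is_1`.
#' @export
build_table <- function(gm, site_index, bp) {
  if (site_index < 1L || site_index > n_sites(gm))
    stop("site_index out of range")
  strains <- tested_strains(gm, bp)
  parts <- site_count_parts(subset_gm(gm, sites = site_index), strains)
  low <- as.numeric(bp$classes[strains] == "low")
  a <- as.integer(parts$minor_mat %*% low)
  n_low_obs <- as.integer(parts$nonmiss %*% low)
  tab <- list(a = a, b = n_low_obs - a, c = parts$n_minor - a,
              d = (parts$n_obs - parts$n_minor) - (n_low_obs - a),
              degenerate = parts$n_minor == 0L,
              minor_is_1 = parts$minor_is_1)
  tab <- lapply(tab, unname)
  structure(tab, class = "contingency_table")
}

#' Per-SNP Fisher exact association scan
#'
#' Tests every site of `gm` for co-inheritance of its minor allele with the
#' binary communication class, in site order. Sites that are monomorphic
#' among the tested strains (e.g. after missing-call exclusion) are retained
#' with `p = 1` and flagged, so site counts reconcile across pipeline
#' stages. p-values are memoized across identical tables (see
#' [fisher_p()]).
#'
#' @param gm a [genotype_matrix()], normally already biallelic- and
#'   MAF-filtered.
#' @param bp a [binarize()] result.
#' @param sided `"two"` (default) or `"one"`; see [fisher_p()].
#' @return data.frame with one row per site: `chrom`, `pos`, `a`, `b`, `c`,
#'   `d`, `p`, `neglog10_p`, `degenerate`.
#' @export
assoc_scan <- function(gm, bp, sided = c("two", "one")) {
  sided <- match.arg(sided)
  strains <- tested_strains(gm, bp)
  parts <- site_count_parts(gm, strains)
  low <- as.numeric(bp$classes[strains] == "low")
  a <- as.integer(parts$minor_mat %*% low)
  n_low_obs <- as.integer(parts$nonmiss %*% low)
  b <- n_low_obs - a
  cc <- parts$n_minor - a
  d <- (parts$n_obs - parts$n_minor) - b
  p <- fisher_p_vec(cbind(a, b, cc, d), sided)
  p[parts$n_minor == 0L] <- 1
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
             a = a, b = b, c = cc, d = d, p = p,
             neglog10_p = -log10(p),
             degenerate = parts$n_minor == 0L)
}
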
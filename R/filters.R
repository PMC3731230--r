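#' Minor-allele-frequency filter settings
#'
#' @param min_minor_fraction strict lower bound on the minor allele fraction,
#'   in `(0, 0.5]`. The study's operating value is 0.25 ("minor allele
#'   present in more than 25% of strains"), and the bound is strict: a site
#'   at exactly the threshold is removed.
#' @param missing_policy how missing calls enter the denominator:
#'   `"observed"` (default) divides by the non-missing strain count at the
#'   site; `"total"` divides by the full strain count.
#' @return a `maf_filter_spec` list.
#' @export
maf_filter_spec <- function(min_minor_fraction = 0.25,
                            missing_policy = c("observed", "total")) {
  if (!is.numeric(min_minor_fraction) || length(min_minor_fraction) != 1L ||
      is.na(min_minor_fraction) ||
      min_minor_fraction <= 0 || min_minor_fraction > 0.5)
    stop("min_minor_fraction must lie in (0, 0.5]")
  structure(list(min_minor_fraction = min_minor_fraction,
                 missing_policy = match.arg(missing_policy)),
            class = "maf_filter_spec")
}

allele1_counts <- function(gm) {
  nm <- !is.na(gm$calls)
  ones <- gm$calls == 1L & nm
  list(n1 = rowSums(ones), n_obs = rowSums(nm))
}

#' Keep only sites that are biallelic in-sample
#'
#' A retained site has both allele states observed in at least one
#' non-missing strain; monomorphic and all-missing sites are dropped. The
#' strain set is unchanged. Matches the upstream variant filter "retain only
#' bi-allelic sites" applied after per-strain calls are assembled.
#'
#' @param gm a [genotype_matrix()].
#' @return a filtered `genotype_matrix` (possibly with zero sites).
#' @export
filter_biallelic <- function(gm) {
  ct <- allele1_counts(gm)
  subset_gm(gm, sites = ct$n1 > 0L & ct$n1 < ct$n_obs)
}

#' Filter sites by minor allele frequency
#'
#' Retains sites where the fraction of strains carrying the rarer allele
#' strictly exceeds `spec$min_minor_fraction`. The denominator follows
#' `spec$missing_policy`. Site order is preserved. With the default 0.25
#' this reproduces the "high-frequency SNP" set used for association.
#'
#' @param gm a [genotype_matrix()], normally already biallelic-filtered.
#' @param spec a [maf_filter_spec()].
#' @return a filtered `genotype_matrix`.
#' @export
filter_maf <- function(gm, spec = maf_filter_spec()) {
  if (!inherits(spec, "maf_filter_spec")) stop("spec must be a maf_filter_spec")
  ct <- allele1_counts(gm)
  minor <- pmin(ct$n1, ct$n_obs - ct$n1)
  denom <- if (spec$missing_policy == "observed") ct$n_obs
           else rep(n_strains(gm), n_sites(gm))
  keep <- denom > 0L & minor / denom > spec$min_minor_fraction
  subset_gm(gm, sites = keep)
}

#' Extract the sites of a genomic interval
#'
#' 1-based closed interval `[start, end]` on one chromosome, matching the
#' coordinate convention of the site metadata.
#'
#' @param gm a [genotype_matrix()].
#' @param chromosome chromosome label (must be present in `gm`).
#' @param start,end interval bounds, `start <= end`.
#' @return the sub-matrix of sites in the interval; strains unchanged.
#' @export
region_query <- function(gm, chromosome, start, end) {
  if (!(chromosome %in% gm$chrom_levels))
    stop("unknown chromosome: ", chromosome)
  if (start > end) stop("start must be <= end")
  keep <- gm$sites$chrom == chromosome &
    gm$sites$pos >= start & gm$sites$pos <= end
  subset_gm(gm, sites = keep)
}
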
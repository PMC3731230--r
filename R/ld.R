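#' Pairwise linkage disequilibrium r-squared between two sites
#'
#' Haploid formulation: strains are phased haplotypes, so with allele
#' frequencies `p_i`, `p_j` and joint frequency `p_ij` over
#' pairwise-complete strains, `D = p_ij - p_i p_j` and
#' `r2 = D^2 / (p_i (1 - p_i) p_j (1 - p_j))`. Invariant under allele
#' relabeling at either site.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j 1-based site indices.
#' @return list with `r2` (`NA` when either site is monomorphic among
#'   pairwise-complete strains: undefined, not 0) and `n_used`, the number
#'   of strains with both calls present.
#' @export
r2_pair <- function(gm, i, j) {
  if (any(c(i, j) < 1L) || any(c(i, j) > n_sites(gm)))
    stop("site index out of range")
  xi <- gm$calls[i, ]; xj <- gm$calls[j, ]
  ok <- !is.na(xi) & !is.na(xj)
  n <- sum(ok)
  if (n == 0L) return(list(r2 = NA_real_, n_used = 0L))
  xi <- xi[ok]; xj <- xj[ok]
  # integer-count form of D^2 / (p_i q_i p_j q_j): exact, so duplicated
  # site vectors give r2 = 1 with no floating-point dust
  n1 <- sum(xi == 1L); n2 <- sum(xj == 1L)
  if (n1 %in% c(0L, n) || n2 %in% c(0L, n))
    return(list(r2 = NA_real_, n_used = n))
  n11 <- sum(xi == 1L & xj == 1L)
  n <- as.numeric(n); n1 <- as.numeric(n1); n2 <- as.numeric(n2)
  num <- (n * n11 - n1 * n2)^2
  den <- n1 * (n - n1) * n2 * (n - n2)
  list(r2 = num / den, n_used = as.integer(n))
}

#' All-pairs LD matrix for a region
#'
#' Computes `r2` for every pair of sites, typically on a [region_query()]
#' result already MAF-filtered, as the source of an LD heatmap around an
#' association peak.
#'
#' @param gm a [genotype_matrix()].
#' @return an `ld_matrix`: list with `sites` (ordered by position), `r2`
#'   (symmetric matrix, unit diagonal for polymorphic sites, `NA` for
#'   undefined pairs) and `n_used` (pairwise-complete strain counts).
#' @export
r2_matrix <- function(gm) {
  m <- n_sites(gm)
  r2 <- matrix(NA_real_, m, m)
  n_used <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      pr <- r2_pair(gm, i, j)
      r2[i, j] <- r2[j, i] <- pr$r2
      n_used[i, j] <- n_used[j, i] <- pr$n_used
    }
  }
  structure(list(sites = gm$sites, r2 = r2, n_used = n_used),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d sites; mean off-diagonal r2 %.3f\n",
              nrow(x$sites),
              mean(x$r2[upper.tri(x$r2)], na.rm = TRUE)))
  invisible(x)
}

#' Long-format export of an LD matrix
#'
#' One row per unordered site pair (`i < j`), heatmap-ready.
#'
#' @param ld an [r2_matrix()] result.
#' @param min_pair_n drop pairs supported by fewer pairwise-complete
#'   strains than this.
#' @return data.frame with `chrom`, `pos_i`, `pos_j`, `r2`, `n_used`.
#' @export
ld_long <- function(ld, min_pair_n = 0L) {
  m <- nrow(ld$sites)
  if (m < 2L)
    return(data.frame(chrom = character(), pos_i = integer(),
                      pos_j = integer(), r2 = numeric(),
                      n_used = integer()))
  idx <- which(upper.tri(ld$r2), arr.ind = TRUE)
  out <- data.frame(chrom = ld$sites$chrom[idx[, 1L]],
                    pos_i = ld$sites$pos[idx[, 1L]],
                    pos_j = ld$sites$pos[idx[, 2L]],
                    r2 = ld$r2[idx],
                    n_used = ld$n_used[idx])
  out[out$n_used >= min_pair_n, , drop = FALSE]
}
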
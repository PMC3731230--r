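# Memoization cache for fisher_p. Keys are "a,b,c,d,sided"; values exact
# p-values. hits/misses support the cache-efficiency contract: a genome scan
# (and especially a permutation workload) encounters few distinct tables, so
# cost must grow with distinct tables, not sites.
.fisher_cache <- new.env(parent = emptyenv())
.fisher_stats <- new.env(parent = emptyenv())
.fisher_stats$hits <- 0
.fisher_stats$misses <- 0

#' Reset the Fisher p-value memoization cache
#' @return invisibly, the previous cache size.
#' @export
fisher_cache_reset <- function() {
  n <- length(ls(.fisher_cache))
  rm(list = ls(.fisher_cache), envir = .fisher_cache)
  .fisher_stats$hits <- 0
  .fisher_stats$misses <- 0
  invisible(n)
}

#' Fisher cache statistics
#' @return list with `size`, `hits`, `misses`, `hit_rate`.
#' @export
fisher_cache_stats <- function() {
  h <- .fisher_stats$hits; m <- .fisher_stats$misses
  list(size = length(ls(.fisher_cache)), hits = h, misses = m,
       hit_rate = if (h + m > 0) h / (h + m) else NA_real_)
}

# Relative tolerance when comparing point probabilities to the observed
# table's probability in the two-sided rule; guards against floating-point
# misses on symmetric tables.
FISHER_REL_TOL <- 1e-7

fisher_p_raw <- function(a, b, c, d, sided) {
  # Condition on both margins: the low-class row total r1 = a + b and the
  # minor-allele column total m = a + c. X = a is hypergeometric.
  m <- a + c; n <- b + d; r1 <- a + b
  lo <- max(0L, r1 - n); hi <- min(r1, m)
  if (lo == hi) return(1)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, r1)
  if (sided == "one") {
    # enrichment of the minor allele in the low class: P(X >= a)
    sum(probs[x >= a])
  } else {
    p_obs <- probs[x == a]
    min(1, sum(probs[probs <= p_obs * (1 + FISHER_REL_TOL)]))
  }
}

#' Fisher's exact test for a 2x2 table, memoized
#'
#' Exact hypergeometric test with both margins fixed, as used to test
#' co-inheritance of a SNP allele with the binary communication class. The
#' table convention is `a` = low-class strains carrying the minor allele,
#' `b` = low-class/major, `c` = high-class/minor, `d` = high-class/major.
#'
#' Two-sided (default): the sum of probabilities of all tables with the same
#' margins whose point probability is no greater than the observed table's
#' (minimum-likelihood rule, relative tolerance `1e-7` on the comparison
#' to absorb floating-point ties). One-sided: the upper tail toward
#' enrichment of the minor allele in the low class.
#'
#' Results are memoized on `(a, b, c, d, sided)`; see
#' [fisher_cache_stats()].
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param sided `"two"` (default) or `"one"`.
#' @return exact p-value in `(0, 1]`.
#' @export
fisher_p <- function(a, b, c, d, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (anyNA(c(a, b, c, d)) || any(c(a, b, c, d) < 0))
    stop("table entries must be non-negative")
  key <- paste(a, b, c, d, sided, sep = ",")
  hit <- .fisher_cache[[key]]
  if (!is.null(hit)) {
    .fisher_stats$hits <- .fisher_stats$hits + 1
    return(hit)
  }
  .fisher_stats$misses <- .fisher_stats$misses + 1
  p <- fisher_p_raw(as.integer(a), as.integer(b), as.integer(c),
                    as.integer(d), sided)
  .fisher_cache[[key]] <- p
  p
}

# Vectorized memoized lookup for packed tables (a,b,c,d columns of a
# matrix). Computes each distinct table once per call and consults/updates
# the shared cache, counting one hit or miss per input row.
fisher_p_vec <- function(tab, sided = "two") {
  if (!nrow(tab)) return(numeric(0))
  key <- paste(tab[, 1L], tab[, 2L], tab[, 3L], tab[, 4L], sided, sep = ",")
  ukey <- unique(key)
  up <- vapply(ukey, function(k) {
    v <- .fisher_cache[[k]]
    if (is.null(v)) NA_real_ else v
  }, numeric(1), USE.NAMES = FALSE)
  new <- which(is.na(up))
  if (length(new)) {
    urows <- tab[match(ukey[new], key), , drop = FALSE]
    for (i in seq_along(new)) {
      p <- fisher_p_raw(urows[i, 1L], urows[i, 2L], urows[i, 3L],
                        urows[i, 4L], sided)
      .fisher_cache[[ukey[new[i]]]] <- p
      up[new[i]] <- p
    }
  }
  idx <- match(key, ukey)
  .fisher_stats$misses <- .fisher_stats$misses + length(new)
  .fisher_stats$hits <- .fisher_stats$hits + length(key) - length(new)
  up[idx]
}
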
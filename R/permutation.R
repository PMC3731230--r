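#' Describe a permutation-null plan
#'
#' @param n_permutations number of Monte-Carlo permutations (study default
#'   1000).
#' @param seed integer seed fixing the permutation sequence.
#' @param mode `"monte_carlo"` (default) or `"exhaustive"`. Exhaustive mode
#'   enumerates every distinct assignment of the low labels to strains and
#'   yields exact null expectations; it is only permitted when
#'   `choose(S, n_low) <= exhaustive_limit`.
#' @param exhaustive_limit cap on the number of distinct assignments.
#' @return a `permutation_plan` list.
#' @export
permutation_plan <- function(n_permutations = 1000, seed = 1,
                             mode = c("monte_carlo", "exhaustive"),
                             exhaustive_limit = 20000) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), mode = match.arg(mode),
                 exhaustive_limit = exhaustive_limit),
            class = "permutation_plan")
}

#' Shuffle phenotype classes among strains
#'
#' Builds the permutation null by shuffling the post-binarization class
#' vector among strains; class counts are preserved in every permutation
#' and strains are never re-binarized. In `monte_carlo` mode the sequence is
#' a reproducible function of `plan$seed`; in `exhaustive` mode every
#' distinct assignment of the low labels appears exactly once.
#'
#' @param bp a [binarize()] result.
#' @param plan a [permutation_plan()].
#' @return character matrix, strains x permutations, entries
#'   `"high"`/`"low"`, rownames the strain identifiers.
#' @export
permute_classes <- function(bp, plan = permutation_plan()) {
  lowmat <- permute_low_matrix(bp, plan)
  out <- ifelse(lowmat == 1, "low", "high")
  rownames(out) <- names(bp$classes)
  out
}

# 0/1 (low = 1) numeric matrix S x P; the workhorse representation.
permute_low_matrix <- function(bp, plan) {
  s <- length(bp$classes)
  low <- as.numeric(bp$classes == "low")
  n_low <- sum(low)
  if (plan$mode == "exhaustive") {
    n_assign <- choose(s, n_low)
    if (n_assign > plan$exhaustive_limit)
      stop(sprintf(
        "exhaustive mode needs %g assignments (> limit %g); use monte_carlo",
        n_assign, plan$exhaustive_limit))
    out <- matrix(0, nrow = s, ncol = n_assign)
    if (n_low > 0) {
      idx <- utils::combn(s, n_low)
      out[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n_low))] <- 1
    }
    out
  } else {
    with_seed(plan$seed, {
      vapply(seq_len(plan$n_permutations),
             function(i) low[sample.int(s)], numeric(s))
    })
  }
}

# Packed-table p-value lookup shared by the permutation workload: tables are
# packed into a single double (exact below 2^53), computed once per distinct
# table, and cached across calls.
.packed_cache <- new.env(parent = emptyenv())

packed_fisher <- function(a, b, cc, d, base, sided) {
  packed <- ((a * base + b) * base + cc) * base + d
  key <- paste0(sided, ":", base)
  env <- .packed_cache[[key]]
  if (is.null(env)) {
    env <- new.env(parent = emptyenv())
    .packed_cache[[key]] <- env
  }
  up <- unique(packed)
  uk <- format(up, scientific = FALSE, trim = TRUE)
  vals <- vapply(seq_along(up), function(i) {
    v <- env[[uk[i]]]
    if (!is.null(v)) return(v)
    q <- up[i]
    d_ <- q %% base; q <- q %/% base
    c_ <- q %% base; q <- q %/% base
    b_ <- q %% base; a_ <- q %/% base
    v <- fisher_p_raw(a_, b_, c_, d_, sided)
    env[[uk[i]]] <- v
    v
  }, numeric(1))
  vals[match(packed, up)]
}

#' p-values of the permutation null
#'
#' Repeats the association scan under every permuted class assignment.
#' Per-site minor/major orientation and margins are fixed across
#' permutations, so the whole null reduces to one matrix product plus a
#' memoized table lookup.
#'
#' @param gm a filtered [genotype_matrix()].
#' @param bp a [binarize()] result.
#' @param plan a [permutation_plan()].
#' @param sided `"two"` (default) or `"one"`.
#' @return numeric matrix, sites x permutations, of exact p-values.
#' @export
null_pvalues <- function(gm, bp, plan = permutation_plan(),
                         sided = c("two", "one")) {
  sided <- match.arg(sided)
  strains <- tested_strains(gm, bp)
  bp_t <- binary_phenotype(bp$classes[strains], bp$grand_mean, bp$grand_sd,
                           bp$sd_mode)
  parts <- site_count_parts(gm, strains)
  lowmat <- permute_low_matrix(bp_t, plan)
  a <- parts$minor_mat %*% lowmat            # M x P minor-in-low counts
  n_low_obs <- parts$nonmiss %*% lowmat
  b <- n_low_obs - a
  cc <- parts$n_minor - a
  d <- (parts$n_obs - parts$n_minor) - b
  base <- length(strains) + 1
  p <- packed_fisher(as.vector(a), as.vector(b), as.vector(cc),
                     as.vector(d), base, sided)
  p <- matrix(p, nrow = n_sites(gm))
  p[parts$n_minor == 0L, ] <- 1
  p
}

#' Expected hit count at a p-value threshold under the permutation null
#'
#' The mean, over permuted class assignments, of the number of sites whose
#' Fisher p-value is strictly below `p_thresh`. Exhaustive plans give the
#' exact null expectation.
#'
#' @inheritParams null_pvalues
#' @param p_thresh threshold(s); strict `p < p_thresh` counting.
#' @return non-negative real, one per threshold.
#' @export
expected_count <- function(gm, bp, plan = permutation_plan(), p_thresh,
                           sided = c("two", "one")) {
  np <- null_pvalues(gm, bp, plan, match.arg(sided))
  vapply(p_thresh, function(t) sum(np < t) / ncol(np), numeric(1))
}

#' Experiment-wise FDR at a threshold
#'
#' `fdr = expected_count / observed_count`, reported unclipped (it can
#' exceed 1 when the null expects more hits than were observed). When
#' nothing is observed the FDR is undefined and rendered as such, never as
#' 0. Percent rendering follows the reporting convention of the source
#' study: one decimal below 1%, integer percent otherwise.
#'
#' @param observed_count integer, real-data sites with `p < p_thresh`.
#' @param expected_count non-negative real, permutation-null mean.
#' @return list with `observed_count`, `expected_count`, `fdr` (`NA` when
#'   undefined), `fdr_percent` (string), `tp_fraction` (`NA` when
#'   undefined), `tp_percent`.
#' @export
fdr_estimate <- function(observed_count, expected_count) {
  if (observed_count < 0 || expected_count < 0)
    stop("counts must be non-negative")
  if (observed_count == 0) {
    return(list(observed_count = 0L, expected_count = expected_count,
                fdr = NA_real_, fdr_percent = "undefined",
                tp_fraction = NA_real_, tp_percent = "undefined"))
  }
  fdr <- expected_count / observed_count
  tp <- max(0, (observed_count - expected_count) / observed_count)
  list(observed_count = as.integer(observed_count),
       expected_count = expected_count,
       fdr = fdr, fdr_percent = render_percent(fdr),
       tp_fraction = tp, tp_percent = render_percent(tp))
}

#' True-positive fraction at a threshold
#'
#' `max(0, (observed - expected) / observed)`: the complement of the FDR,
#' floored at zero.
#'
#' @inheritParams fdr_estimate
#' @return proportion in `[0, 1]`.
#' @export
tp_fraction <- function(observed_count, expected_count) {
  if (observed_count <= 0) stop("tp_fraction requires observed_count > 0")
  if (expected_count < 0) stop("expected_count must be non-negative")
  max(0, (observed_count - expected_count) / observed_count)
}

#' Render a proportion as a percentage string
#'
#' One decimal place below 1%, integer percent otherwise.
#'
#' @param x proportion (0.78 renders as `"78%"`).
#' @return character.
#' @export
render_percent <- function(x) {
  pct <- 100 * x
  if (pct < 1) sprintf("%.1f%%", pct) else sprintf("%.0f%%", pct)
}

#' Summaries at a set of p-value thresholds
#'
#' For each threshold: observed real-data hit count, permutation-expected
#' count, FDR and true-positive fraction. The permutation null is computed
#' once and shared across thresholds.
#'
#' @inheritParams null_pvalues
#' @param thresholds numeric vector of p-value thresholds.
#' @param results optional precomputed [assoc_scan()] data.frame (saves the
#'   real-data scan).
#' @return data.frame with columns `p_thresh`, `observed_count`,
#'   `expected_count`, `fdr`, `fdr_percent`, `tp_fraction`, `tp_percent`.
#' @export
threshold_summary <- function(gm, bp, plan = permutation_plan(), thresholds,
                              sided = c("two", "one"), results = NULL) {
  sided <- match.arg(sided)
  if (is.null(results)) results <- assoc_scan(gm, bp, sided)
  np <- null_pvalues(gm, bp, plan, sided)
  rows <- lapply(thresholds, function(t) {
    obs <- sum(results$p < t)
    exp_ <- sum(np < t) / ncol(np)
    est <- fdr_estimate(obs, exp_)
    data.frame(p_thresh = t, observed_count = obs, expected_count = exp_,
               fdr = est$fdr, fdr_percent = est$fdr_percent,
               tp_fraction = est$tp_fraction, tp_percent = est$tp_percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Largest threshold with a bounded expected chance hit count
#'
#' Inverts the permutation null: returns the largest threshold on the grid
#' of distinct null p-values whose expected chance hit count does not
#' exceed `target_expected` (the "expect 0.1 SNP by chance" genome-wide
#' line is `target_expected = 0.1`).
#'
#' @inheritParams null_pvalues
#' @param target_expected non-negative real.
#' @return a p-value threshold (strict-`<` semantics downstream).
#' @export
threshold_for_expected <- function(gm, bp, plan = permutation_plan(),
                                   target_expected,
                                   sided = c("two", "one")) {
  if (target_expected < 0) stop("target_expected must be >= 0")
  np <- null_pvalues(gm, bp, plan, match.arg(sided))
  grid <- sort(unique(as.vector(np)))
  if (!length(grid)) stop("degenerate null: no p-values")
  allp <- sort(as.vector(np))
  # expected_count(t) = (# null p-values strictly < t) / n_perms
  exp_at <- findInterval(grid, allp, left.open = TRUE) / ncol(np)
  ok <- which(exp_at <= target_expected)
  if (!length(ok)) stop("no threshold meets the target expected count")
  grid[max(ok)]
}
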
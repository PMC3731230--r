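# Shared fixture builders. Everything is generated in code; no binary data.

# Random valid genotype matrix with both alleles observed at every site
# (so TSV round-trips are field-exact).
random_gm <- function(m = 20, s = 8, n_chrom = 3, missing_rate = 0.05,
                      seed = 1) {
  set.seed(seed)
  chroms <- c("I", "II", "III", "IV", "V", "VI", "VII")[seq_len(n_chrom)]
  chrom <- sort(factor(sample(chroms, m, replace = TRUE), levels = chroms))
  pos <- unlist(lapply(table(chrom), function(k) sort(sample.int(1e6, k))))
  pair <- t(vapply(seq_len(m),
                   function(i) sort(sample(c("A", "C", "G", "T"), 2)),
                   character(2)))
  calls <- matrix(rbinom(m * s, 1, 0.4), m, s)
  # guarantee both alleles observed per site
  calls[, 1] <- 0L
  calls[, 2] <- 1L
  if (missing_rate > 0 && s > 2) {
    mask <- matrix(runif(m * s) < missing_rate, m, s)
    mask[, 1:2] <- FALSE
    calls[mask] <- NA_integer_
  }
  genotype_matrix(
    sites = data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                       allele0 = pair[, 1], allele1 = pair[, 2]),
    strains = sprintf("S%02d", seq_len(s)),
    calls = calls)
}

# Tiny genotype matrix from explicit call rows (list of integer vectors).
gm_from_calls <- function(rows, strains = NULL, chrom = "I",
                          pos = NULL) {
  m <- length(rows)
  s <- length(rows[[1]])
  if (is.null(strains)) strains <- sprintf("S%d", seq_len(s))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  genotype_matrix(
    sites = data.frame(chrom = rep(chrom, m), pos = as.integer(pos),
                       allele0 = "A", allele1 = "G"),
    strains = strains,
    calls = do.call(rbind, rows))
}

# Phenotype table with one 50-pair measurement per strain hitting the
# given per-strain frequencies exactly.
pt_from_freqs <- function(freqs, total = 100L) {
  phenotype_table(data.frame(
    strain = names(freqs) %||% sprintf("S%d", seq_along(freqs)),
    replicate = 1L, timepoint = 1L,
    fused = as.integer(round(freqs * total)), total = total))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Fisher two-sided oracle from first principles: enumerate all
# tables with the observed margins, with point probabilities computed from
# binomial coefficients (independent of the dhyper-based implementation).
fisher_oracle <- function(a, b, c, d, sided = "two") {
  r1 <- a + b; m <- a + c; n <- b + d
  tot <- r1 + c + d
  xs <- max(0, r1 - n):min(r1, m)
  prob <- vapply(xs, function(x)
    choose(m, x) * choose(n, r1 - x) / choose(tot, r1), numeric(1))
  p_obs <- prob[xs == a]
  if (sided == "one") sum(prob[xs >= a])
  else min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}
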
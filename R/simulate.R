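#' Specify a synthetic haploid GWAS dataset
#'
#' The generator emulates the statistical structure of the wild-isolate
#' study the pipeline targets: ~24 haploid strains genotyped at
#' high-frequency biallelic SNPs spread over 7 chromosomes, sharply
#' decaying local LD, and fusion frequencies spanning roughly 40-90% with
#' binomial replicate noise around strain-level means.
#'
#' LD is produced by a first-order copying chain along each chromosome:
#' site `k+1` copies each strain's site-`k` allele with probability
#' `ld_rho`, else redraws it from the site's own allele frequency, giving
#' r-squared that decays geometrically with site lag.
#'
#' @param n_strains number of haploid strains (default 24, the phenotyped
#'   panel size of the study).
#' @param n_chromosomes number of chromosomes (default 7).
#' @param n_sites_per_chrom sites per chromosome (default 72, ~500 genome
#'   wide).
#' @param chrom_length chromosome length in bp; positions are drawn
#'   uniformly without replacement (default 5e6).
#' @param maf_range range of per-site allele-1 frequencies (default
#'   `c(0.26, 0.5)`, i.e. the ">25% minor allele" regime).
#' @param ld_rho per-adjacent-site copy probability in `[0, 1)` wrapping
#'   `1` for the degenerate all-identical chain (default 0.8).
#' @param causal_site optional 1-based site index carrying the phenotype
#'   effect (`NULL` = no causal site).
#' @param penetrance length-2 vector `c(major, minor)` of fusion
#'   probabilities by causal-allele class (default `c(0.89, 0.24)`: the
#'   wild-type ~89% fusion efficiency versus the 24% of the strongest
#'   validated mutant).
#' @param n_replicates replicate measurements per strain (default 3).
#' @param pairs_per_replicate germling pairs scored per replicate
#'   (default 50).
#' @param strain_effect_sd SD of a logit-scale strain-level random effect
#'   (default 0.4, spreading strain means over roughly 40-90% around the
#'   high-penetrance class).
#' @param missing_rate independent per-call missingness (default 0).
#' @param seed master seed; genotypes, phenotypes and masking draw from
#'   derived sub-streams so adding sites does not perturb phenotype draws.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_strains = 24, n_chromosomes = 7,
                     n_sites_per_chrom = 72, chrom_length = 5e6,
                     maf_range = c(0.26, 0.5), ld_rho = 0.8,
                     causal_site = NULL, penetrance = c(0.89, 0.24),
                     n_replicates = 3, pairs_per_replicate = 50,
                     strain_effect_sd = 0.4, missing_rate = 0, seed = 1) {
  stopifnot(n_strains >= 2, n_chromosomes >= 1, n_sites_per_chrom >= 1,
            pairs_per_replicate >= 1, n_replicates >= 1)
  if (any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (ld_rho < 0 || ld_rho > 1) stop("ld_rho must lie in [0, 1]")
  if (any(penetrance < 0) || any(penetrance > 1))
    stop("penetrance probabilities must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (strain_effect_sd < 0) stop("strain_effect_sd must be >= 0")
  structure(list(
    n_strains = as.integer(n_strains),
    n_chromosomes = as.integer(n_chromosomes),
    n_sites_per_chrom = as.integer(n_sites_per_chrom),
    chrom_length = chrom_length, maf_range = maf_range, ld_rho = ld_rho,
    causal_site = if (is.null(causal_site)) NULL else as.integer(causal_site),
    penetrance = penetrance, n_replicates = as.integer(n_replicates),
    pairs_per_replicate = as.integer(pairs_per_replicate),
    strain_effect_sd = strain_effect_sd, missing_rate = missing_rate,
    seed = as.integer(seed)), class = "sim_spec")
}

sim_chrom_labels <- function(n) {
  if (n <= 7L) ROMAN7[seq_len(n)] else paste0("chr", seq_len(n))
}

#' Generate a synthetic haploid genotype matrix
#'
#' See [sim_spec()] for the model. Returned calls are the masked matrix;
#' the truth object keeps the unmasked causal-site alleles.
#'
#' @param spec a [sim_spec()].
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (a
#'   `sim_truth` carrying the causal site identity, unmasked causal
#'   alleles, realized allele frequencies and the seed).
#' @export
gen_genotypes <- function(spec) {
  s <- spec$n_strains
  strains <- sprintf("LA%03d", seq_len(s))
  labels <- sim_chrom_labels(spec$n_chromosomes)
  nucs <- c("A", "C", "G", "T")
  per_chrom <- lapply(seq_len(spec$n_chromosomes), function(ci) {
    with_seed(derive_seed(spec$seed, 100 + ci), {
      m <- spec$n_sites_per_chrom
      pos <- sort(sample.int(spec$chrom_length, m))
      maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
      pair <- t(vapply(seq_len(m), function(i) sort(sample(nucs, 2L)),
                       character(2)))
      calls <- matrix(0L, nrow = m, ncol = s)
      calls[1L, ] <- stats::rbinom(s, 1L, maf[1L])
      for (k in seq_len(m - 1L) + 1L) {
        copy <- stats::runif(s) < spec$ld_rho
        fresh <- stats::rbinom(s, 1L, maf[k])
        calls[k, ] <- ifelse(copy, calls[k - 1L, ], fresh)
      }
      list(sites = data.frame(chrom = labels[ci], pos = pos,
                              allele0 = pair[, 1L], allele1 = pair[, 2L]),
           calls = calls)
    })
  })
  sites <- do.call(rbind, lapply(per_chrom, `[[`, "sites"))
  calls <- do.call(rbind, lapply(per_chrom, `[[`, "calls"))
  causal_alleles <- NULL
  if (!is.null(spec$causal_site)) {
    if (spec$causal_site < 1L || spec$causal_site > nrow(sites))
      stop("causal_site out of range")
    causal_alleles <- stats::setNames(calls[spec$causal_site, ], strains)
  }
  if (spec$missing_rate > 0) {
    with_seed(derive_seed(spec$seed, 300), {
      mask <- stats::runif(length(calls)) < spec$missing_rate
      calls[mask] <- NA_integer_
    })
  }
  gm <- genotype_matrix(sites, strains, calls, chrom_levels = labels)
  truth <- structure(list(
    causal_index = spec$causal_site,
    causal_chrom = if (is.null(spec$causal_site)) NULL
                   else sites$chrom[spec$causal_site],
    causal_pos = if (is.null(spec$causal_site)) NULL
                 else sites$pos[spec$causal_site],
    causal_alleles = causal_alleles,
    allele1_freq = rowMeans(gm$calls == 1L, na.rm = TRUE),
    strain_probs = NULL, seed = spec$seed), class = "sim_truth")
  list(gm = gm, truth = truth)
}

#' Generate replicate fusion-count phenotypes
#'
#' Each strain's true fusion probability is
#' `plogis(qlogis(penetrance[class]) + e)` with `e ~ N(0, strain_effect_sd)`
#' and class determined by the strain's (unmasked) allele at the causal
#' site, minor versus major by realized counts (tie toward allele 0).
#' Without a causal site every strain uses `penetrance[1]`. Each replicate
#' then draws `fused ~ Binomial(pairs_per_replicate, p_true)`.
#'
#' @param gm the [gen_genotypes()] matrix (strain order is taken from it).
#' @param truth the matching `sim_truth`.
#' @param spec the [sim_spec()].
#' @return list with `pt` (a [phenotype_table()]) and `truth` updated with
#'   `strain_probs`.
#' @export
gen_phenotypes <- function(gm, truth, spec) {
  strains <- gm$strains
  s <- length(strains)
  with_seed(derive_seed(spec$seed, 200), {
    eff <- stats::rnorm(s, 0, spec$strain_effect_sd)
    if (!is.null(truth$causal_index)) {
      calls <- truth$causal_alleles[strains]
      minor_allele <- if (sum(calls == 1L) < sum(calls == 0L)) 1L else 0L
      base <- ifelse(calls == minor_allele, spec$penetrance[2L],
                     spec$penetrance[1L])
    } else {
      base <- rep(spec$penetrance[1L], s)
    }
    p_true <- stats::plogis(stats::qlogis(pmin(pmax(base, 1e-9), 1 - 1e-9))
                            + eff)
    fused <- matrix(stats::rbinom(s * spec$n_replicates,
                                  spec$pairs_per_replicate,
                                  rep(p_true, each = spec$n_replicates)),
                    nrow = spec$n_replicates)
  })
  pt <- phenotype_table(data.frame(
    strain = rep(strains, each = spec$n_replicates),
    replicate = rep(seq_len(spec$n_replicates), times = s),
    timepoint = 1L,
    fused = as.vector(fused),
    total = spec$pairs_per_replicate))
  truth$strain_probs <- stats::setNames(p_true, strains)
  list(pt = pt, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Composition of [gen_genotypes()] and [gen_phenotypes()] under one master
#' seed. Identical specs give byte-identical outputs.
#'
#' @param spec a [sim_spec()].
#' @return list with `gm`, `pt`, `truth`.
#' @export
gen_dataset <- function(spec) {
  g <- gen_genotypes(spec)
  p <- gen_phenotypes(g$gm, g$truth, spec)
  list(gm = g$gm, pt = p$pt, truth = p$truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits `genotypes.tsv`, `phenotypes.csv` and `truth.json` under `dir`.
#'
#' @param ds a [gen_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotype_tsv(ds$gm, file.path(dir, "genotypes.tsv"))
  write_phenotype_csv(ds$pt, file.path(dir, "phenotypes.csv"))
  tr <- ds$truth
  tr$causal_alleles <- as.list(tr$causal_alleles)
  tr$strain_probs <- as.list(tr$strain_probs)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
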
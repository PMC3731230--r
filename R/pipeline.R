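#' Assemble a pipeline run configuration
#'
#' @param genotype_tsv,phenotype_csv input paths.
#' @param out_dir output directory.
#' @param min_maf,missing_policy see [maf_filter_spec()].
#' @param sd_mode see [binarize()].
#' @param sided see [fisher_p()].
#' @param n_permutations,perm_seed,perm_mode see [permutation_plan()].
#' @param thresholds p-value thresholds for the summary table.
#' @param target_expected expected-chance-hit targets to invert into
#'   thresholds (the Manhattan significance line uses the first).
#' @param ld_regions character vector of `CHROM:START-END` regions for LD
#'   profiling.
#' @param lenient lenient genotype parsing.
#' @return a `run_config` list.
#' @export
run_config <- function(genotype_tsv, phenotype_csv, out_dir,
                       min_maf = 0.25, missing_policy = "observed",
                       sd_mode = "sample", sided = "two",
                       n_permutations = 1000, perm_seed = 1,
                       perm_mode = "monte_carlo",
                       thresholds = c(5.6e-6, 0.015),
                       target_expected = 0.1,
                       ld_regions = character(), lenient = FALSE) {
  structure(list(genotype_tsv = genotype_tsv, phenotype_csv = phenotype_csv,
                 out_dir = out_dir, min_maf = min_maf,
                 missing_policy = missing_policy, sd_mode = sd_mode,
                 sided = sided, n_permutations = n_permutations,
                 perm_seed = perm_seed, perm_mode = perm_mode,
                 thresholds = thresholds, target_expected = target_expected,
                 ld_regions = ld_regions, lenient = lenient),
            class = "run_config")
}

parse_region <- function(txt) {
  m <- regmatches(txt, regexec("^([^:]+):([0-9]+)-([0-9]+)$", txt))[[1]]
  if (length(m) != 4L) stop("malformed region '", txt, "' (want CHROM:START-END)")
  list(chrom = m[[2]], start = as.integer(m[[3]]), end = as.integer(m[[4]]))
}

#' Manhattan-plot table
#'
#' One record per tested site with its `-log10(p)` and a significance flag
#' under strict `p < threshold_p` comparison (a site exactly at the
#' threshold is not flagged).
#'
#' @param results an [assoc_scan()] data.frame.
#' @param threshold_p significance threshold in `(0, 1]`.
#' @return data.frame `chrom`, `pos`, `neglog10_p`, `significant`.
#' @export
manhattan_table <- function(results, threshold_p) {
  if (!nrow(results)) stop("no association results")
  if (!is.numeric(threshold_p) || threshold_p <= 0 || threshold_p > 1)
    stop("threshold_p must lie in (0, 1]")
  data.frame(chrom = results$chrom, pos = results$pos,
             neglog10_p = results$neglog10_p,
             significant = results$p < threshold_p)
}

#' Run the full association pipeline
#'
#' filter (biallelic + MAF) -> phenotype aggregation and binarization ->
#' Fisher exact scan -> permutation null, threshold summaries and
#' calibrated significance line -> Manhattan table -> regional LD.
#' Deterministic given the config (including the permutation seed).
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the report bundle: list with `gm` (filtered),
#'   `pt`, `bp`, `results`, `summary`, `sig_threshold`, `manhattan`,
#'   `ld` (named list per region), `manifest`. All tables are also written
#'   under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  gm <- read_genotype_tsv(cfg$genotype_tsv, lenient = cfg$lenient)
  pt <- read_phenotype_csv(cfg$phenotype_csv)
  n_raw <- n_sites(gm)

  common <- intersect(gm$strains, unique(pt$measurements$strain))
  if (!length(common)) stop("no overlap between genotyped and phenotyped strains")
  drop_g <- setdiff(gm$strains, common)
  drop_p <- setdiff(unique(pt$measurements$strain), common)
  for (s in drop_g) say("dropped strain (no phenotype): ", s)
  for (s in drop_p) say("dropped strain (no genotype): ", s)
  gm <- subset_gm(gm, strains = common)
  pt <- phenotype_table(
    pt$measurements[pt$measurements$strain %in% common, ])

  gm <- filter_biallelic(gm)
  say("sites after biallelic filter: ", n_sites(gm), " (of ", n_raw, ")")
  gm <- filter_maf(gm, maf_filter_spec(cfg$min_maf, cfg$missing_policy))
  say("sites after MAF > ", cfg$min_maf, " filter: ", n_sites(gm))

  bp <- binarize(pt, sd_mode = cfg$sd_mode)
  if (all(bp$classes == "high"))
    warning("degenerate binarization: every strain is high-communicating")
  say(sprintf("class split: %d low / %d high (grand mean %.3f, SD %.3f)",
              sum(bp$classes == "low"), sum(bp$classes == "high"),
              bp$grand_mean, bp$grand_sd))

  results <- assoc_scan(gm, bp, sided = cfg$sided)
  plan <- permutation_plan(cfg$n_permutations, cfg$perm_seed, cfg$perm_mode)
  summary <- threshold_summary(gm, bp, plan, cfg$thresholds,
                               sided = cfg$sided, results = results)
  sig <- vapply(cfg$target_expected, function(t)
    threshold_for_expected(gm, bp, plan, t, sided = cfg$sided), numeric(1))
  manhattan <- manhattan_table(results, sig[[1]])

  ld <- list()
  for (rtxt in cfg$ld_regions) {
    r <- parse_region(rtxt)
    sub <- region_query(gm, r$chrom, r$start, r$end)
    ld[[rtxt]] <- ld_long(r2_matrix(sub))
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) utils::write.table(
    df, file.path(cfg$out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wtsv(results, "association.tsv")
  wtsv(summary, "threshold_summary.tsv")
  wtsv(manhattan, "manhattan.tsv")
  for (nm in names(ld))
    wtsv(ld[[nm]], paste0("ld_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fungwas")),
    config = unclass(cfg),
    n_sites_raw = n_raw, n_sites_tested = n_sites(gm),
    n_strains = length(common),
    class_split = list(low = sum(bp$classes == "low"),
                       high = sum(bp$classes == "high")),
    sig_thresholds = as.list(stats::setNames(
      sig, paste0("target_", cfg$target_expected))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(gm = gm, pt = pt, bp = bp, results = results,
                 summary = summary, sig_threshold = sig,
                 manhattan = manhattan, ld = ld, manifest = manifest))
}
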
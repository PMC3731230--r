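#' Construct a phenotype table of replicate fusion measurements
#'
#' Each measurement records, for one strain at one replicate and timepoint,
#' how many germling pairs out of `total` scored showed chemotropic
#' communication or fusion (typically 50 pairs per replicate).
#'
#' @param measurements data.frame with columns `strain`, `replicate`,
#'   `timepoint`, `fused`, `total`.
#' @return an object of class `phenotype_table`.
#' @export
phenotype_table <- function(measurements) {
  m <- as.data.frame(measurements)
  needed <- c("strain", "replicate", "timepoint", "fused", "total")
  if (!all(needed %in% names(m)))
    stop("measurements must have columns ", paste(needed, collapse = ", "))
  m <- m[needed]
  m$strain <- as.character(m$strain)
  for (col in c("replicate", "timepoint", "fused", "total"))
    m[[col]] <- as.integer(m[[col]])
  bad <- which(is.na(m$fused) | is.na(m$total) | m$fused < 0 |
                 m$total < 1 | m$fused > m$total |
                 m$replicate < 1 | m$timepoint < 1)
  if (length(bad))
    stop("invalid measurement row(s): ", paste(bad, collapse = ", "),
         " (need 0 <= fused <= total, total >= 1, replicate/timepoint >= 1)")
  if (!nrow(m)) stop("phenotype table must contain at least one measurement")
  structure(list(measurements = m), class = "phenotype_table")
}

#' Read a phenotype CSV
#'
#' Expected columns: `strain, replicate, timepoint, fused, total`.
#'
#' @param path CSV file.
#' @return a [phenotype_table()].
#' @export
read_phenotype_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a phenotype table as CSV
#' @param pt a [phenotype_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(pt, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(pt$measurements, con, row.names = FALSE, quote = FALSE,
                   eol = "\n")
  invisible(path)
}

#' @export
print.phenotype_table <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("phenotype_table: %d measurements, %d strains\n",
              nrow(m), length(unique(m$strain))))
  invisible(x)
}

#' Per-strain mean communication frequency
#'
#' The unweighted mean of `fused/total` over all of a strain's replicate x
#' timepoint measurements; every measurement carries equal weight (counts
#' are not pooled before dividing).
#'
#' @param pt a [phenotype_table()].
#' @param strain strain identifier.
#' @return a proportion in `[0, 1]`.
#' @export
mean_frequency <- function(pt, strain) {
  m <- pt$measurements[pt$measurements$strain == strain, ]
  if (!nrow(m)) stop("unknown strain: ", strain)
  mean(m$fused / m$total)
}

#' Per-strain mean frequencies for all strains
#' @param pt a [phenotype_table()].
#' @return named numeric vector, in order of first appearance.
#' @export
strain_means <- function(pt) {
  m <- pt$measurements
  freq <- m$fused / m$total
  means <- tapply(freq, factor(m$strain, levels = unique(m$strain)), mean)
  structure(as.numeric(means), names = names(means))
}

#' Binarize communication frequencies by the standard-deviation rule
#'
#' Computes the grand mean and standard deviation of the per-strain mean
#' frequencies and classifies a strain as `low` iff its mean frequency is
#' strictly more than one standard deviation below the grand mean; all other
#' strains (including any exactly at `mean - sd`) are `high`.
#'
#' @param pt a [phenotype_table()].
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`.
#' @return an object of class `binary_phenotype`: list with `classes`
#'   (named character vector of `"high"`/`"low"`), `grand_mean`, `grand_sd`,
#'   `sd_mode`.
#' @export
binarize <- function(pt, sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  means <- strain_means(pt)
  if (length(means) < 2L)
    stop("binarize needs at least 2 strains (SD undefined)")
  gmean <- mean(means)
  gsd <- stats::sd(means)
  if (sd_mode == "population")
    gsd <- gsd * sqrt((length(means) - 1) / length(means))
  classes <- ifelse(means < gmean - gsd, "low", "high")
  structure(list(classes = classes, grand_mean = gmean, grand_sd = gsd,
                 sd_mode = sd_mode),
            class = "binary_phenotype")
}

#' Construct a binary phenotype directly from class labels
#' @param classes named character vector of `"high"`/`"low"`.
#' @param grand_mean,grand_sd,sd_mode optional provenance fields.
#' @return a `binary_phenotype`.
#' @export
binary_phenotype <- function(classes, grand_mean = NA_real_,
                             grand_sd = NA_real_, sd_mode = "sample") {
  if (is.null(names(classes)) || anyDuplicated(names(classes)))
    stop("classes must be uniquely named by strain")
  if (!all(classes %in% c("high", "low")))
    stop("classes must be 'high' or 'low'")
  structure(list(classes = classes, grand_mean = grand_mean,
                 grand_sd = grand_sd, sd_mode = sd_mode),
            class = "binary_phenotype")
}

#' @export
print.binary_phenotype <- function(x, ...) {
  cat(sprintf(
    "binary_phenotype: %d strains (%d low, %d high); grand mean %.4f, SD %.4f (%s)\n",
    length(x$classes), sum(x$classes == "low"), sum(x$classes == "high"),
    x$grand_mean, x$grand_sd, x$sd_mode))
  invisible(x)
}

#' Histogram-ready binned summary of communication frequencies
#'
#' Bins per-strain mean frequencies into intervals of `width` percentage
#' points over \[0, 100\], the layout of the study's communication-frequency
#' histogram.
#'
#' @param pt a [phenotype_table()].
#' @param width bin width in percentage points (default 5).
#' @return data.frame with `bin_lo`, `bin_hi` (percent) and `n_strains`.
#' @export
frequency_histogram <- function(pt, width = 5) {
  pct <- strain_means(pt) * 100
  breaks <- seq(0, 100, by = width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  idx <- findInterval(pct, breaks, rightmost.closed = TRUE, left.open = TRUE)
  idx[pct == 0] <- 1L
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             n_strains = tabulate(idx, nbins = length(breaks) - 1L))
}
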
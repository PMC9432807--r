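#' Estimate amplification dropout rates from germline hets
#'
#' Operationalizes dropout on the evidence over phased germline heterozygous
#' sites: a site is a locus dropout when its total single-cell depth is
#' below 5 reads; a non-locus-dropped site is an allelic dropout when fewer
#' than 2 reads support either allele. The locus rate is taken over all
#' hets; by default the allelic rate is taken over non-locus-dropped hets
#' (set `allelic_over_all = TRUE` to use all hets as the denominator).
#'
#' @param evidence evidence table restricted internally to germline rows
#'   (rows with `kind == "germline"` if present, otherwise all rows)
#' @param allelic_over_all logical; include locus-dropped sites in the
#'   allelic-rate denominator
#' @return list of class `dropout_estimate`: `locus_rate`, `allelic_rate`,
#'   `n_sites`
#' @examples
#' ev <- data.frame(depth = c(30, 30, 4), ref_reads = c(15, 29, 2),
#'                  alt_reads = c(15, 1, 2))
#' estimate_dropout(ev)
#' @export
estimate_dropout <- function(evidence, allelic_over_all = FALSE) {
  if (!is.null(evidence$kind))
    evidence <- evidence[evidence$kind == "germline", , drop = FALSE]
  n <- nrow(evidence)
  if (n == 0) stop_invalid("no germline heterozygous sites in evidence")
  locus <- evidence$depth < 5
  allelic <- !locus & pmin(evidence$ref_reads, evidence$alt_reads) < 2
  denom <- if (allelic_over_all) n else sum(!locus)
  structure(list(locus_rate = mean(locus),
                 allelic_rate = if (denom > 0) sum(allelic) / denom else 0,
                 n_sites = n),
            class = "dropout_estimate")
}

#' @export
print.dropout_estimate <- function(x, ...) {
  cat(sprintf("Dropout over %d germline hets: locus %.3f, allelic %.3f\n",
              x$n_sites, x$locus_rate, x$allelic_rate))
  invisible(x)
}

#' Bin read counts into equal-expected-read bins and normalize
#'
#' Aggregates unit-bin read counts into variable-length super-bins each
#' expected to hold `reads_per_bin` reads under a uniform baseline, forms
#' observed/expected copy ratios, GC-corrects by dividing by the median
#' ratio of the bin's GC decile, and rescales so the mean ratio is 1.
#'
#' @param counts per-unit-bin observed read counts, in genomic order
#' @param reads_per_bin expected reads per output bin
#' @param gc optional per-unit-bin GC proportion for decile correction
#' @param chrom optional per-unit-bin chromosome labels (kept per output bin)
#' @return data.frame with `chrom`, `ratio`, `gc`, `n_units`
#' @export
bin_and_normalize <- function(counts, reads_per_bin, gc = NULL, chrom = NULL) {
  total <- sum(counts)
  if (total < 10 * reads_per_bin)
    stop_invalid("need at least 10 bins' worth of reads")
  if (is.null(chrom)) chrom <- rep("chr1", length(counts))
  expected_unit <- total / length(counts)
  units_per_bin <- max(1L, round(reads_per_bin / expected_unit))
  out <- lapply(unique(chrom), function(ch) {
    i <- which(chrom == ch)
    grp <- (seq_along(i) - 1L) %/% units_per_bin
    obs <- tapply(counts[i], grp, sum)
    nu <- tapply(rep(1, length(i)), grp, sum)
    g <- if (!is.null(gc)) as.vector(tapply(gc[i], grp, mean)) else NA_real_
    data.frame(chrom = ch, ratio = as.vector(obs) / (expected_unit * as.vector(nu)),
               gc = g, n_units = as.vector(nu), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # drop ragged trailing bins with under half the expected content
  out <- out[out$n_units >= max(1L, units_per_bin / 2), , drop = FALSE]
  if (nrow(out) < 10) stop_invalid("fewer than 10 bins after aggregation")
  if (!is.null(gc)) {
    dec <- cut(out$gc, breaks = quantile(out$gc, probs = seq(0, 1, 0.1)),
               include.lowest = TRUE, labels = FALSE)
    med <- tapply(out$ratio, dec, median)
    out$ratio <- out$ratio / as.vector(med)[dec]
  }
  out$ratio <- out$ratio / mean(out$ratio)
  rownames(out) <- NULL
  out
}

#' Median absolute pairwise difference of neighboring bin ratios (MAPD)
#'
#' The median over adjacent bin pairs of `|r[i+1] - r[i]|`, computed on
#' linear ratios and never across chromosome boundaries. Higher values mean
#' less even amplification.
#'
#' @param ratios copy-number ratios in genomic order
#' @param chrom optional chromosome labels (differences restricted within)
#' @return non-negative scalar
#' @examples
#' mapd(c(1.0, 1.2, 0.9))  # median(0.2, 0.3) = 0.25
#' @export
mapd <- function(ratios, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep("chr1", length(ratios))
  diffs <- unlist(lapply(unique(chrom), function(ch) {
    r <- ratios[chrom == ch]
    if (length(r) >= 2) abs(diff(r)) else numeric()
  }))
  if (!length(diffs))
    stop_invalid("need at least 2 bins on some chromosome")
  median(diffs)
}

#' Coefficient of variation of bin ratios
#'
#' Sample standard deviation divided by the mean.
#'
#' @param ratios copy-number ratios
#' @return non-negative scalar
#' @export
cov_ratio <- function(ratios) {
  if (length(ratios) < 2) stop_invalid("need at least 2 bins")
  m <- mean(ratios)
  if (m == 0) stop_invalid("mean ratio is zero")
  sd(ratios) / m
}

#' Per-cell QC metrics for a simulated or real cell
#'
#' Convenience wrapper computing dropout rates and evenness metrics from a
#' cell's evidence and binned coverage.
#'
#' @param cell a [simulate_cell()] result (or a list with `evidence`, `bins`)
#' @param reads_per_bin expected reads per QC bin
#' @return one-row data.frame: `locus_rate`, `allelic_rate`, `n_hets`,
#'   `mapd`, `cov`
#' @export
cell_qc <- function(cell, reads_per_bin = 2e4) {
  dr <- estimate_dropout(cell$evidence)
  nb <- bin_and_normalize(cell$bins$observed_reads, reads_per_bin,
                          gc = cell$bins$gc, chrom = cell$bins$chrom)
  data.frame(locus_rate = dr$locus_rate, allelic_rate = dr$allelic_rate,
             n_hets = dr$n_sites, mapd = mapd(nb$ratio, nb$chrom),
             cov = cov_ratio(nb$ratio))
}
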
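#' Decompose tetraploid dropout rates into diploid-origin rates
#'
#' A tetraploid nucleus carries two diploid origin copies of each
#' haplotype. Its observed locus-dropout rate `L4` arises only when both
#' origins dropped the locus, so (assuming equal and independent origins)
#' the per-origin locus rate is `L2 = sqrt(L4)`. An allele is unobserved in
#' the 4n cell only when both of its two copies were lost; with per-copy
#' allele-loss probability `u`, `u^2 = L4 + (1 - L4) * A4`, and the
#' per-origin allelic rate (conditional on no locus dropout) is
#' `a2 = (u - L2) / (1 - L2)`.
#'
#' `A4` is a per-allele rate. Estimators that count *sites* with either
#' allele dropped (as [estimate_dropout()] does) report roughly twice the
#' per-allele rate; pass `site_level = TRUE` to convert via
#' `A4_allele = 1 - sqrt(1 - A4_site)` (independent loss of the two
#' alleles) before decomposing.
#'
#' @param L4 tetraploid locus-dropout rate in `[0, 1)`
#' @param A4 tetraploid allelic-dropout rate in `[0, 1]` (denominator:
#'   non-locus-dropped sites)
#' @param site_level logical; `A4` counts sites with either allele dropped
#' @return list of class `tetraploid_dropout`: `L4`, `A4`, `L2`, `a2`, `u`
#' @examples
#' decompose_dropout(0.04, 0)    # L2 = 0.2, u = 0.2, a2 = 0
#' decompose_dropout(0, 0.25)    # u = 0.5, a2 = 0.5
#' @export
decompose_dropout <- function(L4, A4, site_level = FALSE) {
  if (L4 < 0 || L4 >= 1) stop_invalid("L4 must be in [0, 1)")
  if (A4 < 0 || A4 > 1) stop_invalid("A4 must be in [0, 1]")
  if (site_level) A4 <- 1 - sqrt(1 - A4)
  L2 <- sqrt(L4)
  u <- sqrt(L4 + (1 - L4) * A4)
  if (u < L2) {
    warning("per-copy loss probability below locus rate; clipping")
    u <- L2
  }
  a2 <- if (L2 < 1) (u - L2) / (1 - L2) else 0
  a2 <- min(max(a2, 0), 1)
  structure(list(L4 = L4, A4 = A4, L2 = L2, a2 = a2, u = u),
            class = "tetraploid_dropout")
}

#' @export
print.tetraploid_dropout <- function(x, ...) {
  cat(sprintf(
    "Tetraploid dropout (L4 = %.3f, A4 = %.3f) -> per-origin L2 = %.3f, a2 = %.3f (u = %.3f)\n",
    x$L4, x$A4, x$L2, x$a2, x$u))
  invisible(x)
}

#' Somatic detection sensitivity in a tetraploid cell
#'
#' A variant on one of the four haplotype copies can show complete linkage
#' only when the duplicate reference copy on the same haplotype dropped out
#' (probability `u`), and its alternate-read support comes from a single
#' copy, i.e. roughly half the per-haplotype depth of a germline allele.
#' The germline-estimated sensitivity is therefore scaled by the
#' linkage-opportunity probability `u` and a depth factor measured by
#' binomial thinning of read counts at rate 0.5
#' (`depth_factor = s(thin = 0.5) / s(thin = 1)`):
#' `s_tetra = s_germline * u * depth_factor`.
#'
#' Because complete linkage requires literally zero reference-linked reads
#' on the variant haplotype, the right operationalization of `u` is the
#' per-copy zero-read probability (see [zero_read_copy_rate()]), which is
#' smaller than the threshold-based (< 2 reads) allelic-dropout rate.
#'
#' @param s_germline germline-estimated sensitivity in `[0, 1]`
#' @param model a `tetraploid_dropout` (or any list with element `u`)
#' @param depth_factor per-haplotype depth sensitivity ratio in `[0, 1]`
#' @return tetraploid sensitivity in `[0, 1]`, never above `s_germline`
#' @export
tetraploid_sensitivity <- function(s_germline, model, depth_factor = 1) {
  min(s_germline * model$u * depth_factor, s_germline)
}

#' Per-copy zero-read probability in a tetraploid cell
#'
#' Estimates the probability that a single haplotype copy contributes no
#' reads at all, from the fraction of germline het alleles with zero
#' supporting reads: an allele (carried by two copies in a 4n nucleus) has
#' zero reads only when both copies yielded none, so
#' `u = sqrt(P(allele has 0 reads))`. This is the linkage-opportunity
#' probability used by [tetraploid_sensitivity()].
#'
#' @param evidence evidence table (germline rows are used)
#' @return probability in `[0, 1]`
#' @export
zero_read_copy_rate <- function(evidence) {
  g <- evidence[evidence$kind == "germline", , drop = FALSE]
  if (!nrow(g)) stop_invalid("no germline sites in evidence")
  z4 <- (sum(g$ref_reads == 0) + sum(g$alt_reads == 0)) / (2 * nrow(g))
  sqrt(z4)
}

#' Sensitivity- and ploidy-corrected burden for one cell
#'
#' Scales the raw call count by the detection sensitivity and expresses it
#' per Mb of the cell's total DNA content
#' (`genome_mb = ploidy / 2 * diploid_genome_mb`).
#'
#' @param raw_count called sSNVs
#' @param sensitivity detection sensitivity; cells at or below `qc_min`
#'   are flagged QC-fail (`qc_pass = FALSE`, estimates `NA`) rather than
#'   corrected by an unbounded factor
#' @param ploidy 2 or 4
#' @param diploid_genome_mb Mb of DNA in a diploid genome (synthetic:
#'   2 x haploid reference Mb; human default 6200)
#' @param cell_id optional identifier
#' @param qc_min sensitivity floor
#' @return one-row data.frame: `cell_id`, `raw_count`, `sensitivity`,
#'   `est_count`, `genome_mb`, `density_per_mb`, `qc_pass`
#' @export
estimate_burden <- function(raw_count, sensitivity, ploidy = 2,
                            diploid_genome_mb = 6200, cell_id = NA_character_,
                            qc_min = 0.01) {
  genome_mb <- ploidy / 2 * diploid_genome_mb
  if (is.na(sensitivity) || sensitivity <= qc_min) {
    return(data.frame(cell_id = cell_id, raw_count = raw_count,
                      sensitivity = sensitivity, est_count = NA_real_,
                      genome_mb = genome_mb, density_per_mb = NA_real_,
                      qc_pass = FALSE))
  }
  est <- raw_count / sensitivity
  data.frame(cell_id = cell_id, raw_count = raw_count,
             sensitivity = sensitivity, est_count = est,
             genome_mb = genome_mb, density_per_mb = est / genome_mb,
             qc_pass = TRUE)
}

#' Subtract amplification-artifact signature contributions from a density
#'
#' Removes the fitted weight of the artifact signatures (scE/scF) from an
#' overall sSNV density: `corrected = density * (1 - sum(weights))`.
#'
#' @param density sSNV per Mb
#' @param artifact_weights refit weights of the artifact signatures
#' @return corrected density, non-negative
#' @export
subtract_artifact_density <- function(density, artifact_weights) {
  if (any(artifact_weights < 0) || any(artifact_weights > 1))
    stop_invalid("artifact weights must be in [0, 1]")
  w <- sum(artifact_weights)
  if (w > 1) stop_invalid("artifact weights sum above 1")
  density * (1 - w)
}

#' Run QC, calling and burden correction over a simulated cohort
#'
#' Per cell: estimate dropout and evenness QC, calibrate the phasable-read
#' threshold, call sSNVs, estimate germline sensitivity (with the
#' tetraploid dropout decomposition and depth-factor thinning for 4n
#' cells), and correct the burden. Optionally refits each cell's 96-context
#' call profile against a fixed signature set and subtracts the artifact
#' signatures' weights from the density.
#'
#' @param cohort a [simulate_cohort()] result
#' @param prior_artifact_fraction prior for threshold calibration
#' @param subtract_artifacts logical; refit signatures per cell and report
#'   `density_corrected`
#' @param fixed_signatures signature matrix for the refit (default: shipped
#'   biological + artifact fixtures)
#' @param artifact_names columns of `fixed_signatures` treated as artifacts
#' @return data.frame, one row per cell, joining metadata, QC metrics,
#'   caller model summaries and burden estimates (with `truth_count` from
#'   the generator for validation)
#' @export
analyze_cohort <- function(cohort, prior_artifact_fraction = 0.5,
                           subtract_artifacts = TRUE,
                           fixed_signatures = NULL,
                           artifact_names = c("scE_like", "scF_like")) {
  if (is.null(fixed_signatures))
    fixed_signatures <- reference_signatures(c("SBS5_like", "SBS44_like",
                                               "SBS18_like", "scE_like",
                                               "scF_like"))
  diploid_mb <- 2 * total_mb(cohort$ref)
  out <- NULL
  for (i in seq_len(nrow(cohort$meta))) {
    m <- cohort$meta[i, ]
    cell <- cohort$cells[[m$cell_id]]
    qc <- cell_qc(cell)
    model <- calibrate_threshold(
      prior_artifact_fraction = prior_artifact_fraction,
      depth = stats::median(cell$evidence$depth[cell$evidence$kind == "germline"]),
      allele_fraction = 2 / m$ploidy / 2)
    calls <- call_cell(cell$evidence, cohort$germline, model)
    s_g <- estimate_sensitivity(cell$evidence, model)
    if (m$ploidy == 4) {
      u0 <- zero_read_copy_rate(cell$evidence)
      s_half <- estimate_sensitivity(cell$evidence, model, thin = 0.5,
                                     seed = i)
      df <- if (s_g > 0) s_half / s_g else 0
      sens <- tetraploid_sensitivity(s_g, list(u = u0), df)
    } else {
      sens <- s_g
    }
    b <- estimate_burden(nrow(calls), sens, m$ploidy, diploid_mb, m$cell_id)
    row <- cbind(m, qc, b[-1],
                 data.frame(threshold_k = model$threshold_k,
                            s_germline = s_g,
                            truth_count = nrow(cell$truth),
                            n_artifact_calls = sum(calls$kind == "artifact"),
                            precision = if (nrow(calls))
                              mean(calls$kind == "somatic") else NA_real_))
    if (subtract_artifacts && nrow(calls)) {
      prof <- tabulate_contexts(calls$class)
      w <- refit_fixed(prof, fixed_signatures)
      aw <- sum(w$weights[artifact_names])
      row$artifact_weight <- aw
      row$density_corrected <- subtract_artifact_density(row$density_per_mb, aw)
    } else {
      row$artifact_weight <- NA_real_
      row$density_corrected <- row$density_per_mb
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}
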
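#' Run the full synthetic-cohort pipeline
#'
#' Executes every stage end to end on a synthetic cohort: reference and
#' cohort simulation, per-cell QC, threshold calibration and calling,
#' burden correction with artifact subtraction, signature refitting, the
#' mixed-effects age model, age-group spectra and strand bias, and the KO
#' probability curves. Stage outputs are written as plain TSV/VCF/JSON
#' files under `out_dir` together with a manifest of file hashes, so the
#' run is reproducible and real-data users can pick up any intermediate.
#'
#' @param config list (or YAML path) with optional entries `seed`,
#'   `n_chrom`, `chrom_length`, `gc_fraction`, `cells_per_donor`,
#'   `cell_type`, `ploidy`, `rate_per_mb_per_year`, `intercept_per_mb`,
#'   `het_density`, `amp` (arguments of [amplification_params()]),
#'   `n_genes`; unknown keys are rejected
#' @param out_dir output directory (created if needed)
#' @return the run manifest (list), invisibly; written as `manifest.json`
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("sSNVrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "n_chrom", "chrom_length", "gc_fraction",
             "cells_per_donor", "cell_type", "ploidy",
             "rate_per_mb_per_year", "intercept_per_mb", "het_density",
             "amp", "n_genes")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(
    list(seed = 1, n_chrom = 2, chrom_length = 5e6, gc_fraction = 0.4,
         cells_per_donor = 2, cell_type = "cardiomyocyte", ploidy = 4,
         rate_per_mb_per_year = NULL, intercept_per_mb = 0.1,
         het_density = 0.67, amp = list(), n_genes = 60),
    config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    expr
  }
  ref <- stage("simulate: reference", generate_reference(
    cfg$n_chrom, cfg$chrom_length, cfg$gc_fraction, seed = cfg$seed))
  write_reference_fasta(ref, file.path(out_dir, "reference.fa"))
  amp <- do.call(amplification_params, cfg$amp)
  cohort <- stage("simulate: cohort", simulate_cohort(
    ref, cells_per_donor = cfg$cells_per_donor, cell_type = cfg$cell_type,
    ploidy = cfg$ploidy, rate_per_mb_per_year = cfg$rate_per_mb_per_year,
    intercept_per_mb = cfg$intercept_per_mb, params = amp,
    het_density = cfg$het_density, seed = cfg$seed))
  write_germline_vcf(cohort$germline, file.path(out_dir, "germline.vcf"))
  burden <- stage("qc + call + burden", analyze_cohort(cohort))
  write.table(burden, file.path(out_dir, "burden.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  calls_by_cell <- list()
  for (cid in cohort$meta$cell_id) {
    cell <- cohort$cells[[cid]]
    model <- calibrate_threshold(
      depth = stats::median(cell$evidence$depth[cell$evidence$kind == "germline"]),
      allele_fraction = 1 / cohort$meta$ploidy[cohort$meta$cell_id == cid])
    calls_by_cell[[cid]] <- call_cell(cell$evidence, cohort$germline, model)
  }
  all_calls <- do.call(rbind, c(calls_by_cell,
                                list(make.row.names = FALSE)))
  write_calls_vcf(all_calls, file.path(out_dir, "calls.vcf"))
  cm <- stage("signatures: context matrix", context_matrix(calls_by_cell))
  write.table(data.frame(cell_id = rownames(cm), cm, check.names = FALSE),
              file.path(out_dir, "context_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ok <- burden$qc_pass
  fit <- stage("aging regression", fit_age_model(
    burden$density_corrected[ok], burden$age[ok], burden$donor_id[ok]))
  jsonlite::write_json(
    list(beta = fit$beta, mu = fit$mu, ci = fit$ci, p_age = fit$p_age,
         n_cells = fit$n_cells, n_donors = fit$n_donors),
    file.path(out_dir, "age_model.json"), auto_unbox = TRUE, digits = NA)
  grp <- age_group(burden$age)
  cell_grp <- setNames(as.character(grp), burden$cell_id)
  var_grp <- unlist(lapply(names(calls_by_cell), function(cid)
    rep(cell_grp[[cid]], nrow(calls_by_cell[[cid]]))))
  burden_by_group <- tapply(burden$est_count, grp, mean, na.rm = TRUE)
  spec <- stage("spectra", group_spectrum(all_calls$class, var_grp,
                                          burden_by_group))
  write.table(data.frame(group = rownames(spec$proportions),
                         spec$proportions, check.names = FALSE),
              file.path(out_dir, "spectrum.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  models <- stage("annotation", generate_genes(ref, cfg$n_genes,
                                               seed = cfg$seed))
  write_genes_gtf(models, file.path(out_dir, "genes.gtf"))
  strand <- assign_strand(all_calls$chrom, all_calls$pos, all_calls$ref,
                          genes_granges(models))
  sb <- strand_bias_table(all_calls$class, strand)
  write.table(sb, file.path(out_dir, "strand_bias.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ko <- stage("KO model", cohort_ko_curve(burden[ok, ]))
  write.table(ko$donors, file.path(out_dir, "ko_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = as.character(utils::packageVersion("scSomaticAging")),
    seed = cfg$seed,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = setNames(as.list(unname(tools::md5sum(files))), basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
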
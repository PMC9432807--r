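test_that("complete-linkage rule classifies canonical configurations", {
  expect_equal(test_linkage(c(3, 0), c(0, 4)), "pass")
  expect_equal(test_linkage(c(2, 1), c(0, 4)), "fail")       # alt on both
  expect_equal(test_linkage(c(3, 0), c(2, 4)), "fail")       # ref on alt hap
  expect_equal(test_linkage(c(0, 0), c(5, 5)), "unphasable")
  expect_equal(test_linkage(c(3, 0), c(0, 4), has_het = FALSE), "unphasable")
  expect_equal(test_linkage(c(0, 2), c(3, 0)), "pass")       # symmetric on hap2
})

test_that("threshold calibration matches a brute-force posterior oracle", {
  # oracle: independent exhaustive evaluation of the posterior over k = 1..10
  oracle_k <- function(prior, depth, af, p_geom, target = 0.9) {
    post <- sapply(1:10, function(k) {
      st <- sum(dbinom(k:depth, depth, af))
      sa <- sum(p_geom * (1 - p_geom)^((k:200) - 1))
      (1 - prior) * st / ((1 - prior) * st + prior * sa)
    })
    ok <- which(post >= target)
    if (length(ok)) min(ok) else 2L
  }
  for (prior in c(0.2, 0.5, 0.8)) {
    for (depth in c(20, 30, 60)) {
      m <- calibrate_threshold(prior, depth = depth, allele_fraction = 0.5)
      expect_equal(m$threshold_k, oracle_k(prior, depth, 0.5, 0.5),
                   info = sprintf("prior=%g depth=%d", prior, depth))
    }
  }
  expect_gte(calibrate_threshold(0.5, depth = 30,
                                 allele_fraction = 0.5)$estimated_precision,
             0.9)
})

test_that("vanishing artifact prior drives the threshold to one read", {
  m <- calibrate_threshold(prior_artifact_fraction = 1e-9, depth = 30,
                           allele_fraction = 0.5)
  expect_equal(m$threshold_k, 1L)
  expect_error(calibrate_threshold(0), "in \\(0, 1\\)")
  expect_error(calibrate_threshold(0.5, error_model = list(type = "geometric",
                                                           p = 0)),
               "degenerate")
})

test_that("calling a cell without somatic truth or artifacts yields nothing", {
  ref <- test_ref()
  g <- head(test_germline(), 300)
  p <- amplification_params(artifact_rate_per_mb = 0)
  sim <- simulate_amplification(list(germline = g, somatic = NULL), p, ref,
                                seed = 10)
  m <- calibrate_threshold(depth = 30, allele_fraction = 0.5)
  expect_equal(nrow(call_cell(sim$evidence, g, m)), 0)
})

test_that("calls are a subset of truth plus artifacts, never germline", {
  cell <- test_diploid_cell()
  m <- default_caller_model(cell)
  calls <- call_cell(cell$evidence, test_germline(), m)
  expect_true(all(calls$kind %in% c("somatic", "artifact")))
  g <- test_germline()
  expect_length(intersect(paste(calls$chrom, calls$pos),
                          paste(g$chrom, g$pos)), 0)
  # a single synthetic candidate at exactly the threshold is called
  ev <- data.frame(chrom = "chr1", pos = 500L, ref = "C", alt = "T",
                   depth = 20L, ref_reads = 10L, alt_reads = 10L,
                   het_pos = 600L, het_hap = 1L,
                   c_ref_h1 = 0L, c_ref_h2 = 10L,
                   c_alt_h1 = m$threshold_k, c_alt_h2 = 0L,
                   kind = "somatic", hap = 1L, class = "A[C>T]G",
                   locus_dropped = FALSE)
  expect_equal(nrow(call_cell(ev, g, m)), 1)
  ev$c_alt_h1 <- m$threshold_k - 1L
  expect_equal(nrow(call_cell(ev, g, m)), 0)
})

test_that("sensitivity reflects linkage-window geometry at deep coverage", {
  ref <- test_ref()
  g <- test_germline()
  p <- amplification_params(locus_dropout_rate = 0, allelic_dropout_rate = 0,
                            unevenness_sigma = 0, artifact_rate_per_mb = 0,
                            mean_depth = 80, depth_dispersion = 50)
  sim <- simulate_amplification(list(germline = g, somatic = NULL), p, ref,
                                seed = 11)
  m1 <- calibrate_threshold(1e-9, depth = 80, allele_fraction = 0.5)
  expect_equal(m1$threshold_k, 1L)
  s <- estimate_sensitivity(sim$evidence, m1)
  frac_linked <- mean(!is.na(sim$evidence$het_pos))
  expect_equal(s, frac_linked, tolerance = 0.02)
})

test_that("sensitivity is monotone non-increasing in the read threshold", {
  cell <- test_diploid_cell()
  sens <- sapply(1:8, function(k)
    estimate_sensitivity(cell$evidence,
                         list(threshold_k = k)))
  expect_true(all(diff(sens) <= 0))
})

test_that("fully locus-dropped evidence has zero sensitivity", {
  g <- head(test_germline(), 120)
  ev <- data.frame(chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
                   depth = 0L, ref_reads = 0L, alt_reads = 0L,
                   het_pos = c(g$pos[-1], NA), het_hap = 1L,
                   c_ref_h1 = 0L, c_ref_h2 = 0L, c_alt_h1 = 0L,
                   c_alt_h2 = 0L, kind = "germline", hap = g$hap,
                   class = NA_character_, locus_dropped = TRUE)
  expect_equal(estimate_sensitivity(ev, list(threshold_k = 2)), 0)
})

test_that("tetraploid variants pass linkage only when the duplicate reference copy dropped", {
  cell <- test_tetraploid_cell()
  ev <- cell$evidence
  tr <- cell$truth
  rows <- ev[match(paste(tr$chrom, tr$pos), paste(ev$chrom, ev$pos)), ]
  st <- scSomaticAging:::linkage_status(rows)
  same_hap_ref <- ifelse(rows$hap == 1, rows$c_ref_h1, rows$c_ref_h2)
  # conditioning on generator truth: every passing variant has a clean
  # same-haplotype reference channel
  expect_true(all(same_hap_ref[st == "pass"] == 0))
})
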
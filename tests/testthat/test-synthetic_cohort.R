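test_that("reference generation respects GC content, determinism and bounds", {
  ref <- generate_reference(1, 10000, 0.4, seed = 1)
  expect_equal(unname(ref$lengths), 10000)
  gc <- sum(strsplit(ref$seq[[1]], "")[[1]] %in% c("G", "C"))
  ci <- binom_ci99(10000, 0.4)
  expect_gte(gc, ci[1]); expect_lte(gc, ci[2])

  a <- generate_reference(2, 1e6, 0.5, seed = 7)
  b <- generate_reference(2, 1e6, 0.5, seed = 7)
  expect_identical(a$seq, b$seq)

  at <- generate_reference(1, 10000, 0, seed = 3)
  expect_false(grepl("[GC]", at$seq[[1]]))

  expect_error(generate_reference(1, 100, 0.4, 1), "10 kb")
  expect_error(generate_reference(0, 1e5, 0.4, 1), ">= 1")
})

test_that("reference FASTA round-trips", {
  ref <- generate_reference(2, 1e4, 0.5, seed = 2)
  path <- tempfile(fileext = ".fa")
  write_reference_fasta(ref, path)
  back <- read_reference_fasta(path)
  expect_identical(back$seq, ref$seq)
})

test_that("germline hets follow the requested density and avoid the ref base", {
  ref <- memo("ref10mb", function() generate_reference(1, 1e7, 0.4, seed = 5))
  g <- generate_germline(ref, het_density = 0.67, seed = 9)
  ci <- pois_ci99(0.67 * 1e7 / 1000)
  expect_gte(nrow(g), ci[1]); expect_lte(nrow(g), ci[2])
  expect_true(all(g$alt != g$ref))
  ref_at <- substring(ref$seq[[1]], g$pos, g$pos)
  expect_true(all(g$ref == ref_at))
  expect_true(all(g$hap %in% 1:2))

  tiny <- generate_germline(generate_reference(1, 1e4, 0.4, 1),
                            het_density = 1e-4, seed = 1)
  expect_true(nrow(tiny) >= 0)   # possibly empty, still a valid table
  expect_error(generate_germline(ref, het_density = 0), "> 0")
})

test_that("phased germline VCF round-trips", {
  g <- head(test_germline(), 50)
  path <- tempfile(fileext = ".vcf")
  write_germline_vcf(g, path)
  back <- read_germline_vcf(path)
  rownames(g) <- NULL
  expect_equal(back, g)
})

test_that("somatic truth count follows (intercept + rate*age) * ploidy * Mb", {
  ref <- test_ref()                       # 2 Mb haploid
  expect_equal(nrow(generate_somatic(ref, 50, rate_per_mb_per_year = 0,
                                     intercept_per_mb = 0, seed = 1)), 0)
  # tetraploid: mean = 0.010 * 50 * 4 * 2 = 4 on this 2 Mb reference;
  # aggregate 40 cells so the Poisson CI is informative
  tot <- sum(vapply(1:40, function(s)
    nrow(generate_somatic(ref, 50, 0.010, 0, ploidy = 4, seed = s)), 0))
  ci <- pois_ci99(40 * 0.010 * 50 * 4 * 2)
  expect_gte(tot, ci[1]); expect_lte(tot, ci[2])
})

test_that("somatic classes respect the signature mixture support", {
  ref <- test_ref()
  som <- generate_somatic(ref, 80, 0.05, 0.5, ploidy = 4,
                          signature_mix = c(scF_like = 1), seed = 4)
  expect_gt(nrow(som), 10)
  expect_true(all(substr(som$class, 3, 5) == "C>T"))
  # class labels agree with the reference context at the sampled positions
  expect_identical(trinucleotide_context(som$chrom, som$pos, som$ref,
                                         som$alt, ref), som$class)
})

test_that("somatic positions never collide with germline sites", {
  g <- test_germline()
  som <- generate_somatic(test_ref(), 80, 0.05, 0.5, ploidy = 4,
                          germline = g, seed = 6)
  expect_length(intersect(paste(som$chrom, som$pos),
                          paste(g$chrom, g$pos)), 0)
  expect_false(any(duplicated(paste(som$chrom, som$pos))))
})

test_that("amplification with no dropout and no unevenness covers both alleles", {
  ref <- test_ref()
  g <- head(test_germline(), 500)
  p <- amplification_params(locus_dropout_rate = 0, allelic_dropout_rate = 0,
                            unevenness_sigma = 0, artifact_rate_per_mb = 0,
                            mean_depth = 60, depth_dispersion = 50)
  sim <- simulate_amplification(list(germline = g, somatic = NULL), p, ref,
                                seed = 3)
  ev <- sim$evidence
  expect_equal(nrow(ev), nrow(g))
  expect_true(all(ev$kind == "germline"))
  # NB(30, size 50) per allele: zero-read alleles are vanishingly rare
  expect_gt(mean(ev$ref_reads >= 2 & ev$alt_reads >= 2), 0.99)
  expect_equal(mean(ev$depth), 60, tolerance = 0.05)
})

test_that("artifact-free amplification emits no sites beyond the truth", {
  ref <- test_ref()
  g <- head(test_germline(), 200)
  som <- generate_somatic(ref, 50, 0.02, 0.2, germline = g, seed = 2)
  p <- amplification_params(artifact_rate_per_mb = 0)
  sim <- simulate_amplification(list(germline = g, somatic = som), p, ref,
                                seed = 4)
  expect_setequal(paste(sim$evidence$chrom, sim$evidence$pos),
                  c(paste(g$chrom, g$pos), paste(som$chrom, som$pos)))
})

test_that("empty truth yields empty evidence but valid bins", {
  p <- amplification_params(artifact_rate_per_mb = 0)
  sim <- simulate_amplification(list(germline = test_germline()[0, ],
                                     somatic = NULL), p, test_ref(), seed = 1)
  expect_equal(nrow(sim$evidence), 0)
  expect_gt(nrow(sim$bins), 0)
})

test_that("merging a realization with itself doubles every read count", {
  cellsim <- memo("selfmerge", function() {
    g <- head(test_germline(), 300)
    p <- amplification_params()
    simulate_amplification(list(germline = g, somatic = NULL), p,
                           test_ref(), seed = 5)
  })
  m <- make_tetraploid(cellsim, cellsim)
  for (cc in c("depth", "ref_reads", "alt_reads", "c_alt_h1", "c_alt_h2"))
    expect_equal(m$evidence[[cc]],
                 2L * cellsim$evidence[[cc]][match(
                   paste(m$evidence$chrom, m$evidence$pos),
                   paste(cellsim$evidence$chrom, cellsim$evidence$pos))])
  expect_identical(m$evidence$locus_dropped,
                   cellsim$evidence$locus_dropped[match(
                     paste(m$evidence$chrom, m$evidence$pos),
                     paste(cellsim$evidence$chrom, cellsim$evidence$pos))])
})

test_that("mismatched germline sets are rejected when merging", {
  g <- head(test_germline(), 300)
  p <- amplification_params()
  a <- simulate_amplification(list(germline = g, somatic = NULL), p,
                              test_ref(), seed = 5)
  b <- simulate_amplification(list(germline = g[-1, ], somatic = NULL), p,
                              test_ref(), seed = 6)
  expect_error(make_tetraploid(a, b), "germline")
})

test_that("tetraploid locus dropout follows the product law over many hets", {
  ref <- memo("ref10mb", function() generate_reference(1, 1e7, 0.4, seed = 5))
  g <- memo("germ10mb", function() generate_germline(ref, 0.67, seed = 20))
  p <- amplification_params(locus_dropout_rate = 0.2,
                            allelic_dropout_rate = 0.1)
  prodlaw <- memo("prodlaw", function() {
    a <- simulate_amplification(list(germline = g, somatic = NULL), p, ref,
                                seed = 31)
    b <- simulate_amplification(list(germline = g, somatic = NULL), p, ref,
                                seed = 32)
    list(a = a, b = b, m = make_tetraploid(a, b))
  })
  la <- mean(prodlaw$a$evidence$locus_dropped)
  lb <- mean(prodlaw$b$evidence$locus_dropped)
  lm <- mean(prodlaw$m$evidence$locus_dropped)
  n <- nrow(prodlaw$m$evidence)
  expect_gt(n, 5000)
  se <- sqrt(la * lb * (1 - la * lb) / n)
  expect_lt(abs(lm - la * lb), 3 * se)
})

test_that("cell simulation is deterministic given the seed", {
  a <- simulate_cell(test_ref(), test_germline(), age = 30, ploidy = 4,
                     seed = 123)
  b <- simulate_cell(test_ref(), test_germline(), age = 30, ploidy = 4,
                     seed = 123)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$truth, b$truth)
  expect_identical(a$bins, b$bins)
})

test_that("truth 96-class frequencies recover the generating mixture", {
  ref <- test_ref()
  mix <- c(SBS5_like = 0.6, SBS18_like = 0.4)
  cls <- unlist(lapply(1:10, function(s)
    generate_somatic(ref, 80, 0.5, 1, ploidy = 4, signature_mix = mix,
                     seed = 50 + s)$class))
  expect_gt(length(cls), 2000)
  S <- reference_signatures(names(mix))
  target <- as.vector(S %*% (mix / sum(mix)))
  expect_gte(cosine_sim(as.vector(tabulate_contexts(cls)), target), 0.98)
})
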
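make_toy_gene <- function() {
  # chr1: 60 bp; gene on + strand 11..52, single exon, CDS 21..44 (24 bp)
  seq <- paste0("AAAAAAAAAA",              # 1-10 upstream
                "GGGGGGGGGG",              # 11-20 5' UTR
                "ATGGCAGCTTGGTCACGTTGTTAA", # 21-44 CDS: M A A W S R C *
                "CCCCCCCC",                # 45-52 3' UTR
                "TTTTTTTT")                # 53-60 downstream
  ref <- structure(list(seq = c(chr1 = seq), lengths = c(chr1 = 60L)),
                   class = "ref_genome")
  models <- structure(list(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 11L,
                       end = 52L, strand = "+", length = 42L),
    exons = data.frame(gene_id = "g1", chrom = "chr1", start = 11L,
                       end = 52L, strand = "+"),
    cds = data.frame(gene_id = "g1", chrom = "chr1", start = 21L,
                     end = 44L, strand = "+", frame = 0L)),
    class = "gene_models")
  list(ref = ref, models = models)
}

test_that("genic annotation distinguishes coding effects through the genetic code", {
  toy <- make_toy_gene()
  ann <- function(pos, ref_b, alt_b)
    annotate_genic("chr1", pos, ref_b, alt_b, toy$models, toy$ref)$category
  # TGG (Trp, genomic 30-32) -> TGA stop
  expect_equal(ann(32, "G", "A"), "exonic-stopgain")
  # GCA (Ala, 24-26) third position -> GCT still Ala
  expect_equal(ann(26, "A", "T"), "exonic-synonymous")
  # GCT (Ala, 27-29) first position -> CCT Pro
  expect_equal(ann(27, "G", "C"), "exonic-nonsynonymous")
  expect_equal(ann(15, "G", "A"), "UTR")
  expect_equal(ann(5, "A", "C"), "intergenic")
  expect_equal(ann(55, "T", "G"), "intergenic")
})

test_that("genic annotation handles minus-strand and spliced CDS from generated models", {
  ref <- test_ref()
  models <- generate_genes(ref, n_genes = 30, seed = 3)
  # every CDS length is divisible by 3
  for (id in models$genes$gene_id) {
    cd <- models$cds[models$cds$gene_id == id, ]
    expect_equal(sum(cd$end - cd$start + 1L) %% 3L, 0L)
    cseq <- scSomaticAging:::coding_sequence(models, id, ref)
    expect_equal(nchar(cseq) %% 3L, 0L)
  }
  # GTF round trip preserves the models
  path <- tempfile(fileext = ".gtf")
  write_genes_gtf(models, path)
  back <- read_genes_gtf(path)
  expect_equal(back$genes[order(back$genes$gene_id),
                          c("gene_id", "start", "end", "strand")],
               models$genes[order(models$genes$gene_id),
                            c("gene_id", "start", "end", "strand")],
               ignore_attr = TRUE)
})

test_that("excess test matches the exact enumeration oracle", {
  expect_equal(excess_test(c(1, 0), c(0, 1))$p, 1.0)
  t1 <- excess_test(c(5, 2), c(2, 5))
  t2 <- excess_test(c(2, 5), c(5, 2))
  expect_equal(t1$p, t2$p)
  expect_equal(t1$odds_ratio, 1 / t2$odds_ratio, tolerance = 1e-6)
  set.seed(4)
  for (i in 1:25) {
    tab <- rmultinom(1, sample(8:20, 1), rep(0.25, 4))
    a <- tab[1] + 1; b <- tab[2] + 1; c <- tab[3] + 1; d <- tab[4] + 1
    expect_equal(excess_test(c(a, b), c(c, d))$p,
                 fisher_enum_p(a, b, c, d), tolerance = 1e-9)
  }
  expect_error(excess_test(c(0, 0), c(1, 2)), "margins")
})

test_that("Wallenius distribution matches the sequential-draw oracle", {
  for (omega in c(0.5, 1, 2.3)) {
    dp <- wallenius_dp_pmf(6, 8, 7, omega)
    ours <- vapply(0:7, scSomaticAging:::dwallenius, 0,
                   m1 = 6, m2 = 8, n = 7, omega = omega)
    expect_equal(ours, dp[1:8], tolerance = 1e-6)
  }
  # omega = 1 reduces to the central hypergeometric
  expect_equal(scSomaticAging:::pwallenius_upper(4, 6, 8, 7, 1),
               phyper(3, 6, 8, 7, lower.tail = FALSE), tolerance = 1e-9)
})

test_that("equal gene lengths reduce enrichment to the hypergeometric tail", {
  genes <- sprintf("g%02d", 1:20)
  lengths <- setNames(rep(1000, 20), genes)
  hits <- setNames(c(rep(1, 6), rep(0, 14)), genes)
  sets <- list(sA = genes[1:8], universe = genes)
  res <- geneset_enrichment(hits, sets, lengths, min_hits = 1)
  x <- sum(hits[sets$sA])
  expect_equal(res$p[res$set == "sA"],
               phyper(x - 1, 8, 12, 6, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("set filters exclude sparse and oversized sets", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(5)
  lengths <- setNames(sample(1000:10000, 200), genes)
  hits <- setNames(rbinom(200, 1, 0.3), genes)
  sets <- list(tiny = genes[1:6],            # < 5 mutated members likely
               ok = genes[1:80],
               universe_pad = genes)
  res <- geneset_enrichment(hits, sets, lengths, max_size = 100)
  expect_false("universe_pad" %in% res$set)  # above max_size
  expect_true(all(res$hits_in_set >= 5))
})

test_that("a strongly enriched set is detected at small p", {
  set.seed(6)
  genes <- sprintf("g%04d", 1:2000)
  lengths <- setNames(sample(1000:20000, 2000, replace = TRUE), genes)
  inset <- genes[1:50]
  pr <- ifelse(genes %in% inset, 0.5, 0.1)   # 5x in-set mutation rate
  hits <- setNames(rbinom(2000, 1, pr), genes)
  sets <- c(list(target = inset),
            lapply(1:5, function(i) sample(genes, 50)))
  names(sets) <- c("target", paste0("null", 1:5))
  res <- geneset_enrichment(hits, sets, lengths)
  expect_lt(res$p[res$set == "target"], 0.01)
})

test_that("quartile association handles null, constructed and scaled inputs", {
  genes <- sprintf("g%03d", 1:100)
  expr <- setNames(seq(1, 100), genes)
  lengths <- setNames(rep(2000, 100), genes)
  # variants only in top-quartile genes
  vg <- rep(genes[80:99], each = 2)
  qa <- quartile_association(vg, expr, lengths, power = 0.5, n_perm = 200)
  expect_equal(qa$density[1:3], rep(0, 3))
  expect_gt(qa$density[4], 0)
  # doubling gene lengths halves densities
  qa2 <- quartile_association(vg, expr, lengths * 2, power = 0.5,
                              n_perm = 10)
  expect_equal(qa2$density, qa$density / 2)
  expect_error(quartile_association(vg, setNames(rep(1, 100), genes),
                                    lengths), "degenerate|equal")
})

test_that("quartile permutation s.d. stabilizes with more rounds", {
  set.seed(7)
  genes <- sprintf("g%03d", 1:120)
  expr <- setNames(rlnorm(120), genes)
  lengths <- setNames(sample(1000:5000, 120), genes)
  vg <- sample(genes, 150, replace = TRUE)
  a <- quartile_association(vg, expr, lengths, n_perm = 500, seed = 1)
  b <- quartile_association(vg, expr, lengths, n_perm = 1000, seed = 2)
  expect_true(all(abs(b$perm_sd - a$perm_sd) / a$perm_sd < 0.25))
})

test_that("BH correction matches the step-up definition on a hand list", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  manual <- rev(cummin(rev(p * 6 / seq_len(6))))
  expect_equal(p.adjust(p, "BH"), pmin(manual, 1))
})

test_that("identical tables give no cell-type-specific set", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:300)
  lengths <- setNames(sample(1000:10000, 300), genes)
  hits <- setNames(rbinom(300, 1, 0.3), genes)
  sets <- lapply(1:6, function(i) sample(genes, 40))
  names(sets) <- paste0("s", 1:6)
  res <- rank_difference_permutation(hits, hits, sets, lengths,
                                     n_perm = 200, candidate_p = 1.01,
                                     seed = 3)
  expect_true(all(res$rank_diff == 0))
  expect_true(all(res$p_perm >= 1 / 201))
  expect_false(any(res$fdr < 0.05))
})

test_that("a set enriched in one type only reaches FDR significance", {
  # mimics the study situation: one cell-type-A-specific set among a pool
  # of sets enriched in type B, so the A-specific set sits at the extremes
  # of both enrichment rankings
  res <- memo("rankdiff", function() {
    set.seed(9)
    genes <- sprintf("g%04d", 1:800)
    lengths <- setNames(sample(1000:20000, 800, replace = TRUE), genes)
    sets <- c(list(target = genes[1:40]),
              setNames(lapply(1:39, function(i)
                sample(genes[41:800], 40)), paste0("bset", 1:39)))
    in_b <- unique(unlist(sets[-1]))
    pr_a <- ifelse(genes %in% sets$target, 0.6, 0.12)   # 5x in-set rate in A
    pr_b <- ifelse(genes %in% in_b, 0.35, 0.10)         # B enriched elsewhere
    hits_a <- setNames(rbinom(800, 1, pr_a), genes)
    hits_b <- setNames(rbinom(800, 1, pr_b), genes)
    rank_difference_permutation(hits_a, hits_b, sets, lengths,
                                n_perm = 4000, seed = 10)
  })
  expect_true("target" %in% res$set)
  expect_lt(res$fdr[res$set == "target"], 0.05)
})
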
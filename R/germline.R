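#' Generate phased germline heterozygous SNVs
#'
#' Places heterozygous germline SNVs along the reference as a Poisson process
#' at the requested density, assigns the alternate allele to one of the two
#' donor haplotypes uniformly, and returns a phased table. In real-data use
#' these sites come from phased bulk calls; the synthetic set plays the same
#' role for dropout estimation, linkage phasing and sensitivity estimation.
#'
#' @param ref a `ref_genome`
#' @param het_density expected heterozygous sites per kb (default 0.67,
#'   about one het per 1.5 kb as in human genomes)
#' @param seed integer seed
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `hap` (1 or 2, the haplotype carrying the alternate allele)
#' @export
generate_germline <- function(ref, het_density = 0.67, seed = 1) {
  if (het_density <= 0) stop_invalid("het_density must be > 0")
  if (het_density > 1000) stop_invalid("het_density implies > 1 het per bp")
  with_seed(seed, {
    out <- lapply(names(ref$seq), function(ch) {
      L <- ref$lengths[[ch]]
      n <- rpois(1, het_density * L / 1000)
      n <- min(n, L - 2L)
      if (n == 0) return(NULL)
      pos <- sort(sample.int(L - 2L, n) + 1L)   # avoid chromosome ends
      data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(), hap = integer()))
    out$ref <- ref_base(ref, out$chrom, out$pos)
    bases <- c("A", "C", "G", "T")
    out$alt <- vapply(out$ref, function(r)
      sample(setdiff(bases, r), 1), "", USE.NAMES = FALSE)
    out$hap <- sample(1:2, nrow(out), replace = TRUE)
    rownames(out) <- NULL
    out
  })
}

#' Generate per-cell somatic SNV truth
#'
#' Draws the somatic count for one cell as Poisson with mean
#' `(intercept_per_mb + rate_per_mb_per_year * age) * ploidy * haploid Mb`,
#' samples each variant's 96-class from the signature mixture, and places it
#' at a reference position with matching trinucleotide context. Haplotype and
#' (for tetraploid cells) origin copy are assigned uniformly.
#'
#' @param ref a `ref_genome`
#' @param age donor age in years
#' @param rate_per_mb_per_year somatic rate (sSNV per Mb of DNA per year)
#' @param intercept_per_mb burden at age 0 (sSNV per Mb)
#' @param ploidy 2 or 4
#' @param signature_mix named non-negative weights over columns of
#'   `signatures` (normalized internally)
#' @param signatures 96 x K signature matrix (defaults to the shipped
#'   reference fixtures)
#' @param germline germline het table; somatic positions avoid these sites
#' @param seed integer seed
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `hap`,
#'   `origin_copy`, `class`
#' @export
generate_somatic <- function(ref, age, rate_per_mb_per_year = 0.010,
                             intercept_per_mb = 0.1, ploidy = 2,
                             signature_mix = c(SBS5_like = 0.6,
                                               SBS44_like = 0.25,
                                               SBS18_like = 0.15),
                             signatures = reference_signatures(),
                             germline = NULL, seed = 1) {
  if (age < 0) stop_invalid("age must be >= 0")
  if (rate_per_mb_per_year < 0 || intercept_per_mb < 0)
    stop_invalid("rate and intercept must be >= 0")
  if (!ploidy %in% c(2, 4)) stop_invalid("ploidy must be 2 or 4")
  if (any(signature_mix < 0)) stop_invalid("signature weights must be >= 0")
  w <- signature_mix / sum(signature_mix)
  profile <- as.vector(signatures[, names(w), drop = FALSE] %*% w)
  mean_count <- (intercept_per_mb + rate_per_mb_per_year * age) *
    ploidy * total_mb(ref)
  with_seed(seed, {
    n <- rpois(1, mean_count)
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        hap = integer(), origin_copy = integer(),
                        class = character())
    if (n == 0) return(empty)
    cls <- sample(context_classes(), n, replace = TRUE, prob = profile)
    sites <- sample_positions_for_classes(cls, ref, exclude = germline)
    sites$hap <- sample(1:2, n, replace = TRUE)
    sites$origin_copy <- if (ploidy == 4) sample(1:2, n, replace = TRUE)
                         else rep(1L, n)
    sites$class <- cls
    sites
  })
}

#' Write a phased germline het table as VCF
#'
#' Emits a minimal VCF v4.2 with phased genotypes (`0|1` when the alternate
#' allele is on haplotype 2, `1|0` when on haplotype 1).
#'
#' @param germline germline table from [generate_germline()]
#' @param path output path
#' @param sample_name sample column name
#' @return `path`, invisibly
#' @export
write_germline_vcf <- function(germline, path, sample_name = "bulk") {
  gt <- ifelse(germline$hap == 1, "1|0", "0|1")
  header <- c("##fileformat=VCFv4.2",
              "##source=scSomaticAging",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     sample_name))
  body <- paste(germline$chrom, germline$pos, ".", germline$ref, germline$alt,
                ".", "PASS", ".", "GT", gt, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased germline VCF back into a het table
#' @param path VCF path
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `hap`
#' @export
read_germline_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), hap = integer()))
  f <- strsplit(body, "\t", fixed = TRUE)
  gt <- substr(vapply(f, `[[`, "", 10L), 1, 3)
  data.frame(chrom = vapply(f, `[[`, "", 1L),
             pos = as.integer(vapply(f, `[[`, "", 2L)),
             ref = vapply(f, `[[`, "", 4L),
             alt = vapply(f, `[[`, "", 5L),
             hap = ifelse(gt == "1|0", 1L, 2L),
             stringsAsFactors = FALSE)
}

#' Write somatic calls (or truth) as VCF with haplotype INFO tags
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `hap`, `origin_copy`, and phasable read counts
#' @param path output path
#' @return `path`, invisibly
#' @export
write_calls_vcf <- function(calls, path) {
  info <- rep(".", nrow(calls))
  if (nrow(calls) && !is.null(calls$hap)) {
    info <- paste0("HAP=", calls$hap)
    if (!is.null(calls$origin_copy))
      info <- paste0(info, ";COPY=", calls$origin_copy)
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=scSomaticAging",
              '##INFO=<ID=HAP,Number=1,Type=Integer,Description="Haplotype carrying ALT">',
              '##INFO=<ID=COPY,Number=1,Type=Integer,Description="Origin diploid copy (tetraploid cells)">',
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls))
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          info, sep = "\t") else character()
  writeLines(c(header, body), path)
  invisible(path)
}
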
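#' Generate a synthetic reference genome
#'
#' Draws i.i.d. bases with `P(G) = P(C) = gc_fraction/2` to build a small
#' multi-chromosome reference that stands in for real autosomes in synthetic
#' cohorts. Deterministic given `seed`.
#'
#' @param n_chrom number of chromosomes (>= 1)
#' @param chrom_length length of each chromosome in bp (>= 10000)
#' @param gc_fraction genome GC content in `[0, 1)`; 0 gives an all-AT genome
#' @param seed integer seed
#' @return an object of class `ref_genome`: a list with `seq` (named character
#'   vector of chromosome sequences) and `lengths` (named integer vector)
#' @examples
#' ref <- generate_reference(2, 50000, 0.4, seed = 1)
#' ref$lengths
#' @export
generate_reference <- function(n_chrom = 2, chrom_length = 1e7,
                               gc_fraction = 0.4, seed = 1) {
  if (n_chrom < 1) stop_invalid("n_chrom must be >= 1")
  if (chrom_length < 1e4) stop_invalid("chrom_length must be >= 10 kb")
  if (gc_fraction < 0 || gc_fraction >= 1)
    stop_invalid("gc_fraction must be in [0, 1)")
  chrom_length <- as.integer(chrom_length)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_chrom), function(i) {
      paste(sample(names(p), chrom_length, replace = TRUE, prob = p),
            collapse = "")
    }, "")
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  structure(list(seq = seqs,
                 lengths = setNames(rep(chrom_length, n_chrom), names(seqs))),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("Synthetic reference:", length(x$seq), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

total_mb <- function(ref) sum(as.numeric(ref$lengths)) / 1e6

#' Write / read a reference genome as FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O.
#'
#' @param ref a `ref_genome`
#' @param path output FASTA path
#' @return `write_reference_fasta` returns `path` invisibly;
#'   `read_reference_fasta` returns a `ref_genome`
#' @export
write_reference_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seq)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(seq = seqs,
                 lengths = setNames(nchar(seqs), names(seqs))),
            class = "ref_genome")
}

# base at 1-based positions, vectorized over one chromosome
ref_base <- function(ref, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- substring(ref$seq[[ch]], pos[i], pos[i])
  }
  out
}

#' Trinucleotide substitution class of a variant
#'
#' Maps a SNV to one of the 96 pyrimidine-centric trinucleotide classes.
#' When the mutated reference base is a purine, the triplet and substitution
#' are reverse-complemented so that the class is always reported with a C or
#' T at the centre.
#'
#' @param chrom,pos,ref_allele,alt_allele vectors describing the variants
#'   (1-based positions)
#' @param ref a `ref_genome`
#' @return character vector of classes, e.g. `"A[C>T]G"`
#' @export
trinucleotide_context <- function(chrom, pos, ref_allele, alt_allele, ref) {
  if (any(pos <= 1 | pos >= ref$lengths[chrom]))
    stop_invalid("variant at a chromosome end has no trinucleotide context")
  trip <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    trip[i] <- substring(ref$seq[[ch]], pos[i] - 1, pos[i] + 1)
  }
  centre <- substring(trip, 2, 2)
  if (any(centre != ref_allele))
    stop_invalid("reference allele does not match the genome sequence")
  flip <- ref_allele %in% c("A", "G")
  trip[flip] <- revcomp3(trip[flip])
  r <- ref_allele; a <- alt_allele
  r[flip] <- comp_base(r[flip]); a[flip] <- comp_base(a[flip])
  paste0(substring(trip, 1, 1), "[", r, ">", a, "]", substring(trip, 3, 3))
}

# Sample reference positions whose trinucleotide context matches each
# requested class. Uses batched uniform draws classified in bulk rather than
# a genome-wide context index. Returns data.frame(chrom, pos, ref, alt).
sample_positions_for_classes <- function(classes, ref, exclude = NULL,
                                         max_tries = 8L) {
  n <- length(classes)
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  want_pyr <- substring(classes, 3, 3)            # pyrimidine ref base
  want_alt <- substring(classes, 5, 5)
  want_trip <- paste0(substring(classes, 1, 1), want_pyr, substring(classes, 7, 7))
  lens <- ref$lengths
  chroms <- names(lens)
  taken <- if (!is.null(exclude) && nrow(exclude))
    paste(exclude$chrom, exclude$pos) else character()
  out_chrom <- character(n); out_pos <- integer(n)
  out_ref <- character(n); out_alt <- character(n)
  unfilled <- seq_len(n)
  for (try in seq_len(max_tries)) {
    batch <- max(4000L, 60L * length(unfilled))
    bc <- sample(chroms, batch, replace = TRUE, prob = lens / sum(lens))
    bp <- integer(batch)
    for (ch in chroms) {
      i <- bc == ch
      bp[i] <- sample.int(lens[[ch]] - 2L, sum(i), replace = TRUE) + 1L
    }
    trip <- character(batch)
    for (ch in chroms) {
      i <- bc == ch
      trip[i] <- substring(ref$seq[[ch]], bp[i] - 1L, bp[i] + 1L)
    }
    centre <- substring(trip, 2, 2)
    pur <- centre %in% c("A", "G")
    trip[pur] <- revcomp3(trip[pur])
    key <- paste(bc, bp)
    ok <- !(key %in% taken) & !duplicated(key)
    pool <- split(which(ok), trip[ok])
    for (idx in unfilled) {
      cand <- pool[[want_trip[idx]]]
      if (length(cand)) {
        j <- cand[[1]]
        pool[[want_trip[idx]]] <- cand[-1]
        out_chrom[idx] <- bc[j]; out_pos[idx] <- bp[j]
        out_ref[idx] <- substring(ref$seq[[bc[j]]], bp[j], bp[j])
        taken <- c(taken, key[j])
      }
    }
    unfilled <- which(out_pos == 0L)
    if (!length(unfilled)) break
    if (try < max_tries && length(unfilled))
      warning("resampling positions for ", length(unfilled),
              " variant class(es) without a match in this batch")
  }
  if (length(unfilled))
    stop_invalid("no reference position with matching trinucleotide context ",
                 "for class(es): ",
                 paste(unique(classes[unfilled]), collapse = ", "))
  # orient alt to the strand of the reference base
  pur <- out_ref %in% c("A", "G")
  alt <- want_alt
  alt[pur] <- comp_base(alt[pur])
  data.frame(chrom = out_chrom, pos = out_pos, ref = out_ref, alt = alt,
             stringsAsFactors = FALSE)
}
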
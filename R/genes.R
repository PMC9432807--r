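#' Generate a synthetic gene annotation
#'
#' Places non-overlapping single-transcript genes along the reference with
#' random strand, 1-3 exons, and a frame-valid CDS (length divisible by 3)
#' flanked by UTR margins in the terminal exons. Intended as a synthetic
#' stand-in for a real transcript annotation when testing genic annotation,
#' strand assignment and enrichment.
#'
#' @param ref a `ref_genome`
#' @param n_genes number of genes to place
#' @param seed integer seed
#' @return list of class `gene_models`: `genes` (gene_id, chrom, start,
#'   end, strand, length), `exons`, `cds` (with `frame`)
#' @export
generate_genes <- function(ref, n_genes = 100, seed = 1) {
  with_seed(seed, {
    per_chrom <- table(sample(names(ref$seq), n_genes, replace = TRUE,
                              prob = ref$lengths / sum(ref$lengths)))
    genes <- NULL; exons <- NULL; cds <- NULL
    gid <- 0L
    for (ch in names(per_chrom)) {
      ng <- per_chrom[[ch]]
      L <- ref$lengths[[ch]]
      slot <- L %/% ng
      for (g in seq_len(ng)) {
        gid <- gid + 1L
        id <- sprintf("gene%04d", gid)
        glen <- sample(3000:min(15000, slot - 200), 1)
        start <- (g - 1L) * slot + sample.int(max(1L, slot - glen - 100L), 1)
        end <- start + glen - 1L
        strand <- sample(c("+", "-"), 1)
        n_ex <- sample(1:3, 1)
        # split gene into exons separated by introns
        cuts <- sort(sample(seq(start + 200L, end - 200L), 2L * (n_ex - 1L)))
        ex_start <- c(start, cuts[seq_along(cuts) %% 2 == 0])
        ex_end <- c(cuts[seq_along(cuts) %% 2 == 1], end)
        utr5 <- sample(50:150, 1); utr3 <- sample(50:150, 1)
        # CDS: exon bodies minus UTR margins at the gene ends
        cstart <- ex_start; cend <- ex_end
        cstart[1] <- cstart[1] + utr5
        cend[n_ex] <- cend[n_ex] - utr3
        clen <- sum(cend - cstart + 1L)
        trim <- clen %% 3L                    # keep CDS frame-valid
        if (trim > 0) {
          if (strand == "+") cend[n_ex] <- cend[n_ex] - trim
          else cstart[1] <- cstart[1] + trim
        }
        genes <- rbind(genes, data.frame(
          gene_id = id, chrom = ch, start = start, end = end,
          strand = strand, length = glen, stringsAsFactors = FALSE))
        exons <- rbind(exons, data.frame(
          gene_id = id, chrom = ch, start = ex_start, end = ex_end,
          strand = strand, stringsAsFactors = FALSE))
        ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
        lens <- (cend - cstart + 1L)[ord]
        frame <- (c(0L, cumsum(lens))[seq_len(n_ex)]) %% 3L
        cds <- rbind(cds, data.frame(
          gene_id = id, chrom = ch, start = cstart[ord], end = cend[ord],
          strand = strand, frame = frame, stringsAsFactors = FALSE))
      }
    }
    structure(list(genes = genes, exons = exons, cds = cds),
              class = "gene_models")
  })
}

#' Convert gene models to a GRanges of genes
#' @param models a `gene_models`
#' @return `GRanges` with `gene_id` and `type = "gene"` metadata
#' @export
genes_granges <- function(models) {
  g <- models$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  gr$gene_id <- g$gene_id
  gr$type <- "gene"
  gr
}

#' Write gene models as GTF
#' @param models a `gene_models`
#' @param path output GTF path
#' @return `path`, invisibly
#' @export
write_genes_gtf <- function(models, path) {
  rows <- function(df, type, frame = NULL) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                     df$gene_id, df$gene_id)
    data.frame(seqname = df$chrom, source = "scSomaticAging", feature = type,
               start = df$start, end = df$end, score = ".",
               strand = df$strand,
               frame = if (is.null(frame)) "." else as.character(frame),
               attribute = attrs, stringsAsFactors = FALSE)
  }
  tab <- rbind(rows(models$genes, "gene"),
               rows(models$exons, "exon"),
               rows(models$cds, "CDS", models$cds$frame))
  lines <- apply(tab, 1, paste, collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF into gene models
#' @param path GTF path
#' @return a `gene_models`
#' @export
read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  pick <- function(type) {
    x <- df[df$type == type,
            c("gene_id", "seqnames", "start", "end", "strand")]
    names(x) <- c("gene_id", "chrom", "start", "end", "strand")
    x$chrom <- as.character(x$chrom); x$strand <- as.character(x$strand)
    rownames(x) <- NULL
    x
  }
  genes <- pick("gene")
  genes$length <- genes$end - genes$start + 1L
  cds <- pick("CDS")
  cds$frame <- as.integer(as.character(df$phase[df$type == "CDS"]))
  structure(list(genes = genes, exons = pick("exon"), cds = cds),
            class = "gene_models")
}

# spliced CDS sequence of a gene on its coding strand
coding_sequence <- function(models, gene_id, ref) {
  cd <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  ord <- order(cd$start)
  if (cd$strand[1] == "-") ord <- rev(ord)
  pieces <- vapply(ord, function(i)
    substring(ref$seq[[cd$chrom[i]]], cd$start[i], cd$end[i]), "")
  if (cd$strand[1] == "-") pieces <- vapply(pieces, revcomp, "")
  paste(pieces, collapse = "")
}

# 1-based position within the spliced CDS, NA if outside
cds_position <- function(models, gene_id, pos) {
  cd <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  if (cd$strand[1] == "-") cd <- cd[rev(seq_len(nrow(cd))), , drop = FALSE]
  off <- 0L
  for (i in seq_len(nrow(cd))) {
    if (pos >= cd$start[i] && pos <= cd$end[i]) {
      within <- if (cd$strand[1] == "+") pos - cd$start[i] + 1L
                else cd$end[i] - pos + 1L
      return(off + within)
    }
    off <- off + (cd$end[i] - cd$start[i] + 1L)
  }
  NA_integer_
}

#' Genic annotation of variants with codon-aware coding effects
#'
#' Classifies each variant as exonic-stopgain, exonic-nonsynonymous,
#' exonic-synonymous, UTR, intronic or intergenic. Coding effects are
#' computed through the standard genetic code on the annotated coding
#' strand; when a variant touches several transcripts the most severe
#' effect wins (stopgain > nonsynonymous > synonymous > UTR > intronic).
#'
#' @param chrom,pos,ref_allele,alt_allele variant vectors
#' @param models a `gene_models`
#' @param ref the `ref_genome`
#' @return list with `category` (character vector) and `gene_id`
#' @export
annotate_genic <- function(chrom, pos, ref_allele, alt_allele, models, ref) {
  gc_tab <- Biostrings::GENETIC_CODE
  severity <- c(`exonic-stopgain` = 5, `exonic-nonsynonymous` = 4,
                `exonic-synonymous` = 3, UTR = 2, intronic = 1,
                intergenic = 0)
  cds_cache <- new.env(parent = emptyenv())
  n <- length(pos)
  category <- rep("intergenic", n)
  gene_hit <- rep(NA_character_, n)
  g <- models$genes
  for (v in seq_len(n)) {
    hits <- g$gene_id[g$chrom == chrom[v] & g$start <= pos[v] & g$end >= pos[v]]
    best <- "intergenic"; best_gene <- NA_character_
    for (id in hits) {
      ex <- models$exons[models$exons$gene_id == id, , drop = FALSE]
      in_exon <- any(ex$start <= pos[v] & ex$end >= pos[v])
      cat_v <- if (!in_exon) "intronic" else {
        cpos <- cds_position(models, id, pos[v])
        if (is.na(cpos)) "UTR" else {
          if (!exists(id, cds_cache))
            assign(id, coding_sequence(models, id, ref), cds_cache)
          cseq <- get(id, cds_cache)
          if (cpos %% 3L == 0L) {
            ci <- cpos %/% 3L; wi <- 3L
          } else {
            ci <- cpos %/% 3L + 1L; wi <- cpos %% 3L
          }
          codon <- substring(cseq, 3L * ci - 2L, 3L * ci)
          strand <- g$strand[g$gene_id == id]
          base <- alt_allele[v]
          if (strand == "-") base <- comp_base(base)
          newc <- codon
          substr(newc, wi, wi) <- base
          aa_old <- gc_tab[[codon]]
          aa_new <- gc_tab[[newc]]
          if (aa_new == "*" && aa_old != "*") "exonic-stopgain"
          else if (aa_new == aa_old) "exonic-synonymous"
          else "exonic-nonsynonymous"
        }
      }
      if (severity[cat_v] > severity[best]) {
        best <- cat_v; best_gene <- id
      }
    }
    category[v] <- best
    gene_hit[v] <- if (!is.na(best_gene)) best_gene
                   else if (length(hits)) hits[1] else NA_character_
  }
  list(category = category, gene_id = gene_hit)
}
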
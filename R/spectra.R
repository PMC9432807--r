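#' Assign donors to age groups
#'
#' Infant (<= 4 years), middle-aged (30-66 years), aged (>= 75 years);
#' donors between the bands get `NA`.
#'
#' @param age numeric ages in years
#' @return factor with levels infant, middle, aged
#' @export
age_group <- function(age) {
  g <- rep(NA_character_, length(age))
  g[age <= 4] <- "infant"
  g[age >= 30 & age <= 66] <- "middle"
  g[age >= 75] <- "aged"
  factor(g, levels = c("infant", "middle", "aged"))
}

# six substitution types from 96-class labels
sub_type <- function(classes) substr(classes, 3, 5)

#' Per-group mutation spectrum and mean burden
#'
#' Pools calls across the cells of each age group into proportions over the
#' six substitution types (or the 96 classes) and records the group's mean
#' per-cell corrected burden.
#'
#' @param classes per-variant class labels
#' @param group per-variant age-group labels
#' @param burden_by_group named vector of mean per-cell burdens
#' @param granularity `"type6"` or `"class96"`
#' @return list of class `age_spectrum`: `proportions` (group x type
#'   matrix) and `burden`
#' @export
group_spectrum <- function(classes, group, burden_by_group,
                           granularity = c("type6", "class96")) {
  granularity <- match.arg(granularity)
  lev <- if (granularity == "type6")
    c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G") else context_classes()
  lab <- if (granularity == "type6") sub_type(classes) else classes
  tab <- table(factor(group), factor(lab, levels = lev))
  props <- prop.table(tab, 1)
  structure(list(proportions = as.matrix(props),
                 burden = burden_by_group[rownames(props)]),
            class = "age_spectrum")
}

#' Net increase of mutation types between aged and infant cells
#'
#' Converts group proportions to absolute per-cell counts by multiplying by
#' the group's mean burden, then subtracts infant from aged per type. The
#' totals conserve: the per-type values sum to the difference of the two
#' mean burdens. Negative entries are reported as-is.
#'
#' @param aged_props,infant_props per-type proportion vectors (sum 1)
#' @param aged_burden,infant_burden mean sSNVs per cell in each group
#' @return named numeric vector of per-type net counts
#' @export
net_increase_spectrum <- function(aged_props, infant_props,
                                  aged_burden, infant_burden) {
  if (aged_burden == 0 && infant_burden == 0)
    stop_invalid("both groups have zero burden")
  if (!isTRUE(all.equal(names(aged_props), names(infant_props))))
    stop_invalid("proportion vectors must share type names")
  aged_props * aged_burden - infant_props * infant_burden
}

#' Transcriptional strand of a variant
#'
#' Works on the pyrimidine representation: if the pyrimidine of the
#' substitution lies on the annotated gene's sense strand the variant is
#' `untranscribed`; on the template strand, `transcribed`. Sites outside
#' all genes are `intergenic`; sites covered by genes on both strands are
#' `ambiguous` and excluded from bias tests.
#'
#' @param chrom,pos,ref_allele variant coordinates and reference base
#' @param genes a `GRanges` of genes with strand, or a GTF path readable by
#'   [rtracklayer::import()]
#' @return character vector over transcribed/untranscribed/intergenic/ambiguous
#' @export
assign_strand <- function(chrom, pos, ref_allele, genes) {
  if (is.character(genes)) {
    gr <- rtracklayer::import(genes)
    gr <- gr[gr$type == "gene"]
  } else gr <- genes
  if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
    stop_invalid("gene annotation must have +/- strands")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  ov <- GenomicRanges::findOverlaps(q, gr)
  res <- rep("intergenic", length(q))
  qh <- S4Vectors::queryHits(ov)
  strands <- split(as.character(GenomicRanges::strand(gr))[S4Vectors::subjectHits(ov)], qh)
  # strand of the pyrimidine base: "+" when the reference shows C or T
  pyr_strand <- ifelse(ref_allele %in% c("C", "T"), "+", "-")
  for (k in names(strands)) {
    i <- as.integer(k)
    s <- unique(strands[[k]])
    if (length(s) > 1) res[i] <- "ambiguous"
    else res[i] <- if (pyr_strand[i] == s) "untranscribed" else "transcribed"
  }
  res
}

#' Exact two-sided strand-bias test
#'
#' Conditional form of the two-rate Poisson comparison: tests the
#' transcribed count against Binomial(total, 1/2), two-sided.
#'
#' @param n_transcribed,n_untranscribed strand counts (total >= 1)
#' @return p-value in `(0, 1]`
#' @examples
#' strand_bias_test(0, 8)  # 2 * 0.5^8
#' @export
strand_bias_test <- function(n_transcribed, n_untranscribed) {
  total <- n_transcribed + n_untranscribed
  if (total < 1) stop_invalid("need at least one stranded variant")
  binom.test(n_transcribed, total, p = 0.5)$p.value
}

#' Strand-bias table per substitution type
#'
#' @param classes per-variant 96-class labels
#' @param strand per-variant strand assignment from [assign_strand()]
#' @return data.frame: type, n_transcribed, n_untranscribed, p
#' @export
strand_bias_table <- function(classes, strand) {
  keep <- strand %in% c("transcribed", "untranscribed")
  ty <- sub_type(classes[keep]); st <- strand[keep]
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- lapply(types, function(t) {
    nt <- sum(ty == t & st == "transcribed")
    nu <- sum(ty == t & st == "untranscribed")
    data.frame(type = t, n_transcribed = nt, n_untranscribed = nu,
               p = if (nt + nu > 0) strand_bias_test(nt, nu) else NA_real_)
  })
  do.call(rbind, out)
}
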
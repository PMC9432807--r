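#' @importFrom stats rbinom rpois rnbinom rnorm rlnorm rgeom runif median sd
#'   quantile binom.test fisher.test chisq.test wilcox.test ks.test p.adjust
#'   integrate logLik anova pchisq qnorm coef lm as.dist cophenetic hclust
#'   cor complete.cases setNames aggregate phyper dbinom pbinom
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Reverse-complement a vector of DNA strings
#' @param x character vector over A/C/G/T
#' @return reverse-complemented strings
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE),
                                function(s) paste(rev(s), collapse = ""), ""))
}

# complement of single bases, vectorized
comp_base <- function(x) chartr("ACGT", "TGCA", x)

# fast reverse-complement for triplets (vectorized, no strsplit)
revcomp3 <- function(x) {
  chartr("ACGT", "TGCA",
         paste0(substr(x, 3, 3), substr(x, 2, 2), substr(x, 1, 1)))
}

#' The 96 trinucleotide substitution classes in canonical order
#'
#' Pyrimidine-centric classes, ordered by substitution type
#' (C>A, C>G, C>T, T>A, T>C, T>G) and alphabetically by 5' then 3' flank,
#' e.g. `"A[C>A]A"`. This is the column order of every 96-context matrix
#' in the package.
#'
#' @return character vector of length 96
#' @export
context_classes <- function() {
  bases <- c("A", "C", "G", "T")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(f5) paste0(f5, "[", s, "]", bases)))))
}

#' Shipped synthetic 96-context reference signatures
#'
#' Five synthetic single-base-substitution profiles shipped with the package:
#' `SBS5_like` (flat, clock-like), `SBS18_like` (C>A-heavy, oxidative),
#' `SBS44_like` (C>T-heavy, MMR-deficiency-like), and the MDA
#' whole-genome-amplification artifact profiles `scE_like` and `scF_like`
#' (C>T dominated; `scF_like` has zero mass outside C>T). These are
#' synthetic stand-ins constructed for testing, not COSMIC downloads.
#'
#' @param which optional character vector of signature names to return
#' @return numeric matrix, 96 rows (named by [context_classes()]),
#'   one column per signature; columns sum to 1
#' @export
reference_signatures <- function(which = NULL) {
  path <- system.file("extdata", "signatures_96_synthetic.tsv",
                      package = "scSomaticAging", mustWork = TRUE)
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$context
  stopifnot(identical(rownames(m), context_classes()))
  if (!is.null(which)) {
    missing <- setdiff(which, colnames(m))
    if (length(missing))
      stop_invalid("unknown signature(s): ", paste(missing, collapse = ", "))
    m <- m[, which, drop = FALSE]
  }
  m
}

# Derive a stream-specific child seed from a base seed. Keeps results
# reproducible when one user-facing seed drives several generation steps.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483563)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}
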
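#' Complete-linkage test for a candidate somatic SNV
#'
#' A candidate passes when every read linking its alternate allele to a
#' phased germline het falls on exactly one haplotype and no reference-
#' supporting read is linked to that same haplotype (complete linkage).
#' Candidates with no linked het, or with no phasable alternate reads, are
#' unphasable. Amplification or base-call errors typically place alternate
#' reads on both haplotypes, or leave genuine reference reads on the
#' candidate haplotype, and fail.
#'
#' @param c_alt vector of length 2: alt-linked read counts on haplotypes 1, 2
#' @param c_ref vector of length 2: ref-linked read counts on haplotypes 1, 2
#' @param has_het logical; is there a phased het within the linkage window
#' @return one of `"pass"`, `"fail"`, `"unphasable"`
#' @examples
#' test_linkage(c(3, 0), c(0, 4))  # "pass"
#' test_linkage(c(2, 1), c(0, 4))  # "fail"
#' test_linkage(c(3, 0), c(2, 4))  # "fail"
#' @export
test_linkage <- function(c_alt, c_ref, has_het = TRUE) {
  if (!has_het || sum(c_alt) == 0) return("unphasable")
  if (all(c_alt > 0)) return("fail")
  h <- which(c_alt > 0)
  if (c_ref[h] == 0) "pass" else "fail"
}

# vectorized linkage status over an evidence table
linkage_status <- function(ev) {
  phasable <- !is.na(ev$het_pos) & (ev$c_alt_h1 + ev$c_alt_h2) > 0
  one_hap <- xor(ev$c_alt_h1 > 0, ev$c_alt_h2 > 0)
  ref_clean <- ifelse(ev$c_alt_h1 > 0, ev$c_ref_h1 == 0, ev$c_ref_h2 == 0)
  status <- rep("unphasable", nrow(ev))
  status[phasable & one_hap & ref_clean] <- "pass"
  status[phasable & !(one_hap & ref_clean)] <- "fail"
  status
}

#' Calibrate the phasable-read threshold for a target precision
#'
#' Chooses the smallest threshold `k` on phasable alternate reads such that
#' the posterior probability that a linkage-passing candidate with at least
#' `k` phasable alternate reads is a true somatic variant reaches the
#' precision target (default 0.90, the "more than 90% true positive rate"
#' control). The posterior is evaluated under a two-component mixture: true
#' variants carry binomial read support at the expected allele fraction and
#' depth; artifacts carry support from `error_model` (default geometric,
#' p = 0.5, support >= 1). Falls back to `k = 2` when no `k <= 10`
#' qualifies.
#'
#' @param prior_artifact_fraction prior fraction of artifact candidates
#'   among linkage-passing candidates, in `(0, 1)`
#' @param depth expected site depth
#' @param allele_fraction expected somatic allele fraction (1/ploidy x 2
#'   haplotypes: 0.5 for diploid, 0.25 for tetraploid)
#' @param error_model list with `type = "geometric"` and `p`
#' @param target_precision required posterior precision
#' @param k_max largest threshold considered
#' @return list of class `caller_model`: `threshold_k`,
#'   `estimated_precision` (posterior at the chosen k), plus the inputs
#' @export
calibrate_threshold <- function(prior_artifact_fraction = 0.5, depth = 30,
                                allele_fraction = 0.5,
                                error_model = list(type = "geometric", p = 0.5),
                                target_precision = 0.9, k_max = 10) {
  if (prior_artifact_fraction <= 0 || prior_artifact_fraction >= 1)
    stop_invalid("prior_artifact_fraction must be in (0, 1)")
  if (!identical(error_model$type, "geometric"))
    stop_invalid("unsupported error model type")
  if (error_model$p <= 0 || error_model$p > 1)
    stop_invalid("degenerate error model")
  surv_true <- function(k) pbinom(k - 1, size = round(depth),
                                  prob = allele_fraction, lower.tail = FALSE)
  surv_art <- function(k) (1 - error_model$p)^(k - 1)   # support >= 1
  post <- vapply(seq_len(k_max), function(k) {
    wt <- (1 - prior_artifact_fraction) * surv_true(k)
    wa <- prior_artifact_fraction * surv_art(k)
    if (wt + wa == 0) return(1)
    wt / (wt + wa)
  }, 0)
  ok <- which(post >= target_precision)
  k <- if (length(ok)) min(ok) else 2L
  structure(list(threshold_k = as.integer(k),
                 estimated_precision = post[[k]],
                 posterior = post,
                 depth = depth, allele_fraction = allele_fraction,
                 prior_artifact_fraction = prior_artifact_fraction,
                 error_model = error_model),
            class = "caller_model")
}

#' @export
print.caller_model <- function(x, ...) {
  cat(sprintf(
    "Linkage caller: k = %d phasable alt reads (posterior precision %.3f)\n",
    x$threshold_k, x$estimated_precision))
  if (!is.null(x$sensitivity))
    cat(sprintf("  germline-estimated sensitivity: %.3f\n", x$sensitivity))
  invisible(x)
}

#' Call somatic SNVs in one cell
#'
#' Candidate discovery takes any non-germline site with at least 2
#' alternate reads; calls are candidates that pass the complete-linkage
#' test with at least `threshold_k` phasable alternate reads.
#'
#' @param evidence the cell's evidence table
#' @param germline phased germline het table (sites excluded from calling)
#' @param model a `caller_model`
#' @return data.frame of calls (subset of evidence rows, plus
#'   `phasable_alt`)
#' @export
call_cell <- function(evidence, germline, model) {
  key_g <- paste(germline$chrom, germline$pos)
  cand <- evidence[!(paste(evidence$chrom, evidence$pos) %in% key_g) &
                     evidence$alt_reads >= 2, , drop = FALSE]
  if (!nrow(cand)) {
    cand$phasable_alt <- integer(0)
    return(cand)
  }
  status <- linkage_status(cand)
  phasable_alt <- cand$c_alt_h1 + cand$c_alt_h2
  calls <- cand[status == "pass" & phasable_alt >= model$threshold_k, ,
                drop = FALSE]
  calls$phasable_alt <- (calls$c_alt_h1 + calls$c_alt_h2)
  rownames(calls) <- NULL
  calls
}

#' Estimate calling sensitivity from germline hets
#'
#' Treats each phased germline het as a pseudo-somatic site on its known
#' haplotype and measures the fraction that survive the full calling rule
#' (candidate discovery, complete linkage against the next-nearest het, and
#' the phasable-read threshold). Optionally thins all read counts
#' binomially first, which is how the tetraploid per-haplotype depth factor
#' is measured.
#'
#' @param evidence the cell's evidence table (germline rows are used)
#' @param model a `caller_model`
#' @param thin binomial read-retention probability in `(0, 1]`
#' @param seed seed for the thinning draw
#' @return sensitivity in `[0, 1]`
#' @export
estimate_sensitivity <- function(evidence, model, thin = 1, seed = 1) {
  g <- evidence[evidence$kind == "germline", , drop = FALSE]
  if (nrow(g) < 100)
    warning("fewer than 100 germline hets; sensitivity estimate is noisy")
  if (!nrow(g)) stop_invalid("no germline sites in evidence")
  if (!any(!is.na(g$het_pos)))
    stop_invalid("no het pairs within the linkage window")
  cols <- c("depth", "ref_reads", "alt_reads",
            "c_ref_h1", "c_ref_h2", "c_alt_h1", "c_alt_h2")
  if (thin < 1) {
    with_seed(seed, {
      for (cc in cols) g[[cc]] <- rbinom(nrow(g), g[[cc]], thin)
    })
  }
  status <- linkage_status(g)
  phasable_alt <- g$c_alt_h1 + g$c_alt_h2
  mean(g$alt_reads >= 2 & status == "pass" &
         phasable_alt >= model$threshold_k)
}
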
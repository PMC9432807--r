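#' Expected number of deleterious somatic mutations per cell
#'
#' `n = n_snvs * del_fraction * p_ploidy`, where the ploidy factor captures
#' the probability of hitting the remaining alleles of a gene: 0.5 for
#' diploid and 0.125 for tetraploid genomes.
#'
#' @param n_snvs estimated genome-wide sSNVs in the cell
#' @param del_fraction deleterious fraction of variants
#' @param p_ploidy ploidy factor (0.5 diploid, 0.125 tetraploid)
#' @return expected deleterious mutation count (continuous)
#' @export
expected_deleterious <- function(n_snvs, del_fraction, p_ploidy) {
  if (any(n_snvs < 0) || any(del_fraction < 0) || any(del_fraction > 1) ||
      any(p_ploidy < 0))
    stop_invalid("inputs must be non-negative, del_fraction <= 1")
  n_snvs * del_fraction * p_ploidy
}

#' Ploidy factor for the KO model
#' @param ploidy 2 or 4
#' @return 0.5 for diploid, 0.125 for tetraploid
#' @export
ko_ploidy_factor <- function(ploidy) {
  if (!all(ploidy %in% c(2, 4))) stop_invalid("ploidy must be 2 or 4")
  ifelse(ploidy == 2, 0.5, 0.125)
}

#' Probability that a gene is knocked out
#'
#' `Pr(KO | pi, D, n) = pi * (1 - (1 - D)^n) + (1 - pi) * (1 - exp(-n D))`:
#' dosage-sensitive genes (fraction `pi`, pLI > 0.9, default 0.17) are
#' knocked out by a single deleterious hit; the remainder require the
#' Poisson-approximated chance of at least one hit on the gene. Continuous
#' `n` is allowed.
#'
#' @param pi fraction of dosage-sensitive (high-pLI) genes
#' @param D per-gene deleterious-mutation probability
#' @param n expected deleterious mutations (after the ploidy factor)
#' @return probability in `[0, 1]`, strictly increasing in `n` for `D > 0`
#' @examples
#' pr_ko(0, 0.01, 100)   # 1 - exp(-1)
#' @export
pr_ko <- function(pi, D, n) {
  if (any(pi < 0 | pi > 1) || any(D < 0 | D > 1) || any(n < 0))
    stop_invalid("pi, D in [0,1]; n >= 0")
  pi * (1 - (1 - D)^n) + (1 - pi) * (1 - exp(-n * D))
}

#' Cell-level probability of at least one knocked-out gene
#'
#' With per-gene KO probability `q = pr_ko(pi, D, n)`, the cell-level
#' probability is `1 - (1 - q)^g_eff`. The default `g_eff = 1` reads the
#' KO formula as already cell-level; `g_eff = n_genes` treats it per gene.
#'
#' @param pi,D,n as in [pr_ko()]
#' @param g_eff effective gene count
#' @return probability in `[0, 1]`
#' @export
cell_ko_probability <- function(pi, D, n, g_eff = 1) {
  if (any(g_eff < 1)) stop_invalid("g_eff must be >= 1")
  q <- pr_ko(pi, D, n)
  1 - (1 - q)^g_eff
}

#' Donor-level KO probability curves and ploidy comparison
#'
#' Maps per-cell corrected burdens to KO probabilities under both the
#' tetraploid model and a matched diploid model (diploid per-genome burden
#' taken as 50% of the tetraploid burden when no diploid cells are
#' supplied), aggregates mean and s.e.m. per donor, fits the exponential
#' trend `Pr ~ a * exp(b * age)` by log-linear least squares on donor
#' means (zero-probability donors excluded from the fit), and compares the
#' two ploidy models by a two-tailed paired Wilcoxon test across donors.
#'
#' @param burden data.frame with `donor_id`, `age`, `est_count` (per-cell
#'   genome-wide sSNVs of tetraploid cells)
#' @param del_fraction deleterious fraction (default 36/10407, the
#'   damaging-coding fraction among called sSNVs)
#' @param pi dosage-sensitive gene fraction (default 0.17)
#' @param D per-gene deleterious-mutation probability (default
#'   `1/n_genes`)
#' @param n_genes annotated gene count (default 20000)
#' @param g_eff effective gene count for [cell_ko_probability()]
#' @return list of class `ko_curve`: `donors` (donor, age, ploidy, mean,
#'   sem), `fits` (per-ploidy a, b), `wilcoxon_p`
#' @export
cohort_ko_curve <- function(burden, del_fraction = 36 / 10407, pi = 0.17,
                            D = NULL, n_genes = 20000, g_eff = 1) {
  if (is.null(D)) D <- 1 / n_genes
  b <- burden[!is.na(burden$est_count), , drop = FALSE]
  if (length(unique(b$donor_id)) < 3) stop_invalid("need >= 3 donors")
  skipped <- setdiff(unique(burden$donor_id), unique(b$donor_id))
  if (length(skipped))
    warning("donor(s) without usable cells skipped: ",
            paste(skipped, collapse = ", "))
  pr <- function(count, ploidy) {
    n <- expected_deleterious(count, del_fraction, ko_ploidy_factor(ploidy))
    cell_ko_probability(pi, D, n, g_eff)
  }
  b$pr_tetra <- pr(b$est_count, 4)
  b$pr_diplo <- pr(0.5 * b$est_count, 2)   # 50% of tetraploid burden
  agg <- function(col, lab) {
    m <- aggregate(b[[col]], list(donor_id = b$donor_id), mean)
    s <- aggregate(b[[col]], list(donor_id = b$donor_id),
                   function(x) sd(x) / sqrt(length(x)))
    a <- aggregate(b$age, list(donor_id = b$donor_id), mean)
    data.frame(donor_id = m$donor_id, age = a$x, ploidy = lab,
               mean = m$x, sem = s$x, stringsAsFactors = FALSE)
  }
  donors <- rbind(agg("pr_tetra", "tetraploid"), agg("pr_diplo", "diploid"))
  expfit <- function(d) {
    d <- d[d$mean > 0, , drop = FALSE]
    if (nrow(d) < 2) return(c(a = NA_real_, b = NA_real_))
    f <- lm(log(mean) ~ age, data = d)
    c(a = unname(exp(coef(f)[1])), b = unname(coef(f)[2]))
  }
  fits <- rbind(tetraploid = expfit(donors[donors$ploidy == "tetraploid", ]),
                diploid = expfit(donors[donors$ploidy == "diploid", ]))
  dt <- donors[donors$ploidy == "tetraploid", ]
  dd <- donors[donors$ploidy == "diploid", ]
  dd <- dd[match(dt$donor_id, dd$donor_id), ]
  wp <- if (all(dt$mean == dd$mean)) NA_real_ else
    suppressWarnings(wilcox.test(dd$mean, dt$mean, paired = TRUE)$p.value)
  structure(list(donors = donors, fits = fits, wilcoxon_p = wp,
                 params = list(del_fraction = del_fraction, pi = pi, D = D,
                               g_eff = g_eff)),
            class = "ko_curve")
}

#' @export
print.ko_curve <- function(x, ...) {
  cat("Gene-KO probability curves (per donor):\n")
  print(x$fits)
  cat(sprintf("Diploid vs tetraploid paired Wilcoxon p = %.3g\n",
              x$wilcoxon_p))
  invisible(x)
}
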
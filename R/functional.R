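#' Excess of a variant category relative to germline variants
#'
#' Two-sided Fisher's exact test on the 2x2 table of (in-category,
#' out-of-category) counts for somatic versus germline variants, with the
#' conditional-MLE odds ratio.
#'
#' @param somatic integer vector `c(in_category, out_of_category)`
#' @param germline integer vector `c(in_category, out_of_category)`
#' @return list with `odds_ratio` and `p`
#' @export
excess_test <- function(somatic, germline) {
  tab <- rbind(somatic, germline)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_invalid("all table margins must be positive")
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

# Wallenius noncentral hypergeometric pmf (log scale prefactor, adaptive
# quadrature after the t = s^D substitution). x successes from m1 weighted
# omega, n draws from m1 + m2.
dwallenius <- function(x, m1, m2, n, omega) {
  if (x < max(0, n - m2) || x > min(n, m1)) return(0)
  D <- omega * (m1 - x) + (m2 - (n - x))
  if (D <= 0) return(as.numeric(x == min(n, m1)))
  f <- function(s) exp(lchoose(m1, x) + lchoose(m2, n - x) + log(D) +
                         (D - 1) * log(s)) *
    (1 - s^omega)^x * (1 - s)^(n - x)
  val <- tryCatch(integrate(f, 0, 1, rel.tol = 1e-10,
                            subdivisions = 1000L)$value,
                  error = function(e) NA_real_)
  if (is.na(val)) {
    s <- seq(1e-9, 1 - 1e-9, length.out = 20001)
    val <- mean(f(s))
  }
  val
}

# upper-tail p over the full (renormalized) support
pwallenius_upper <- function(x, m1, m2, n, omega) {
  supp <- max(0, n - m2):min(n, m1)
  pmf <- vapply(supp, dwallenius, 0, m1 = m1, m2 = m2, n = n, omega = omega)
  pmf <- pmf / sum(pmf)
  sum(pmf[supp >= x])
}

#' Gene-length probability weighting function
#'
#' Fits the probability that a gene carries any sSNV as a monotone function
#' of log gene length (binned proportions joined by a monotone cubic
#' spline), mirroring length-bias correction in gene-set enrichment.
#'
#' @param hits named binary vector (1 = gene carries an sSNV)
#' @param lengths named gene lengths (bp), same genes
#' @param n_bins number of length bins
#' @return function mapping lengths to weights in (0, 1)
#' @export
length_weight_function <- function(hits, lengths, n_bins = 10) {
  ll <- log(lengths)
  br <- unique(quantile(ll, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) {
    # (near-)constant lengths carry no information: constant weight
    w0 <- min(max(mean(hits), 1e-6), 1 - 1e-6)
    return(function(l) rep(w0, length(l)))
  }
  bin <- cut(ll, br, include.lowest = TRUE, labels = FALSE)
  px <- tapply(ll, bin, mean)
  py <- tapply(hits, bin, mean)
  # enforce monotone non-decreasing bin means before the monotone spline
  py <- cummax(py)
  fun <- stats::splinefun(px, py, method = "monoH.FC")
  function(l) pmin(pmax(fun(log(l)), 1e-6), 1 - 1e-6)
}

#' Gene-set enrichment with gene-length bias correction
#'
#' Tests each gene set for over-representation of sSNV-carrying genes using
#' the Wallenius noncentral hypergeometric distribution, with per-set odds
#' equal to the ratio of mean gene weights inside versus outside the set.
#' Weights come from [length_weight_function()]. Sets with fewer than
#' `min_hits` sSNV-carrying members or more than `max_size` members are
#' excluded; genes absent from every set are removed from the universe.
#'
#' @param hits named binary vector over genes (1 = any sSNV in any cell)
#' @param sets named list of gene-id vectors
#' @param lengths named gene lengths
#' @param min_hits,max_size set filters (defaults 5 and 1000)
#' @param weights optional precomputed per-gene weights (skips the fit)
#' @return data.frame: set, size, hits_in_set, odds, p
#' @export
geneset_enrichment <- function(hits, sets, lengths, min_hits = 5,
                               max_size = 1000, weights = NULL) {
  universe <- intersect(names(hits), unique(unlist(sets)))
  if (!length(universe)) stop_invalid("empty gene universe")
  hits <- hits[universe]; lengths <- lengths[universe]
  if (is.null(weights)) {
    w_fun <- length_weight_function(hits, lengths)
    weights <- w_fun(lengths)
  } else weights <- weights[universe]
  names(weights) <- universe
  n <- sum(hits)
  out <- NULL
  for (s in names(sets)) {
    memb <- intersect(sets[[s]], universe)
    m1 <- length(memb)
    if (m1 > max_size || m1 == 0 || m1 == length(universe)) next
    x <- sum(hits[memb])
    if (x < min_hits) next
    omega <- mean(weights[memb]) / mean(weights[setdiff(universe, memb)])
    p <- pwallenius_upper(x, m1, length(universe) - m1, n, omega)
    out <- rbind(out, data.frame(set = s, size = m1, hits_in_set = x,
                                 odds = omega, p = p,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Association of sSNV density with gene-expression quartiles
#'
#' Assigns genes to quartiles of mean expression (ties to the lower
#' quartile), computes per-quartile sSNV densities normalized by total gene
#' length and mean per-cell detection power, and estimates the permutation
#' s.d. of each density by shuffling the quartile labels. When per-variant
#' classes are supplied, per-quartile 96-context profiles are refit against
#' a fixed signature set.
#'
#' @param variant_genes gene id of each variant (NA ignored)
#' @param expression named mean expression per gene
#' @param lengths named gene lengths
#' @param power mean per-cell detection sensitivity
#' @param n_perm permutation rounds for the s.d. (default 1000)
#' @param classes optional per-variant 96-class labels
#' @param fixed_signatures optional signature matrix for per-quartile refit
#' @param seed integer seed
#' @return data.frame: quartile, n_genes, n_variants, density, perm_sd,
#'   plus one weight column per signature when refitting
#' @export
quartile_association <- function(variant_genes, expression, lengths,
                                 power = 1, n_perm = 1000, classes = NULL,
                                 fixed_signatures = NULL, seed = 1) {
  genes <- names(expression)
  if (length(genes) < 40) stop_invalid("need >= 40 genes")
  if (length(unique(expression)) == 1)
    stop_invalid("all expression values equal; quartiles degenerate")
  br <- quantile(expression, probs = seq(0, 1, 0.25))
  q <- cut(expression, unique(br), include.lowest = TRUE, labels = FALSE)
  # ties spanning a break collapse to the lower quartile via unique breaks
  counts <- table(factor(variant_genes[!is.na(variant_genes)], levels = genes))
  counts <- as.vector(counts)
  dens <- function(qv) vapply(1:4, function(k) {
    i <- which(qv == k)
    sum(counts[i]) / (sum(lengths[genes][i]) * power)
  }, 0)
  obs <- dens(q)
  perm <- with_seed(seed, {
    replicate(n_perm, dens(sample(q)))
  })
  out <- data.frame(quartile = 1:4,
                    n_genes = as.vector(table(factor(q, levels = 1:4))),
                    n_variants = vapply(1:4, function(k)
                      sum(counts[q == k]), 0),
                    density = obs,
                    perm_sd = apply(perm, 1, sd))
  if (!is.null(classes) && !is.null(fixed_signatures)) {
    vq <- q[match(variant_genes, genes)]
    for (sig in colnames(fixed_signatures)) out[[sig]] <- NA_real_
    for (k in 1:4) {
      cl <- classes[!is.na(vq) & vq == k]
      if (length(cl) >= 1) {
        w <- refit_fixed(tabulate_contexts(cl), fixed_signatures)$weights
        for (sig in names(w)) out[out$quartile == k, sig] <- w[[sig]]
      }
    }
  }
  out
}

#' Cell-type-specific enrichment by rank-difference permutation
#'
#' Compares two cell types' gene-set enrichment rankings. Candidate sets
#' are those reaching `p < candidate_p` in either type. The observed
#' statistic per set is `rank_B - rank_A` (ranks of the enrichment
#' p-values among candidate sets; large values mean specific enrichment in
#' type A). The null is built by shuffling each type's sSNV-gene table
#' over genes and recomputing both rankings; the empirical p uses the
#' add-one estimator, followed by Benjamini-Hochberg FDR.
#'
#' @param hits_a,hits_b named binary sSNV-gene vectors for the two types
#' @param sets named list of gene sets
#' @param lengths named gene lengths
#' @param n_perm permutation rounds (default 1000; < 100 warns)
#' @param candidate_p candidate filter on either type's enrichment p
#' @param seed integer seed
#' @return data.frame: set, p_a, p_b, rank_diff, p_perm, fdr
#' @export
rank_difference_permutation <- function(hits_a, hits_b, sets, lengths,
                                        n_perm = 1000, candidate_p = 0.01,
                                        seed = 1) {
  if (n_perm < 100) warning("fewer than 100 permutation rounds")
  # the sparse-set filter is applied at the union level: a type-specific
  # set legitimately has few mutated members in the other type
  ea <- geneset_enrichment(hits_a, sets, lengths, min_hits = 0)
  eb <- geneset_enrichment(hits_b, sets, lengths, min_hits = 0)
  keep_a <- ea$set[ea$hits_in_set >= 5]
  keep_b <- eb$set[eb$hits_in_set >= 5]
  common <- intersect(ea$set, eb$set)
  common <- common[common %in% union(keep_a, keep_b)]
  if (!length(common))
    return(data.frame(set = character(), p_a = numeric(), p_b = numeric(),
                      rank_diff = numeric(), p_perm = numeric(),
                      fdr = numeric()))
  ea <- ea[match(common, ea$set), ]; eb <- eb[match(common, eb$set), ]
  # ranks computed over every set passing the enrichment filters; the
  # candidate filter only selects which sets are reported
  obs <- rank(eb$p) - rank(ea$p)
  cand <- which(ea$p < candidate_p | eb$p < candidate_p)
  if (!length(cand))
    return(data.frame(set = character(), p_a = numeric(), p_b = numeric(),
                      rank_diff = numeric(), p_perm = numeric(),
                      fdr = numeric()))
  universe <- intersect(names(hits_a), unique(unlist(sets)))
  prep <- function(hits) {
    h <- hits[universe]
    w <- length_weight_function(h, lengths[universe])(lengths[universe])
    list(h = as.numeric(h), w = setNames(w, universe), n = sum(h))
  }
  pa <- prep(hits_a); pb <- prep(hits_b)
  memb <- lapply(sets[common], intersect, universe)
  # Wallenius tails memoized per set and table: across shuffles only the
  # in-set hit count varies (totals are preserved), so each set needs its
  # pmf once
  tail_fun <- function(pp, mb) {
    m1 <- length(mb)
    omega <- mean(pp$w[mb]) / mean(pp$w[setdiff(universe, mb)])
    m2 <- length(universe) - m1
    supp <- max(0, pp$n - m2):min(pp$n, m1)
    pmf <- vapply(supp, dwallenius, 0, m1 = m1, m2 = m2, n = pp$n,
                  omega = omega)
    pmf <- pmf / sum(pmf)
    tails <- rev(cumsum(rev(pmf)))
    full <- rep(0, m1 + 1)
    full[supp + 1] <- tails
    if (supp[1] > 0) full[seq_len(supp[1])] <- 1
    full
  }
  tails_a <- lapply(memb, tail_fun, pp = pa)
  tails_b <- lapply(memb, tail_fun, pp = pb)
  idx <- lapply(memb, function(mb) match(mb, universe))
  null_ge <- rep(0L, length(common))
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ha <- sample(pa$h); hb <- sample(pb$h)
      p_a <- vapply(seq_along(common), function(s)
        tails_a[[s]][sum(ha[idx[[s]]]) + 1L], 0)
      p_b <- vapply(seq_along(common), function(s)
        tails_b[[s]][sum(hb[idx[[s]]]) + 1L], 0)
      stat <- rank(p_b) - rank(p_a)
      null_ge <- null_ge + (stat >= obs)
    }
  })
  p_perm <- (1 + null_ge) / (n_perm + 1)
  out <- data.frame(set = common, p_a = ea$p, p_b = eb$p, rank_diff = obs,
                    p_perm = p_perm, stringsAsFactors = FALSE)[cand, ]
  out$fdr <- p.adjust(out$p_perm, method = "BH")
  rownames(out) <- NULL
  out
}

#' Generate a synthetic expression matrix and gene sets
#'
#' Companion generators for the functional-impact analyses: log-normal
#' mean expression per gene and random gene-set memberships.
#'
#' @param models a `gene_models`
#' @param n_sets number of sets
#' @param set_size genes per set
#' @param seed integer seed
#' @return list with `expression` (named vector) and `sets` (named list)
#' @export
generate_expression_and_sets <- function(models, n_sets = 20, set_size = 30,
                                         seed = 1) {
  with_seed(seed, {
    genes <- models$genes$gene_id
    expr <- setNames(rlnorm(length(genes), meanlog = 3, sdlog = 1.2), genes)
    sets <- lapply(seq_len(n_sets), function(i)
      sample(genes, min(set_size, length(genes))))
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
    list(expression = expr, sets = sets)
  })
}
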
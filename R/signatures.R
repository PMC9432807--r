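#' Tabulate variant classes into a 96-context count vector
#'
#' @param classes character vector of classes (as from
#'   [trinucleotide_context()])
#' @return named integer vector of length 96 in [context_classes()] order
#' @export
tabulate_contexts <- function(classes) {
  cl <- context_classes()
  tab <- table(factor(classes, levels = cl))
  setNames(as.integer(tab), cl)
}

#' Build the cells x 96 context matrix for a set of per-cell calls
#'
#' @param call_list named list of per-cell call tables, each with a `class`
#'   column (or a character vector of classes)
#' @return integer matrix, rows = cells, 96 columns
#' @export
context_matrix <- function(call_list) {
  rows <- lapply(call_list, function(x)
    tabulate_contexts(if (is.data.frame(x)) x$class else x))
  m <- do.call(rbind, rows)
  rownames(m) <- names(call_list)
  m
}

#' Cosine similarity of two 96-context profiles
#'
#' @param a,b non-negative, non-zero numeric vectors of equal length
#' @return similarity in `[0, 1]`
#' @export
cosine_sim <- function(a, b) {
  if (sum(a) == 0 || sum(b) == 0) stop_invalid("zero vector")
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# one multiplicative-update NMF run (Frobenius objective)
nmf_run <- function(V, k, max_iter = 2000, tol = 1e-6) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * k, 0.1, 1), n, k)
  H <- matrix(runif(k * m, 0.1, 1), k, m)
  eps <- .Machine$double.eps
  rss_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      rss <- sum((V - W %*% H)^2)
      if (is.finite(rss_prev) && (rss_prev - rss) < tol * rss_prev) break
      rss_prev <- rss
    }
  }
  list(W = W, H = H, rss = sum((V - W %*% H)^2))
}

# cophenetic correlation of the consensus matrix over restarts
consensus_cophenetic <- function(memberships) {
  m <- length(memberships[[1]])
  C <- matrix(0, m, m)
  for (mb in memberships) C <- C + outer(mb, mb, "==")
  C <- C / length(memberships)
  d <- as.dist(1 - C)
  if (max(d) == 0) return(1)          # perfectly stable clustering
  hc <- hclust(d, method = "average")
  suppressWarnings(cc <- cor(cophenetic(hc), d))
  if (is.na(cc)) 1 else cc
}

#' De novo signature discovery by NMF with cophenetic rank selection
#'
#' Factorizes the cells x 96 count matrix with multiplicative-update NMF
#' (Frobenius loss), taking the best of `restarts` random initializations
#' per rank. Rank stability is scored by the cophenetic correlation of the
#' consensus clustering of cells (by dominant signature) across restarts;
#' the selected rank maximizes it, with ties broken toward the smaller
#' rank. Signatures are L1-normalized with exposures rescaled to
#' compensate.
#'
#' @param counts cells x 96 non-negative count matrix
#' @param rank_range integer ranks to evaluate (default `2:5`)
#' @param restarts random restarts per rank
#' @param max_iter,tol multiplicative-update stopping rule (relative RSS)
#' @param seed integer seed
#' @return list of class `signature_set`: `signatures` (K x 96,
#'   row-stochastic), `exposures` (cells x K), `rank`, `metrics`
#'   (per-rank cophenetic and RSS)
#' @export
nmf_decompose <- function(counts, rank_range = 2:5, restarts = 30,
                          max_iter = 2000, tol = 1e-6, seed = 1) {
  V <- t(as.matrix(counts))            # 96 x cells
  if (all(V == 0)) stop_invalid("all-zero context matrix")
  if (sum(rowSums(as.matrix(counts)) >= 50) < 2)
    warning("fewer than 2 cells with >= 50 mutations; NMF may be unstable")
  rank_range <- rank_range[rank_range < ncol(V)]
  best <- list(); metrics <- NULL
  with_seed(seed, {
    for (k in rank_range) {
      runs <- lapply(seq_len(restarts), function(r)
        nmf_run(V, k, max_iter, tol))
      rss <- vapply(runs, `[[`, 0, "rss")
      memb <- lapply(runs, function(x) apply(x$H, 2, which.max))
      coph <- consensus_cophenetic(memb)
      metrics <- rbind(metrics, data.frame(rank = k, cophenetic = coph,
                                           rss = min(rss)))
      best[[as.character(k)]] <- runs[[which.min(rss)]]
    }
    sel <- metrics$rank[which.max(metrics$cophenetic)]  # ties -> smaller rank
    fit <- best[[as.character(sel)]]
    scale <- rowSums(t(fit$W))          # L1 norm per signature
    S <- t(fit$W) / scale               # K x 96, rows sum to 1
    E <- t(fit$H) * rep(scale, each = ncol(fit$H))
    colnames(S) <- context_classes()
    rownames(S) <- paste0("S", seq_len(sel))
    dimnames(E) <- list(rownames(counts), rownames(S))
    structure(list(signatures = S, exposures = E, rank = sel,
                   metrics = metrics),
              class = "signature_set")
  })
}

#' @export
print.signature_set <- function(x, ...) {
  cat("NMF signature set: rank", x$rank, "selected by cophenetic criterion\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Match discovered signatures to references by optimal assignment
#'
#' Maximizes total cosine similarity over one-to-one assignments
#' (exhaustive over permutations; intended for small K).
#'
#' @param discovered K x 96 matrix (rows = signatures)
#' @param reference 96 x R reference matrix (columns = signatures)
#' @return data.frame with `discovered`, `reference`, `cosine`
#' @export
match_signatures <- function(discovered, reference) {
  K <- nrow(discovered); R <- ncol(reference)
  cs <- outer(seq_len(K), seq_len(R), Vectorize(function(i, j)
    cosine_sim(discovered[i, ], reference[, j])))
  k <- min(K, R)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  if (K <= R) {
    cand <- perms(seq_len(R))
    sc <- vapply(cand, function(p) sum(cs[cbind(seq_len(K), p[seq_len(K)])]), 0)
    p <- cand[[which.max(sc)]][seq_len(K)]
    data.frame(discovered = rownames(discovered) %||% paste0("S", seq_len(K)),
               reference = colnames(reference)[p],
               cosine = cs[cbind(seq_len(K), p)])
  } else {
    cand <- perms(seq_len(K))
    sc <- vapply(cand, function(p) sum(cs[cbind(p[seq_len(R)], seq_len(R))]), 0)
    p <- cand[[which.max(sc)]][seq_len(R)]
    data.frame(discovered = (rownames(discovered) %||% paste0("S", seq_len(K)))[p],
               reference = colnames(reference),
               cosine = cs[cbind(p, seq_len(R))])
  }
}

#' Refit a 96-context profile against fixed signatures
#'
#' Non-negative least-squares fit of the L1-normalized profile on the
#' signature rows; weights are renormalized to sum to 1.
#'
#' @param profile 96-vector of counts (or proportions)
#' @param fixed_signatures 96 x K matrix (columns sum to 1) or K x 96
#' @return list with `weights` (named, sum 1) and `residual` (L2 norm of
#'   the fit residual)
#' @export
refit_fixed <- function(profile, fixed_signatures) {
  S <- as.matrix(fixed_signatures)
  if (nrow(S) != 96 && ncol(S) == 96) S <- t(S)
  if (nrow(S) != 96) stop_invalid("signatures must have a 96-context axis")
  if (ncol(S) == 0) stop_invalid("need at least one fixed signature")
  if (sum(profile) == 0) stop_invalid("empty profile")
  b <- profile / sum(profile)
  fit <- pracma::lsqnonneg(S, as.vector(b))
  w <- fit$x
  if (sum(w) == 0) w <- rep(1 / ncol(S), ncol(S))
  res <- sqrt(sum((S %*% w - b)^2))
  list(weights = setNames(w / sum(w), colnames(S)), residual = res)
}

#' Signature-specific sSNV densities for one cell
#'
#' Splits a cell's overall density across signatures in proportion to the
#' refit weights; the per-signature densities sum to the input density.
#'
#' @param density overall sSNV per Mb
#' @param weights named non-negative weights summing to 1
#' @return named numeric vector of per-signature densities
#' @export
signature_density <- function(density, weights) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop_invalid("weights must sum to 1")
  density * weights
}
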
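#' MDA amplification parameters
#'
#' Bundles the parameters of the whole-genome-amplification model used by
#' [simulate_amplification()]. A site is locus-dropped (no copy amplifies)
#' with probability `locus_dropout_rate`; each surviving haplotype copy is
#' independently allele-dropped with probability `allelic_dropout_rate`.
#' Surviving copies receive negative-binomial read counts whose mean is
#' modulated by a per-100-kb log-normal amplification factor
#' (`unevenness_sigma` on the log scale, mean 1). MDA C>T artifacts are
#' injected at `artifact_rate_per_mb` per Mb of amplified DNA on a single
#' haplotype, with geometric (p = 0.5) read support, so that the caller's
#' read-threshold calibration has discriminating signal.
#'
#' @param locus_dropout_rate probability in `[0, 1]`
#' @param allelic_dropout_rate probability in `[0, 1]`
#' @param mean_depth total mean depth at a diploid site (reads)
#' @param depth_dispersion negative-binomial size parameter per copy
#' @param unevenness_sigma log-scale s.d. of the per-bin amplification factor
#' @param artifact_rate_per_mb artifacts per Mb of amplified (haploid) DNA
#' @param artifact_profile 96-vector over [context_classes()], non-negative,
#'   concentrated on C>T classes; defaults to the shipped `scF_like` fixture
#' @param linkage_window bp window for read-pair linkage to a phased het
#' @return a list of class `amp_params`
#' @export
amplification_params <- function(locus_dropout_rate = 0.1,
                                 allelic_dropout_rate = 0.1,
                                 mean_depth = 30,
                                 depth_dispersion = 5,
                                 unevenness_sigma = 0.3,
                                 artifact_rate_per_mb = 1.0,
                                 artifact_profile = NULL,
                                 linkage_window = 500) {
  if (locus_dropout_rate < 0 || locus_dropout_rate > 1 ||
      allelic_dropout_rate < 0 || allelic_dropout_rate > 1)
    stop_invalid("dropout rates must be probabilities in [0, 1]")
  if (mean_depth <= 0 || depth_dispersion <= 0)
    stop_invalid("mean_depth and depth_dispersion must be > 0")
  if (unevenness_sigma < 0) stop_invalid("unevenness_sigma must be >= 0")
  if (artifact_rate_per_mb < 0) stop_invalid("artifact_rate_per_mb must be >= 0")
  if (is.null(artifact_profile))
    artifact_profile <- reference_signatures("scF_like")[, 1]
  if (any(artifact_profile < 0) || sum(artifact_profile) <= 0)
    stop_invalid("artifact_profile must be non-negative with positive mass")
  artifact_profile <- artifact_profile / sum(artifact_profile)
  structure(list(locus_dropout_rate = locus_dropout_rate,
                 allelic_dropout_rate = allelic_dropout_rate,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 unevenness_sigma = unevenness_sigma,
                 artifact_rate_per_mb = artifact_rate_per_mb,
                 artifact_profile = artifact_profile,
                 linkage_window = linkage_window),
            class = "amp_params")
}

BIN_BP <- 1e5L      # amplification-unevenness bin size
READ_LEN <- 150L    # nominal read length for bin read-count scaling

# nearest phased germline het within the window, excluding the site itself;
# equidistant ties break to the lower coordinate
nearest_het <- function(chrom, pos, germline, window) {
  het_pos_out <- rep(NA_integer_, length(pos))
  het_hap_out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    h <- germline[germline$chrom == ch, , drop = FALSE]
    if (!nrow(h)) next
    H <- h$pos
    idx <- findInterval(pos[qi], H)
    self <- idx >= 1 & idx <= length(H)
    self[self] <- H[idx[self]] == pos[qi][self]
    li <- ifelse(self, idx - 1L, idx)
    ri <- idx + 1L
    ld <- ifelse(li >= 1, pos[qi] - H[pmax(li, 1L)], Inf)
    rd <- ifelse(ri <= length(H), H[pmin(ri, length(H))] - pos[qi], Inf)
    pick_left <- ld <= rd & ld <= window       # tie -> lower coordinate
    pick_right <- !pick_left & rd <= window
    het_pos_out[qi[pick_left]] <- H[li[pick_left]]
    het_hap_out[qi[pick_left]] <- h$hap[li[pick_left]]
    het_pos_out[qi[pick_right]] <- H[ri[pick_right]]
    het_hap_out[qi[pick_right]] <- h$hap[ri[pick_right]]
  }
  list(pos = het_pos_out, hap = het_hap_out)
}

.bin_gc_cache <- new.env(parent = emptyenv())

bin_gc <- function(ref) {
  key <- paste(c(names(ref$seq), ref$lengths,
                 substr(ref$seq, 1, 64)), collapse = "|")
  if (!is.null(.bin_gc_cache[[key]])) return(.bin_gc_cache[[key]])
  out <- lapply(names(ref$seq), function(ch) {
    L <- ref$lengths[[ch]]
    starts <- seq(1L, L, by = BIN_BP)
    ends <- pmin(starts + BIN_BP - 1L, L)
    dna <- Biostrings::DNAString(ref$seq[[ch]])
    v <- Biostrings::Views(dna, start = starts, end = ends)
    gc <- as.vector(Biostrings::letterFrequency(v, "GC", as.prob = TRUE))
    data.frame(chrom = ch, bin = seq_along(starts), start = starts,
               end = ends, gc = gc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  .bin_gc_cache[[key]] <- res
  res
}

# draw MDA artifact sites for one diploid amplification realization
draw_artifacts <- function(params, ref, exclude, seed) {
  with_seed(seed, {
    n <- rpois(1, params$artifact_rate_per_mb * 2 * total_mb(ref))
    if (n == 0)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        hap = integer(), class = character(),
                        art_reads = integer()))
    cls <- sample(context_classes(), n, replace = TRUE,
                  prob = params$artifact_profile)
    sites <- sample_positions_for_classes(cls, ref, exclude = exclude)
    sites$hap <- sample(1:2, n, replace = TRUE)
    sites$class <- cls
    sites$art_reads <- rgeom(n, 0.5) + 1L     # support >= 1, mean 2
    sites
  })
}

#' Simulate MDA amplification evidence for one diploid realization
#'
#' Applies the locus/allelic dropout and uneven-depth model to a truth set
#' (phased germline hets plus this realization's somatic variants), injects
#' MDA artifacts, and emits the per-site evidence table used by all
#' downstream stages together with binned coverage for evenness QC.
#'
#' The evidence table cross-tabulates linked reads by (site allele x donor
#' haplotype): `c_ref_h1`, `c_ref_h2`, `c_alt_h1`, `c_alt_h2` count reads
#' jointly covering the site and its nearest phased het within the linkage
#' window. Hidden truth columns (`kind`, `hap`, `locus_dropped`, ...) are
#' retained for validation only and are not part of the user contract.
#'
#' @param truth list with elements `germline` (from [generate_germline()])
#'   and `somatic` (from [generate_somatic()]; may be empty)
#' @param params an `amp_params` object
#' @param ref the `ref_genome`
#' @param seed integer seed
#' @param artifacts optional pre-drawn artifact table (internal, used for
#'   tetraploid cross-coverage); if `NULL` artifacts are drawn here
#' @param cross_sites optional data.frame of positions carried by the sister
#'   realization (`chrom`, `pos`, `ref`, `alt`); this realization contributes
#'   reference reads there
#' @return list with `evidence` (data.frame) and `bins` (data.frame of
#'   per-100-kb observed/expected read counts and GC)
#' @export
simulate_amplification <- function(truth, params, ref, seed = 1,
                                   artifacts = NULL, cross_sites = NULL) {
  germline <- truth$germline
  somatic <- truth$somatic
  if (is.null(artifacts))
    artifacts <- draw_artifacts(params, ref,
                                exclude = rbind(germline[c("chrom", "pos")],
                                                somatic[c("chrom", "pos")]),
                                seed = child_seed(seed, 7L))
  mk <- function(df, kind) {
    if (is.null(df) || !nrow(df))
      return(NULL)
    data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               kind = kind,
               hap = if (!is.null(df$hap)) df$hap else NA_integer_,
               class = if (!is.null(df$class)) df$class else NA_character_,
               art_reads = if (!is.null(df$art_reads)) df$art_reads else 0L,
               stringsAsFactors = FALSE)
  }
  sites <- rbind(mk(germline, "germline"), mk(somatic, "somatic"),
                 mk(artifacts, "artifact"), mk(cross_sites, "cross"))
  gcb <- bin_gc(ref)
  with_seed(child_seed(seed, 11L), {
    # per-bin log-normal amplification factors, mean 1
    s <- params$unevenness_sigma
    gcb$factor <- rlnorm(nrow(gcb), -s^2 / 2, s)
    nominal <- params$mean_depth * (gcb$end - gcb$start + 1) / READ_LEN
    gcb$expected_reads <- nominal
    gcb$observed_reads <- rnbinom(nrow(gcb), mu = gcb$factor * nominal,
                                  size = 200)
    if (is.null(sites)) {
      ev <- data.frame(chrom = character(), pos = integer(), ref = character(),
                       alt = character(), depth = integer(),
                       ref_reads = integer(), alt_reads = integer(),
                       het_pos = integer(), het_hap = integer(),
                       c_ref_h1 = integer(), c_ref_h2 = integer(),
                       c_alt_h1 = integer(), c_alt_h2 = integer(),
                       kind = character(), hap = integer(), class = character(),
                       locus_dropped = logical())
      return(list(evidence = ev, bins = gcb))
    }
    n <- nrow(sites)
    key <- paste(sites$chrom, (sites$pos - 1L) %/% BIN_BP + 1L)
    fac <- gcb$factor[match(key, paste(gcb$chrom, gcb$bin))]
    ld <- runif(n) < params$locus_dropout_rate
    ad1 <- runif(n) < params$allelic_dropout_rate
    ad2 <- runif(n) < params$allelic_dropout_rate
    mu <- params$mean_depth / 2 * fac
    reads1 <- ifelse(ld | ad1, 0L,
                     rnbinom(n, mu = mu, size = params$depth_dispersion))
    reads2 <- ifelse(ld | ad2, 0L,
                     rnbinom(n, mu = mu, size = params$depth_dispersion))
    # allele carried by each haplotype copy at each site
    alt_on_1 <- sites$kind %in% c("germline", "somatic") & sites$hap == 1L
    alt_on_2 <- sites$kind %in% c("germline", "somatic") & sites$hap == 2L
    art1 <- ifelse(sites$kind == "artifact" & sites$hap == 1L,
                   sites$art_reads, 0L)
    art2 <- ifelse(sites$kind == "artifact" & sites$hap == 2L,
                   sites$art_reads, 0L)
    alt_h1 <- ifelse(alt_on_1, reads1, 0L) + art1
    alt_h2 <- ifelse(alt_on_2, reads2, 0L) + art2
    ref_h1 <- ifelse(alt_on_1, 0L, reads1)
    ref_h2 <- ifelse(alt_on_2, 0L, reads2)
    nh <- nearest_het(sites$chrom, sites$pos, germline,
                      params$linkage_window)
    linked <- !is.na(nh$pos)
    ev <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                     alt = sites$alt,
                     depth = ref_h1 + ref_h2 + alt_h1 + alt_h2,
                     ref_reads = ref_h1 + ref_h2,
                     alt_reads = alt_h1 + alt_h2,
                     het_pos = nh$pos, het_hap = nh$hap,
                     c_ref_h1 = ifelse(linked, ref_h1, 0L),
                     c_ref_h2 = ifelse(linked, ref_h2, 0L),
                     c_alt_h1 = ifelse(linked, alt_h1, 0L),
                     c_alt_h2 = ifelse(linked, alt_h2, 0L),
                     kind = sites$kind, hap = sites$hap, class = sites$class,
                     locus_dropped = ld, stringsAsFactors = FALSE)
    ev <- ev[order(ev$chrom, ev$pos), ]
    rownames(ev) <- NULL
    list(evidence = ev, bins = gcb)
  })
}

#' Merge two diploid amplification realizations into a tetraploid cell
#'
#' Models a tetraploid nucleus as the in-silico mixture of two independent
#' diploid amplification realizations that share the same phased germline:
#' read counts (including linkage counts) are summed site-wise. The hidden
#' truth locus-dropout flag of the merged cell is true only when both
#' realizations dropped the locus.
#'
#' @param a,b results of [simulate_amplification()] sharing the same germline
#' @return list with merged `evidence` and `bins`
#' @export
make_tetraploid <- function(a, b) {
  ea <- a$evidence; eb <- b$evidence
  ga <- ea[ea$kind == "germline", c("chrom", "pos")]
  gb <- eb[eb$kind == "germline", c("chrom", "pos")]
  if (!identical(paste(ga$chrom, ga$pos), paste(gb$chrom, gb$pos)))
    stop_invalid("realizations do not share the same germline truth")
  key_a <- paste(ea$chrom, ea$pos)
  key_b <- paste(eb$chrom, eb$pos)
  keys <- union(key_a, key_b)
  ia <- match(keys, key_a)
  ib <- match(keys, key_b)
  cnt_cols <- c("depth", "ref_reads", "alt_reads",
                "c_ref_h1", "c_ref_h2", "c_alt_h1", "c_alt_h2")
  take <- function(df, idx, col, default) {
    v <- df[[col]][idx]
    v[is.na(idx)] <- default
    v
  }
  # a site that is a variant in one realization and cross-coverage in the
  # other keeps its variant identity
  rank_kind <- c(germline = 1, somatic = 2, artifact = 3, cross = 4)
  ka <- take(ea, ia, "kind", "cross"); kb <- take(eb, ib, "kind", "cross")
  use_a <- is.na(ib) | (!is.na(ia) & rank_kind[ka] <= rank_kind[kb])
  pick_df <- function(col) ifelse(use_a, ea[[col]][ia], eb[[col]][ib])
  out <- data.frame(chrom = pick_df("chrom"), pos = pick_df("pos"),
                    ref = pick_df("ref"), alt = pick_df("alt"),
                    stringsAsFactors = FALSE)
  for (cc in cnt_cols)
    out[[cc]] <- take(ea, ia, cc, 0L) + take(eb, ib, cc, 0L)
  out$het_pos <- pick_df("het_pos"); out$het_hap <- pick_df("het_hap")
  for (cc in c("kind", "hap", "class"))
    out[[cc]] <- pick_df(cc)
  out$locus_dropped <- take(ea, ia, "locus_dropped", TRUE) &
    take(eb, ib, "locus_dropped", TRUE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  bins <- a$bins
  bins$observed_reads <- a$bins$observed_reads + b$bins$observed_reads
  bins$expected_reads <- a$bins$expected_reads + b$bins$expected_reads
  bins$factor <- (a$bins$factor + b$bins$factor) / 2
  list(evidence = out, bins = bins)
}

#' Simulate one single-cell WGS amplification
#'
#' Generates the somatic truth for one nucleus and pushes it through the MDA
#' amplification model. Diploid cells are one amplification realization at
#' the full configured depth; tetraploid cells are two independent diploid
#' realizations at half depth each, merged with [make_tetraploid()], with
#' somatic variants assigned to one origin copy (1/4 allele fraction).
#'
#' @param ref a `ref_genome`
#' @param germline shared phased germline het table
#' @param age donor age (years)
#' @param ploidy 2 or 4
#' @param rate_per_mb_per_year,intercept_per_mb,signature_mix somatic truth
#'   model, see [generate_somatic()]
#' @param params an `amp_params` object (depth interpreted as total cell depth)
#' @param seed integer seed
#' @return list with `evidence`, `bins`, `truth` (somatic truth table) and
#'   `meta` (age, ploidy)
#' @export
simulate_cell <- function(ref, germline, age, ploidy = 2,
                          rate_per_mb_per_year = 0.010,
                          intercept_per_mb = 0.1,
                          signature_mix = c(SBS5_like = 0.6,
                                            SBS44_like = 0.25,
                                            SBS18_like = 0.15),
                          params = amplification_params(), seed = 1) {
  somatic <- generate_somatic(ref, age, rate_per_mb_per_year,
                              intercept_per_mb, ploidy, signature_mix,
                              germline = germline,
                              seed = child_seed(seed, 1L))
  if (ploidy == 2) {
    sim <- simulate_amplification(list(germline = germline, somatic = somatic),
                                  params, ref, seed = child_seed(seed, 2L))
  } else {
    half <- params
    half$mean_depth <- params$mean_depth / 2
    exclude <- rbind(germline[c("chrom", "pos")], somatic[c("chrom", "pos")])
    art1 <- draw_artifacts(half, ref, exclude, child_seed(seed, 3L))
    art2 <- draw_artifacts(half, ref,
                           rbind(exclude, art1[c("chrom", "pos")]),
                           child_seed(seed, 4L))
    som1 <- somatic[somatic$origin_copy == 1L, , drop = FALSE]
    som2 <- somatic[somatic$origin_copy == 2L, , drop = FALSE]
    cross_for <- function(som_other, art_other)
      rbind(som_other[c("chrom", "pos", "ref", "alt")],
            art_other[c("chrom", "pos", "ref", "alt")])
    r1 <- simulate_amplification(list(germline = germline, somatic = som1),
                                 half, ref, seed = child_seed(seed, 5L),
                                 artifacts = art1,
                                 cross_sites = cross_for(som2, art2))
    r2 <- simulate_amplification(list(germline = germline, somatic = som2),
                                 half, ref, seed = child_seed(seed, 6L),
                                 artifacts = art2,
                                 cross_sites = cross_for(som1, art1))
    sim <- make_tetraploid(r1, r2)
  }
  list(evidence = sim$evidence, bins = sim$bins, truth = somatic,
       meta = list(age = age, ploidy = ploidy))
}

#' Default donor panel
#'
#' Twelve donors spanning infancy to old age (0.4-82.2 years), the default
#' age design of synthetic cohorts.
#'
#' @return data.frame with `donor_id` and `age`
#' @export
default_donors <- function() {
  data.frame(donor_id = paste0("D", sprintf("%02d", 1:12)),
             age = c(0.4, 2, 4, 30, 35, 39, 49.2, 63, 66, 75, 75.3, 82.2))
}

#' Per-cell-type default somatic accumulation rates
#'
#' Default age slopes (sSNV per Mb of DNA per year) for the four configured
#' cell types: cardiomyocyte 0.010, neuron 0.003, hepatocyte 0.009,
#' lymphocyte 0.004.
#'
#' @return named numeric vector
#' @export
cell_type_rates <- function() {
  c(cardiomyocyte = 0.010, neuron = 0.003,
    hepatocyte = 0.009, lymphocyte = 0.004)
}

#' Simulate a synthetic single-cell WGS cohort
#'
#' Generates the full study design: a shared phased germline per donor-free
#' reference, then per-cell somatic truth and amplification evidence.
#'
#' @param ref a `ref_genome`
#' @param donors data.frame with `donor_id` and `age`; defaults to
#'   [default_donors()]
#' @param cells_per_donor cells per donor
#' @param cell_type one of `names(cell_type_rates())`; sets the default rate
#' @param ploidy 2 or 4
#' @param rate_per_mb_per_year age slope; defaults to the cell type's rate
#' @param intercept_per_mb burden at age 0
#' @param signature_mix somatic signature mixture
#' @param params an `amp_params`
#' @param het_density germline hets per kb
#' @param seed integer seed
#' @return list with `cells` (list of [simulate_cell()] results), `meta`
#'   (data.frame: cell_id, donor_id, age, cell_type, ploidy), `germline`,
#'   and `ref`
#' @export
simulate_cohort <- function(ref, donors = default_donors(),
                            cells_per_donor = 4,
                            cell_type = "cardiomyocyte", ploidy = 4,
                            rate_per_mb_per_year = NULL,
                            intercept_per_mb = 0.1,
                            signature_mix = c(SBS5_like = 0.6,
                                              SBS44_like = 0.25,
                                              SBS18_like = 0.15),
                            params = amplification_params(),
                            het_density = 0.67, seed = 1) {
  if (is.null(rate_per_mb_per_year)) {
    if (!cell_type %in% names(cell_type_rates()))
      stop_invalid("unknown cell type: ", cell_type)
    rate_per_mb_per_year <- cell_type_rates()[[cell_type]]
  }
  germline <- generate_germline(ref, het_density, seed = child_seed(seed, 99L))
  cells <- list(); meta <- NULL
  k <- 0L
  for (j in seq_len(nrow(donors))) {
    for (i in seq_len(cells_per_donor)) {
      k <- k + 1L
      cell_id <- sprintf("%s_%s_c%d", donors$donor_id[j], cell_type, i)
      cells[[cell_id]] <- simulate_cell(
        ref, germline, donors$age[j], ploidy,
        rate_per_mb_per_year, intercept_per_mb, signature_mix, params,
        seed = child_seed(seed, k))
      meta <- rbind(meta, data.frame(cell_id = cell_id,
                                     donor_id = donors$donor_id[j],
                                     age = donors$age[j],
                                     cell_type = cell_type, ploidy = ploidy,
                                     stringsAsFactors = FALSE))
    }
  }
  list(cells = cells, meta = meta, germline = germline, ref = ref)
}
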
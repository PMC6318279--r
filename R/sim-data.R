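#' Generate the informative-SNP table of a synthetic hybrid chromosome
#'
#' SNP positions are a Poisson sample at the configured density (duplicates
#' dropped), emulating the strain-distinguishing SNP resource used to
#' partition reads between parental genomes. Each SNP carries two distinct
#' allele symbols, one per haplotype.
#'
#' @param config A [sim_config()] object.
#' @return A `snp_table` data frame with columns `chrom`, `pos` (0-based),
#'   `allele_hap1`, `allele_hap2`, sorted by position.
#' @export
generate_snp_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  expected <- config$snp_density * config$chrom_length
  if (expected < 1)
    stop("snp_density * chrom_length must be >= 1", call. = FALSE)
  sim_seed(config, 1L)
  n <- stats::rpois(1, expected)
  pos <- sort(unique(sample.int(config$chrom_length, n) - 1L))
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, length(pos), replace = TRUE)
  shift <- sample.int(3, length(pos), replace = TRUE)
  a2 <- bases[(match(a1, bases) - 1L + shift) %% 4L + 1L]
  snp_table(data.frame(chrom = config$chrom, pos = pos,
                       allele_hap1 = a1, allele_hap2 = a2,
                       stringsAsFactors = FALSE))
}

#' Construct / validate a SNP table
#'
#' @param df Data frame with columns `chrom`, `pos`, `allele_hap1`,
#'   `allele_hap2`.
#' @return The validated data frame with class `snp_table`.
#' @export
snp_table <- function(df) {
  need <- c("chrom", "pos", "allele_hap1", "allele_hap2")
  if (!all(need %in% names(df)))
    stop("snp table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(df$pos)) df <- df[order(df$pos), , drop = FALSE]
  if (any(df$allele_hap1 == df$allele_hap2))
    stop("alleles must differ at every SNP", call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Simulate reads from a diploid chromosome
#'
#' Read start positions are drawn proportional to a per-bin weight track
#' (per haplotype if `weights` is a two-element list); each read records
#' the allele of its true haplotype at every SNP it covers, flipped to the
#' other haplotype's allele with probability `config$base_error_rate`.
#' The true origin is returned separately from the read records so that
#' analysis code can never see it.
#'
#' @param config A [sim_config()] object.
#' @param snps A `snp_table`.
#' @param n_reads Number of reads.
#' @param weights Per-bin sampling rates: a numeric vector shared by both
#'   haplotypes, or `list(hap1 =, hap2 =)` vectors. `NULL` for uniform.
#' @param weights_bin Bin size (bp) of the weight track.
#' @param hap1_fraction Marginal probability a read originates from
#'   haplotype 1 (applied on top of the weight tracks).
#' @param seed_offset Offset added to the config seed for this draw, so
#'   different libraries from one config are independent yet reproducible.
#' @return A list with `reads` (data frame: `chrom`, `start`, `end`,
#'   `snp_obs` encoded `pos:base;...`) and `truth` (character vector of
#'   `"hap1"`/`"hap2"`, same order).
#' @export
simulate_reads <- function(config, snps, n_reads,
                           weights = NULL,
                           weights_bin = config$chip_coarse_bin,
                           hap1_fraction = 0.5,
                           seed_offset = 2L) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chrom_length
  n_bins <- ceiling(L / weights_bin)
  if (is.null(weights)) weights <- rep(1, n_bins)
  if (!is.list(weights)) weights <- list(hap1 = weights, hap2 = weights)
  w1 <- weights$hap1; w2 <- weights$hap2
  if (length(w1) != n_bins || length(w2) != n_bins)
    stop("weights must have one value per bin of the chromosome",
         call. = FALSE)
  if (any(w1 < 0) || any(w2 < 0))
    stop("weights must be non-negative", call. = FALSE)
  rates <- c(w1 * hap1_fraction, w2 * (1 - hap1_fraction))
  if (sum(rates) <= 0) stop("all weights are zero", call. = FALSE)
  sim_seed(config, seed_offset)

  cell <- sample.int(2L * n_bins, n_reads, replace = TRUE, prob = rates)
  hap <- ifelse(cell > n_bins, "hap2", "hap1")
  bin <- (cell - 1L) %% n_bins
  bin_lo <- bin * weights_bin
  bin_hi <- pmin(bin_lo + weights_bin, L)
  start <- bin_lo + floor(stats::runif(n_reads) * (bin_hi - bin_lo))
  start <- pmin(start, L - config$read_length)
  start <- pmax(start, 0)
  end <- start + config$read_length

  # SNPs covered per read: [start, end) on the sorted SNP positions
  lo <- findInterval(start - 0.5, snps$pos) + 1L
  hi <- findInterval(end - 0.5, snps$pos)
  nsnp <- pmax(hi - lo + 1L, 0L)
  obs <- character(n_reads)
  has <- which(nsnp > 0L)
  if (length(has)) {
    ridx <- rep.int(has, nsnp[has])
    sidx <- sequence(nsnp[has], from = lo[has])
    err <- stats::runif(length(sidx)) < config$base_error_rate
    from_h1 <- xor(hap[ridx] == "hap1", err)
    base <- ifelse(from_h1, snps$allele_hap1[sidx], snps$allele_hap2[sidx])
    tok <- paste0(snps$pos[sidx], ":", base)
    obs[has] <- vapply(unname(split(tok, factor(ridx, levels = has))),
                       paste, character(1), collapse = ";")
  }
  list(reads = data.frame(chrom = config$chrom, start = start, end = end,
                          snp_obs = obs, stringsAsFactors = FALSE),
       truth = hap)
}

#' Simulate allele-specific CpG methylation calls
#'
#' CpG sites are laid down at a fixed density; each site's methylated read
#' count is Binomial(coverage, planted %), with the planted percentage
#' taken from the overlapping domain's `meth_percent` (hypermethylation in
#' derepression domains) or `baseline_percent` elsewhere (the
#' chromosome-wide Xi hypomethylation baseline).
#'
#' @param config A [sim_config()] object.
#' @param domains Data frame of domains with `start`, `end`,
#'   `meth_percent`; `NULL` uses `config$planted_domains`, an empty data
#'   frame plants none.
#' @param baseline_percent Methylation % outside domains.
#' @param site_density Expected CpG sites per bp.
#' @param seed_offset See [simulate_reads()].
#' @return Data frame: `chrom`, `pos`, `meth_count`, `total_count`.
#' @export
simulate_methylation <- function(config, domains = NULL,
                                 baseline_percent = 15,
                                 site_density = 1 / 200,
                                 seed_offset = 4L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(domains)) domains <- config$planted_domains
  pct <- c(baseline_percent,
           if (nrow(domains)) domains$meth_percent else numeric(0))
  if (any(pct < 0 | pct > 100))
    stop("methylation percentages must lie in [0, 100]", call. = FALSE)
  sim_seed(config, seed_offset)
  n <- stats::rpois(1, site_density * config$chrom_length)
  pos <- sort(unique(sample.int(config$chrom_length, n) - 1L))
  p <- rep(baseline_percent / 100, length(pos))
  if (nrow(domains)) {
    for (k in seq_len(nrow(domains))) {
      inside <- pos >= domains$start[k] & pos < domains$end[k]
      p[inside] <- domains$meth_percent[k] / 100
    }
  }
  cov <- rcounts(length(pos), config$meth_coverage, config$noise_dispersion)
  meth <- stats::rbinom(length(pos), cov, p)
  data.frame(chrom = config$chrom, pos = pos, meth_count = meth,
             total_count = cov, stringsAsFactors = FALSE)
}

#' Simulate Repli-seq S and G1 fraction counts
#'
#' Expected S-fraction reads per bin follow `timing_profile` (relative
#' S-phase enrichment; higher = earlier replication); G1 reads are flat.
#'
#' @param config A [sim_config()] object.
#' @param timing_profile Positive numeric, one value per `repli_bin`;
#'   `NULL` for flat (uniform timing).
#' @param seed_offset See [simulate_reads()].
#' @return Data frame: `chrom`, `start`, `end`, `s_count`, `g1_count`.
#' @export
simulate_repliseq <- function(config, timing_profile = NULL,
                              seed_offset = 5L) {
  stopifnot(inherits(config, "sim_config"))
  n_bins <- ceiling(config$chrom_length / config$repli_bin)
  if (is.null(timing_profile)) timing_profile <- rep(1, n_bins)
  if (length(timing_profile) != n_bins)
    stop("timing_profile must have one value per repli bin", call. = FALSE)
  if (any(timing_profile < 0))
    stop("timing_profile must be non-negative", call. = FALSE)
  sim_seed(config, seed_offset)
  s <- rcounts(n_bins, config$repli_depth * timing_profile,
               config$noise_dispersion)
  g1 <- rcounts(n_bins, config$repli_depth, config$noise_dispersion)
  start <- (seq_len(n_bins) - 1L) * config$repli_bin
  data.frame(chrom = config$chrom, start = start,
             end = pmin(start + config$repli_bin, config$chrom_length),
             s_count = s, g1_count = g1)
}

#' Plant an X-linked gene cohort with known silencing classes
#'
#' Genes are assigned one of four Xi classes: `escapee` (expressed from
#' the wild-type Xi), `dependent` (silenced in wt, fully reactivated in
#' the mutant), `partial` (reactivated to an intermediate level) and
#' `independent` (silenced on Xi in both genotypes). Reactivated classes
#' are placed inside the planted derepression domains (spilling outside
#' when full); the other classes fill the inter-domain space.
#'
#' @param config A [sim_config()] object.
#' @param n Number of genes.
#' @param class_counts Named integer vector over the four classes;
#'   `NULL` scales the default 400-gene mix
#'   (67 dependent / 163 partial / 28 escapee / 142 independent) to `n`.
#' @param seed_offset See [simulate_reads()].
#' @return Data frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `class`.
#' @export
plant_genes <- function(config, n = 120, class_counts = NULL,
                        seed_offset = 6L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(class_counts)) {
    base <- c(dependent = 67, partial = 163, escapee = 28,
              independent = 142)
    class_counts <- round(base / sum(base) * n)
    class_counts[1] <- class_counts[1] + n - sum(class_counts)
  }
  stopifnot(sum(class_counts) == n)
  sim_seed(config, seed_offset)
  classes <- rep(names(class_counts), class_counts)
  inside_classes <- classes[classes %in% c("dependent", "partial")]
  outside_classes <- classes[!classes %in% c("dependent", "partial")]
  inside_classes <- sample(inside_classes)
  outside_classes <- sample(outside_classes)

  gene_len <- function() round(stats::runif(1, 5e3, 3e4))
  gap <- 5e3
  genes <- list()
  fill <- function(lo, hi, pool, genes) {
    pos <- lo
    while (length(pool) && pos + 5e3 + gap <= hi) {
      len <- min(gene_len(), hi - pos - gap)
      genes[[length(genes) + 1L]] <-
        data.frame(start = pos, end = pos + len, class = pool[1],
                   stringsAsFactors = FALSE)
      pool <- pool[-1]
      pos <- pos + len + gap
    }
    list(pool = pool, genes = genes)
  }
  dom <- config$planted_domains
  for (k in seq_len(nrow(dom))) {
    r <- fill(dom$start[k], dom$end[k], inside_classes, genes)
    inside_classes <- r$pool; genes <- r$genes
  }
  # complement of the domains, for the remaining genes
  bnd <- sort(c(0, dom$start, dom$end, config$chrom_length))
  outside_pool <- c(outside_classes, inside_classes)  # spill-over
  for (k in seq_len(length(bnd) - 1)) {
    lo <- bnd[k]; hi <- bnd[k + 1]
    if (nrow(dom) && any(dom$start <= lo & dom$end >= hi)) next
    r <- fill(lo + gap, hi, outside_pool, genes)
    outside_pool <- r$pool; genes <- r$genes
  }
  g <- do.call(rbind, genes)
  g <- g[order(g$start), , drop = FALSE]
  data.frame(gene_id = sprintf("gene%04d", seq_len(nrow(g))),
             chrom = config$chrom, start = g$start, end = g$end,
             strand = sample(c("+", "-"), nrow(g), replace = TRUE),
             class = g$class, stringsAsFactors = FALSE)
}

#' Simulate allelic chromatin RNA-seq gene counts
#'
#' Per-gene Xa counts are negative-binomial around `config$expr_depth`
#' (with a lognormal gene-level rate); Xi counts follow the planted class:
#' escapees express from the wild-type Xi at Xa level, dependent genes
#' reactivate fully in the mutant, partial genes to `partial_fraction` of
#' Xa, independent genes stay at the silenced background in both
#' genotypes.
#'
#' Gene-level biological variability is the shared lognormal rate: both
#' alleles of a gene in a condition draw from the same rate, so it
#' cancels in allelic ratios, and the conditional counts are Poisson
#' sampling (extra allele-independent overdispersion can be switched on
#' with `dispersion`).
#'
#' @param config A [sim_config()] object.
#' @param genes Gene data frame from [plant_genes()] (needs `gene_id` and
#'   `class`).
#' @param background_fraction Xi leak expression as a fraction of Xa for
#'   silenced genes.
#' @param partial_fraction Mutant-Xi expression of `partial` genes as a
#'   fraction of Xa.
#' @param dispersion Conditional (per-allele) negative-binomial
#'   dispersion; 0 (default) is Poisson sampling around the shared gene
#'   rate.
#' @param seed_offset See [simulate_reads()].
#' @return The gene data frame with columns `count_xa_wt`, `count_xi_wt`,
#'   `count_xa_mut`, `count_xi_mut` appended.
#' @export
simulate_expression <- function(config, genes,
                                background_fraction = 0.02,
                                partial_fraction = 0.3,
                                dispersion = 0,
                                seed_offset = 7L) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(background_fraction >= 0, partial_fraction > 0,
            partial_fraction < 1)
  sim_seed(config, seed_offset)
  n <- nrow(genes)
  mu <- config$expr_depth *
    stats::rlnorm(n, -0.3^2 / 2, 0.3)   # mean-1 gene-level rate
  frac <- function(cls, genotype) {
    bg <- background_fraction
    switch(cls,
           escapee = 1,
           dependent = if (genotype == "mut") 1 else bg,
           partial = if (genotype == "mut") partial_fraction else bg,
           independent = bg,
           stop("unknown gene class: ", cls, call. = FALSE))
  }
  f_wt <- vapply(genes$class, frac, numeric(1), genotype = "wt")
  f_mut <- vapply(genes$class, frac, numeric(1), genotype = "mut")
  disp <- dispersion
  genes$count_xa_wt <- rcounts(n, mu, disp)
  genes$count_xi_wt <- rcounts(n, mu * f_wt, disp)
  genes$count_xa_mut <- rcounts(n, mu, disp)
  genes$count_xi_mut <- rcounts(n, mu * f_mut, disp)
  genes
}

#' Simulate binned allelic ChIP-seq tracks (IP and input)
#'
#' Generates per-fine-bin allelic read counts for an
#' H3K27me3-like IP and its input. Haplotype 2 (the Xi) carries the
#' configured enrichment baseline (`xi_k27_baseline` log2 units over
#' input) across the chromosome; in the mutant genotype the planted
#' derepression domains drop to their `k27_effect` level. Haplotype 1
#' (the Xa) is flat at log2 ratio 0.
#'
#' @param config A [sim_config()] object.
#' @param genotype `"wt"` or `"mut"`.
#' @param seed_offset See [simulate_reads()].
#' @return List of two [allelic_track()]s at `chip_fine_bin`: `ip` and
#'   `input`.
#' @export
simulate_chip_tracks <- function(config, genotype = c("wt", "mut"),
                                 seed_offset = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genotype <- match.arg(genotype)
  if (is.null(seed_offset))
    seed_offset <- if (genotype == "wt") 20L else 21L
  nf <- as.integer(ceiling(config$chrom_length / config$chip_fine_bin))
  mu_input <- config$chip_depth
  prof_xi <- rep(config$xi_k27_baseline, nf)
  if (genotype == "mut" && nrow(config$planted_domains)) {
    dom <- config$planted_domains
    mids <- (seq_len(nf) - 0.5) * config$chip_fine_bin
    for (k in seq_len(nrow(dom))) {
      inside <- mids >= dom$start[k] & mids < dom$end[k]
      prof_xi[inside] <- dom$k27_effect[k]
    }
  }
  sim_seed(config, seed_offset)
  disp <- config$noise_dispersion
  ip <- allelic_track(config$chrom, config$chip_fine_bin,
                      values_hap1 = rcounts(nf, mu_input, disp),
                      values_hap2 = rcounts(nf, mu_input * 2^prof_xi,
                                            disp))
  input <- allelic_track(config$chrom, config$chip_fine_bin,
                         values_hap1 = rcounts(nf, mu_input, disp),
                         values_hap2 = rcounts(nf, mu_input, disp))
  list(ip = ip, input = input)
}

#' Planted replication-timing profile
#'
#' Relative S-phase enrichment per Repli-seq bin: 1 everywhere, raised
#' to `advance_factor` over bins whose midpoint falls in a planted
#' domain (advanced replication in derepression domains) when
#' `advanced = TRUE`.
#'
#' @param config A [sim_config()] object.
#' @param advanced Plant the advance inside `config$planted_domains`?
#' @param advance_factor S-enrichment factor of advanced bins.
#' @param bin_size Repli-seq bin size (default `config$repli_bin`).
#' @return Numeric vector, one value per bin.
#' @export
planted_timing <- function(config, advanced = FALSE, advance_factor = 2,
                           bin_size = config$repli_bin) {
  n <- as.integer(ceiling(config$chrom_length / bin_size))
  prof <- rep(1, n)
  if (advanced && nrow(config$planted_domains)) {
    mids <- (seq_len(n) - 0.5) * bin_size
    dom <- config$planted_domains
    for (k in seq_len(nrow(dom))) {
      inside <- mids >= dom$start[k] & mids < dom$end[k]
      prof[inside] <- advance_factor
    }
  }
  prof
}
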
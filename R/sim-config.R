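#' Simulation configuration for a synthetic diploid chromosome
#'
#' Builds and validates the configuration object consumed by all
#' `simulate_*()` generators. The defaults describe a hybrid diploid
#' chromosome whose second haplotype behaves like an inactive X (Xi):
#' chromosome-wide gene silencing, CpG hypomethylation, H3K27me3-enriched
#' blocks, late replication, two Hi-C mega-domains and attenuated TADs.
#' A "mutant Xi" variant carries planted sub-megabase derepression domains
#' in which genes reactivate, CpGs hypermethylate, H3K27me3 is depleted,
#' replication timing advances and TADs/compartments are restored.
#'
#' Coordinates are 0-based half-open throughout; intervals are written to
#' disk as BED.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param snp_density Expected informative SNPs per bp (default 1/500,
#'   the order of magnitude of divergence between distantly related mouse
#'   strains).
#' @param read_length Read length in bp.
#' @param chip_fine_bin,chip_coarse_bin ChIP track bin sizes in bp.
#' @param hic_bin Hi-C matrix bin size in bp.
#' @param compartment_bin Compartment-profile bin size in bp.
#' @param repli_bin Repli-seq bin size in bp.
#' @param chip_depth Mean input reads per fine ChIP bin.
#' @param hic_depth Expected contact count for adjacent bins before
#'   structural factors.
#' @param meth_coverage Mean read coverage per CpG site.
#' @param expr_depth Mean Xa read count per gene.
#' @param repli_depth Mean reads per Repli-seq bin and fraction.
#' @param planted_domains Data frame of derepression (H3K27me3 depletion)
#'   domains with columns `start`, `end` and optional per-domain effect
#'   columns `k27_effect` (log2 IP/input inside the domain),
#'   `meth_percent` (planted CpG methylation %), `expr_fold`.
#'   `NULL` generates a default set via [plant_domains()].
#' @param tad_set Data frame of TAD intervals (`start`, `end`, and logical
#'   `restored` marking the subset whose structure returns in the mutant).
#'   `NULL` generates a default tiling via [plant_tads()].
#' @param compartment_profile Integer vector of +1 (A) / -1 (B) labels, one
#'   per compartment bin, or `NULL` for alternating blocks.
#' @param mega_domain_boundary Position (bp) of the Xi mega-domain hinge.
#' @param decay_exponent Power-law exponent of contact decay; must be
#'   negative.
#' @param tad_factor Within-TAD contact boost.
#' @param compartment_factor Same-compartment contact boost (attenuated to
#'   1 on the wild-type inactive haplotype).
#' @param mega_domain_factor Cross-hinge contact attenuation on inactive
#'   haplotypes.
#' @param noise_dispersion Negative-binomial dispersion of all count noise;
#'   0 gives Poisson counts.
#' @param base_error_rate Per-observed-SNP probability that a read reports
#'   the other haplotype's allele.
#' @param xi_k27_baseline Baseline Xi H3K27me3 log2(IP/input) outside
#'   depletion domains.
#' @param seed Integer seed recorded in the config; generators reseed from
#'   it (plus a fixed per-assay offset) so identical configs give identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chrom = "chrS",
                       chrom_length = 20e6,
                       snp_density = 1 / 500,
                       read_length = 50,
                       chip_fine_bin = 500,
                       chip_coarse_bin = 10000,
                       hic_bin = 100000,
                       compartment_bin = 500000,
                       repli_bin = 500000,
                       chip_depth = 10,
                       hic_depth = 60,
                       meth_coverage = 20,
                       expr_depth = 100,
                       repli_depth = 100,
                       planted_domains = NULL,
                       tad_set = NULL,
                       compartment_profile = NULL,
                       mega_domain_boundary = NULL,
                       decay_exponent = -1,
                       tad_factor = 3,
                       compartment_factor = 2,
                       mega_domain_factor = 0.2,
                       noise_dispersion = 0.05,
                       base_error_rate = 0,
                       xi_k27_baseline = 1,
                       seed = 1L) {
  if (!is.numeric(chrom_length) || chrom_length <= 0)
    stop("chrom_length must be positive", call. = FALSE)
  if (!is.numeric(snp_density) || snp_density < 0)
    stop("snp_density must be non-negative", call. = FALSE)
  if (decay_exponent >= 0)
    stop("decay_exponent must be negative (contact decay must decrease)",
         call. = FALSE)
  if (noise_dispersion < 0)
    stop("noise_dispersion must be >= 0", call. = FALSE)
  if (base_error_rate < 0 || base_error_rate > 1)
    stop("base_error_rate must be in [0, 1]", call. = FALSE)
  for (b in c(chip_fine_bin, chip_coarse_bin, hic_bin, compartment_bin,
              repli_bin, read_length))
    if (b <= 0) stop("bin sizes and read_length must be positive",
                     call. = FALSE)
  if (chip_coarse_bin %% chip_fine_bin != 0)
    stop("chip_coarse_bin must be a multiple of chip_fine_bin",
         call. = FALSE)

  if (is.null(mega_domain_boundary))
    mega_domain_boundary <- floor(chrom_length / 2 / hic_bin) * hic_bin
  if (is.null(planted_domains))
    planted_domains <- plant_domains(chrom_length, bin = chip_coarse_bin)
  if (is.null(tad_set))
    tad_set <- plant_tads(chrom_length, bin = hic_bin)
  n_comp <- ceiling(chrom_length / compartment_bin)
  if (is.null(compartment_profile)) {
    block <- max(1L, as.integer(2e6 / compartment_bin))
    compartment_profile <-
      ifelse((seq_len(n_comp) - 1L) %/% block %% 2L == 0L, 1L, -1L)
  }
  if (length(compartment_profile) != n_comp)
    stop("compartment_profile must have one label per compartment bin",
         call. = FALSE)
  check_domains <- function(d, what) {
    if (nrow(d) == 0) return(invisible())
    if (any(d$start < 0) || any(d$end > chrom_length) ||
        any(d$start >= d$end))
      stop(what, " intervals must be half-open, non-empty and within ",
           "[0, chrom_length)", call. = FALSE)
  }
  check_domains(planted_domains, "planted_domains")
  check_domains(tad_set, "tad_set")
  if (is.null(planted_domains$k27_effect))
    planted_domains$k27_effect <- -1
  if (is.null(planted_domains$meth_percent))
    planted_domains$meth_percent <- 60
  if (is.null(tad_set$restored))
    tad_set$restored <- TRUE

  structure(list(
    chrom = chrom, chrom_length = chrom_length, snp_density = snp_density,
    read_length = read_length, chip_fine_bin = chip_fine_bin,
    chip_coarse_bin = chip_coarse_bin, hic_bin = hic_bin,
    compartment_bin = compartment_bin, repli_bin = repli_bin,
    chip_depth = chip_depth, hic_depth = hic_depth,
    meth_coverage = meth_coverage, expr_depth = expr_depth,
    repli_depth = repli_depth, planted_domains = planted_domains,
    tad_set = tad_set, compartment_profile = compartment_profile,
    mega_domain_boundary = mega_domain_boundary,
    decay_exponent = decay_exponent, tad_factor = tad_factor,
    compartment_factor = compartment_factor,
    mega_domain_factor = mega_domain_factor,
    noise_dispersion = noise_dispersion,
    base_error_rate = base_error_rate,
    xi_k27_baseline = xi_k27_baseline,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic diploid chromosome configuration\n")
  cat(sprintf("  %s: %.1f Mb, %d planted derepression domains, %d TADs (%d restored)\n",
              x$chrom, x$chrom_length / 1e6, nrow(x$planted_domains),
              nrow(x$tad_set), sum(x$tad_set$restored)))
  cat(sprintf("  SNP density 1/%.0f bp, seed %d\n",
              1 / x$snp_density, x$seed))
  invisible(x)
}

#' Default planted derepression-domain set
#'
#' Lays sub-megabase domains along the chromosome at roughly regular
#' spacing, aligned to the coarse ChIP bin grid. Lengths cycle through
#' 60-300 kb so the set's mean length is ~140 kb, the scale at which Xi
#' H3K27me3 depletion domains are observed.
#'
#' @param chrom_length Chromosome length (bp).
#' @param bin Alignment grid (bp).
#' @param n Number of domains (default scales with chromosome length, one
#'   per ~1.6 Mb).
#' @return Data frame with `start`, `end`, `k27_effect`, `meth_percent`.
#' @export
plant_domains <- function(chrom_length, bin = 10000,
                          n = max(3L, floor(chrom_length / 1.6e6))) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      k27_effect = numeric(0), meth_percent = numeric(0))
  if (chrom_length < 20 * bin) return(empty)
  lens <- rep(c(6L, 10L, 14L, 18L, 22L, 30L), length.out = n) * 10000
  lens <- pmin(lens, floor(chrom_length / (2 * n) / bin) * bin)
  spacing <- floor(chrom_length / n / bin) * bin
  start <- round((seq_len(n) - 1) * spacing / bin) * bin +
    floor(spacing / 4 / bin) * bin
  out <- data.frame(start = start, end = pmin(start + lens, chrom_length),
                    k27_effect = -1, meth_percent = 60)
  out[out$end > out$start, , drop = FALSE]
}

#' Default TAD tiling
#'
#' Tiles the chromosome with TADs of 600 kb - 1.4 Mb aligned to the Hi-C
#' bin grid, separated by one-bin gaps, and marks 75% of them (every
#' fourth TAD excluded) as `restored` in the mutant, reflecting
#' chromosome-wide TAD re-establishment with a minority of refractory
#' domains.
#'
#' @inheritParams plant_domains
#' @return Data frame with `start`, `end`, `restored`.
#' @export
plant_tads <- function(chrom_length, bin = 100000) {
  lens <- c(6L, 10L, 8L, 14L, 12L, 8L) * 100000
  starts <- integer(0); ends <- integer(0); pos <- 0; i <- 1
  while (pos + 6e5 <= chrom_length) {
    len <- min(lens[(i - 1) %% length(lens) + 1], chrom_length - pos)
    len <- floor(len / bin) * bin
    if (len < 2 * bin) break
    starts <- c(starts, pos); ends <- c(ends, pos + len)
    pos <- pos + len + bin   # one-bin boundary gap
    i <- i + 1
  }
  data.frame(start = starts, end = ends,
             restored = (seq_along(starts) %% 4L) != 0L)
}

# Count noise shared by all generators: negative binomial with dispersion
# `disp` (Var = mu + disp * mu^2); disp = 0 is the Poisson limit.
rcounts <- function(n, mu, disp) {
  mu <- pmax(mu, 0)
  if (disp <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / disp)
}

# Seed helper: generators derive a stream from config seed + assay offset.
sim_seed <- function(config, offset) {
  s <- (config$seed + offset) %% .Machine$integer.max
  set.seed(as.integer(s))
}
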
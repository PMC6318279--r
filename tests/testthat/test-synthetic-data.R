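test_that("config validation rejects impossible chromosomes", {
  expect_error(sim_config(chrom_length = 0), "chrom_length")
  expect_error(sim_config(decay_exponent = 0.5), "decay_exponent")
  expect_error(sim_config(chip_fine_bin = 600, chip_coarse_bin = 10000),
               "multiple")
  expect_error(sim_config(planted_domains =
                            data.frame(start = 5e6, end = 4e6)),
               "half-open")
  cfg <- sim_config(chrom_length = 1e4, snp_density = 0)
  expect_error(generate_snp_table(cfg), ">= 1")
})

test_that("SNP table density, uniqueness and ordering", {
  cfg <- sim_config(chrom_length = 1e5, snp_density = 1 / 500, seed = 1)
  snps <- generate_snp_table(cfg)
  # Poisson(200) central 99% interval
  expect_gt(nrow(snps), stats::qpois(0.005, 200))
  expect_lt(nrow(snps), stats::qpois(0.995, 200))
  expect_false(is.unsorted(snps$pos))
  expect_equal(anyDuplicated(snps$pos), 0)
  expect_true(all(snps$allele_hap1 != snps$allele_hap2))
})

test_that("generators are deterministic given the config seed", {
  cfg <- small_config(seed = 7L)
  expect_identical(generate_snp_table(cfg), generate_snp_table(cfg))
  snps <- generate_snp_table(cfg)
  expect_identical(simulate_reads(cfg, snps, 500),
                   simulate_reads(cfg, snps, 500))
  expect_identical(simulate_hic(cfg, "inactive-like")$counts,
                   simulate_hic(cfg, "inactive-like")$counts)
  expect_identical(simulate_methylation(cfg), simulate_methylation(cfg))
})

test_that("read simulation respects weights, haplotype ratio and alleles", {
  cfg <- sim_config(chrom_length = 1e6, seed = 3)
  snps <- generate_snp_table(cfg)
  expect_error(simulate_reads(cfg, snps, 10,
                              weights = rep(0, 100)), "zero")
  # hap1:hap2 = 3:1 -> hap1 fraction within binomial(1e4, 0.75) 99% CI
  sim <- simulate_reads(cfg, snps, 1e4, hap1_fraction = 0.75)
  frac <- mean(sim$truth == "hap1")
  expect_gt(frac, 0.72)
  expect_lt(frac, 0.78)
  # noiseless observations match the origin's alleles exactly
  part <- sort_reads(sim$reads, snps)
  acc <- score_assignment(part$labels, sim$truth)
  expect_equal(acc$accuracy, 1)
  # conservation through binning
  tr <- bin_reads(sim$reads, part$labels, bin_size = 1e4,
                  chrom_length = cfg$chrom_length)
  expect_equal(sum(tr$values_hap1) + sum(tr$values_hap2) +
                 sum(tr$values_unassigned), 1e4)
})

test_that("Hi-C simulation plants TADs, hinge and decay as configured", {
  tads <- data.frame(start = 0, end = 1e6, restored = TRUE)
  cfg <- sim_config(chrom_length = 4e6, hic_bin = 5e4, tad_set = tads,
                    compartment_factor = 1, mega_domain_factor = 0.2,
                    tad_factor = 3, hic_depth = 50, seed = 11)
  expect_error(sim_config(decay_exponent = 0), "decay_exponent")

  zero <- sim_config(chrom_length = 4e6, hic_bin = 5e4, hic_depth = 0,
                     seed = 1)
  expect_true(all(simulate_hic(zero, "active-like")$counts == 0))

  m <- simulate_hic(cfg, "active-like")
  expect_identical(m$counts, t(m$counts))
  # mean within-TAD / cross count at matched separations ~ tad_factor
  n <- nrow(m$counts)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  in_tad <- seq_len(n) <= 20          # bins of [0, 1 Mb)
  same <- outer(in_tad, in_tad, "&")
  sel <- d >= 2 & d <= 10
  ratio <- mean(m$counts[same & sel]) /
    mean(m$counts[!same & sel & !outer(in_tad, in_tad, "|")])
  expect_gt(ratio, 3 * 0.85)
  expect_lt(ratio, 3 * 1.15)

  # inactive-like: cross-hinge attenuation at matched distance
  mi <- simulate_hic(cfg, "inactive-like")
  hinge <- cfg$mega_domain_boundary / cfg$hic_bin
  side <- (seq_len(n) - 1) >= hinge
  cross <- outer(side, side, "!=")
  sel2 <- d >= 30 & d <= 50
  r2 <- mean(mi$counts[cross & sel2]) / mean(mi$counts[!cross & sel2])
  expect_gt(r2, 0.2 * 0.85)
  expect_lt(r2, 0.2 * 1.15)
})

test_that("methylation simulation follows planted percentages", {
  cfg <- sim_config(chrom_length = 1e5, meth_coverage = 50, seed = 5)
  expect_error(
    simulate_methylation(cfg, domains = data.frame(start = 0, end = 10,
                                                   meth_percent = 120)),
    "\\[0, 100\\]")
  none <- simulate_methylation(cfg, domains = cfg$planted_domains[0, ],
                               baseline_percent = 0)
  expect_true(all(none$meth_count == 0))
  all80 <- simulate_methylation(cfg, domains = cfg$planted_domains[0, ],
                                baseline_percent = 80)
  frac <- mean(all80$meth_count / all80$total_count, na.rm = TRUE)
  expect_gt(frac, 0.75)
  expect_lt(frac, 0.85)
})

test_that("expression simulation encodes the planted silencing classes", {
  cfg <- sim_config(seed = 2)
  genes <- plant_genes(cfg, n = 40)
  rec <- simulate_expression(cfg, genes)
  bg <- 0.02
  ind <- rec[rec$class == "independent", ]
  # silenced genes stay near the background rate on both mutant alleles
  expect_lt(mean(ind$count_xi_mut), 3 * bg * cfg$expr_depth)
  dep <- rec[rec$class == "dependent", ]
  expect_gt(mean(dep$count_xi_mut), 0.5 * cfg$expr_depth)
  expect_lt(mean(dep$count_xi_wt), 3 * bg * cfg$expr_depth)
})
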
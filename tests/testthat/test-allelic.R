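toy_snps <- function() {
  snp_table(data.frame(chrom = "chr", pos = c(100L, 200L, 300L),
                       allele_hap1 = c("A", "C", "G"),
                       allele_hap2 = c("G", "T", "A"),
                       stringsAsFactors = FALSE))
}

test_that("single-read assignment follows the SNP voting rule", {
  snps <- toy_snps()
  read <- function(obs) list(snp_obs = obs)
  expect_equal(assign_read(read("100:A"), snps), "hap1")
  expect_equal(assign_read(read("100:G"), snps), "hap2")
  expect_equal(assign_read(read(""), snps), "unassigned")
  expect_equal(assign_read(read("100:C"), snps), "unassigned") # neither
  expect_equal(assign_read(read("100:A;200:T"), snps), "conflicting")
  expect_equal(assign_read(read("100:A;200:C"), snps), "hap1")
})

test_that("partition is exhaustive, exclusive and symmetric", {
  cfg <- sim_config(chrom_length = 5e5, seed = 9)
  snps <- generate_snp_table(cfg)
  sim <- simulate_reads(cfg, snps, 2000)
  part <- sort_reads(sim$reads, snps)
  expect_equal(sum(part$counts), 2000)
  expect_equal(sum(part$fractions), 1)
  # swapping the table's alleles swaps hap1/hap2 labels exactly
  swapped <- snps
  tmp <- swapped$allele_hap1
  swapped$allele_hap1 <- swapped$allele_hap2
  swapped$allele_hap2 <- tmp
  part2 <- sort_reads(sim$reads, snp_table(swapped))
  map <- c(hap1 = "hap2", hap2 = "hap1", unassigned = "unassigned",
           conflicting = "conflicting")
  expect_equal(as.character(part2$labels),
               unname(map[as.character(part$labels)]))
})

test_that("adding SNPs never flips a label between haplotypes directly", {
  snps <- toy_snps()
  df <- data.frame(snp_obs = c("100:A", "100:A;200:C", ""),
                   stringsAsFactors = FALSE)
  before <- as.character(sort_reads(df, snps)$labels)
  # new SNPs at unobserved positions leave labels untouched
  bigger <- snp_table(rbind(snps, data.frame(
    chrom = "chr", pos = 150L, allele_hap1 = "T", allele_hap2 = "C")))
  expect_equal(as.character(sort_reads(df, bigger)$labels), before)
  # making an observed base ambiguous moves hap1 only to conflicting
  flipped <- snps
  flipped$allele_hap2[2] <- "C"   # obs "200:C" now matches hap2 too? no:
  flipped$allele_hap1[2] <- "T"   # hap1 no longer matches at 200
  res <- as.character(sort_reads(df, snp_table(flipped))$labels)
  expect_equal(res[2], "conflicting")
  expect_equal(res[1], "hap1")
})

test_that("empty input gives an empty partition with zero fractions", {
  part <- sort_reads(data.frame(snp_obs = character(0)), toy_snps())
  expect_equal(sum(part$counts), 0)
  expect_true(all(part$fractions == 0))
})

test_that("paired-end mates share one combined label", {
  snps <- toy_snps()
  df <- data.frame(snp_obs = c("100:A", "", "200:C", "300:A"),
                   pair_id = c("p1", "p1", "p2", "p2"),
                   stringsAsFactors = FALSE)
  labs <- as.character(sort_reads(df, snps)$labels)
  expect_equal(labs[1:2], c("hap1", "hap1"))
  expect_equal(labs[3:4], c("conflicting", "conflicting"))
})

test_that("misassignment with 1% base error stays below 2%", {
  cfg <- sim_config(chrom_length = 2e6, base_error_rate = 0.01,
                    seed = 13)
  snps <- generate_snp_table(cfg)
  sim <- simulate_reads(cfg, snps, 1e4)
  part <- sort_reads(sim$reads, snps)
  acc <- score_assignment(part$labels, sim$truth)
  expect_gt(acc$n_assigned, 500)
  expect_lt(acc$misassignment, 0.02)
})

test_that("binning by start coordinate conserves reads", {
  reads <- data.frame(start = c(10000, 5, 19999), end = c(10050, 55, 20049))
  labels <- factor(c("hap1", "hap2", "unassigned"),
                   levels = c("hap1", "hap2", "unassigned", "conflicting"))
  tr <- bin_reads(reads, labels, bin_size = 10000, chrom_length = 30000)
  expect_equal(tr$values_hap1, c(0, 1, 0))   # read at 10,000 -> second bin
  expect_equal(tr$values_hap2, c(1, 0, 0))
  expect_equal(tr$values_unassigned, c(0, 1, 0))
  expect_error(bin_reads(reads, labels, bin_size = 0), "positive")
  # bin larger than the chromosome: one bin holding everything
  one <- bin_reads(reads, labels, bin_size = 1e6, chrom_length = 30000)
  expect_equal(one$n_bins, 1)
  expect_equal(sum(one$values_hap1, one$values_hap2,
                   one$values_unassigned), 3)
})
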
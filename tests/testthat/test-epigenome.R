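test_that("enrichment track arithmetic and averaging", {
  # ip = input everywhere -> all zeros
  et <- enrichment_track(rep(4, 40), rep(4, 40), fine_bin = 500,
                         coarse_bin = 10000, pseudocount = 1,
                         lib_scale = 1)
  expect_true(all(et$log2_ratio == 0))
  # single fine bin: log2((8+1)/(2+1)) = log2 3
  et2 <- enrichment_track(8, 2, fine_bin = 500, coarse_bin = 500,
                          pseudocount = 1, lib_scale = 1)
  expect_equal(et2$log2_ratio, log2(3))
  # fine values {+1, -1} in one coarse bin average to 0
  et3 <- enrichment_track(c(3, 1), c(1, 3), fine_bin = 500,
                          coarse_bin = 1000, pseudocount = 1,
                          lib_scale = 1)
  expect_equal(et3$fine_values, c(1, -1))
  expect_equal(et3$log2_ratio, 0)
  # zero-input fine bins are missing; empty coarse bins are missing
  et4 <- enrichment_track(c(5, 5), c(0, 0), fine_bin = 500,
                          coarse_bin = 1000, lib_scale = 1)
  expect_true(is.na(et4$log2_ratio))
  expect_error(enrichment_track(1:3, 1:3, fine_bin = 400,
                                coarse_bin = 1000), "multiple")
})

test_that("depletion caller handles the inclusive merge bound", {
  bs <- 10000
  v <- rep(1, 30)
  v[1:10] <- -1          # [0, 100 kb)
  v[13:20] <- -1         # [120 kb, 200 kb): gap exactly 20 kb
  res <- call_depletion_domains(v, bin_size = bs)
  expect_equal(nrow(res$domains), 1)
  expect_equal(res$domains$start, 0)
  expect_equal(res$domains$end, 200000)
  v2 <- rep(1, 30)
  v2[1:10] <- -1
  v2[14:20] <- -1        # 30 kb gap: stays split
  res2 <- call_depletion_domains(v2, bin_size = bs)
  expect_equal(nrow(res2$domains), 2)
  expect_equal(call_depletion_domains(rep(0.5, 20),
                                      bin_size = bs)$count, 0)
  expect_error(call_depletion_domains(v, bin_size = bs, max_gap = -1),
               "max_gap")
})

test_that("depletion caller matches the brute-force scan on random tracks", {
  set.seed(101)
  for (rep_i in 1:100) {
    n <- sample(50:1000, 1)
    bs <- sample(c(5000, 10000, 20000), 1)
    v <- stats::rnorm(n, mean = 0.2)
    v[sample(n, n %/% 10)] <- NA
    gap <- sample(c(0, 20000, 45000), 1)
    ml <- sample(c(0, 30000), 1)
    got <- call_depletion_domains(v, bin_size = bs, max_gap = gap,
                                  min_len = ml)$domains
    want <- bf_depletion_domains(v, bs, max_gap = gap, min_len = ml)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("merging is mirror-symmetric", {
  set.seed(7)
  v <- stats::rnorm(200, 0.1)
  bs <- 10000
  fwd <- call_depletion_domains(v, bin_size = bs)$domains
  revd <- call_depletion_domains(rev(v), bin_size = bs)$domains
  n_bp <- length(v) * bs
  expect_equal(fwd$start, rev(n_bp - revd$end))
  expect_equal(fwd$end, rev(n_bp - revd$start))
})

test_that("planted depletion domains are recovered at high Jaccard", {
  cfg <- sim_config(seed = 21)
  bs <- cfg$chip_coarse_bin
  n <- cfg$chrom_length / bs
  prof <- rep(1, n)                      # baseline log2 ratio +1
  mids <- (seq_len(n) - 0.5) * bs
  for (k in seq_len(nrow(cfg$planted_domains))) {
    ins <- mids >= cfg$planted_domains$start[k] &
      mids < cfg$planted_domains$end[k]
    prof[ins] <- -1                      # planted effect -1 log2
  }
  set.seed(22)
  input <- stats::rpois(n, 30)           # 30 reads per 10 kb bin
  ip <- stats::rpois(n, 30 * 2^prof)
  et <- enrichment_track(ip, input, fine_bin = bs, coarse_bin = bs,
                         lib_scale = 1)
  called <- call_depletion_domains(et)$domains
  ov <- domain_overlap(called, cfg$planted_domains)
  expect_gte(ov$jaccard, 0.9)
})

test_that("allelic specificity score is bounded and antisymmetric", {
  expect_equal(allelic_specificity_score(5, 0), 100)
  expect_equal(allelic_specificity_score(0, 7), -100)
  expect_equal(allelic_specificity_score(4, 4), 0)
  expect_true(is.na(allelic_specificity_score(0, 0)))
  set.seed(1)
  xi <- rpois(50, 20); xa <- rpois(50, 20)
  ok <- xi + xa > 0
  expect_equal(allelic_specificity_score(xi, xa)[ok],
               -allelic_specificity_score(xa, xi)[ok])
})

test_that("peak exclusivity uses a strict 90% rule", {
  expect_equal(classify_peak_allelicity(95, 5), "Xi-specific")
  expect_equal(classify_peak_allelicity(90, 10), "both")  # exactly 90%
  expect_equal(classify_peak_allelicity(5, 95), "Xa-specific")
  expect_equal(classify_peak_allelicity(5, 5), "both")
  expect_true(is.na(classify_peak_allelicity(0, 0)))
})

test_that("threshold peak caller finds runs", {
  expect_equal(nrow(call_peaks_simple(rep(0, 50), threshold = 1,
                                      bin_size = 500)), 0)
  v <- rep(0, 20); v[5:7] <- 2
  pk <- call_peaks_simple(v, threshold = 2, min_bins = 2, bin_size = 500)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 4 * 500)
  expect_equal(pk$end, 7 * 500)
})

test_that("methylation binning applies the coverage filter", {
  sites <- data.frame(pos = c(100, 200), meth_count = c(2, 0),
                      total_count = c(2, 2))
  mt <- methylation_track(sites, bin_size = 10000, min_coverage = 3,
                          chrom_length = 10000)
  expect_true(is.na(mt$values))
  sites2 <- data.frame(pos = c(100, 200), meth_count = c(4, 1),
                       total_count = c(5, 5))
  mt2 <- methylation_track(sites2, bin_size = 10000,
                           chrom_length = 10000)
  expect_equal(mt2$values, 50)
  expect_error(methylation_track(
    data.frame(pos = 1, meth_count = 6, total_count = 5)), "exceeds")
  # values stay inside [0, 100] on random data
  set.seed(3)
  tot <- rpois(500, 10) + 3
  sr <- data.frame(pos = sort(sample(1e5, 500)),
                   meth_count = rbinom(500, tot, 0.4), total_count = tot)
  mtr <- methylation_track(sr, bin_size = 5000, chrom_length = 1e5)
  expect_true(all(mtr$values >= 0 & mtr$values <= 100, na.rm = TRUE))
})

test_that("metagene profiles are flat on constant signal and mirror by strand", {
  track <- list(values = rep(70, 100), bin_size = 1000)
  genes <- data.frame(start = 30000, end = 50000, strand = "+")
  prof <- metagene_profile(genes, track, flank = 10000,
                           n_body_bins = 10, n_flank_bins = 5)
  expect_equal(unname(prof$profile), rep(70, 20))
  # gradient reverses for a minus-strand gene
  grad <- list(values = seq_len(100), bin_size = 1000)
  plus <- metagene_profile(data.frame(start = 30000, end = 50000,
                                      strand = "+"), grad,
                           flank = 10000, n_body_bins = 10,
                           n_flank_bins = 5)
  minus <- metagene_profile(data.frame(start = 30000, end = 50000,
                                       strand = "-"), grad,
                            flank = 10000, n_body_bins = 10,
                            n_flank_bins = 5)
  expect_equal(unname(minus$profile), rev(unname(plus$profile)))
  expect_warning(
    metagene_profile(data.frame(start = c(1000, 30000),
                                end = c(1005, 50000), strand = "+"),
                     track, flank = 1000, n_body_bins = 10,
                     n_flank_bins = 2),
    "skipped")
})

test_that("values_at_sites aggregates and orders stably", {
  track <- list(values = c(10, 20, NA, NA), bin_size = 1000)
  sites <- data.frame(start = c(0, 2000), end = c(2000, 4000))
  out <- values_at_sites(sites, track)
  expect_equal(out$value, c(15, NA))
  sorted <- values_at_sites(
    data.frame(start = c(0, 1000), end = c(1000, 2000)), track,
    sort = TRUE)
  expect_equal(sorted$value, c(20, 10))
  expect_setequal(sorted$start, c(0, 1000))
})
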
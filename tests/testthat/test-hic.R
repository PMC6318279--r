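random_sym <- function(n, seed, positive = TRUE) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, if (positive) 0.1 else 0, 5), n, n)
  A <- (A + t(A)) / 2
  A
}

test_that("contact matrix constructor validates shape and symmetry", {
  expect_error(contact_matrix(matrix(1, 2, 3), 1), "square")
  M <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(contact_matrix(M, 1), "symmetric")
  expect_error(contact_matrix(matrix(-1, 2, 2), 1), "non-negative")
})

test_that("KR balancing solves the 2x2 closed form", {
  m <- kr_balance(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(m$weights, rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(m$balanced, matrix(c(0, 1, 1, 0), 2, 2),
               tolerance = 1e-9)
  # doubly-uniform matrix: equal weights
  u <- kr_balance(matrix(1, 5, 5))
  expect_equal(max(u$weights) / min(u$weights), 1, tolerance = 1e-9)
  expect_error(kr_balance(matrix(0, 3, 3)), "no unmasked")
})

test_that("KR row sums are uniform to 1e-6 by independent summation", {
  worst <- 0
  for (s in 1:50) {
    A <- random_sym(50, seed = 1000 + s)
    m <- kr_balance(A, tol = 1e-6)
    rs <- apply(m$balanced, 1, sum)       # independent summation
    worst <- max(worst, max(abs(rs - 1)))
  }
  expect_lt(worst, 1e-6)
})

test_that("KR balancing is idempotent and masks empty bins", {
  A <- random_sym(30, seed = 4)
  A[5, ] <- 0; A[, 5] <- 0
  m <- kr_balance(A)
  expect_true(is.na(m$weights[5]))
  expect_equal(m$mask, 5L)
  B <- m$balanced[-5, -5]
  again <- kr_balance(B)
  expect_equal(again$weights, rep(1, 29), tolerance = 1e-4)
})

test_that("downsampling matches totals and preserves symmetry", {
  m1 <- contact_matrix(random_count_matrix(40, total = 5000, seed = 1),
                       1e5)
  m2 <- contact_matrix(random_count_matrix(40, total = 4000, seed = 2),
                       1e5)
  eq <- downsample_equalize(list(a = list(chr = m1), b = list(chr = m2)),
                            seed = 3)
  expect_equal(matrix_total(eq$a$chr), matrix_total(eq$b$chr))
  expect_equal(matrix_total(eq$a$chr), 4000)
  expect_identical(eq$a$chr$counts, t(eq$a$chr$counts))
  # equal inputs with the same seed stay identical
  eq2 <- downsample_equalize(list(a = list(chr = m1),
                                  b = list(chr = m1)), seed = 5)
  expect_identical(eq2$a$chr$counts, m1$counts)
  expect_identical(eq2$b$chr$counts, m1$counts)
})

test_that("distance decay recovers constructed power laws", {
  n <- 100
  for (expo in c(-1, -1.5)) {
    E <- abs(outer(seq_len(n), seq_len(n), "-"))
    E[E == 0] <- 1
    C <- 1000 * E^expo
    diag(C) <- 1000
    m <- contact_matrix(C, bin_size = 1e5)
    dd <- distance_decay(m, fit_range = c(2e5, 5e6))
    expect_equal(dd$slope, expo, tolerance = 0.01)
    expect_equal(sum(dd$ps$p), 1)
  }
  # contacts almost exclusively at s = 1 bin concentrate P(s) there
  sparse <- matrix(0, 6, 6)
  sparse[cbind(1:5, 2:6)] <- 100
  sparse[cbind(1:4, 3:6)] <- 1
  sparse[cbind(1:3, 4:6)] <- 1
  sparse <- sparse + t(sparse)
  dd2 <- distance_decay(contact_matrix(sparse, 1e5),
                        fit_range = c(1e5, 3e5))
  expect_gt(dd2$ps$p[1], 0.95)
  expect_error(distance_decay(contact_matrix(sparse, 1e5),
                              fit_range = c(4e5, 5e5)),
               "fewer than 3")
})

test_that("insulation equals the brute-force square-mean oracle", {
  for (s in 1:5) {
    A <- random_sym(30, seed = 200 + s)
    m <- contact_matrix(A, bin_size = 5e4)
    ins <- insulation_score(m, window = 2.5e5, delta_span = 1e5)
    w <- 5
    raw_bf <- bf_insulation_raw(A, w)
    expect_identical(ins$raw, raw_bf)
    score_bf <- log2(raw_bf / mean(raw_bf, na.rm = TRUE))
    expect_identical(ins$score, score_bf)
  }
})

test_that("insulation is zero on uniform matrices and minimal at block junctions", {
  n <- 40
  u <- insulation_score(contact_matrix(matrix(2, n, n), 5e4),
                        window = 2.5e5, delta_span = 1e5)
  expect_true(all(abs(u$score) < 1e-12, na.rm = TRUE))
  B <- matrix(1, n, n)
  B[1:20, 1:20] <- 10
  B[21:40, 21:40] <- 10
  ins <- insulation_score(contact_matrix(B, 5e4), window = 2.5e5,
                          delta_span = 1e5)
  expect_equal(which.min(ins$score), 20)
  expect_true(any(ins$boundaries %in% c(20, 21)))
  expect_error(insulation_score(contact_matrix(matrix(1, 5, 5), 5e4),
                                window = 2.5e5), "fit")
})

test_that("compartment eigenvector recovers a planted checkerboard", {
  profile <- rep(rep(c(1L, -1L), each = 4), length.out = 40)
  cfg <- sim_config(chrom_length = 2e7, hic_bin = 5e5,
                    compartment_bin = 5e5, compartment_profile = profile,
                    tad_set = data.frame(start = numeric(0),
                                         end = numeric(0),
                                         restored = logical(0)),
                    mega_domain_factor = 1, compartment_factor = 2,
                    hic_depth = 100, seed = 41)
  m <- simulate_hic(cfg, "active-like")
  cp <- compartment_eigenvector(m, gene_density = profile)
  ok <- !is.na(cp$eigenvector)
  expect_equal(sign(cp$eigenvector[ok]), profile[ok])
  expect_gt(abs(stats::cor(cp$eigenvector[ok], profile[ok])), 0.95)
  # orientation flip: negated gene density flips all labels
  cp2 <- compartment_eigenvector(m, gene_density = -profile)
  expect_equal(cp2$eigenvector[ok], -cp$eigenvector[ok])
  # eigenvector invariant (up to sign/scale) under global matrix scaling
  m4 <- contact_matrix(m$counts * 4, m$bin_size)
  cp4 <- compartment_eigenvector(m4, gene_density = profile)
  expect_gt(abs(stats::cor(cp4$eigenvector[ok], cp$eigenvector[ok])),
            0.999)
  # no compartment structure -> no correlation with the labels
  null_cfg <- sim_config(chrom_length = 2e7, hic_bin = 5e5,
                         compartment_bin = 5e5,
                         compartment_profile = profile,
                         tad_set = data.frame(start = numeric(0),
                                              end = numeric(0),
                                              restored = logical(0)),
                         mega_domain_factor = 1, compartment_factor = 1,
                         hic_depth = 100, seed = 43)
  mnull <- simulate_hic(null_cfg, "active-like")
  cpn <- compartment_eigenvector(mnull, gene_density = profile)
  okn <- !is.na(cpn$eigenvector)
  expect_lt(abs(stats::cor(cpn$eigenvector[okn], profile[okn])), 0.3)
})

test_that("eigenvector correlation behaves at the extremes", {
  v <- stats::rnorm(50)
  expect_equal(eigenvector_correlation(v, v), 1)
  expect_equal(eigenvector_correlation(v, -v), -1)
  set.seed(9)
  a <- stats::rnorm(500); b <- stats::rnorm(500)
  expect_lt(abs(eigenvector_correlation(a, b)), 0.15)
  expect_error(eigenvector_correlation(c(1, NA, NA), c(NA, 1, 2)),
               "at least 3")
})

test_that("TAD re-establishment scores and classes", {
  n <- 30
  C <- matrix(5, n, n)
  m <- contact_matrix(C, bin_size = 1e5)
  tads <- data.frame(start = c(0, 1.5e6), end = c(1e6, 2.5e6))
  same <- tad_reestablishment(tads, m, m, min_sep = 1e5)
  expect_true(all(same$score == 0))
  # C_mut = 1.5 x C_wt -> score 0.5
  m2 <- contact_matrix(C * 1.5, bin_size = 1e5)
  up <- tad_reestablishment(tads, m, m2, min_sep = 1e5)
  expect_equal(up$score, rep(0.5, 2))
  # score invariant under simultaneous rescaling of both matrices
  mw <- contact_matrix(C * 2, bin_size = 1e5)
  mm <- contact_matrix(C * 3, bin_size = 1e5)
  s1 <- tad_reestablishment(tads, mw, mm)$score
  s2 <- tad_reestablishment(tads,
                            contact_matrix(C * 4, 1e5),
                            contact_matrix(C * 6, 1e5))$score
  expect_equal(s1, s2)
})

test_that("mega-domain hinge depresses cross-boundary contact", {
  cfg <- small_config(hic_depth = 80, seed = 47)
  m <- kr_balance(simulate_hic(cfg, "inactive-like"))
  n <- nrow(m$counts)
  hinge <- cfg$mega_domain_boundary / cfg$hic_bin
  side <- (seq_len(n) - 1) >= hinge
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  sel <- d >= 10 & d <= 25
  cross <- outer(side, side, "!=")
  expect_lt(mean(m$balanced[cross & sel], na.rm = TRUE),
            mean(m$balanced[!cross & sel], na.rm = TRUE))
})

test_that("insulation at reference boundaries gives paired tables", {
  A <- random_sym(40, seed = 77)
  t1 <- insulation_score(contact_matrix(A, 5e4), window = 2.5e5,
                         delta_span = 1e5)
  tab <- insulation_at_boundaries(c(10, 20, 30),
                                  list(a = t1, b = t1))
  expect_equal(tab$a, tab$b)
  expect_error(insulation_at_boundaries(99, list(a = t1)), "range")
})

test_that("matrix aggregation sums blocks", {
  C <- matrix(1, 4, 4)
  m <- aggregate_matrix(contact_matrix(C, 1e5), 2)
  expect_equal(m$counts, matrix(4, 2, 2))
  expect_equal(m$bin_size, 2e5)
})
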
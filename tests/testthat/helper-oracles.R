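# Independent brute-force oracles used to validate the package's
# implementations on small inputs.

# Depletion-domain caller: explicit per-bin scan. A bin is "depleted"
# when defined and strictly below threshold; domains are maximal
# depleted runs, then neighbouring domains whose separating gap (bp,
# missing bins included) is <= max_gap are merged left to right; short
# domains dropped.
bf_depletion_domains <- function(values, bin_size, threshold = 0,
                                 max_gap = 20000, min_len = 0) {
  dep <- !is.na(values) & values < threshold
  doms <- list()
  i <- 1
  n <- length(values)
  while (i <= n) {
    if (dep[i]) {
      j <- i
      while (j < n && dep[j + 1]) j <- j + 1
      doms[[length(doms) + 1]] <- c((i - 1) * bin_size, j * bin_size)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(doms) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  out <- list(doms[[1]])
  for (k in seq_along(doms)[-1]) {
    last <- out[[length(out)]]
    if (doms[[k]][1] - last[2] <= max_gap)
      out[[length(out)]][2] <- doms[[k]][2]
    else out[[length(out) + 1]] <- doms[[k]]
  }
  m <- do.call(rbind, out)
  keep <- (m[, 2] - m[, 1]) >= min_len
  data.frame(start = m[keep, 1], end = m[keep, 2])
}

# Insulation raw score: explicit double loop collecting the w x w
# square of values up-left/down-right of each bin.
bf_insulation_raw <- function(V, w) {
  n <- nrow(V)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    vals <- c()
    for (jj in (i + 1):(i + w))        # column-major collection
      for (ii in (i - w):(i - 1))
        vals <- c(vals, V[ii, jj])
    if (all(is.na(vals))) next
    raw[i] <- mean(vals, na.rm = TRUE)
  }
  raw
}

# Exact Mann-Whitney p-value by full enumeration of all
# choose(n_a + n_b, n_a) group assignments of the pooled mid-ranks.
bf_ranksum_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  U_all <- apply(idx, 2, function(ii)
    sum(r[ii]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  switch(alternative,
         greater = mean(U_all >= U_obs),
         less = mean(U_all <= U_obs),
         two.sided = min(1, 2 * min(mean(U_all >= U_obs),
                                    mean(U_all <= U_obs))))
}

# tiny config for fast unit tests
small_config <- function(...) {
  args <- list(...)
  defaults <- list(chrom_length = 2e6, hic_bin = 5e4,
                   compartment_bin = 2e5, repli_bin = 1e5, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# symmetric count matrix with an exact grand total (counting each pair
# once), for subsampling tests
random_count_matrix <- function(n, total, seed) {
  set.seed(seed)
  up <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  counts <- stats::rmultinom(1, total, prob = stats::runif(length(up)))
  C <- matrix(0, n, n)
  C[up] <- counts
  C + t(C) - diag(diag(C))
}
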
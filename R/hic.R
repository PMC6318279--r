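#' Construct a Hi-C contact matrix
#'
#' @param counts Symmetric non-negative square matrix of contact counts.
#' @param bin_size Bin size in bp.
#' @param chrom Chromosome name.
#' @param haplotype Optional haplotype/sample label.
#' @return An object of class `contact_matrix`: list with `counts`,
#'   `bin_size`, `chrom`, `haplotype`, and after [kr_balance()] also
#'   `weights`, `mask` and `balanced`.
#' @export
contact_matrix <- function(counts, bin_size, chrom = "chr",
                           haplotype = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("counts must be square", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8)))
    stop("counts must be symmetric", call. = FALSE)
  structure(list(counts = counts, bin_size = bin_size, chrom = chrom,
                 haplotype = haplotype, weights = NULL,
                 mask = integer(0), balanced = NULL),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix %s [%s]: %d bins of %s bp, %.0f contacts%s\n",
              x$chrom, x$haplotype, nrow(x$counts),
              format(x$bin_size, big.mark = ","), matrix_total(x),
              if (!is.null(x$weights)) ", KR-balanced" else ""))
  invisible(x)
}

# balanced matrix if present, else raw counts
cm_values <- function(m) if (!is.null(m$balanced)) m$balanced else m$counts

# total contacts, counting each pair once
matrix_total <- function(m) {
  C <- m$counts
  sum(C[upper.tri(C, diag = TRUE)])
}

#' Aggregate a contact matrix to a coarser bin size
#'
#' Sums counts over `factor x factor` blocks of bins, e.g. to move from a
#' 100 kb matrix to the 500 kb resolution used for compartment analysis.
#'
#' @param m A [contact_matrix()].
#' @param factor Integer number of bins merged per new bin.
#' @return A new `contact_matrix` at `bin_size * factor`.
#' @export
aggregate_matrix <- function(m, factor) {
  stopifnot(inherits(m, "contact_matrix"), factor >= 1)
  factor <- as.integer(factor)
  n <- nrow(m$counts)
  grp <- (seq_len(n) - 1L) %/% factor + 1L
  ng <- max(grp)
  G <- matrix(0, n, ng)
  G[cbind(seq_len(n), grp)] <- 1
  contact_matrix(t(G) %*% m$counts %*% G, bin_size = m$bin_size * factor,
                 chrom = m$chrom, haplotype = m$haplotype)
}

#' Down-sample and equalise Hi-C samples
#'
#' First stage: every sample's genome-wide contact total is down-sampled
#' (without replacement) to the smallest sample's total. Second stage:
#' per-chromosome totals are equalised across samples to the
#' per-chromosome minimum, normalising residual DNA copy-number
#' differences. Symmetry is preserved throughout.
#'
#' @param samples Named list of samples; each sample is a named list of
#'   [contact_matrix()] objects keyed by chromosome.
#' @param seed Optional integer seed for the subsampling draws.
#' @return The list of samples with matched totals.
#' @export
downsample_equalize <- function(samples, seed = NULL) {
  stopifnot(length(samples) >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  totals <- vapply(samples, function(s)
    sum(vapply(s, matrix_total, numeric(1))), numeric(1))
  if (any(totals <= 0)) stop("empty sample", call. = FALSE)
  target <- min(totals)
  samples <- lapply(samples, function(s) subsample_sample(s, target))
  chroms <- names(samples[[1]])
  for (ch in chroms) {
    per <- vapply(samples, function(s) matrix_total(s[[ch]]), numeric(1))
    tgt <- min(per)
    for (i in seq_along(samples))
      samples[[i]][[ch]] <- subsample_matrix(samples[[i]][[ch]], tgt)
  }
  samples
}

# subsample a whole sample (list of matrices) jointly to `target` contacts
subsample_sample <- function(s, target) {
  cells <- lapply(s, function(m) {
    C <- m$counts
    C[upper.tri(C, diag = TRUE)]
  })
  counts <- unlist(cells, use.names = FALSE)
  keep <- draw_without_replacement(counts, target)
  off <- 0L
  for (i in seq_along(s)) {
    k <- length(cells[[i]])
    s[[i]] <- rebuild_upper(s[[i]], keep[(off + 1):(off + k)])
    off <- off + k
  }
  s
}

subsample_matrix <- function(m, target) {
  C <- m$counts
  up <- C[upper.tri(C, diag = TRUE)]
  rebuild_upper(m, draw_without_replacement(up, target))
}

# multivariate hypergeometric draw: keep `k` of sum(counts) unit contacts
draw_without_replacement <- function(counts, k) {
  N <- sum(counts)
  stopifnot(k <= N)
  if (k == N) return(counts)
  breaks <- cumsum(counts)
  picked <- sample.int(N, k)
  tabulate(findInterval(picked - 0.5, breaks) + 1L,
           nbins = length(counts))
}

rebuild_upper <- function(m, up) {
  n <- nrow(m$counts)
  C <- matrix(0, n, n)
  C[upper.tri(C, diag = TRUE)] <- up
  C <- C + t(C) - diag(diag(C))
  m$counts <- C
  m$weights <- NULL; m$balanced <- NULL; m$mask <- integer(0)
  m
}

#' Contact-probability decay with distance
#'
#' P(s) is the mean (balanced, if available) contact count at each
#' genomic separation s > 0, normalised to sum to 1; the slope is a
#' least-squares fit of log10 P against log10 s restricted to
#' `fit_range`. Also reports the fraction of contact probability in
#' far-cis interactions (> 10 Mb).
#'
#' @param m A [contact_matrix()].
#' @param fit_range Length-2 numeric, bp range of separations used for
#'   the log-log slope fit.
#' @return List with `ps` (data frame `separation`, `p`), `slope`,
#'   `far_cis_fraction`.
#' @export
distance_decay <- function(m, fit_range = c(2e5, 5e6)) {
  stopifnot(inherits(m, "contact_matrix"))
  V <- cm_values(m)
  n <- nrow(V)
  if (n < 3) stop("need at least 3 bins", call. = FALSE)
  seps <- seq_len(n - 1)
  p <- vapply(seps, function(s) {
    d <- V[cbind(seq_len(n - s), seq_len(n - s) + s)]
    mean(d, na.rm = TRUE)
  }, numeric(1))
  p[is.nan(p)] <- NA
  tot <- sum(p, na.rm = TRUE)
  if (tot <= 0) stop("no contacts off the diagonal", call. = FALSE)
  p <- p / tot
  sep_bp <- seps * m$bin_size
  in_fit <- !is.na(p) & p > 0 & sep_bp >= fit_range[1] &
    sep_bp <= fit_range[2]
  if (sum(in_fit) < 3)
    stop("fit_range contains fewer than 3 usable separations",
         call. = FALSE)
  fit <- stats::lm(log10(p[in_fit]) ~ log10(sep_bp[in_fit]))
  list(ps = data.frame(separation = sep_bp, p = p),
       slope = unname(stats::coef(fit)[2]),
       far_cis_fraction = sum(p[sep_bp > 1e7], na.rm = TRUE))
}

#' Insulation score along the matrix diagonal
#'
#' The raw score at bin i is the mean contact value in the square window
#' pairing the `w` bins left of i with the `w` bins right of i
#' (`w = window / bin_size`); the reported score is log2 of the raw
#' score over the chromosome-wide mean of raw scores. The delta track is
#' the mean score over the `d` bins right of i minus the mean over the
#' `d` bins left (`d = delta_span / bin_size`); boundaries are called at
#' score minima where delta crosses zero from negative to positive with
#' crossing strength (delta amplitude across the crossing) above
#' `min_strength`.
#'
#' @param m A [contact_matrix()] (balanced values used when available).
#' @param window Square window size in bp.
#' @param delta_span Delta half-span in bp.
#' @param min_strength Minimum delta crossing strength for a boundary.
#' @return An `insulation_track`: list with `bin_size`, `raw`, `score`,
#'   `delta`, `boundaries` (1-based bin indices).
#' @export
insulation_score <- function(m, window = 5e5, delta_span = 2e5,
                             min_strength = 0.1) {
  stopifnot(inherits(m, "contact_matrix"))
  V <- cm_values(m)
  n <- nrow(V)
  w <- as.integer(round(window / m$bin_size))
  d <- as.integer(round(delta_span / m$bin_size))
  if (w < 2) stop("window must span at least 2 bins", call. = FALSE)
  if (2 * w + 1 > n) stop("window does not fit in the chromosome",
                          call. = FALSE)
  raw <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    block <- V[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
    v <- mean(block, na.rm = TRUE)
    raw[i] <- if (is.nan(v)) NA else v
  }
  mu <- mean(raw, na.rm = TRUE)
  score <- log2(raw / mu)
  score[!is.finite(score)] <- NA
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1, i - d); hi <- min(n, i + d)
    if (i - lo < 1 || hi - i < 1) next
    right <- mean(score[(i + 1):hi], na.rm = TRUE)
    left <- mean(score[lo:(i - 1)], na.rm = TRUE)
    if (is.nan(right) || is.nan(left)) next
    delta[i] <- right - left
  }
  boundaries <- integer(0)
  strengths <- numeric(0)
  for (i in seq_len(n - 1)) {
    if (is.na(delta[i]) || is.na(delta[i + 1])) next
    if (delta[i] < 0 && delta[i + 1] >= 0) {
      lo <- max(1, i - d); hi <- min(n, i + 1 + d)
      s <- max(delta[(i + 1):hi], na.rm = TRUE) -
        min(delta[lo:i], na.rm = TRUE)
      if (is.finite(s) && s >= min_strength) {
        b <- if (!is.na(score[i + 1]) &&
                 (is.na(score[i]) || score[i + 1] < score[i])) i + 1L else i
        boundaries <- c(boundaries, b)
        strengths <- c(strengths, s)
      }
    }
  }
  structure(list(chrom = m$chrom, bin_size = m$bin_size, raw = raw,
                 score = score, delta = delta, boundaries = boundaries,
                 boundary_strength = strengths),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat(sprintf("Insulation track %s: %d bins of %s bp, %d boundaries\n",
              x$chrom, length(x$score), format(x$bin_size, big.mark = ","),
              length(x$boundaries)))
  invisible(x)
}

#' A/B compartment first eigenvector
#'
#' Computes observed/expected counts (expected = per-diagonal mean over
#' unmasked bins), the Pearson correlation matrix of O/E columns, and its
#' first eigenvector. Bins with marginal coverage below the
#' `coverage_quantile` quantile (or zero) are masked. The sign is
#' oriented so the eigenvector correlates positively with
#' `gene_density`; positive values are labelled A, negative B.
#'
#' @param m A [contact_matrix()] (balanced values used when available).
#' @param gene_density Optional numeric per-bin track used to orient the
#'   eigenvector (A = gene dense).
#' @param coverage_quantile Marginal-coverage quantile below which bins
#'   are masked.
#' @return A `compartment_profile`: list with `bin_size`, `eigenvector`
#'   (NA at masked bins), `label` ("A"/"B"/NA), `masked`.
#' @export
compartment_eigenvector <- function(m, gene_density = NULL,
                                    coverage_quantile = 0.005) {
  stopifnot(inherits(m, "contact_matrix"))
  V <- cm_values(m)
  n <- nrow(V)
  marg <- rowSums(m$counts)
  cut <- stats::quantile(marg[marg > 0], coverage_quantile)
  keep <- which(marg > 0 & marg >= cut)
  if (length(keep) < 10)
    stop("need at least 10 unmasked bins", call. = FALSE)
  A <- V[keep, keep, drop = FALSE]
  k <- nrow(A)
  idx <- abs(outer(seq_len(k), seq_len(k), "-"))
  expd <- vapply(0:(k - 1), function(s)
    mean(A[idx == s], na.rm = TRUE), numeric(1))
  OE <- A / expd[idx + 1]
  OE[!is.finite(OE)] <- NA
  if (any(apply(OE, 2, function(col) stats::sd(col, na.rm = TRUE)) == 0,
          na.rm = TRUE))
    stop("degenerate O/E matrix: constant columns; ",
         "check coverage filtering", call. = FALSE)
  P <- suppressWarnings(stats::cor(OE, use = "pairwise.complete.obs"))
  P[!is.finite(P)] <- 0
  ev <- eigen(P, symmetric = TRUE)$vectors[, 1]
  full <- rep(NA_real_, n)
  full[keep] <- ev
  if (!is.null(gene_density)) {
    r <- suppressWarnings(stats::cor(ev, gene_density[keep],
                                     use = "complete.obs"))
    if (!is.na(r) && r < 0) full <- -full
  }
  lab <- ifelse(is.na(full), NA_character_,
                ifelse(full >= 0, "A", "B"))
  structure(list(chrom = m$chrom, bin_size = m$bin_size,
                 eigenvector = full, label = lab,
                 masked = setdiff(seq_len(n), keep)),
            class = "compartment_profile")
}

#' Pearson correlation between two compartment eigenvectors
#'
#' @param profile_1,profile_2 `compartment_profile` objects (or numeric
#'   vectors) on the same bin grid.
#' @return Pearson r over bins defined in both.
#' @export
eigenvector_correlation <- function(profile_1, profile_2) {
  v1 <- if (inherits(profile_1, "compartment_profile"))
    profile_1$eigenvector else profile_1
  v2 <- if (inherits(profile_2, "compartment_profile"))
    profile_2$eigenvector else profile_2
  ok <- !is.na(v1) & !is.na(v2)
  if (sum(ok) < 3)
    stop("need at least 3 bins defined in both profiles", call. = FALSE)
  stats::cor(v1[ok], v2[ok])
}

#' TAD re-establishment score
#'
#' For each TAD, sums contact counts over bin pairs inside the TAD
#' separated by more than `min_sep`, in a wild-type and a mutant matrix
#' with matched totals (see [downsample_equalize()]); the score is
#' `(C_mut - C_wt) / C_wt`. TADs are classed by the quartiles of the
#' score distribution: `weak` < Q1, `strong` > Q3, `medium` otherwise.
#'
#' @param tads Data frame of TAD intervals (`start`, `end`, bp).
#' @param wt,mut [contact_matrix()] objects on the same grid.
#' @param min_sep Minimum pair separation scored, in bp.
#' @return The `tads` data frame with `c_wt`, `c_mut`, `score`, `class`
#'   appended (`score` NA where `c_wt` is 0).
#' @export
tad_reestablishment <- function(tads, wt, mut, min_sep = 1e5) {
  stopifnot(inherits(wt, "contact_matrix"),
            inherits(mut, "contact_matrix"),
            wt$bin_size == mut$bin_size,
            nrow(wt$counts) == nrow(mut$counts))
  bs <- wt$bin_size
  n <- nrow(wt$counts)
  tad_sum <- function(C, b) {
    if (length(b) < 2) return(0)
    sub <- C[b, b, drop = FALSE]
    k <- length(b)
    sep <- abs(outer(seq_len(k), seq_len(k), "-")) * bs
    sum(sub[upper.tri(sub) & sep > min_sep])
  }
  c_wt <- c_mut <- numeric(nrow(tads))
  for (i in seq_len(nrow(tads))) {
    b <- bin_span(tads$start[i], tads$end[i], bs, n)
    c_wt[i] <- tad_sum(wt$counts, b)
    c_mut[i] <- tad_sum(mut$counts, b)
  }
  score <- ifelse(c_wt > 0, (c_mut - c_wt) / c_wt, NA_real_)
  q <- stats::quantile(score, c(0.25, 0.75), na.rm = TRUE)
  cls <- ifelse(is.na(score), NA_character_,
                ifelse(score < q[1], "weak",
                       ifelse(score > q[2], "strong", "medium")))
  out <- tads
  out$c_wt <- c_wt; out$c_mut <- c_mut
  out$score <- score; out$class <- cls
  out
}

#' Insulation at a reference boundary set across samples
#'
#' @param boundaries Integer vector of boundary bin indices (1-based),
#'   e.g. from the wild-type active-X [insulation_score()] track.
#' @param tracks Named list of `insulation_track` objects on the same
#'   grid.
#' @return Data frame: `boundary` plus one score column per sample,
#'   suitable for paired rank tests.
#' @export
insulation_at_boundaries <- function(boundaries, tracks) {
  out <- data.frame(boundary = boundaries)
  for (nm in names(tracks)) {
    sc <- tracks[[nm]]$score
    if (any(boundaries < 1 | boundaries > length(sc)))
      stop("boundary outside track range", call. = FALSE)
    out[[nm]] <- sc[boundaries]
  }
  out
}
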
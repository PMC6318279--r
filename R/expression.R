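#' Estimate chromosomal copy-number factors from allelic input coverage
#'
#' The factor for each (chromosome, haplotype) is its median per-bin
#' allelic input coverage divided by the reference chromosome's
#' per-haplotype expectation (the mean of the reference's two haplotype
#' medians), so that the reference chromosome's combined factor is
#' exactly 1.
#'
#' @param tracks Named list of [allelic_track()] objects keyed by
#'   chromosome (ChIP-seq input or Repli-seq coverage).
#' @param reference Name of the reference (diploid autosome) chromosome.
#' @return A `copy_number_factors` data frame: `chrom`, `haplotype`,
#'   `factor`.
#' @export
estimate_copy_number <- function(tracks, reference) {
  stopifnot(reference %in% names(tracks))
  med <- function(tr, hap)
    stats::median(tr[[paste0("values_", hap)]])
  ref <- tracks[[reference]]
  ref_expect <- mean(c(med(ref, "hap1"), med(ref, "hap2")))
  if (ref_expect <= 0)
    stop("reference chromosome has zero allelic input coverage",
         call. = FALSE)
  rows <- list()
  for (ch in names(tracks)) {
    for (hap in c("hap1", "hap2")) {
      m <- med(tracks[[ch]], hap)
      if (m <= 0)
        stop("zero allelic input coverage on ", ch, " ", hap,
             call. = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, haplotype = hap, factor = m / ref_expect,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("copy_number_factors", "data.frame")
  out
}

copy_factor <- function(factors, chrom, hap) {
  f <- factors$factor[factors$chrom == chrom &
                        factors$haplotype == hap]
  if (length(f) != 1)
    stop("no copy-number factor for ", chrom, " ", hap, call. = FALSE)
  f
}

#' Copy-number- and length-normalised allelic expression
#'
#' Expression = count / copy-number factor / gene length in kb, i.e.
#' reads per kb of gene body after correcting chromosomal copy number.
#' Adds columns `expr_<hap>_<cond>` for every `count_<hap>_<cond>`
#' column present, plus `xi_percent_wt` / `xi_percent_mut` (Xi
#' expression as % of Xa; NA where Xa expression is 0).
#'
#' @param records Gene data frame with `chrom`, `start`, `end` and
#'   `count_xa_*` / `count_xi_*` columns; Xa is taken to be haplotype 1
#'   and Xi haplotype 2 unless `xa_hap` says otherwise.
#' @param factors A `copy_number_factors` data frame from
#'   [estimate_copy_number()], or NULL for unit factors.
#' @param xa_hap Which haplotype is the active X.
#' @return The records with expression and percent columns appended.
#' @export
normalize_expression <- function(records, factors = NULL,
                                 xa_hap = "hap1") {
  len_kb <- (records$end - records$start) / 1000
  if (any(len_kb <= 0)) stop("gene length must be positive", call. = FALSE)
  xi_hap <- if (xa_hap == "hap1") "hap2" else "hap1"
  count_cols <- grep("^count_(xa|xi)_", names(records), value = TRUE)
  for (cc in count_cols) {
    allele <- sub("^count_(xa|xi)_.*$", "\\1", cc)
    hap <- if (allele == "xa") xa_hap else xi_hap
    f <- if (is.null(factors)) 1
         else vapply(records$chrom, copy_factor, numeric(1),
                     factors = factors, hap = hap)
    records[[sub("^count_", "expr_", cc)]] <- records[[cc]] / f / len_kb
  }
  for (cond in c("wt", "mut")) {
    xa <- records[[paste0("expr_xa_", cond)]]
    xi <- records[[paste0("expr_xi_", cond)]]
    if (!is.null(xa) && !is.null(xi))
      records[[paste0("xi_percent_", cond)]] <- xi_percent(xi, xa)
  }
  records
}

#' Xi expression as a percentage of Xa expression
#'
#' @param xi,xa Expression values (vectorised).
#' @return `100 * xi / xa`; NA where `xa` is 0 (such genes are excluded
#'   from percent summaries).
#' @export
xi_percent <- function(xi, xa) ifelse(xa > 0, 100 * xi / xa, NA_real_)

# Binomial test of allelic fraction x / n against p0: exact below 1000
# total counts, normal approximation with continuity correction above.
allelic_fraction_test <- function(x, n, p0,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  if (n == 0) return(1)
  if (n < 1000)
    return(stats::binom.test(x, n, p0,
                             alternative = alternative)$p.value)
  mu <- n * p0
  sd <- sqrt(n * p0 * (1 - p0))
  z_hi <- (x - 0.5 - mu) / sd
  z_lo <- (x + 0.5 - mu) / sd
  switch(alternative,
         greater = stats::pnorm(z_hi, lower.tail = FALSE),
         less = stats::pnorm(z_lo),
         two.sided = min(1, 2 * min(stats::pnorm(z_hi, lower.tail = FALSE),
                                    stats::pnorm(z_lo))))
}

#' Classify X-linked genes by their silencing response
#'
#' Genes expressed on Xa are split into four Xi classes:
#' \describe{
#'   \item{escapee}{expressed from the wild-type Xi: wt Xi counts
#'     significantly above the silenced background (`escape_threshold`
#'     fraction of Xa) and wt Xi/Xa at or above the threshold.}
#'   \item{dependent}{silenced in wt but reactivated in the mutant to a
#'     level not significantly different from Xa: mutant Xi
#'     significantly above wt Xi, mutant Xi vs Xa not significant.}
#'   \item{partial}{reactivated but still significantly below Xa.}
#'   \item{independent}{otherwise (remains silenced on Xi).}
#' }
#' Significance uses the binomial allelic-fraction test (exact below
#' 1000 counts, normal approximation above) with Benjamini-Hochberg
#' correction per test family at level `alpha`. The Xi-vs-Xa null
#' fraction is 0.5 after copy-number correction; the
#' derepression test compares mutant and wild-type Xi counts against the
#' conditions' sequencing-depth ratio (estimated from total Xa counts).
#'
#' @param records Gene data frame with `count_xa_wt`, `count_xi_wt`,
#'   `count_xa_mut`, `count_xi_mut` (and anything else, carried
#'   through).
#' @param alpha BH-adjusted significance level.
#' @param escape_threshold Silenced-background Xi expression as a
#'   fraction of Xa (default 0.10).
#' @param xi_null_fraction Expected Xi read fraction of Xi+Xa under
#'   equal expression (0.5 after copy-number equalisation).
#' @return The records (genes with zero Xa counts in both conditions
#'   dropped) with `class`, `xi_percent_wt`, `xi_percent_mut`, and the
#'   three BH-adjusted p-value columns; class counts in
#'   `attr(, "class_counts")`.
#' @export
classify_genes <- function(records, alpha = 0.05,
                           escape_threshold = 0.10,
                           xi_null_fraction = 0.5) {
  keep <- (records$count_xa_wt + records$count_xa_mut) > 0
  records <- records[keep, , drop = FALSE]
  n <- nrow(records)
  if (n == 0) stop("no genes expressed on Xa", call. = FALSE)
  t <- escape_threshold
  p_bg <- t * xi_null_fraction / (t * xi_null_fraction +
                                    (1 - xi_null_fraction))
  depth_mut <- sum(records$count_xa_mut)
  depth_wt <- sum(records$count_xa_wt)
  p_depth <- depth_mut / (depth_mut + depth_wt)

  p_escape <- p_dererep <- p_vs_xa <- numeric(n)
  for (i in seq_len(n)) {
    xiw <- records$count_xi_wt[i]; xaw <- records$count_xa_wt[i]
    xim <- records$count_xi_mut[i]; xam <- records$count_xa_mut[i]
    p_escape[i] <- allelic_fraction_test(xiw, xiw + xaw, p_bg, "greater")
    p_dererep[i] <- allelic_fraction_test(xim, xim + xiw, p_depth,
                                          "greater")
    p_vs_xa[i] <- allelic_fraction_test(xim, xim + xam,
                                        xi_null_fraction, "two.sided")
  }
  q_escape <- stats::p.adjust(p_escape, "BH")
  q_dererep <- stats::p.adjust(p_dererep, "BH")
  q_vs_xa <- stats::p.adjust(p_vs_xa, "BH")

  xi_pct_wt <- xi_percent(records$count_xi_wt, records$count_xa_wt)
  xi_pct_mut <- xi_percent(records$count_xi_mut, records$count_xa_mut)
  frac_mut <- ifelse(records$count_xi_mut + records$count_xa_mut > 0,
                     records$count_xi_mut /
                       (records$count_xi_mut + records$count_xa_mut), NA)

  cls <- rep("independent", n)
  is_escapee <- q_escape < alpha & !is.na(xi_pct_wt) &
    xi_pct_wt >= 100 * escape_threshold
  derep <- !is_escapee & q_dererep < alpha
  cls[derep & q_vs_xa >= alpha] <- "dependent"
  cls[derep & q_vs_xa < alpha & !is.na(frac_mut) &
        frac_mut < xi_null_fraction] <- "partial"
  cls[is_escapee] <- "escapee"

  records$class <- cls
  records$xi_percent_wt <- xi_pct_wt
  records$xi_percent_mut <- xi_pct_mut
  records$q_escape <- q_escape
  records$q_derepression <- q_dererep
  records$q_vs_xa <- q_vs_xa
  counts <- table(factor(cls, levels = c("escapee", "dependent",
                                         "partial", "independent")))
  attr(records, "class_counts") <- stats::setNames(as.integer(counts),
                                                   names(counts))
  records
}
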
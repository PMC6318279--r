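#' Mann-Whitney rank-sum test
#'
#' Two-sided by default; the exact null distribution is used when the
#' combined sample size is at most 20 and there are no ties, otherwise
#' the normal approximation with mid-rank tie correction and continuity
#' correction.
#'
#' @param values_a,values_b Numeric vectors (each non-empty).
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return List with `statistic` (Mann-Whitney U for group a),
#'   `p_value`, `method`.
#' @export
rank_sum_test <- function(values_a, values_b,
                          alternative = c("two.sided", "greater",
                                          "less")) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups need at least one value", call. = FALSE)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (length(values_a) + length(values_b) <= 20) && !ties
  ht <- stats::wilcox.test(values_a, values_b,
                           alternative = alternative,
                           exact = exact, correct = TRUE)
  p <- ht$p.value
  if (is.nan(p)) p <- 1   # zero-variance degenerate case: all values tied
  list(statistic = unname(ht$statistic), p_value = p,
       method = if (exact) "exact" else "normal approximation")
}

#' Bonferroni correction
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param m Number of comparisons (default `length(p_values)`).
#' @return `min(1, m * p)` element-wise.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p_values)
}

#' Contrast a binned track inside vs outside a domain set
#'
#' Splits the track's defined bins into those whose midpoint lies inside
#' any domain and the rest, compares the groups with the rank-sum test
#' and reports boxplot summaries (quartiles, median) per group — the
#' analysis behind comparisons of methylation/transcription/enrichment
#' within depletion domains against the rest of the chromosome.
#'
#' @param track A track accepted by [call_depletion_domains()] (list
#'   with `values`/`log2_ratio` and `bin_size`, or numeric plus
#'   `bin_size`).
#' @param domains Data frame of intervals (`start`, `end`, bp).
#' @param alternative Passed to [rank_sum_test()].
#' @param bin_size Bin size when `track` is a bare numeric vector.
#' @return A `region_contrast` list: group sizes, medians, quartiles,
#'   `statistic`, `p_value`.
#' @export
contrast_by_regions <- function(track, domains,
                                alternative = "two.sided",
                                bin_size = NULL) {
  tv <- track_values(track, bin_size)
  v <- tv$values; bs <- tv$bin_size
  mid <- (seq_along(v) - 0.5) * bs
  inside <- rep(FALSE, length(v))
  for (k in seq_len(nrow(domains)))
    inside <- inside | (mid >= domains$start[k] & mid < domains$end[k])
  g_in <- v[inside & !is.na(v)]
  g_out <- v[!inside & !is.na(v)]
  if (length(g_in) == 0 || length(g_out) == 0)
    stop("inside/outside group is empty", call. = FALSE)
  test <- rank_sum_test(g_in, g_out, alternative = alternative)
  qs <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75))
  structure(list(n_inside = length(g_in), n_outside = length(g_out),
                 inside = g_in, outside = g_out,
                 median_inside = stats::median(g_in),
                 median_outside = stats::median(g_out),
                 quartiles_inside = qs(g_in),
                 quartiles_outside = qs(g_out),
                 statistic = test$statistic, p_value = test$p_value),
            class = "region_contrast")
}

#' @export
print.region_contrast <- function(x, ...) {
  cat(sprintf(
    "Region contrast: inside n=%d median %.3f | outside n=%d median %.3f | p = %.3g\n",
    x$n_inside, x$median_inside, x$n_outside, x$median_outside,
    x$p_value))
  invisible(x)
}

#' Overlap statistics between two domain sets
#'
#' Base-pair Jaccard index (|A intersect B| / |A union B| after merging
#' self-overlaps) plus per-domain matched flags at a reciprocal-overlap
#' fraction threshold: a domain is matched if some domain of the other
#' set covers at least `reciprocal` of both domains' lengths.
#'
#' @param set_a,set_b Data frames of intervals (`start`, `end`, bp).
#' @param reciprocal Reciprocal-overlap fraction (default 0.25).
#' @return List with `jaccard`, `matched_a`, `matched_b` (logical
#'   vectors), `n_matched_a`, `n_matched_b`.
#' @export
domain_overlap <- function(set_a, set_b, reciprocal = 0.25) {
  to_ir <- function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
  if (nrow(set_a) == 0 || nrow(set_b) == 0)
    return(list(jaccard = 0,
                matched_a = logical(nrow(set_a)),
                matched_b = logical(nrow(set_b)),
                n_matched_a = 0L, n_matched_b = 0L))
  ia <- to_ir(set_a); ib <- to_ir(set_b)
  inter <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  uni <- sum(IRanges::width(IRanges::union(ia, ib)))
  ja <- IRanges::IRanges(start = set_a$start + 1, end = set_a$end)
  jb <- IRanges::IRanges(start = set_b$start + 1, end = set_b$end)
  hits <- IRanges::findOverlaps(ja, jb)
  ov <- IRanges::width(IRanges::pintersect(
    ja[S4Vectors::queryHits(hits)], jb[S4Vectors::subjectHits(hits)]))
  good <- ov >= reciprocal * IRanges::width(ja[S4Vectors::queryHits(hits)]) &
    ov >= reciprocal * IRanges::width(jb[S4Vectors::subjectHits(hits)])
  matched_a <- seq_len(nrow(set_a)) %in%
    S4Vectors::queryHits(hits)[good]
  matched_b <- seq_len(nrow(set_b)) %in%
    S4Vectors::subjectHits(hits)[good]
  list(jaccard = if (uni > 0) inter / uni else 0,
       matched_a = matched_a, matched_b = matched_b,
       n_matched_a = sum(matched_a), n_matched_b = sum(matched_b))
}
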
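#' ChIP enrichment track: log2(IP/input) at fine bins averaged into
#' coarse bins
#'
#' IP counts are library-size scaled to the input totals, a pseudocount
#' is added to both, and the per-fine-bin log2 ratio is averaged (missing
#' aware) within each coarse bin. Fine bins with zero input coverage are
#' treated as missing; a coarse bin with no defined fine bins is missing.
#'
#' @param ip,input Numeric vectors of read counts per fine bin (e.g. one
#'   haplotype layer of an [allelic_track()]).
#' @param fine_bin,coarse_bin Bin sizes in bp; `coarse_bin` must be a
#'   multiple of `fine_bin`.
#' @param pseudocount Added to both IP and input before the ratio.
#' @param lib_scale IP-to-input library scaling factor; `NULL` computes
#'   `sum(input) / sum(ip)`.
#' @param chrom Chromosome name.
#' @return An `enrichment_track`: list with `bin_size` (= coarse),
#'   `log2_ratio` (one value per coarse bin), and the `fine_bin` /
#'   `fine_values` it was averaged from.
#' @export
enrichment_track <- function(ip, input, fine_bin = 500,
                             coarse_bin = 10000, pseudocount = 1,
                             lib_scale = NULL, chrom = "chr") {
  if (coarse_bin %% fine_bin != 0)
    stop("coarse_bin must be a multiple of fine_bin", call. = FALSE)
  stopifnot(length(ip) == length(input))
  if (is.null(lib_scale)) {
    if (sum(ip) == 0) stop("IP track has no reads", call. = FALSE)
    lib_scale <- sum(input) / sum(ip)
  }
  fine <- log2((ip * lib_scale + pseudocount) / (input + pseudocount))
  fine[input == 0] <- NA
  ratio <- coarse_bin / fine_bin
  grp <- (seq_along(fine) - 1L) %/% ratio + 1L
  coarse <- vapply(split(fine, grp), function(v) {
    m <- mean(v, na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }, numeric(1))
  structure(list(chrom = chrom, bin_size = coarse_bin,
                 log2_ratio = unname(coarse),
                 fine_bin = fine_bin, fine_values = fine),
            class = "enrichment_track")
}

#' @export
print.enrichment_track <- function(x, ...) {
  cat(sprintf("Enrichment track %s: %d bins of %s bp, mean log2 ratio %.2f\n",
              x$chrom, length(x$log2_ratio),
              format(x$bin_size, big.mark = ","),
              mean(x$log2_ratio, na.rm = TRUE)))
  invisible(x)
}

# accept an enrichment_track, a list(bin_size, values), or a numeric
# vector with an explicit bin size
track_values <- function(track, bin_size = NULL) {
  if (inherits(track, "enrichment_track"))
    return(list(values = track$log2_ratio, bin_size = track$bin_size))
  if (is.list(track)) {
    v <- if (!is.null(track$log2_ratio)) track$log2_ratio else track$values
    return(list(values = v, bin_size = track$bin_size))
  }
  if (is.null(bin_size))
    stop("numeric track needs an explicit bin_size", call. = FALSE)
  list(values = track, bin_size = bin_size)
}

#' Call depletion domains from a binned enrichment track
#'
#' Maximal runs of bins whose value is below `threshold` become domains;
#' adjacent domains separated by no more than `max_gap` bp are merged
#' transitively (the bound is inclusive, and missing bins inside a gap
#' count toward its length); merged domains shorter than `min_len` are
#' dropped. This is the H3K27me3 depletion-domain definition: regions of
#' mean log2(IP/input) < 0 with gaps of at most 20 kb merged.
#'
#' @param track An `enrichment_track` (or list with `values`/`log2_ratio`
#'   and `bin_size`, or numeric vector plus `bin_size`).
#' @param threshold Bins strictly below this value are "depleted".
#' @param max_gap Maximum separating gap merged, bp (inclusive).
#' @param min_len Minimum domain length kept, bp.
#' @param bin_size Bin size when `track` is a bare numeric vector.
#' @param chrom Chromosome name for the output.
#' @return List with `domains` (data frame `chrom`, `start`, `end`,
#'   `label`), `count` and `mean_length` (bp, NA when no domains).
#' @export
call_depletion_domains <- function(track, threshold = 0, max_gap = 20000,
                                   min_len = 0, bin_size = NULL,
                                   chrom = "chr") {
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  tv <- track_values(track, bin_size)
  v <- tv$values; bs <- tv$bin_size
  below <- !is.na(v) & v < threshold
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  neg <- which(runs$values)
  if (length(neg) == 0)
    return(list(domains = empty_domains(), count = 0L,
                mean_length = NA_real_))
  dom <- data.frame(start = (starts[neg] - 1L) * bs,
                    end = ends[neg] * bs)
  # inclusive transitive merge over gaps <= max_gap
  merged <- dom[1, , drop = FALSE]
  if (nrow(dom) > 1) {
    for (i in 2:nrow(dom)) {
      gap <- dom$start[i] - merged$end[nrow(merged)]
      if (gap <= max_gap) merged$end[nrow(merged)] <- dom$end[i]
      else merged <- rbind(merged, dom[i, ])
    }
  }
  merged <- merged[merged$end - merged$start >= min_len, , drop = FALSE]
  rownames(merged) <- NULL
  n <- nrow(merged)
  if (n == 0)
    return(list(domains = empty_domains(), count = 0L,
                mean_length = NA_real_))
  list(domains = data.frame(chrom = chrom, start = merged$start,
                            end = merged$end, label = "depletion",
                            stringsAsFactors = FALSE),
       count = n,
       mean_length = if (n) mean(merged$end - merged$start) else NA_real_)
}

empty_domains <- function()
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             label = character(0), stringsAsFactors = FALSE)

#' Allelic specificity score of a peak
#'
#' `100 * (Xi - Xa) / (Xi + Xa)`: 100 means fully Xi-specific, -100
#' fully Xa-specific. Vectorised; peaks with zero total are flagged NA.
#'
#' @param xi,xa Non-negative (input-corrected) allelic read counts.
#' @return Numeric score(s) in \[-100, 100\], NA where `xi + xa == 0`.
#' @export
allelic_specificity_score <- function(xi, xa) {
  stopifnot(all(xi >= 0, na.rm = TRUE), all(xa >= 0, na.rm = TRUE))
  tot <- xi + xa
  ifelse(tot > 0, 100 * (xi - xa) / tot, NA_real_)
}

#' Classify a peak as Xi-specific, Xa-specific or present on both
#'
#' A peak is chromosome-exclusive only when strictly more than
#' `exclusivity` (default 90%) of its allelic reads map to one
#' haplotype.
#'
#' @param xi,xa Allelic read counts (vectorised).
#' @param exclusivity Exclusive-fraction threshold (strict inequality).
#' @return Character vector: `"Xi-specific"`, `"Xa-specific"` or
#'   `"both"`; NA where the total is zero.
#' @export
classify_peak_allelicity <- function(xi, xa, exclusivity = 0.90) {
  tot <- xi + xa
  frac_xi <- ifelse(tot > 0, xi / tot, NA_real_)
  ifelse(is.na(frac_xi), NA_character_,
         ifelse(frac_xi > exclusivity, "Xi-specific",
                ifelse(1 - frac_xi > exclusivity, "Xa-specific", "both")))
}

#' Threshold peak caller on a binned track
#'
#' Maximal runs of at least `min_bins` bins at or above `threshold`.
#' A plumbing-level stand-in for model-based peak callers, used on
#' synthetic tracks where peak truth is planted.
#'
#' @inheritParams call_depletion_domains
#' @param min_bins Minimum run length, in bins.
#' @return Data frame of peak intervals (`chrom`, `start`, `end`).
#' @export
call_peaks_simple <- function(track, threshold, min_bins = 1,
                              bin_size = NULL, chrom = "chr") {
  tv <- track_values(track, bin_size)
  v <- tv$values; bs <- tv$bin_size
  high <- !is.na(v) & v >= threshold
  runs <- rle(high)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= min_bins)
  data.frame(chrom = rep(chrom, length(keep)),
             start = (starts[keep] - 1) * bs, end = ends[keep] * bs,
             stringsAsFactors = FALSE)
}

#' Binned CpG methylation track
#'
#' Sites covered by fewer than `min_coverage` reads are excluded; the bin
#' value is the mean percent methylation (100 * meth / total) over
#' retained sites, NA for bins without retained sites.
#'
#' @param sites Data frame with `pos`, `meth_count`, `total_count`.
#' @param bin_size Bin size in bp.
#' @param min_coverage Minimum reads per retained site.
#' @param chrom_length Chromosome length (bp); defaults to covering the
#'   last site.
#' @param chrom Chromosome name.
#' @return List with `chrom`, `bin_size`, `values` (% methylation per
#'   bin, NA where empty) and `n_sites` per bin.
#' @export
methylation_track <- function(sites, bin_size = 10000, min_coverage = 3,
                              chrom_length = NULL, chrom = "chr") {
  if (any(sites$meth_count > sites$total_count))
    stop("meth_count exceeds total_count", call. = FALSE)
  if (is.null(chrom_length))
    chrom_length <- if (nrow(sites)) max(sites$pos) + 1 else bin_size
  n_bins <- max(1L, as.integer(ceiling(chrom_length / bin_size)))
  keep <- sites$total_count >= min_coverage
  s <- sites[keep, , drop = FALSE]
  vals <- rep(NA_real_, n_bins)
  nsit <- integer(n_bins)
  if (nrow(s)) {
    bin <- pmin(s$pos %/% bin_size + 1L, n_bins)
    pct <- 100 * s$meth_count / s$total_count
    agg <- tapply(pct, bin, mean)
    idx <- as.integer(names(agg))
    vals[idx] <- as.numeric(agg)
    nsit <- tabulate(bin, nbins = n_bins)
  }
  list(chrom = chrom, bin_size = bin_size, values = vals,
       n_sites = nsit)
}

# overlap-weighted, missing-aware mean of a binned track over [a, b)
interval_mean <- function(values, bin_size, a, b) {
  if (b <= a) return(NA_real_)
  i0 <- floor(a / bin_size) + 1
  i1 <- floor((b - 1e-9) / bin_size) + 1
  i1 <- min(i1, length(values))
  if (i0 > length(values)) return(NA_real_)
  idx <- i0:i1
  lo <- pmax((idx - 1) * bin_size, a)
  hi <- pmin(idx * bin_size, b)
  w <- hi - lo
  v <- values[idx]
  ok <- !is.na(v) & w > 0
  if (!any(ok)) return(NA_real_)
  sum(v[ok] * w[ok]) / sum(w[ok])
}

#' Metagene profile over scaled gene bodies with fixed flanks
#'
#' Each gene body is rescaled to `n_body_bins` windows; the `flank` bp
#' up- and downstream are split into `n_flank_bins` fixed-width windows.
#' Per-window values are overlap-weighted means of the track; profiles of
#' minus-strand genes are reversed before the missing-aware average
#' across genes. Genes shorter than one bp per body bin are skipped with
#' a warning.
#'
#' @param genes Data frame with `start`, `end` and optional `strand`.
#' @param track List with `values` and `bin_size` (e.g. from
#'   [methylation_track()]) or `enrichment_track`.
#' @param flank Flank size in bp.
#' @param n_body_bins,n_flank_bins Window counts.
#' @param bin_size Bin size when `track` is a bare numeric vector.
#' @return List with `profile` (length `n_body_bins + 2 * n_flank_bins`),
#'   `position` labels, and `n_genes` used.
#' @export
metagene_profile <- function(genes, track, flank = 20000,
                             n_body_bins = 40, n_flank_bins = 20,
                             bin_size = NULL) {
  if (nrow(genes) == 0) stop("need at least one gene", call. = FALSE)
  tv <- track_values(track, bin_size)
  v <- tv$values; bs <- tv$bin_size
  total_bins <- n_body_bins + 2L * n_flank_bins
  mat <- matrix(NA_real_, nrow = 0, ncol = total_bins)
  skipped <- 0L
  for (g in seq_len(nrow(genes))) {
    gs <- genes$start[g]; ge <- genes$end[g]
    if ((ge - gs) < n_body_bins) { skipped <- skipped + 1L; next }
    edges <- c(seq(gs - flank, gs, length.out = n_flank_bins + 1),
               seq(gs, ge, length.out = n_body_bins + 1)[-1],
               seq(ge, ge + flank, length.out = n_flank_bins + 1)[-1])
    prof <- vapply(seq_len(total_bins), function(k)
      interval_mean(v, bs, edges[k], edges[k + 1]), numeric(1))
    if (!is.null(genes$strand) && genes$strand[g] == "-")
      prof <- rev(prof)
    mat <- rbind(mat, prof)
  }
  if (skipped > 0)
    warning(skipped, " gene(s) shorter than one body bin skipped")
  if (nrow(mat) == 0) stop("no usable genes", call. = FALSE)
  list(profile = colMeans(mat, na.rm = TRUE),
       position = c(paste0("up", seq_len(n_flank_bins)),
                    paste0("body", seq_len(n_body_bins)),
                    paste0("down", seq_len(n_flank_bins))),
       n_genes = nrow(mat))
}

#' Aggregate a binned track over a set of sites
#'
#' The value at each site is the overlap-weighted mean of the defined
#' track values it covers (NA when the site lies entirely in missing
#' bins). With `sort = TRUE` the sites are returned ordered by
#' decreasing value, ties broken by coordinate, as used to order CGIs or
#' CTCF sites by occupancy.
#'
#' @param sites Data frame of intervals (`start`, `end`).
#' @param track As in [metagene_profile()].
#' @param bin_size Bin size when `track` is a bare numeric vector.
#' @param sort Return sites sorted by decreasing value?
#' @return The `sites` data frame with a `value` column appended.
#' @export
values_at_sites <- function(sites, track, bin_size = NULL, sort = FALSE) {
  tv <- track_values(track, bin_size)
  sites$value <- vapply(seq_len(nrow(sites)), function(i)
    interval_mean(tv$values, tv$bin_size, sites$start[i], sites$end[i]),
    numeric(1))
  if (sort)
    sites <- sites[order(-sites$value, sites$start), , drop = FALSE]
  sites
}
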
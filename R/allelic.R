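#' Assign a single read to a parental haplotype by SNP content
#'
#' A read is assigned to haplotype 1 if at least one of its SNP
#' observations matches the haplotype-1 allele and none matches the
#' haplotype-2 allele (and symmetrically for haplotype 2); `"conflicting"`
#' if observations support both haplotypes; `"unassigned"` if it covers no
#' informative SNP or its observed bases match neither allele.
#'
#' @param read A list or one-row data frame with a `snp_obs` field encoded
#'   `"pos:base;pos:base;..."` (empty string for none).
#' @param snps A [snp_table()].
#' @return One of `"hap1"`, `"hap2"`, `"unassigned"`, `"conflicting"`.
#' @export
assign_read <- function(read, snps) {
  df <- data.frame(snp_obs = read$snp_obs[1], stringsAsFactors = FALSE)
  as.character(sort_reads(df, snps)$labels[1])
}

#' Partition reads between parental haplotypes
#'
#' Vectorised SNP-based read sorting into `hap1`, `hap2`, `unassigned`
#' and `conflicting` subsets. When a `pair_id` column is present,
#' paired-end mates are treated as one unit: their SNP observations are
#' pooled and both mates receive the combined label.
#'
#' @param reads Data frame with a `snp_obs` column (and optional
#'   `pair_id`).
#' @param snps A [snp_table()].
#' @return A list of class `allelic_partition`: `labels` (factor, one per
#'   read), `counts` and `fractions` over the four labels.
#' @export
sort_reads <- function(reads, snps) {
  labs <- c("hap1", "hap2", "unassigned", "conflicting")
  n <- nrow(reads)
  if (n == 0) {
    out <- list(labels = factor(character(0), levels = labs),
                counts = stats::setNames(rep(0L, 4), labs),
                fractions = stats::setNames(rep(0, 4), labs))
    class(out) <- "allelic_partition"
    return(out)
  }
  unit <- if ("pair_id" %in% names(reads)) {
    match(reads$pair_id, unique(reads$pair_id))
  } else seq_len(n)
  n_units <- max(unit)

  obs <- reads$snp_obs
  obs[is.na(obs)] <- ""
  toks <- strsplit(obs, ";", fixed = TRUE)
  nt <- lengths(toks)
  uidx <- rep.int(unit, nt)
  tok <- unlist(toks, use.names = FALSE)
  votes1 <- integer(n_units)
  votes2 <- integer(n_units)
  if (length(tok)) {
    m <- regmatches(tok, regexpr(":", tok, fixed = TRUE), invert = TRUE)
    pos <- as.numeric(vapply(m, `[`, character(1), 1L))
    base <- vapply(m, `[`, character(1), 2L)
    si <- match(pos, snps$pos)
    known <- !is.na(si)
    h1 <- known & base == snps$allele_hap1[ifelse(known, si, 1L)]
    h2 <- known & base == snps$allele_hap2[ifelse(known, si, 1L)]
    votes1 <- tabulate(uidx[h1], nbins = n_units)
    votes2 <- tabulate(uidx[h2], nbins = n_units)
  }
  unit_lab <- rep("unassigned", n_units)
  unit_lab[votes1 > 0 & votes2 == 0] <- "hap1"
  unit_lab[votes2 > 0 & votes1 == 0] <- "hap2"
  unit_lab[votes1 > 0 & votes2 > 0] <- "conflicting"
  labels <- factor(unit_lab[unit], levels = labs)
  counts <- table(labels)
  out <- list(labels = labels,
              counts = stats::setNames(as.integer(counts), labs),
              fractions = stats::setNames(as.numeric(counts) / n, labs))
  class(out) <- "allelic_partition"
  out
}

#' @export
print.allelic_partition <- function(x, ...) {
  cat("Allelic read partition:", sum(x$counts), "reads\n")
  for (l in names(x$counts))
    cat(sprintf("  %-12s %8d  (%.1f%%)\n", l, x$counts[[l]],
                100 * x$fractions[[l]]))
  invisible(x)
}

#' Bin a partitioned read set into an allelic count track
#'
#' Each read is counted in the bin containing its start coordinate.
#' Conflicting reads are pooled with unassigned reads in the track (they
#' are reported separately by [sort_reads()]), preserving the three-way
#' haplotype-1 / haplotype-2 / unassigned split used downstream.
#'
#' @param reads Data frame with a `start` column.
#' @param labels Factor from [sort_reads()] (or equivalent character
#'   vector), one label per read.
#' @param bin_size Bin size in bp.
#' @param chrom_length Chromosome length in bp; defaults to the largest
#'   read end.
#' @param chrom Chromosome name.
#' @return An `allelic_track`: list with `chrom`, `bin_size`, `n_bins`,
#'   and numeric vectors `values_hap1`, `values_hap2`,
#'   `values_unassigned`.
#' @export
bin_reads <- function(reads, labels, bin_size,
                      chrom_length = NULL, chrom = "chr") {
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  if (is.null(chrom_length))
    chrom_length <- if (nrow(reads)) max(reads$end) else bin_size
  n_bins <- max(1L, as.integer(ceiling(chrom_length / bin_size)))
  bin <- pmin(reads$start %/% bin_size + 1L, n_bins)
  lab <- as.character(labels)
  count_of <- function(which_lab)
    tabulate(bin[lab %in% which_lab], nbins = n_bins)
  allelic_track(chrom = chrom, bin_size = bin_size,
                values_hap1 = count_of("hap1"),
                values_hap2 = count_of("hap2"),
                values_unassigned = count_of(c("unassigned", "conflicting")))
}

#' Construct an allelic track
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param values_hap1,values_hap2,values_unassigned Equal-length numeric
#'   vectors, one value per bin.
#' @return An object of class `allelic_track`.
#' @export
allelic_track <- function(chrom, bin_size, values_hap1, values_hap2,
                          values_unassigned = rep(0, length(values_hap1))) {
  stopifnot(length(values_hap1) == length(values_hap2),
            length(values_hap1) == length(values_unassigned),
            bin_size > 0)
  structure(list(chrom = chrom, bin_size = bin_size,
                 n_bins = length(values_hap1),
                 values_hap1 = values_hap1, values_hap2 = values_hap2,
                 values_unassigned = values_unassigned),
            class = "allelic_track")
}

#' @export
print.allelic_track <- function(x, ...) {
  cat(sprintf("Allelic track %s: %d bins of %d bp (hap1 %.0f, hap2 %.0f, unassigned %.0f)\n",
              x$chrom, x$n_bins, x$bin_size, sum(x$values_hap1),
              sum(x$values_hap2), sum(x$values_unassigned)))
  invisible(x)
}

#' Score assigned reads against a simulation truth file
#'
#' @param labels Factor from [sort_reads()].
#' @param truth Character vector of true origins (`"hap1"`/`"hap2"`).
#' @return List with `n_assigned`, `n_correct`, `accuracy` and
#'   `misassignment` rate among assigned reads.
#' @export
score_assignment <- function(labels, truth) {
  assigned <- labels %in% c("hap1", "hap2")
  n_assigned <- sum(assigned)
  n_correct <- sum(as.character(labels)[assigned] == truth[assigned])
  list(n_assigned = n_assigned, n_correct = n_correct,
       accuracy = if (n_assigned) n_correct / n_assigned else NA_real_,
       misassignment = if (n_assigned) 1 - n_correct / n_assigned
                       else NA_real_)
}
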
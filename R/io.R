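#' Read / write the tab-separated formats used by the pipeline
#'
#' All intermediate files are plain text: SNP tables (`chrom`, `pos`,
#' `hap1_base`, `hap2_base`), read records (`chrom`, `start`, `end`,
#' `snp_obs` encoded `pos:base;...`), bedGraph tracks, BED intervals,
#' contact matrices as triplets (`bin_i`, `bin_j`, `count`, 0-based,
#' upper triangle) with a JSON sidecar header, methylation call tables
#' and YAML configs. Coordinates on disk are BED-style 0-based
#' half-open.
#'
#' @name allelix-io
NULL

#' @rdname allelix-io
#' @param snps A [snp_table()].
#' @param path Output file path.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(
    data.frame(chrom = snps$chrom, pos = snps$pos,
               hap1_base = snps$allele_hap1, hap2_base = snps$allele_hap2),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname allelix-io
#' @export
read_snp_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  snp_table(data.frame(chrom = df$chrom, pos = df$pos,
                       allele_hap1 = df$hap1_base,
                       allele_hap2 = df$hap2_base,
                       stringsAsFactors = FALSE))
}

#' @rdname allelix-io
#' @param reads Read records data frame.
#' @export
write_reads <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname allelix-io
#' @export
read_reads <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = NA, na.strings = "__NA__")
  df$snp_obs[is.na(df$snp_obs)] <- ""
  df
}

#' @rdname allelix-io
#' @param track List with `values` (or `log2_ratio`) and `bin_size`, or
#'   numeric vector with `bin_size` given.
#' @param chrom Chromosome name.
#' @param bin_size Bin size when `track` is numeric.
#' @export
write_bedgraph <- function(track, path, chrom = "chr", bin_size = NULL) {
  tv <- track_values(track, bin_size)
  v <- tv$values
  ok <- !is.na(v)
  df <- data.frame(chrom = chrom,
                   start = (seq_along(v) - 1) * tv$bin_size,
                   end = seq_along(v) * tv$bin_size,
                   value = v)[ok, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname allelix-io
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  df
}

#' @rdname allelix-io
#' @param domains Data frame with `chrom`, `start`, `end` and optional
#'   `label`/`score`.
#' @export
write_bed <- function(domains, path) {
  df <- data.frame(chrom = domains$chrom, start = domains$start,
                   end = domains$end,
                   name = if (!is.null(domains$label)) domains$label
                          else ".",
                   score = if (!is.null(domains$score))
                     round(domains$score) else 0L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname allelix-io
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "label"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

#' @rdname allelix-io
#' @param m A [contact_matrix()].
#' @export
write_contact_matrix <- function(m, path) {
  C <- m$counts
  up <- which(upper.tri(C, diag = TRUE) & C != 0, arr.ind = TRUE)
  df <- data.frame(bin_i = up[, 1] - 1L, bin_j = up[, 2] - 1L,
                   count = C[up])
  df <- df[order(df$bin_i, df$bin_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(chrom = m$chrom, bin_size = m$bin_size,
         haplotype = m$haplotype, n_bins = nrow(C)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname allelix-io
#' @export
read_contact_matrix <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = FALSE, sep = "\t")
  names(df) <- c("bin_i", "bin_j", "count")
  n <- hdr$n_bins
  C <- matrix(0, n, n)
  C[cbind(df$bin_i + 1L, df$bin_j + 1L)] <- df$count
  C[cbind(df$bin_j + 1L, df$bin_i + 1L)] <- df$count
  contact_matrix(C, bin_size = hdr$bin_size, chrom = hdr$chrom,
                 haplotype = if (is.null(hdr$haplotype)) NA_character_
                             else hdr$haplotype)
}

#' @rdname allelix-io
#' @param sites Methylation call data frame (`chrom`, `pos`,
#'   `meth_count`, `total_count`).
#' @export
write_methylation <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname allelix-io
#' @export
read_methylation <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname allelix-io
#' @param config A [sim_config()] (data-frame fields are converted to
#'   lists of rows for YAML).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$planted_domains <- as.list(as.data.frame(x$planted_domains))
  x$tad_set <- as.list(as.data.frame(x$tad_set))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname allelix-io
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$planted_domains))
    x$planted_domains <- as.data.frame(x$planted_domains)
  if (!is.null(x$tad_set))
    x$tad_set <- as.data.frame(x$tad_set)
  if (!is.null(x$compartment_profile))
    x$compartment_profile <- as.integer(unlist(x$compartment_profile))
  do.call(sim_config, x)
}
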
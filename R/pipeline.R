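#' Run the full synthetic-chromosome analysis pipeline
#'
#' Simulates a diploid chromosome (haplotype 1 = active X, haplotype 2 =
#' inactive X, in wild-type and mutant genotypes, plus a diploid
#' autosome control for copy-number estimation) and runs every analysis
#' stage end to end: SNP-based read assignment, allelic ChIP enrichment
#' and depletion-domain calling, CpG methylation summaries, allelic
#' expression classification, Hi-C equalisation / balancing / insulation
#' / compartments / TAD re-establishment, replication-timing shifts, and
#' the cross-assay region contrasts. Returns a machine-readable report;
#' the same config and seed always give the same report.
#'
#' @param config A [sim_config()] object or path to a YAML config
#'   written by [write_config()].
#' @param out_dir Optional output directory: stage outputs (BED,
#'   bedGraph, triplet matrices, tables) and `report.json` are written
#'   there.
#' @param n_assign_reads Reads simulated for the assignment stage.
#' @return A `pipeline_report` list of per-stage summaries.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_assign_reads = 2e4) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(fun, name, obj) {
    if (!is.null(out_dir)) fun(obj, file.path(out_dir, name))
    invisible(NULL)
  }
  report <- list(
    version = as.character(utils::packageVersion("allelix")),
    seed = config$seed,
    chrom = config$chrom,
    chrom_length = config$chrom_length)

  ## --- stage 1: SNPs and read assignment ------------------------------
  snps <- generate_snp_table(config)
  emit(write_snp_table, "snps.tsv", snps)
  sim <- simulate_reads(config, snps, n_assign_reads)
  part <- sort_reads(sim$reads, snps)
  acc <- score_assignment(part$labels, sim$truth)
  report$assignment <- list(
    n_reads = n_assign_reads,
    n_snps = nrow(snps),
    fractions = as.list(part$fractions),
    accuracy = acc$accuracy,
    misassignment = acc$misassignment)
  emit(write_reads, "reads.tsv", sim$reads)

  ## --- stage 2: ChIP enrichment and depletion domains -----------------
  chip_wt <- simulate_chip_tracks(config, "wt")
  chip_mut <- simulate_chip_tracks(config, "mut")
  enr <- function(chip, hap) {
    # library scaling from combined-haplotype totals, so per-haplotype
    # enrichment is relative to the whole library as in genome-wide
    # calibration, not re-centred within one haplotype
    lib <- (sum(chip$input$values_hap1) + sum(chip$input$values_hap2)) /
      (sum(chip$ip$values_hap1) + sum(chip$ip$values_hap2))
    enrichment_track(chip$ip[[paste0("values_", hap)]],
                     chip$input[[paste0("values_", hap)]],
                     fine_bin = config$chip_fine_bin,
                     coarse_bin = config$chip_coarse_bin,
                     lib_scale = lib, chrom = config$chrom)
  }
  k27_wt_xi <- enr(chip_wt, "hap2")
  k27_mut_xi <- enr(chip_mut, "hap2")
  dep_wt <- call_depletion_domains(k27_wt_xi, chrom = config$chrom)
  dep_mut <- call_depletion_domains(k27_mut_xi, chrom = config$chrom)
  ov <- domain_overlap(dep_mut$domains, config$planted_domains)
  report$depletion_domains <- list(
    wt_count = dep_wt$count,
    mut_count = dep_mut$count,
    mut_mean_length = dep_mut$mean_length,
    planted_jaccard = ov$jaccard)
  emit(write_bed, "depletion_domains_mut_xi.bed", dep_mut$domains)
  emit(function(o, p) write_bedgraph(o, p, chrom = config$chrom),
       "k27_mut_xi.bedgraph", k27_mut_xi)

  ## --- stage 3: CpG methylation ---------------------------------------
  no_dom <- config$planted_domains[0, , drop = FALSE]
  meth_wt <- simulate_methylation(config, domains = no_dom,
                                  seed_offset = 4L)
  meth_mut <- simulate_methylation(config, seed_offset = 41L)
  mt_wt <- methylation_track(meth_wt, bin_size = config$chip_coarse_bin,
                             chrom_length = config$chrom_length,
                             chrom = config$chrom)
  mt_mut <- methylation_track(meth_mut, bin_size = config$chip_coarse_bin,
                              chrom_length = config$chrom_length,
                              chrom = config$chrom)
  meth_contrast <- contrast_by_regions(mt_mut, dep_mut$domains)
  report$methylation <- list(
    wt_xi_mean_pct = mean(mt_wt$values, na.rm = TRUE),
    mut_xi_mean_pct = mean(mt_mut$values, na.rm = TRUE),
    contrast_median_inside = meth_contrast$median_inside,
    contrast_median_outside = meth_contrast$median_outside,
    contrast_p = meth_contrast$p_value)
  emit(write_methylation, "methylation_mut_xi.tsv", meth_mut)

  ## --- stage 4: expression classification -----------------------------
  genes <- plant_genes(config)
  records <- simulate_expression(config, genes)
  auto_cfg <- sim_config(chrom = "chrA",
                         chrom_length = max(2e6, config$chrom_length / 4),
                         seed = config$seed + 1000L)
  auto_chip <- simulate_chip_tracks(auto_cfg, "wt")
  factors <- estimate_copy_number(
    stats::setNames(list(chip_wt$input, auto_chip$input),
                    c(config$chrom, "chrA")),
    reference = "chrA")
  norm <- normalize_expression(records, factors)
  norm$class <- NULL   # planted truth never enters the classifier
  classified <- classify_genes(norm)
  classified$class_truth <- genes$class[match(classified$gene_id,
                                              genes$gene_id)]
  per_class <- vapply(
    c("escapee", "dependent", "partial", "independent"),
    function(cl) {
      idx <- classified$class_truth == cl
      if (!any(idx)) return(NA_real_)
      mean(classified$class[idx] == cl)
    }, numeric(1))
  expr_track <- gene_expression_track(classified, config)
  expr_contrast <- contrast_by_regions(expr_track, dep_mut$domains)
  report$expression <- list(
    n_genes = nrow(classified),
    class_counts = as.list(attr(classified, "class_counts")),
    per_class_recovery = as.list(per_class),
    overall_recovery = mean(classified$class == classified$class_truth),
    contrast_p = expr_contrast$p_value)
  emit(function(o, p) utils::write.table(o, p, sep = "\t", quote = FALSE,
                                         row.names = FALSE),
       "gene_classes.tsv", classified)

  ## --- stage 5: Hi-C ---------------------------------------------------
  hic_xa <- simulate_hic(config, "active-like", haplotype = "Xa")
  hic_xi_wt <- simulate_hic(config, "inactive-like", haplotype = "Xi_wt")
  hic_xi_mut <- simulate_hic(config, "mutant-inactive-like",
                             haplotype = "Xi_mut")
  eq <- downsample_equalize(
    list(xa = list(chr = hic_xa),
         xi_wt = list(chr = hic_xi_wt),
         xi_mut = list(chr = hic_xi_mut)),
    seed = config$seed + 17L)
  bal <- lapply(eq, function(s) kr_balance(s$chr))
  ins <- lapply(bal, insulation_score)
  bnd <- ins$xa$boundaries
  ins_tab <- insulation_at_boundaries(
    bnd, list(xi_wt = ins$xi_wt, xi_mut = ins$xi_mut))
  ok <- stats::complete.cases(ins_tab)
  ins_test <- rank_sum_test(ins_tab$xi_mut[ok], ins_tab$xi_wt[ok],
                            alternative = "less")
  decay <- lapply(bal, distance_decay)
  gene_density <- rep(config$compartment_profile,
                      each = config$compartment_bin / config$hic_bin)
  agg_factor <- config$compartment_bin / config$hic_bin
  evs <- lapply(eq, function(s) {
    compartment_eigenvector(aggregate_matrix(s$chr, agg_factor),
                            gene_density = config$compartment_profile)
  })
  ev_r_wt <- eigenvector_correlation(evs$xa, evs$xi_wt)
  ev_r_mut <- eigenvector_correlation(evs$xa, evs$xi_mut)
  tad <- tad_reestablishment(config$tad_set, eq$xi_wt$chr, eq$xi_mut$chr)
  restored_above_q1 <- mean(tad$class[tad$restored] != "weak",
                            na.rm = TRUE)
  nonrestored_weak <- mean(tad$class[!tad$restored] == "weak",
                           na.rm = TRUE)
  report$hic <- list(
    n_boundaries_xa = length(bnd),
    insulation_median_wt_xi = stats::median(ins_tab$xi_wt, na.rm = TRUE),
    insulation_median_mut_xi = stats::median(ins_tab$xi_mut,
                                             na.rm = TRUE),
    insulation_shift_p = ins_test$p_value,
    decay_slope = lapply(decay, `[[`, "slope"),
    ev_correlation_xa_wt_xi = ev_r_wt,
    ev_correlation_xa_mut_xi = ev_r_mut,
    tad_class_table = as.list(table(tad$class)),
    tad_restored_above_q1 = restored_above_q1,
    tad_nonrestored_weak = nonrestored_weak)
  if (!is.null(out_dir)) {
    write_contact_matrix(eq$xi_mut$chr,
                         file.path(out_dir, "hic_xi_mut.triplet.tsv"))
    write_bed(data.frame(chrom = config$chrom, start = tad$start,
                         end = tad$end, label = tad$class),
              file.path(out_dir, "tad_classes.bed"))
  }

  ## --- stage 6: replication timing ------------------------------------
  rb <- min(config$repli_bin, 1e5)
  prof_flat <- planted_timing(config, advanced = FALSE, bin_size = rb)
  prof_adv <- planted_timing(config, advanced = TRUE, bin_size = rb)
  cfg_rb <- config; cfg_rb$repli_bin <- rb
  rs_wt <- simulate_repliseq(cfg_rb, prof_flat, seed_offset = 5L)
  rs_mut <- simulate_repliseq(cfg_rb, prof_adv, seed_offset = 51L)
  tp_wt <- timing_profile(rs_wt, haplotype = "Xi_wt")
  tp_mut <- timing_profile(rs_mut, haplotype = "Xi_mut")
  shift <- timing_shift(tp_mut, tp_wt, dep_mut$domains)
  report$repliseq <- list(
    bin_size = rb,
    median_shift_within = shift$median_within,
    median_shift_outside = shift$median_outside,
    shift_p = shift$p_value)

  ## --- stage 7: allelic peak specificity ------------------------------
  peaks <- call_peaks_simple(k27_wt_xi, threshold = 0.5, min_bins = 2,
                             chrom = config$chrom)
  if (nrow(peaks)) {
    sum_track <- function(v, a, b) {
      lo <- max(1L, a %/% config$chip_fine_bin + 1L)
      hi <- min(length(v), ceiling(b / config$chip_fine_bin))
      sum(v[lo:hi])
    }
    xi <- vapply(seq_len(nrow(peaks)), function(i)
      sum_track(chip_wt$ip$values_hap2, peaks$start[i], peaks$end[i]),
      numeric(1))
    xa <- vapply(seq_len(nrow(peaks)), function(i)
      sum_track(chip_wt$ip$values_hap1, peaks$start[i], peaks$end[i]),
      numeric(1))
    in_xi <- vapply(seq_len(nrow(peaks)), function(i)
      sum_track(chip_wt$input$values_hap2, peaks$start[i], peaks$end[i]),
      numeric(1))
    in_xa <- vapply(seq_len(nrow(peaks)), function(i)
      sum_track(chip_wt$input$values_hap1, peaks$start[i], peaks$end[i]),
      numeric(1))
    corr <- ifelse(in_xi > 0, (in_xa + in_xi) / (2 * in_xi), 1)
    corr_a <- ifelse(in_xa > 0, (in_xa + in_xi) / (2 * in_xa), 1)
    score <- allelic_specificity_score(xi * corr, xa * corr_a)
    cls <- classify_peak_allelicity(xi * corr, xa * corr_a)
    report$peaks <- list(
      n_peaks = nrow(peaks),
      mean_specificity = mean(score, na.rm = TRUE),
      class_counts = as.list(table(cls)))
  } else {
    report$peaks <- list(n_peaks = 0L)
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  assignment: %.1f%% reads assigned, accuracy %.3f\n",
              100 * (x$assignment$fractions$hap1 +
                       x$assignment$fractions$hap2),
              x$assignment$accuracy))
  cat(sprintf("  depletion domains (mut Xi): %d, mean %.0f kb, planted Jaccard %.2f\n",
              x$depletion_domains$mut_count,
              x$depletion_domains$mut_mean_length / 1000,
              x$depletion_domains$planted_jaccard))
  cat(sprintf("  methylation contrast p = %.3g; expression contrast p = %.3g\n",
              x$methylation$contrast_p, x$expression$contrast_p))
  cat(sprintf("  gene classes recovered: %.1f%%\n",
              100 * x$expression$overall_recovery))
  cat(sprintf("  insulation shift p = %.3g; EV r (Xa~Xi) wt %.2f -> mut %.2f\n",
              x$hic$insulation_shift_p, x$hic$ev_correlation_xa_wt_xi,
              x$hic$ev_correlation_xa_mut_xi))
  cat(sprintf("  timing shift within-outside = %.2f z (p = %.3g)\n",
              x$repliseq$median_shift_within -
                x$repliseq$median_shift_outside, x$repliseq$shift_p))
  invisible(x)
}

# per-bin mutant-Xi expression track (reads per kb of gene body laid
# over the gene's bins; 0 elsewhere)
gene_expression_track <- function(records, config) {
  bs <- config$chip_coarse_bin
  n <- as.integer(ceiling(config$chrom_length / bs))
  v <- numeric(n)
  expr <- records$expr_xi_mut
  if (is.null(expr)) expr <- records$count_xi_mut /
      ((records$end - records$start) / 1000)
  for (i in seq_len(nrow(records))) {
    lo <- records$start[i] %/% bs + 1L
    hi <- min(n, (records$end[i] - 1) %/% bs + 1L)
    v[lo:hi] <- v[lo:hi] + expr[i]
  }
  list(values = v, bin_size = bs)
}
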
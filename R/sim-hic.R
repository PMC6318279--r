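#' Expected Hi-C contact structure of a synthetic chromosome
#'
#' Builds the noiseless expectation matrix for one of three contact
#' regimes. The expected count for bins `i != j` is
#' `depth * |i-j|^decay_exponent * tad_factor^[same TAD] *
#' compartment_factor^[same compartment] * mega_domain_factor^[cross-hinge]`,
#' with the factors switched by regime:
#' \describe{
#'   \item{active-like}{all TADs boosted, full compartmentalisation, no
#'     mega-domain attenuation (an Xa/autosome).}
#'   \item{inactive-like}{no TAD boost, compartment boost attenuated to 1,
#'     contacts across the mega-domain hinge attenuated (the wild-type
#'     Xi: two mega-domains, attenuated TADs and compartments).}
#'   \item{mutant-inactive-like}{TAD boost restored for the planted
#'     `restored` subset of `tad_set`, compartmentalisation restored, the
#'     mega-domain hinge retained (the Xi after loss of SmcHD1).}
#' }
#'
#' @param config A [sim_config()] object.
#' @param mode One of `"active-like"`, `"inactive-like"`,
#'   `"mutant-inactive-like"`.
#' @return A dense symmetric matrix of expected counts.
#' @export
hic_expected <- function(config,
                         mode = c("active-like", "inactive-like",
                                  "mutant-inactive-like")) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  bs <- config$hic_bin
  n <- as.integer(ceiling(config$chrom_length / bs))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- config$hic_depth * pmax(d, 1)^config$decay_exponent

  tads <- switch(mode,
    "active-like" = config$tad_set,
    "inactive-like" = config$tad_set[0, , drop = FALSE],
    "mutant-inactive-like" =
      config$tad_set[config$tad_set$restored, , drop = FALSE])
  if (nrow(tads)) {
    tad_of <- rep(NA_integer_, n)
    for (k in seq_len(nrow(tads))) {
      b <- bin_span(tads$start[k], tads$end[k], bs, n)
      tad_of[b] <- k
    }
    same_tad <- outer(tad_of, tad_of, function(a, b)
      !is.na(a) & !is.na(b) & a == b)
    E[same_tad] <- E[same_tad] * config$tad_factor
  }

  comp_factor <- if (mode == "inactive-like") 1 else config$compartment_factor
  if (comp_factor != 1) {
    ratio <- config$compartment_bin / bs
    lab <- config$compartment_profile[pmin(
      floor((seq_len(n) - 1) / ratio) + 1L,
      length(config$compartment_profile))]
    same_comp <- outer(lab, lab, "==")
    E[same_comp] <- E[same_comp] * comp_factor
  }

  if (mode != "active-like" && config$mega_domain_factor != 1) {
    hinge_bin <- config$mega_domain_boundary / bs
    side <- (seq_len(n) - 1) >= hinge_bin
    cross <- outer(side, side, "!=")
    E[cross] <- E[cross] * config$mega_domain_factor
  }
  diag(E) <- config$hic_depth
  E
}

#' Simulate an allele-specific Hi-C contact matrix
#'
#' Draws negative-binomial counts (dispersion `config$noise_dispersion`;
#' Poisson at 0) around the [hic_expected()] structure for the requested
#' regime, upper triangle mirrored so the matrix is exactly symmetric.
#'
#' @inheritParams hic_expected
#' @param haplotype Label stored on the matrix.
#' @param seed_offset Offset added to the config seed for this draw.
#' @return A [contact_matrix()].
#' @export
simulate_hic <- function(config,
                         mode = c("active-like", "inactive-like",
                                  "mutant-inactive-like"),
                         haplotype = mode[1], seed_offset = NULL) {
  mode <- match.arg(mode)
  E <- hic_expected(config, mode)
  n <- nrow(E)
  if (is.null(seed_offset))
    seed_offset <- 10L + match(mode, c("active-like", "inactive-like",
                                       "mutant-inactive-like"))
  sim_seed(config, seed_offset)
  up <- upper.tri(E, diag = TRUE)
  C <- matrix(0, n, n)
  C[up] <- rcounts(sum(up), E[up], config$noise_dispersion)
  C <- C + t(C) - diag(diag(C))
  contact_matrix(C, bin_size = config$hic_bin, chrom = config$chrom,
                 haplotype = haplotype)
}

# 1-based indices of bins fully inside [start, end)
bin_span <- function(start, end, bin_size, n_bins) {
  lo <- ceiling(start / bin_size) + 1L
  hi <- floor(end / bin_size)
  if (hi < lo) return(integer(0))
  seq.int(max(1L, lo), min(n_bins, hi))
}
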
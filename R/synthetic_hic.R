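#' @title Synthetic Rabl-configured Hi-C contact matrices
#' @name synthetic_hic
NULL

#' Parameters for the Hi-C simulator
#'
#' The expected contact weight between two bins at genomic distance `s`
#' within a chromosome is `s^exponent`; inter-chromosomal bin pairs get the
#' constant weight of an `inter_baseline_bp` separation.  Telomere-telomere
#' and centromere-centromere clustering (the Rabl configuration) multiply
#' the expectation by `1 + (gain - 1) * w_i * w_j`, where `w` decays
#' exponentially with the bin's distance to the chromosome end (or
#' centromere midpoint) over `cluster_decay_bp`, so the planted signal is
#' concentrated at the repeat-proximal corner.
#'
#' @param resolution bin size in bp (default 5 kb, the aggregation
#'   resolution).
#' @param exponent power-law decay exponent (< 0; default -1).
#' @param intra_telomere_gain,inter_telomere_gain clustering gains (>= 1)
#'   for telomere pairs on the same / different chromosomes.
#' @param centromere_gain clustering gain for centromere pairs.
#' @param cluster_decay_bp e-folding distance of the clustering weight.
#' @param inter_baseline_bp genomic separation whose decay weight is used
#'   as the inter-chromosomal baseline.
#' @param long_range_attenuation multiplier (<= 1) applied to intra-arm
#'   contacts beyond `long_range_bp`; below 1 emulates the loss of
#'   arm-range contacts in condensin-deficient chromatin.
#' @param long_range_bp distance above which the attenuation applies.
#' @param total_pairs read-pair budget.
#' @param noise `"multinomial"` (conserves the budget exactly),
#'   `"poisson"`, or `"none"` (expected counts, scaled to the budget).
#' @return list of class `hic_sim_params`.
#' @export
hic_sim_params <- function(resolution = 5000, exponent = -1,
                           intra_telomere_gain = 4, inter_telomere_gain = 2,
                           centromere_gain = 8, cluster_decay_bp = 20000,
                           inter_baseline_bp = 1e6,
                           long_range_attenuation = 1,
                           long_range_bp = 100000,
                           total_pairs = 2e6,
                           noise = c("multinomial", "poisson", "none")) {
  noise <- match.arg(noise)
  p <- as.list(environment())
  stopifnot(exponent < 0, intra_telomere_gain >= 1,
            inter_telomere_gain >= 1, centromere_gain >= 1,
            long_range_attenuation > 0, long_range_attenuation <= 1,
            total_pairs > 0, resolution >= 1)
  class(p) <- "hic_sim_params"
  p
}

#' Condensin-mutant-like ("cut14-like") re-parameterization
#'
#' Starting from a wild-type-like parameter set, arm-range contacts are
#' attenuated and telomere clustering gains are raised; centromere gain is
#' left unchanged.  Preset values are free modelling parameters, not
#' measured ground truth.
#'
#' @param base a [hic_sim_params()] to modify.
#' @param telomere_gain_factor factor applied to both telomere gains.
#' @param attenuation long-range attenuation to install.
#' @return modified `hic_sim_params`.
#' @export
cut14_like_params <- function(base = hic_sim_params(),
                              telomere_gain_factor = 3,
                              attenuation = 0.6) {
  base$intra_telomere_gain <- base$intra_telomere_gain * telomere_gain_factor
  base$inter_telomere_gain <- base$inter_telomere_gain * telomere_gain_factor
  base$long_range_attenuation <- attenuation
  base
}

# bin table for a genome at a resolution: chrom, start, end, partial flag
.hic_bins <- function(genome, resolution) {
  len <- chrom_lengths(genome)
  do.call(rbind, lapply(names(len), function(cn) {
    L <- len[[cn]]
    nb <- ceiling(L / resolution)
    data.frame(chromosome = cn,
               start = (seq_len(nb) - 1) * resolution,
               end = pmin(seq_len(nb) * resolution, L),
               partial = seq_len(nb) * resolution > L,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a raw Hi-C contact matrix
#'
#' @param genome a target `genome_model`.
#' @param params a [hic_sim_params()].
#' @param seed integer seed.
#' @return a raw [contact_matrix()].  Trailing partial bins (resolution not
#'   dividing the chromosome length) are allowed and flagged in the bin
#'   table.
#' @export
simulate_hic <- function(genome, params = hic_sim_params(), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(params, "hic_sim_params"))
  prev <- .with_seed(seed)
  on.exit(.restore_seed(prev), add = TRUE)
  res <- params$resolution
  bins <- .hic_bins(genome, res)
  n <- nrow(bins)
  mid <- (bins$start + bins$end) / 2
  len <- chrom_lengths(genome)

  # distance-decay weights
  same <- outer(bins$chromosome, bins$chromosome, "==")
  s <- abs(outer(mid, mid, "-"))
  s_eff <- pmax(s, res / 2)
  W <- matrix(params$inter_baseline_bp^params$exponent, n, n)
  W[same] <- s_eff[same]^params$exponent
  if (params$long_range_attenuation < 1) {
    att <- same & s > params$long_range_bp
    W[att] <- W[att] * params$long_range_attenuation
  }

  # clustering weights decaying from each chromosome end / centromere.
  # Clustering acts between DIFFERENT ends (and different centromeres):
  # a bin pair within one end region is plain distance decay, so the
  # planted signal sits at end-end (and cen-cen) corners only and leaves
  # row marginals essentially untouched.
  w_left <- exp(-mid / params$cluster_decay_bp)
  w_right <- exp(-(len[bins$chromosome] - mid) / params$cluster_decay_bp)
  cen <- genome$features[genome$features$class == "centromere", , drop = FALSE]
  d_cen <- rep(Inf, n)
  for (i in seq_len(nrow(cen))) {
    sel <- bins$chromosome == cen$chromosome[i]
    d_cen[sel] <- abs(mid[sel] - (cen$start[i] + cen$end[i]) / 2)
  }
  w_cen <- exp(-d_cen / params$cluster_decay_bp)

  # same chromosome: only the left-end x right-end cross terms cluster
  tel_intra <- outer(w_left, w_right) + outer(w_right, w_left)
  # different chromosomes: any end with any end
  tel_inter <- outer(w_left + w_right, w_left + w_right)
  tel_term <- ifelse(same,
                     (params$intra_telomere_gain - 1) * tel_intra,
                     (params$inter_telomere_gain - 1) * tel_inter)
  # centromeres cluster at the spindle pole body across chromosomes
  cen_term <- ifelse(same, 0,
                     (params$centromere_gain - 1) * outer(w_cen, w_cen))
  W <- W * (1 + tel_term) * (1 + cen_term)

  # sample counts over the upper triangle (incl. diagonal)
  up <- upper.tri(W, diag = TRUE)
  wv <- W[up]
  cnt <- switch(params$noise,
    multinomial = as.numeric(stats::rmultinom(1, params$total_pairs,
                                              wv / sum(wv))),
    poisson = stats::rpois(length(wv),
                           params$total_pairs * wv / sum(wv)),
    none = params$total_pairs * wv / sum(wv))
  M <- matrix(0, n, n)
  M[up] <- cnt
  M <- M + t(M) - diag(diag(M))
  contact_matrix(M, resolution = res, genome = genome,
                 normalization = "raw")
}
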
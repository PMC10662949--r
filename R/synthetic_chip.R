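#' @title Synthetic two-species ChIP fragment sets
#' @name synthetic_chip
NULL

#' Enrichment profile for the ChIP simulator
#'
#' Fold-enrichment multipliers per feature class, relative to a background
#' of 1 (the unit reference).  Defaults place strong occupancy on telomeric
#' repeats, moderate occupancy on STE blocks and a fraction of genes
#' ("gene peaks"), emulating an SMC-complex-like binding landscape where
#' telomere occupancy sits in the range of highly expressed genes.
#'
#' @param telomere_repeat,STE,gene_peak,taz1_island,background,control_locus
#'   multipliers (> 0); `control_locus` applies to the spike-in genome only.
#' @param gene_peak_fraction fraction of genes carrying the `gene_peak`
#'   multiplier (the rest stay at background).
#' @param fragment_bp fragment length (chromatin sheared to ~300 bp).
#' @param ip_depth,total_depth fragments sequenced per fraction (pooled over
#'   both species).
#' @param ip_efficiency global immunoprecipitation capture probability; at 1
#'   (default) the emitted IP depth equals `ip_depth` exactly, below 1 the
#'   IP library is binomially thinned (see the methods vignette).
#' @return list of class `enrichment_profile`.
#' @export
enrichment_profile <- function(telomere_repeat = 8, STE = 2, gene_peak = 6,
                               taz1_island = 4, background = 1,
                               control_locus = 4,
                               gene_peak_fraction = 0.25,
                               fragment_bp = 300,
                               ip_depth = 200000, total_depth = 200000,
                               ip_efficiency = 1) {
  p <- as.list(environment())
  stopifnot(telomere_repeat > 0, STE > 0, gene_peak > 0, background > 0,
            control_locus > 0, fragment_bp >= 1,
            ip_depth > 0, total_depth > 0,
            ip_efficiency > 0, ip_efficiency <= 1,
            gene_peak_fraction >= 0, gene_peak_fraction <= 1)
  if (background != 1)
    stop("background multiplier is the unit reference and must be 1")
  class(p) <- "enrichment_profile"
  p
}

# per-base IP sampling weight over one genome; gene peaks chosen seeded
.enrichment_weights <- function(genome, profile, peak_genes) {
  len <- chrom_lengths(genome)
  lapply(names(len), function(cn) {
    w <- rep(profile$background, len[[cn]])
    f <- genome$features[genome$features$chromosome == cn, , drop = FALSE]
    mult <- function(cls) switch(cls,
      telomere_repeat = profile$telomere_repeat,
      STE = profile$STE,
      taz1_island = profile$taz1_island,
      control_locus = profile$control_locus,
      centromere = profile$background,
      qpcr_amplicon = profile$background,
      gene = profile$background)   # genes handled via peak_genes below
    for (i in seq_len(nrow(f))) {
      m <- if (f$class[i] == "gene" && f$name[i] %in% peak_genes)
        profile$gene_peak else mult(f$class[i])
      if (m != profile$background)
        w[(f$start[i] + 1):f$end[i]] <- m
    }
    w
  })
}

#' Simulate a spike-in calibrated ChIP experiment
#'
#' The Total (input) fraction is drawn uniformly over both genomes with
#' per-species weight proportional to `mixing_ratio` times genome length.
#' The IP fraction is drawn with probability proportional to the local
#' enrichment multiplier (spike-in enriched only at its control locus).
#' Fragment start positions are sampled per base; each fragment has fixed
#' length `profile$fragment_bp`, clipped at chromosome ends.
#'
#' @param genomes list with `target` and `spikein` `genome_model`s (as from
#'   [build_toy_genome()]).
#' @param profile an [enrichment_profile()].
#' @param mixing_ratio target:spike-in cell ratio (scalar, target cells per
#'   spike-in cell; default 5).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list of class `chip_sim` with fragment data.frames
#'   `ip_target`, `total_target`, `ip_spike`, `total_spike`, plus the
#'   applied `profile`, `mixing_ratio` and `peak_genes`.
#' @export
simulate_chip <- function(genomes, profile = enrichment_profile(),
                          mixing_ratio = 5, seed = 1L) {
  stopifnot(inherits(genomes$target, "genome_model"),
            inherits(genomes$spikein, "genome_model"),
            inherits(profile, "enrichment_profile"),
            mixing_ratio > 0)
  if (sum(chrom_lengths(genomes$target)) == 0 ||
      sum(chrom_lengths(genomes$spikein)) == 0)
    stop("empty genome")
  prev <- .with_seed(seed)
  on.exit(.restore_seed(prev), add = TRUE)

  genes <- genomes$target$features[
    genomes$target$features$class == "gene", , drop = FALSE]
  n_peak <- round(nrow(genes) * profile$gene_peak_fraction)
  peak_genes <- if (n_peak > 0) sample(genes$name, n_peak) else character(0)

  len_t <- chrom_lengths(genomes$target)
  len_s <- chrom_lengths(genomes$spikein)
  # species weights: cells x genome mass
  uni_w <- c(rep(mixing_ratio, sum(len_t)), rep(1, sum(len_s)))
  ew_t <- .enrichment_weights(genomes$target, profile, peak_genes)
  ew_s <- .enrichment_weights(genomes$spikein, profile, character(0))
  ip_w <- c(mixing_ratio * unlist(ew_t, use.names = FALSE),
            unlist(ew_s, use.names = FALSE))

  chrom_of <- rep(c(names(len_t), names(len_s)), times = c(len_t, len_s))
  offset_of <- unlist(lapply(c(len_t, len_s), seq_len), use.names = FALSE) - 1L
  species_break <- sum(len_t)
  lens_all <- c(len_t, len_s)

  draw <- function(n, w) {
    if (n == 0) return(integer(0))
    sample.int(length(w), n, replace = TRUE, prob = w)
  }
  to_frags <- function(pos) {
    cn <- chrom_of[pos]
    s <- offset_of[pos]
    e <- pmin(s + profile$fragment_bp, lens_all[cn])
    data.frame(chromosome = cn, start = s, end = e,
               stringsAsFactors = FALSE)
  }
  n_ip <- if (profile$ip_efficiency < 1)
    stats::rbinom(1, profile$ip_depth, profile$ip_efficiency)
  else profile$ip_depth
  ip_pos <- draw(n_ip, ip_w)
  tot_pos <- draw(profile$total_depth, uni_w)

  split_species <- function(pos) {
    list(target = to_frags(pos[pos <= species_break]),
         spike = to_frags(pos[pos > species_break]))
  }
  ip <- split_species(ip_pos)
  tot <- split_species(tot_pos)
  structure(list(ip_target = ip$target, total_target = tot$target,
                 ip_spike = ip$spike, total_spike = tot$spike,
                 profile = profile, mixing_ratio = mixing_ratio,
                 peak_genes = peak_genes, seed = seed),
            class = "chip_sim")
}

#' Write a fragment set as BED
#' @param fragments fragment data.frame (`chromosome`, `start`, `end`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  writeLines(sprintf("%s\t%d\t%d", fragments$chromosome,
                     as.integer(fragments$start),
                     as.integer(fragments$end)), path)
  invisible(path)
}
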
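#' Emit nucleotide sequences for a genome model
#'
#' Background sequence is i.i.d. uniform ACGT; telomere_repeat features are
#' overwritten with tandem copies of the model's repeat unit so that repeat
#' arrays are genuinely repetitive (relevant for coverage-bias arguments).
#'
#' @param genome a `genome_model`.
#' @param seed seed for the background sequence.
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
genome_sequences <- function(genome, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  prev <- .with_seed(seed)
  on.exit(.restore_seed(prev), add = TRUE)
  len <- chrom_lengths(genome)
  seqs <- lapply(names(len), function(cn) {
    L <- len[[cn]]
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    tel <- genome$features[genome$features$class == "telomere_repeat" &
                           genome$features$chromosome == cn, , drop = FALSE]
    unit <- strsplit(genome$repeat_unit, "")[[1]]
    for (i in seq_len(nrow(tel))) {
      w <- tel$end[i] - tel$start[i]
      s[(tel$start[i] + 1):tel$end[i]] <- rep_len(unit, w)
    }
    paste(s, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(len)
  out
}

#' Write genome sequences as FASTA
#' @param genome a `genome_model`.
#' @param path output file.
#' @param seed passed to [genome_sequences()].
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, seed = 1L) {
  Biostrings::writeXStringSet(genome_sequences(genome, seed), path)
  invisible(path)
}

#' Write genome features as BED6
#'
#' The feature class is encoded in the BED name field as `class:name`.
#'
#' @param genome a `genome_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$chromosome,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = ifelse(f$strand == ".", "*", f$strand))
  gr$name <- paste(f$class, f$name, sep = ":")
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED6 feature file written by [write_features_bed()]
#' @param path BED file.
#' @return data.frame in the `genome_model` feature layout.
#' @export
read_features_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- as.character(gr$name)
  cls <- sub(":.*$", "", nm)
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
             class = cls,
             name = sub("^[^:]*:", "", nm),
             stringsAsFactors = FALSE)
}
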
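#' @title Genome models for the two-species toy reference
#' @description Constructors and bookkeeping for a fission-yeast-like target
#'   genome whose chromosome ends carry telomere repeat arrays and
#'   sub-telomeric elements (STE), plus a budding-yeast-like spike-in genome
#'   carrying a single control locus used for ChIP calibration.
#'
#'   All coordinates are 0-based, half-open (BED convention).  Data coming
#'   from 1-based sources must be converted at the boundary with
#'   [coord_0based()].
#' @name genome_model
NULL

.feature_classes <- c("telomere_repeat", "STE", "gene", "centromere",
                      "control_locus", "taz1_island", "qpcr_amplicon")

#' Construct and validate a genome model
#'
#' @param species_id `"target"` or `"spikein"`.
#' @param chromosomes data.frame with columns `name`, `length` (bp).
#' @param features data.frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open), `strand` (`+`, `-` or `.`), `class` (one of
#'   telomere_repeat, STE, gene, centromere, control_locus, taz1_island,
#'   qpcr_amplicon) and `name`.
#' @param repeat_unit telomeric repeat unit used when sequences are emitted.
#'
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(species_id, chromosomes, features,
                         repeat_unit = "GGTTACAC") {
  species_id <- match.arg(species_id, c("target", "spikein"))
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)),
            is.data.frame(features),
            all(c("chromosome", "start", "end", "strand", "class", "name")
                %in% names(features)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name))
    stop("duplicated chromosome names")
  features$chromosome <- as.character(features$chromosome)
  features$name <- as.character(features$name)
  features$class <- as.character(features$class)
  features$strand <- as.character(features$strand)

  bad <- setdiff(features$class, .feature_classes)
  if (length(bad))
    stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  if (!all(features$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (any(features$start >= features$end))
    stop("features must satisfy start < end")
  len <- stats::setNames(chromosomes$length, chromosomes$name)
  if (!all(features$chromosome %in% chromosomes$name))
    stop("feature on unknown chromosome")
  if (any(features$start < 0) ||
      any(features$end > len[features$chromosome]))
    stop("feature outside chromosome bounds")

  tel <- features[features$class == "telomere_repeat", , drop = FALSE]
  if (nrow(tel)) {
    at_left <- tel$start == 0
    at_right <- tel$end == len[tel$chromosome]
    if (!all(at_left | at_right))
      stop("telomere_repeat features must touch a chromosome end")
    key <- paste(tel$chromosome, ifelse(at_left, "left", "right"))
    if (anyDuplicated(key))
      stop("at most one telomere_repeat per chromosome end")
  }
  if (species_id == "spikein" &&
      sum(features$class == "control_locus") != 1L)
    stop("spike-in genome must contain exactly one control_locus")

  structure(list(species_id = species_id,
                 chromosomes = chromosomes,
                 features = features,
                 repeat_unit = repeat_unit,
                 coordinates = "0-based half-open"),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model [%s]: %d chromosome(s), %d feature(s)\n",
              x$species_id, nrow(x$chromosomes), nrow(x$features)))
  cat(sprintf("  total length %.0f bp; coordinates %s\n",
              sum(x$chromosomes$length), x$coordinates))
  invisible(x)
}

#' Named chromosome lengths of a genome model
#' @param genome a `genome_model`.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
}

#' Convert a 1-based coordinate to the internal 0-based convention
#'
#' For a point position, the 0-based index is `pos - 1`.  For a boundary
#' stated as "the last included 1-based position P" (as used for the
#' telomere-repeat quantification limit), the 0-based half-open boundary is
#' P itself: positions `[P, L)` are beyond the limit.
#'
#' @param pos_1based 1-based position(s).
#' @param what `"position"` (default) or `"last_included_boundary"`.
#' @return 0-based coordinate(s).
#' @export
coord_0based <- function(pos_1based, what = c("position",
                                              "last_included_boundary")) {
  what <- match.arg(what)
  if (what == "position") pos_1based - 1 else pos_1based
}

#' Default configuration for the toy two-species reference
#'
#' Layout mirrors a fission-yeast chromosome end: the outermost sequence is a
#' telomeric repeat array, followed inward by sub-telomeric element (STE)
#' blocks, then ordinary gene-containing arm sequence, with a centromere in
#' the chromosome interior.  The spike-in genome is a single chromosome with
#' one control locus (stand-in for a budding-yeast CEN4/CARIV amplicon).
#'
#' @param n_chromosomes number of target chromosomes.
#' @param chromosome_length length(s) in bp, recycled over chromosomes.
#' @param telomere_repeat_bp length of each terminal repeat array.
#' @param repeat_unit telomeric repeat unit sequence (not treated as a real
#'   biological ground truth; configurable).
#' @param ste_blocks named vector of STE block lengths, ordered from the
#'   repeat array inward.
#' @param n_genes genes placed per chromosome (uniformly in the arms).
#' @param gene_length_range min/max gene length in bp.
#' @param centromere_frac centromere midpoint as a fraction of length.
#' @param centromere_bp centromere width.
#' @param n_taz1_islands non-telomeric Taz1-island features per chromosome.
#' @param taz1_island_bp width of each island.
#' @param spikein_length spike-in chromosome length.
#' @param control_locus 0-based `c(start, end)` of the spike-in control locus.
#' @return list of class `toy_genome_config`.
#' @export
toy_genome_config <- function(n_chromosomes = 3,
                              chromosome_length = 300000,
                              telomere_repeat_bp = 2000,
                              repeat_unit = "GGTTACAC",
                              ste_blocks = c(STE1 = 8000, STE2 = 4000),
                              n_genes = 60,
                              gene_length_range = c(800, 3000),
                              centromere_frac = 0.5,
                              centromere_bp = 10000,
                              n_taz1_islands = 2,
                              taz1_island_bp = 1000,
                              spikein_length = 200000,
                              control_locus = c(99000, 101000)) {
  cfg <- as.list(environment())
  class(cfg) <- "toy_genome_config"
  cfg
}

#' Build the toy target and spike-in genome models
#'
#' Deterministic for a given config and seed (the seed governs random gene
#' and island placement only; all mandatory features are laid out by rule).
#' Each chromosome end carries, from the terminus inward: the telomere
#' repeat array, then the STE blocks in the order given by
#' `config$ste_blocks`, then arm sequence.
#'
#' @param config a [toy_genome_config()].
#' @param seed integer seed for gene placement.
#' @return list with elements `target` and `spikein`, both `genome_model`s.
#' @export
build_toy_genome <- function(config = toy_genome_config(), seed = 1L) {
  stopifnot(inherits(config, "toy_genome_config"))
  lens <- rep_len(config$chromosome_length, config$n_chromosomes)
  tel <- config$telomere_repeat_bp
  if (any(tel > lens / 2))
    stop("telomere repeat array longer than half a chromosome")
  chroms <- data.frame(name = sprintf("chrT%d", seq_len(config$n_chromosomes)),
                       length = lens, stringsAsFactors = FALSE)

  feats <- list()
  rng_state <- .with_seed(seed)
  on.exit(.restore_seed(rng_state), add = TRUE)

  for (i in seq_len(nrow(chroms))) {
    cn <- chroms$name[i]; L <- chroms$length[i]
    f <- data.frame(chromosome = cn,
                    start = c(0, L - tel),
                    end = c(tel, L),
                    strand = ".",
                    class = "telomere_repeat",
                    name = paste0(cn, c("-telL", "-telR")),
                    stringsAsFactors = FALSE)
    # STE blocks immediately inside each repeat array, outermost first
    pos_l <- tel; pos_r <- L - tel
    for (k in seq_along(config$ste_blocks)) {
      w <- config$ste_blocks[[k]]; nm <- names(config$ste_blocks)[k]
      f <- rbind(f,
        data.frame(chromosome = cn, start = pos_l, end = pos_l + w,
                   strand = ".", class = "STE",
                   name = paste0(cn, "-", nm, "-L")),
        data.frame(chromosome = cn, start = pos_r - w, end = pos_r,
                   strand = ".", class = "STE",
                   name = paste0(cn, "-", nm, "-R")))
      pos_l <- pos_l + w; pos_r <- pos_r - w
    }
    cen_mid <- round(L * config$centromere_frac)
    cen <- c(cen_mid - config$centromere_bp / 2,
             cen_mid + config$centromere_bp / 2)
    if (cen[1] <= pos_l || cen[2] >= pos_r)
      stop("mandatory features overlap: centromere meets sub-telomeric blocks")
    f <- rbind(f, data.frame(chromosome = cn, start = cen[1], end = cen[2],
                             strand = ".", class = "centromere",
                             name = paste0(cn, "-cen")))
    # genes and islands fill the two arms without overlapping anything placed
    occupied <- f[, c("start", "end")]
    place <- function(n, width_range, class, prefix, stranded) {
      out <- NULL
      tries <- 0L
      while (n > 0 && tries < 10000L) {
        tries <- tries + 1L
        w <- round(stats::runif(1, width_range[1], width_range[2]))
        s <- floor(stats::runif(1, pos_l, pos_r - w))
        if (any(s < occupied$end & s + w > occupied$start)) next
        occupied <<- rbind(occupied, data.frame(start = s, end = s + w))
        out <- rbind(out, data.frame(
          chromosome = cn, start = s, end = s + w,
          strand = if (stranded) sample(c("+", "-"), 1) else ".",
          class = class,
          name = sprintf("%s-%s%d", cn, prefix, n)))
        n <- n - 1L
      }
      out
    }
    f <- rbind(f,
               place(config$n_genes, config$gene_length_range,
                     "gene", "g", stranded = TRUE),
               place(config$n_taz1_islands,
                     rep(config$taz1_island_bp, 2), "taz1_island", "isl",
                     stranded = FALSE))
    feats[[i]] <- f
  }
  target <- genome_model("target", chroms, do.call(rbind, feats),
                         repeat_unit = config$repeat_unit)

  sp_chrom <- data.frame(name = "chrS1", length = config$spikein_length,
                         stringsAsFactors = FALSE)
  sp_feat <- data.frame(chromosome = "chrS1",
                        start = config$control_locus[1],
                        end = config$control_locus[2],
                        strand = ".", class = "control_locus",
                        name = "control", stringsAsFactors = FALSE)
  spikein <- genome_model("spikein", sp_chrom, sp_feat,
                          repeat_unit = config$repeat_unit)
  list(target = target, spikein = spikein)
}

# seed push/pop helpers: run seeded code without clobbering the caller's RNG
.with_seed <- function(seed) {
  prev <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  prev
}
.restore_seed <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", prev, envir = globalenv())
}

#' Distal telomere regions of every chromosome end
#'
#' @param genome a `genome_model`.
#' @param region_bp extent of the distal window (default 150 kb).
#' @return data.frame with columns `chromosome`, `side` (`left`/`right`),
#'   `start`, `end` and `truncated`.  Index 0 of a region is always the
#'   repeat-proximal (outermost) position: left regions read left-to-right,
#'   right regions are used reverse-oriented downstream.
#' @export
telomere_regions <- function(genome, region_bp = 150000) {
  stopifnot(inherits(genome, "genome_model"), region_bp > 0)
  len <- chrom_lengths(genome)
  out <- do.call(rbind, lapply(names(len), function(cn) {
    L <- len[[cn]]
    span <- min(region_bp, L)
    data.frame(chromosome = cn,
               side = c("left", "right"),
               start = c(0, L - span),
               end = c(span, L),
               truncated = span < region_bp,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Enumerate all unordered telomere pairs
#'
#' @param genome a `genome_model` with at least one chromosome.
#' @param region_bp passed to [telomere_regions()].
#' @return data.frame of all C(2C, 2) unordered pairs of distinct telomeres
#'   with columns `chrom_a`, `side_a`, `chrom_b`, `side_b` and `pair_class`
#'   (`intra` if both ends are on the same chromosome, else `inter`).
#' @export
enumerate_telomere_pairs <- function(genome, region_bp = 150000) {
  regs <- telomere_regions(genome, region_bp)
  n <- nrow(regs)
  stopifnot(n >= 2)
  idx <- utils::combn(n, 2)
  data.frame(chrom_a = regs$chromosome[idx[1, ]],
             side_a = regs$side[idx[1, ]],
             chrom_b = regs$chromosome[idx[2, ]],
             side_b = regs$side[idx[2, ]],
             pair_class = ifelse(regs$chromosome[idx[1, ]] ==
                                 regs$chromosome[idx[2, ]],
                                 "intra", "inter"),
             stringsAsFactors = FALSE)
}

#' Exclusion mask for unreliable positions beyond a chromosome-end boundary
#'
#' Positions distal to the boundary (toward the chromosome end) are flagged
#' excluded-from-quantification, emulating the drop in Total-fraction
#' coverage inside terminal repeat arrays.
#'
#' @param genome a `genome_model`.
#' @param boundaries data.frame with columns `chromosome`, `side`
#'   (`left`/`right`) and `boundary` (0-based coordinate; see
#'   [coord_0based()] for converting a 1-based "last included position").
#' @return object of class `position_mask`: a list of logical vectors per
#'   chromosome, `TRUE` where excluded.
#' @export
telomere_mask <- function(genome, boundaries) {
  stopifnot(inherits(genome, "genome_model"),
            all(c("chromosome", "side", "boundary") %in% names(boundaries)))
  len <- chrom_lengths(genome)
  mask <- lapply(len, function(L) rep(FALSE, L))
  for (i in seq_len(nrow(boundaries))) {
    cn <- as.character(boundaries$chromosome[i])
    b <- boundaries$boundary[i]
    side <- match.arg(as.character(boundaries$side[i]), c("left", "right"))
    if (!cn %in% names(len)) stop("unknown chromosome in mask: ", cn)
    L <- len[[cn]]
    if (b < 0 || b > L) stop("boundary outside chromosome: ", cn)
    if (side == "right") {
      if (b < L) mask[[cn]][(b + 1):L] <- TRUE      # 0-based [b, L)
    } else {
      if (b > 0) mask[[cn]][1:b] <- TRUE            # 0-based [0, b)
    }
  }
  structure(mask, class = "position_mask")
}

#' Number of masked positions
#' @param mask a `position_mask`.
#' @return integer count of excluded positions.
#' @export
masked_positions <- function(mask) {
  stopifnot(inherits(mask, "position_mask"))
  sum(vapply(unclass(mask), sum, numeric(1)))
}
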
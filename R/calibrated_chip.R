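#' @title Spike-in calibrated ChIP quantification
#' @description Coverage tracks from fragment intervals, the spike-in
#'   calibration factor, the per-base calibrated IP/Total occupancy ratio,
#'   qPCR-style normalization against the spike-in control locus, and
#'   metagene profiles over gene bodies.
#' @name calibrated_chip
NULL

#' Build a coverage track from fragment intervals
#'
#' Each position (or bin) counts the fragments overlapping it; bin counts
#' are overlap counts, not midpoint counts.
#'
#' @param fragments data.frame with columns `chromosome`, `start`, `end`
#'   (0-based half-open).
#' @param genome the `genome_model` the fragments belong to.
#' @param fraction `"IP"` or `"Total"`.
#' @param bin_size bin width in bp; 1 (default) gives per-base counts.
#' @return object of class `coverage_track`: per-chromosome integer count
#'   vectors plus `species`, `fraction`, `bin_size` and `total` (sum of all
#'   per-fragment emitted counts at bin_size 1; at larger bins, the number
#'   of fragment/bin overlaps).
#' @export
coverage_from_fragments <- function(fragments, genome,
                                    fraction = c("IP", "Total"),
                                    bin_size = 1L) {
  fraction <- match.arg(fraction)
  stopifnot(inherits(genome, "genome_model"), bin_size >= 1)
  len <- chrom_lengths(genome)
  if (nrow(fragments)) {
    bad <- !(fragments$chromosome %in% names(len)) |
      fragments$start < 0 |
      fragments$end > len[as.character(fragments$chromosome)] |
      fragments$start >= fragments$end
    if (any(bad))
      stop("fragments outside chromosome bounds at row(s): ",
           paste(utils::head(which(bad), 10), collapse = ", "))
  }
  counts <- lapply(names(len), function(cn) {
    L <- len[[cn]]
    fr <- fragments[fragments$chromosome == cn, , drop = FALSE]
    if (bin_size == 1) {
      if (!nrow(fr)) return(integer(L))
      cov <- IRanges::coverage(
        IRanges::IRanges(start = fr$start + 1L, end = fr$end), width = L)
      as.integer(cov)
    } else {
      nb <- ceiling(L / bin_size)
      bins <- IRanges::IRanges(start = (seq_len(nb) - 1L) * bin_size + 1L,
                               end = pmin(seq_len(nb) * bin_size, L))
      if (!nrow(fr)) return(integer(nb))
      IRanges::countOverlaps(
        bins, IRanges::IRanges(start = fr$start + 1L, end = fr$end))
    }
  })
  names(counts) <- names(len)
  structure(list(species = genome$species_id, fraction = fraction,
                 counts = counts, bin_size = as.integer(bin_size),
                 n_fragments = nrow(fragments)),
            class = "coverage_track")
}

#' Total assigned counts of a coverage track
#' @param track a `coverage_track`.
#' @return numeric scalar, the sum over all chromosomes.
#' @export
track_total <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  sum(vapply(track$counts, sum, numeric(1)))
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track [%s/%s]: %d chromosome(s), bin %d bp, %d fragments\n",
              x$species, x$fraction, length(x$counts), x$bin_size,
              x$n_fragments))
  invisible(x)
}

#' Spike-in calibration factor
#'
#' `alpha = (spike-in Total fragment count) / (spike-in IP fragment count)`.
#' Multiplying the target IP track by `alpha` equalizes IP and Total on the
#' spike-in, so target occupancy ratios are reported on a scale where
#' genome-average spike-in occupancy is 1.
#'
#' @param ip_spike,total_spike `coverage_track`s of the spike-in species.
#' @return positive scalar `alpha`.
#' @export
calibration_factor <- function(ip_spike, total_spike) {
  stopifnot(inherits(ip_spike, "coverage_track"),
            inherits(total_spike, "coverage_track"))
  if (ip_spike$species != "spikein" || total_spike$species != "spikein")
    stop("calibration_factor expects spike-in tracks")
  ip_n <- ip_spike$n_fragments
  t_n <- total_spike$n_fragments
  if (t_n <= 0) stop("spike-in Total fraction is empty")
  if (ip_n <= 0) stop("calibration failed: zero spike-in IP fragments")
  t_n / ip_n
}

#' Calibrated IP/Total occupancy ratio track
#'
#' At each unmasked position `b`:
#' `R(b) = (alpha * IP(b) + pseudocount) / (Total(b) + pseudocount)`.
#' Positions with Total coverage below `total_floor` are masked as
#' low-coverage; positions under `mask` are excluded a priori.  Masked
#' positions carry `NA`, never zero.
#'
#' @param ip_target,total_target `coverage_track`s of the target species
#'   with identical bin structure.
#' @param alpha calibration factor from [calibration_factor()].
#' @param pseudocount added to numerator and denominator (default 1).
#' @param mask optional `position_mask` (bin_size 1) from [telomere_mask()].
#' @param total_floor minimal Total count for a position to be reported.
#' @return object of class `ratio_track` with per-chromosome ratio vectors
#'   (`NA` at masked positions), the mask actually applied, `pseudocount`
#'   and `alpha`.
#' @export
calibrated_ratio <- function(ip_target, total_target, alpha,
                             pseudocount = 1, mask = NULL, total_floor = 5) {
  stopifnot(inherits(ip_target, "coverage_track"),
            inherits(total_target, "coverage_track"),
            alpha > 0, pseudocount >= 0, total_floor >= 0)
  if (ip_target$species != total_target$species ||
      ip_target$bin_size != total_target$bin_size ||
      !identical(lengths(ip_target$counts), lengths(total_target$counts)))
    stop("IP and Total tracks have mismatched geometries")
  ratios <- mapply(function(ip, tot, cn) {
    r <- (alpha * ip + pseudocount) / (tot + pseudocount)
    r[tot < total_floor] <- NA_real_
    if (!is.null(mask)) {
      m <- unclass(mask)[[cn]]
      if (is.null(m) || length(m) != length(r))
        stop("mask geometry does not match track")
      r[m] <- NA_real_
    }
    r
  }, ip_target$counts, total_target$counts, names(ip_target$counts),
  SIMPLIFY = FALSE)
  structure(list(species = ip_target$species, ratios = ratios,
                 bin_size = ip_target$bin_size, alpha = alpha,
                 pseudocount = pseudocount, total_floor = total_floor,
                 n_masked = sum(vapply(ratios, function(r) sum(is.na(r)),
                                       numeric(1)))),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf(
    "ratio_track [%s]: %d chromosome(s), alpha = %.4g, pseudocount = %g, %d masked position(s)\n",
    x$species, length(x$ratios), x$alpha, x$pseudocount, x$n_masked))
  invisible(x)
}

#' Mean calibrated ratio per feature class
#'
#' Averages unmasked ratio values over all positions covered by each feature
#' class, plus a `background` class for positions covered by no feature.
#' The telomere-fold readout used throughout is
#' `mean(telomere_repeat) / mean(background)`.
#'
#' @param track a `ratio_track` (bin_size 1).
#' @param genome the matching `genome_model`.
#' @param classes feature classes to report.
#' @return named numeric vector of mean ratios.
#' @export
feature_class_means <- function(track, genome,
                                classes = c("telomere_repeat", "STE",
                                            "gene", "background")) {
  stopifnot(inherits(track, "ratio_track"), track$bin_size == 1,
            inherits(genome, "genome_model"))
  out <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    vals <- unlist(lapply(names(track$ratios), function(cn) {
      r <- track$ratios[[cn]]
      f <- genome$features[genome$features$chromosome == cn, , drop = FALSE]
      covered <- rep(FALSE, length(r))
      for (i in seq_len(nrow(f)))
        covered[(f$start[i] + 1):f$end[i]] <- TRUE
      if (cl == "background") {
        r[!covered]
      } else {
        fi <- f[f$class == cl, , drop = FALSE]
        sel <- rep(FALSE, length(r))
        for (i in seq_len(nrow(fi)))
          sel[(fi$start[i] + 1):fi$end[i]] <- TRUE
        r[sel]
      }
    }), use.names = FALSE)
    out[cl] <- mean(vals, na.rm = TRUE)
  }
  out
}

#' qPCR-style normalization against the spike-in control locus
#'
#' Per record, `normalized = percent_ip / control_percent_ip`; records with
#' a missing or non-positive control are excluded and reported.  Replicate
#' mean and n-1 sample SD are returned per locus and condition.
#'
#' @param records data.frame with columns `locus`, `percent_ip`,
#'   `control_percent_ip`, `condition`, `replicate`.
#' @return list with `per_replicate` (records plus `normalized`) and
#'   `summary` (per locus x condition: mean, sd, n); excluded records (if
#'   any) are attached as attribute `"excluded"`.
#' @export
qpcr_normalize <- function(records) {
  need <- c("locus", "percent_ip", "control_percent_ip",
            "condition", "replicate")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  if (any(records$percent_ip < 0, na.rm = TRUE))
    stop("percent_ip must be >= 0")
  ok <- is.finite(records$control_percent_ip) &
    records$control_percent_ip > 0
  excluded <- records[!ok, , drop = FALSE]
  if (nrow(excluded))
    warning(nrow(excluded),
            " record(s) excluded for zero/absent control locus value")
  rec <- records[ok, , drop = FALSE]
  rec$normalized <- rec$percent_ip / rec$control_percent_ip
  key <- interaction(rec$locus, rec$condition, drop = TRUE)
  summ <- do.call(rbind, lapply(split(rec, key), function(d) {
    s <- replicate_summary(d$normalized)
    data.frame(locus = d$locus[1], condition = d$condition[1],
               mean = s$mean, sd = s$sd, n = s$n,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_replicate = rec, summary = summ),
            excluded = excluded)
}

#' Metagene profile over scaled gene bodies with fixed flanks
#'
#' Each gene body is rescaled to `body_bins` equal segments; flanks of
#' `flank_bp` on each side are split into `flank_bins` fixed-width bins.
#' Minus-strand genes are reversed so the transcription start site is always
#' leftmost.  Masked (`NA`) positions are ignored; flank bins falling
#' outside the chromosome are padded with `NA`.
#'
#' @param track a `ratio_track` with bin_size 1.
#' @param genes data.frame of features (rows with `class == "gene"` are
#'   used; a pre-filtered site list is accepted as-is when no class column
#'   is present).
#' @param body_bins number of gene-body bins (default 60).
#' @param flank_bp flank extent in bp (default 500).
#' @param flank_bins number of bins per flank (default 10).
#' @return data.frame with one row per profile bin: `bin`, `zone`
#'   (`upstream`/`body`/`downstream`), `mean`, `sd`, `n_genes`.
#' @export
metagene_profile <- function(track, genes, body_bins = 60,
                             flank_bp = 500, flank_bins = 10) {
  stopifnot(inherits(track, "ratio_track"), track$bin_size == 1,
            body_bins >= 1, flank_bins >= 1, flank_bp >= flank_bins)
  if ("class" %in% names(genes))
    genes <- genes[genes$class == "gene", , drop = FALSE]
  stopifnot(nrow(genes) >= 1)
  fw <- flank_bp / flank_bins
  nb <- 2 * flank_bins + body_bins
  prof <- matrix(NA_real_, nrow = nrow(genes), ncol = nb)
  for (g in seq_len(nrow(genes))) {
    cn <- as.character(genes$chromosome[g])
    r <- track$ratios[[cn]]
    if (is.null(r)) stop("gene on chromosome absent from track: ", cn)
    L <- length(r)
    s <- genes$start[g]; e <- genes$end[g]
    # value of positions [a, b) with out-of-bounds padded NA, 0-based
    span_mean <- function(a, b) {
      a <- floor(a); b <- ceiling(b)
      if (b <= a) b <- a + 1
      idx <- seq(a, b - 1)
      vals <- ifelse(idx >= 0 & idx < L, r[pmax(idx, 0) + 1], NA_real_)
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }
    up <- vapply(seq_len(flank_bins) - 1, function(k)
      span_mean(s - flank_bp + k * fw, s - flank_bp + (k + 1) * fw),
      numeric(1))
    body <- vapply(seq_len(body_bins) - 1, function(k)
      span_mean(s + k * (e - s) / body_bins,
                s + (k + 1) * (e - s) / body_bins), numeric(1))
    down <- vapply(seq_len(flank_bins) - 1, function(k)
      span_mean(e + k * fw, e + (k + 1) * fw), numeric(1))
    row <- c(up, body, down)
    if (identical(genes$strand[g], "-")) row <- rev(row)
    prof[g, ] <- row
  }
  data.frame(
    bin = seq_len(nb),
    zone = c(rep("upstream", flank_bins), rep("body", body_bins),
             rep("downstream", flank_bins)),
    mean = colMeans(prof, na.rm = TRUE),
    sd = apply(prof, 2, stats::sd, na.rm = TRUE),
    n_genes = colSums(!is.na(prof)),
    stringsAsFactors = FALSE)
}

#' Write a coverage or ratio track as bedGraph
#'
#' Missing (masked) positions are omitted, per bedGraph convention; runs of
#' equal value are merged.
#'
#' @param track a `coverage_track` or `ratio_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  vals <- if (inherits(track, "coverage_track")) track$counts
          else if (inherits(track, "ratio_track")) track$ratios
          else stop("unsupported track type")
  bs <- track$bin_size
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (cn in names(vals)) {
    v <- as.numeric(vals[[cn]])
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- c(0, ends[-length(ends)])
    keep <- !is.na(rl$values)
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", cn,
                       as.integer(starts[keep] * bs),
                       as.integer(ends[keep] * bs),
                       rl$values[keep]), con)
  }
  invisible(path)
}
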
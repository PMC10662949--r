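#' @title Hi-C normalization and chromosome-end aggregation
#' @description Square-root vanilla-coverage (VC_SQRT) normalization,
#'   observed/expected, distance-decay curves, differential log2 maps, and
#'   the telomere-pair aggregate analysis with rank quantization and
#'   Mann-Whitney-Wilcoxon condition comparison.
#' @name hic_telomere
NULL

#' Square-root vanilla-coverage normalization
#'
#' `M'(i,j) = M(i,j) / sqrt(r_i * r_j)` with `r_k` the marginal sum of row
#' `k` (NA-aware).  Rows with zero marginal are masked (`NA`), never
#' divided.  Invariant under global scaling of the input.
#'
#' @param m a raw `contact_matrix`.
#' @return a `contact_matrix` with normalization `"vc_sqrt"`.
#' @export
vc_sqrt_normalize <- function(m) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization != "raw")
    stop("vc_sqrt_normalize expects a raw matrix")
  M <- m$matrix
  r <- rowSums(M, na.rm = TRUE)
  zero <- r == 0
  r[zero] <- NA_real_
  out <- M / sqrt(outer(r, r))
  out[zero, ] <- NA_real_
  out[, zero] <- NA_real_
  m$matrix <- out
  m$normalization <- "vc_sqrt"
  m
}

#' Observed/expected transformation
#'
#' The expected value at genomic distance `d` (in bins) is the mean of
#' unmasked intra-chromosomal entries at that distance, pooled across
#' chromosomes; intra entries are divided by it.  Inter-chromosomal entries
#' are divided by the mean unmasked inter-chromosomal value (a single
#' pooled expected by default; `per_pair_inter = TRUE` uses one mean per
#' chromosome pair).  Distance classes with no unmasked entries yield
#' masked output.
#'
#' @param m a `contact_matrix` (vc_sqrt-normalized or raw).
#' @param per_pair_inter logical; per-chromosome-pair inter expected.
#' @return a `contact_matrix` with normalization `"observed_expected"`.
#' @export
observed_over_expected <- function(m, per_pair_inter = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  M <- m$matrix
  n <- nrow(M)
  chrom <- m$bins$chromosome
  intra <- outer(chrom, chrom, "==")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  out <- matrix(NA_real_, n, n)

  dv <- d[intra]; mv <- M[intra]
  exp_d <- tapply(mv, dv, function(v) mean(v, na.rm = TRUE))
  e <- exp_d[as.character(dv)]
  e[!is.finite(e) | e == 0] <- NA_real_
  out[intra] <- mv / e

  if (any(!intra)) {
    if (per_pair_inter) {
      pair_id <- matrix(paste(pmin(chrom[row(M)], chrom[col(M)]),
                              pmax(chrom[row(M)], chrom[col(M)])), n, n)
      ids <- pair_id[!intra]
      mu <- tapply(M[!intra], ids, function(v) mean(v, na.rm = TRUE))
      ev <- mu[ids]
      ev[!is.finite(ev) | ev == 0] <- NA_real_
      out[!intra] <- M[!intra] / ev
    } else {
      mu <- mean(M[!intra], na.rm = TRUE)
      if (is.finite(mu) && mu > 0) out[!intra] <- M[!intra] / mu
    }
  }
  out[is.na(M)] <- NA_real_
  m$matrix <- out
  m$normalization <- "observed_expected"
  m
}

#' Median contact probability as a function of genomic distance
#'
#' For each distance bin, the median of unmasked intra-chromosomal values
#' whose separation falls in the bin, pooled over chromosomes; the series
#' is scaled to sum to 1 over the reported bins (probability convention).
#' Empty distance bins are omitted.
#'
#' @param m a normalized `contact_matrix`.
#' @param n_bins number of log-spaced distance bins; `NULL` (default) uses
#'   one bin per matrix diagonal.
#' @return data.frame with `distance` (bp, bin midpoint) and `prob`.
#' @export
distance_decay_curve <- function(m, n_bins = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  M <- m$matrix
  n <- nrow(M)
  chrom <- m$bins$chromosome
  intra <- outer(chrom, chrom, "==")
  dbin <- abs(outer(seq_len(n), seq_len(n), "-"))
  sel <- intra & upper.tri(M, diag = FALSE)
  dv <- dbin[sel] * m$resolution
  vv <- M[sel]
  keep <- !is.na(vv)
  dv <- dv[keep]; vv <- vv[keep]
  if (!length(dv)) return(data.frame(distance = numeric(0),
                                     prob = numeric(0)))
  if (is.null(n_bins)) {
    med <- tapply(vv, dv, stats::median)
    out <- data.frame(distance = as.numeric(names(med)),
                      prob = as.numeric(med))
  } else {
    brk <- exp(seq(log(min(dv)), log(max(dv) + 1), length.out = n_bins + 1))
    grp <- cut(dv, brk, include.lowest = TRUE)
    med <- tapply(vv, grp, stats::median)
    mid <- tapply(dv, grp, stats::median)
    keep <- !is.na(med)
    out <- data.frame(distance = as.numeric(mid[keep]),
                      prob = as.numeric(med[keep]))
  }
  out <- out[order(out$distance), ]
  out$prob <- out$prob / sum(out$prob)
  rownames(out) <- NULL
  out
}

#' Differential log2 contact map (mutant over control)
#'
#' `log2((a + eps) / (b + eps))` element-wise; entries masked in either
#' input stay masked.  By default `eps` is the smallest positive unmasked
#' value of the control matrix.
#'
#' @param a mutant `contact_matrix`.
#' @param b control `contact_matrix` with identical geometry and
#'   normalization state.
#' @param eps stabilizing offset; `NULL` for the default.
#' @return a `contact_matrix` with normalization `"log2_ratio"`.
#' @export
differential_map <- function(a, b, eps = NULL) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!identical(dim(a$matrix), dim(b$matrix)) ||
      a$resolution != b$resolution ||
      !identical(a$chromosomes, b$chromosomes) ||
      a$normalization != b$normalization)
    stop("contact matrices have mismatched geometry or normalization")
  if (is.null(eps)) {
    pos <- b$matrix[!is.na(b$matrix) & b$matrix > 0]
    eps <- if (length(pos)) min(pos) else 1
  }
  out <- log2((a$matrix + eps) / (b$matrix + eps))
  out[is.na(a$matrix) | is.na(b$matrix)] <- NA_real_
  a$matrix <- out
  a$normalization <- "log2_ratio"
  a$condition <- paste0(a$condition, "/", b$condition)
  a
}

#' Rank quantization of a window
#'
#' Each cell is replaced by `(rank - 1) / (n - 1)` with mid-ranks for ties,
#' `n` the number of non-missing cells, so values lie in `[0, 1]` and any
#' strictly monotone transform of the input yields identical output.  An
#' all-tied window maps to 0.5 everywhere; missing cells stay missing.
#'
#' @param x numeric matrix or vector with at least 2 cells.
#' @return same-shape object of quantized values.
#' @export
rank_quantize <- function(x) {
  v <- as.vector(x)
  stopifnot(length(v) >= 2)
  ok <- !is.na(v)
  n <- sum(ok)
  out <- rep(NA_real_, length(v))
  if (n == 1) out[ok] <- 0.5
  if (n >= 2) out[ok] <- (rank(v[ok], ties.method = "average") - 1) / (n - 1)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

# bin indices of one telomere region, ordered repeat-proximal first
.region_bin_order <- function(m, chrom, side, region_bp) {
  idx <- .chrom_bin_idx(m, chrom)
  nb <- round(region_bp / m$resolution)
  if (length(idx) < nb) return(NULL)
  if (side == "left") idx[seq_len(nb)]
  else rev(idx[seq(length(idx) - nb + 1, length(idx))])
}

# generic pair aggregation over oriented region bin lists
.aggregate_pairs <- function(M, rows_list, cols_list, classes, window,
                             step, summary_fun) {
  stopifnot(length(rows_list) == length(cols_list))
  res <- list()
  for (cls in unique(classes)) {
    q_sum <- NULL; r_sum <- NULL; k <- 0L
    q_means <- numeric(0); r_means <- numeric(0)
    for (p in which(classes == cls)) {
      S <- M[rows_list[[p]], cols_list[[p]], drop = FALSE]
      nb <- nrow(S)
      offs <- seq(1, nb - window + 1, by = step)
      for (i in offs) for (j in offs) {
        fr <- S[i:(i + window - 1), j:(j + window - 1)]
        fq <- rank_quantize(fr)
        if (is.null(q_sum)) {
          q_sum <- matrix(0, window, window)
          r_sum <- matrix(0, window, window)
        }
        q_sum <- q_sum + ifelse(is.na(fq), 0, fq)
        r_sum <- r_sum + ifelse(is.na(fr), 0, fr)
        k <- k + 1L
        q_means <- c(q_means, summary_fun(fq))
        r_means <- c(r_means, mean(fr, na.rm = TRUE))
      }
    }
    res[[cls]] <- list(aggregate_quantized = q_sum / k,
                       aggregate_raw = r_sum / k,
                       window_scores_quantized = q_means,
                       window_scores_raw = r_means,
                       n_windows = k,
                       n_pairs = sum(classes == cls))
  }
  res
}

#' Telomere-pair aggregation with rank quantization
#'
#' For every unordered pair of telomeres, the end-region x end-region
#' submatrix (default 30 x 30 bins: 150 kb at 5 kb) is extracted and
#' orientation-normalized so the repeat-proximal corner sits at index
#' (1, 1).  A `window` x `window` frame (default 21) slides at `step` over
#' the submatrix; every frame is collected, rank-quantized, and aggregated
#' per pair class (`intra`/`inter`) by element-wise mean.  Both quantized
#' and raw aggregates are retained, together with per-frame summary scores
#' fed to [compare_conditions()].
#'
#' Per-frame scores: the raw score is the frame mean; the quantized score
#' is the mean quantized value over the frame's repeat-proximal quadrant
#' (the full-frame mean of ranks is constant by construction, so the
#' quadrant mean is used as the location-sensitive rank summary).
#'
#' @param m a normalized or observed/expected `contact_matrix`.
#' @param genome the matching `genome_model`.
#' @param region_bp distal region per telomere (default 150 kb).
#' @param window sliding frame size in bins (default 21).
#' @param step frame step in bins (default 1).
#' @return object of class `pair_submatrix_stack`: list with one element
#'   per pair class plus attributes `excluded_pairs`, `window`, `region_bp`.
#' @export
telomere_aggregate <- function(m, genome, region_bp = 150000, window = 21,
                               step = 1) {
  stopifnot(inherits(m, "contact_matrix"),
            inherits(genome, "genome_model"))
  nb <- round(region_bp / m$resolution)
  if (nb < window)
    stop("end region holds fewer bins than the sliding window")
  pairs <- enumerate_telomere_pairs(genome, region_bp)
  rows_list <- list(); cols_list <- list(); classes <- character(0)
  excluded <- pairs[0, ]
  for (p in seq_len(nrow(pairs))) {
    ra <- .region_bin_order(m, pairs$chrom_a[p], pairs$side_a[p], region_bp)
    rb <- .region_bin_order(m, pairs$chrom_b[p], pairs$side_b[p], region_bp)
    if (is.null(ra) || is.null(rb)) {
      excluded <- rbind(excluded, pairs[p, ])
      next
    }
    rows_list[[length(rows_list) + 1L]] <- ra
    cols_list[[length(cols_list) + 1L]] <- rb
    classes <- c(classes, pairs$pair_class[p])
  }
  if (nrow(excluded))
    warning(nrow(excluded), " telomere pair(s) excluded (region shorter ",
            "than the sliding window)")
  quad <- seq_len(floor(window / 2))
  qfun <- function(fq) mean(fq[quad, quad], na.rm = TRUE)
  res <- .aggregate_pairs(m$matrix, rows_list, cols_list, classes,
                          window, step, qfun)
  structure(res, class = "pair_submatrix_stack",
            excluded_pairs = excluded, window = window,
            region_bp = region_bp, resolution = m$resolution,
            condition = m$condition)
}

#' Centromere-pair aggregation
#'
#' Same machinery as [telomere_aggregate()] applied to windows of
#' `region_bp` centred on each centromere; all pairs of distinct
#' centromeres are aggregated under class `"cen"` (with one centromere per
#' chromosome all pairs are inter-chromosomal).
#'
#' @inheritParams telomere_aggregate
#' @return a `pair_submatrix_stack` with a single `"cen"` class.
#' @export
centromere_aggregate <- function(m, genome, region_bp = 150000, window = 21,
                                 step = 1) {
  stopifnot(inherits(m, "contact_matrix"),
            inherits(genome, "genome_model"))
  nb <- round(region_bp / m$resolution)
  if (nb < window)
    stop("centromere region holds fewer bins than the sliding window")
  cen <- genome$features[genome$features$class == "centromere", ,
                         drop = FALSE]
  stopifnot(nrow(cen) >= 2)
  reg <- lapply(seq_len(nrow(cen)), function(i) {
    idx <- .chrom_bin_idx(m, cen$chromosome[i])
    mid_bin <- which.min(abs((m$bins$start[idx] + m$bins$end[idx]) / 2 -
                             (cen$start[i] + cen$end[i]) / 2))
    lo <- mid_bin - floor(nb / 2)
    hi <- lo + nb - 1
    if (lo < 1 || hi > length(idx)) return(NULL)
    idx[lo:hi]
  })
  keep <- !vapply(reg, is.null, logical(1))
  reg <- reg[keep]
  stopifnot(length(reg) >= 2)
  cmb <- utils::combn(length(reg), 2)
  rows_list <- lapply(seq_len(ncol(cmb)), function(k) reg[[cmb[1, k]]])
  cols_list <- lapply(seq_len(ncol(cmb)), function(k) reg[[cmb[2, k]]])
  quad <- seq_len(floor(window / 2))
  qfun <- function(fq) mean(fq[quad, quad], na.rm = TRUE)
  res <- .aggregate_pairs(m$matrix, rows_list, cols_list,
                          rep("cen", ncol(cmb)), window, step, qfun)
  structure(res, class = "pair_submatrix_stack",
            excluded_pairs = NULL, window = window,
            region_bp = region_bp, resolution = m$resolution,
            condition = m$condition)
}

#' Compare aggregated contact scores between two conditions
#'
#' Two-sided Mann-Whitney-Wilcoxon on the per-frame summary scores of
#' condition `a` versus condition `b`, run on both the quantized and the
#' non-quantized variants, per pair class.
#'
#' @param stack_a,stack_b `pair_submatrix_stack`s with the same classes and
#'   geometry.
#' @param alpha significance threshold for the reported decision
#'   (default 0.001).
#' @return data.frame of class `comparison_result`: one row per pair class
#'   and test variant, with aggregate score means, U, p-value and decision.
#' @export
compare_conditions <- function(stack_a, stack_b, alpha = 0.001) {
  stopifnot(inherits(stack_a, "pair_submatrix_stack"),
            inherits(stack_b, "pair_submatrix_stack"),
            identical(sort(names(stack_a)), sort(names(stack_b))),
            identical(attr(stack_a, "window"), attr(stack_b, "window")))
  out <- NULL
  for (cls in names(stack_a)) {
    for (variant in c("quantized", "non_quantized")) {
      fa <- if (variant == "quantized")
        stack_a[[cls]]$window_scores_quantized
      else stack_a[[cls]]$window_scores_raw
      fb <- if (variant == "quantized")
        stack_b[[cls]]$window_scores_quantized
      else stack_b[[cls]]$window_scores_raw
      if (length(fa) < 2 || length(fb) < 2)
        stop("fewer than 2 windows in a condition for class ", cls)
      tst <- mann_whitney(fa, fb, alternative = "two.sided",
                          method = "auto")
      out <- rbind(out, data.frame(
        pair_class = cls, variant = variant,
        score_a = mean(fa), score_b = mean(fb),
        statistic = tst$statistic, n_a = tst$n1, n_b = tst$n2,
        p.value = tst$p.value, method = tst$method,
        significant = tst$p.value < alpha,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("comparison_result", class(out))
  out
}
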
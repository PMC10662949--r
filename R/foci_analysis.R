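#' @title Mitotic foci counting and disjunction scoring
#' @description Replaces visual focus counting with deterministic
#'   resolution-limited merging of telomere point objects, classifies
#'   mitotic stage from spindle length (SPB-SPB distance), and scores
#'   sister-telomere separation, full disjunction and non-disjunction.
#' @name foci_analysis
NULL

#' Count foci by resolution-limited merging
#'
#' Single-linkage clustering of telomere points at distance threshold
#' `merge_radius`: any chain of sub-threshold spacings is one spot (the
#' optical intuition for diffraction-limited imaging).  A focus is one
#' cluster; its position is the cluster centroid.  With `merge_radius = 0`
#' distinct points stay distinct.  Points at exactly the threshold
#' distance merge (`<=` convention).
#'
#' @param points numeric matrix (n x 3) of telomere positions in µm (or a
#'   `cell_table` subset; rows with `object_type == "telomere"` are used).
#' @param merge_radius merge threshold in µm (>= 0).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return list with `count`, `centroids` (k x 3 matrix) and `assignment`
#'   (cluster index per input point).
#' @export
count_foci <- function(points, merge_radius = 0.3,
                       linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(merge_radius >= 0)
  if (is.data.frame(points)) {
    if ("object_type" %in% names(points))
      points <- points[points$object_type == "telomere", , drop = FALSE]
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  n <- if (is.null(points)) 0L else nrow(points)
  if (n == 0) {
    warning("no telomere objects: focus count 0")
    return(list(count = 0L, centroids = matrix(numeric(0), 0, 3),
                assignment = integer(0)))
  }
  if (n == 1)
    return(list(count = 1L, centroids = points, assignment = 1L))
  hc <- stats::hclust(stats::dist(points), method = linkage)
  cl <- stats::cutree(hc, h = merge_radius)
  k <- max(cl)
  cent <- t(vapply(seq_len(k), function(i)
    colMeans(points[cl == i, , drop = FALSE]), numeric(3)))
  list(count = k, centroids = cent, assignment = unname(cl))
}

#' Classify mitotic stage from spindle length
#'
#' Spindle length is the Euclidean SPB-SPB distance.  Length <= `t1` is
#' metaphase (spindle growing from 0 to ~4 µm), `t1` < length <= `t2` is
#' anaphase, length > `t2` is late anaphase (the disjunction scoring
#' window).  Lengths exactly at a threshold go to the lower stage.
#'
#' @param spb 2 x 3 matrix of SPB positions (µm), or a `cell_table` subset.
#' @param thresholds `c(t1, t2)` in µm, 0 < t1 < t2 (defaults 4, 5).
#' @return list with `stage` and `spindle_length`.
#' @export
classify_stage <- function(spb, thresholds = c(4, 5)) {
  stopifnot(length(thresholds) == 2, thresholds[1] > 0,
            thresholds[1] < thresholds[2])
  if (is.data.frame(spb)) {
    if ("object_type" %in% names(spb))
      spb <- spb[spb$object_type == "spb", , drop = FALSE]
    spb <- as.matrix(spb[, c("x", "y", "z")])
  }
  stopifnot(nrow(spb) == 2, all(is.finite(spb)))
  len <- sqrt(sum((spb[1, ] - spb[2, ])^2))
  stage <- if (len <= thresholds[1]) "metaphase"
           else if (len <= thresholds[2]) "anaphase"
           else "late_anaphase"
  list(stage = stage, spindle_length = len)
}

#' Foci-versus-spindle-length profile and disjunction scores
#'
#' Per cell: spindle length, stage and focus count after merging.  Summary
#' scores for C chromosomes (2C telomeres, 4C sister copies):
#' * `separation_fraction`: anaphase or later cells with more than 2C foci
#'   (sister-telomere separation has begun);
#' * `full_disjunction_fraction`: anaphase or later cells with at least 4C
#'   foci (all sister telomeres disjoined);
#' * `non_disjunction_fraction`: late-anaphase cells retaining at most 2C
#'   foci.
#' For the three-chromosome genome these thresholds are >6, >=12 and <=6.
#'
#' @param cells a `cell_table` (see [simulate_mitotic_cells()]).
#' @param merge_radius passed to [count_foci()].
#' @param thresholds passed to [classify_stage()].
#' @param n_chromosomes C; defaults to 3.
#' @param spindle_bins breakpoints (µm) for the binned count distribution.
#' @return list of class `mitotic_profile` with `per_cell` (data.frame:
#'   cell_id, spindle_length, stage, foci), `summary` (the three fractions
#'   plus denominators) and `binned` (spindle-length bin x focus-count
#'   table).
#' @export
disjunction_profile <- function(cells, merge_radius = 0.3,
                                thresholds = c(4, 5), n_chromosomes = 3,
                                spindle_bins = seq(0, 12, by = 1)) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1,
            all(c("cell_id", "object_type", "x", "y", "z") %in%
                names(cells)))
  C <- n_chromosomes
  per <- do.call(rbind, lapply(split(cells, cells$cell_id), function(d) {
    st <- classify_stage(d, thresholds)
    fc <- count_foci(d, merge_radius)
    data.frame(cell_id = d$cell_id[1],
               spindle_length = st$spindle_length,
               stage = st$stage, foci = fc$count,
               stringsAsFactors = FALSE)
  }))
  per <- per[order(per$cell_id), ]
  rownames(per) <- NULL
  ana <- per[per$stage %in% c("anaphase", "late_anaphase"), , drop = FALSE]
  late <- per[per$stage == "late_anaphase", , drop = FALSE]
  summary <- data.frame(
    separation_fraction =
      if (nrow(ana)) mean(ana$foci > 2 * C) else NA_real_,
    full_disjunction_fraction =
      if (nrow(ana)) mean(ana$foci >= 4 * C) else NA_real_,
    non_disjunction_fraction =
      if (nrow(late)) mean(late$foci <= 2 * C) else NA_real_,
    n_anaphase = nrow(ana), n_late_anaphase = nrow(late),
    n_cells = nrow(per))
  grp <- cut(per$spindle_length, spindle_bins, include.lowest = TRUE)
  binned <- table(spindle_bin = grp, foci = per$foci)
  structure(list(per_cell = per, summary = summary, binned = binned,
                 merge_radius = merge_radius, thresholds = thresholds,
                 n_chromosomes = C),
            class = "mitotic_profile")
}

#' @export
print.mitotic_profile <- function(x, ...) {
  cat(sprintf("mitotic_profile: %d cell(s); separation %.2f, full disjunction %.2f, non-disjunction %.2f\n",
              x$summary$n_cells, x$summary$separation_fraction,
              x$summary$full_disjunction_fraction,
              x$summary$non_disjunction_fraction))
  invisible(x)
}
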
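#' @title Synthetic mitotic cells as 3D point sets
#' @name synthetic_cells
NULL

#' Parameters for the mitotic cell simulator
#'
#' Cells are 3D point sets (micrometres): two spindle pole bodies (SPBs)
#' plus telomere focus ground-truth positions.  For C chromosomes there are
#' 2C telomeres and 4C sister-telomere copies in mitosis.  Stages:
#' interphase cells keep telomeres clustered in 1-3 peripheral foci
#' (Rabl configuration); metaphase cells decluster up to 2C foci (sisters
#' co-located); anaphase cells split each sister pair with
#' `disjunction_prob`, up to 4C foci.
#'
#' @param n_cells number of cells.
#' @param stage_mix named proportions for interphase/metaphase/anaphase.
#' @param disjunction_prob probability a sister-telomere pair disjoins in
#'   anaphase.
#' @param decluster_prob probability a telomere leaves the cluster in
#'   metaphase (declustering completeness).
#' @param merge_radius focus merge radius carried as ground-truth metadata
#'   (µm); merging itself happens in [count_foci()].
#' @param spb_distance named list of `c(min, max)` spindle lengths (µm) per
#'   stage.
#' @param nucleus_radius nuclear radius (µm).
#' @return list of class `mitotic_sim_params`.
#' @export
mitotic_sim_params <- function(n_cells = 300,
                               stage_mix = c(interphase = 1/3,
                                             metaphase = 1/3,
                                             anaphase = 1/3),
                               disjunction_prob = 1,
                               decluster_prob = 1,
                               merge_radius = 0.3,
                               spb_distance = list(
                                 interphase = c(0.2, 0.8),
                                 metaphase = c(1.5, 4),
                                 anaphase = c(4.5, 11)),
                               nucleus_radius = 1.5) {
  p <- as.list(environment())
  stopifnot(n_cells >= 1,
            all(stage_mix >= 0), abs(sum(stage_mix) - 1) < 1e-9,
            disjunction_prob >= 0, disjunction_prob <= 1,
            decluster_prob >= 0, decluster_prob <= 1,
            merge_radius >= 0)
  class(p) <- "mitotic_sim_params"
  p
}

# uniform point in a sphere of given radius centred at `centre`
.sphere_point <- function(radius, centre = c(0, 0, 0)) {
  repeat {
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(p + centre)
  }
}

#' Simulate mitotic cells with known ground truth
#'
#' @param genome a target `genome_model` (defines C, the chromosome count).
#' @param params a [mitotic_sim_params()].
#' @param condition condition label attached to every cell.
#' @param seed integer seed.
#' @return data.frame of class `cell_table` with columns `cell_id`,
#'   `object_type` (`spb`/`telomere`), `x`, `y`, `z` (µm), `stage_truth`,
#'   `true_foci`, `condition`.
#' @export
simulate_mitotic_cells <- function(genome, params = mitotic_sim_params(),
                                   condition = "wt", seed = 1L) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(params, "mitotic_sim_params"))
  prev <- .with_seed(seed)
  on.exit(.restore_seed(prev), add = TRUE)
  C <- nrow(genome$chromosomes)
  stages <- sample(names(params$stage_mix), params$n_cells, replace = TRUE,
                   prob = params$stage_mix)
  R <- params$nucleus_radius
  rows <- vector("list", params$n_cells)
  for (ci in seq_len(params$n_cells)) {
    st <- stages[ci]
    d <- stats::runif(1, params$spb_distance[[st]][1],
                      params$spb_distance[[st]][2])
    spb <- rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))
    pts <- NULL
    if (st == "interphase") {
      k <- sample(1:3, 1)
      for (i in seq_len(k)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pts <- rbind(pts, 0.93 * R * u)         # nuclear periphery
      }
    } else if (st == "metaphase") {
      clustered <- stats::runif(2 * C) >= params$decluster_prob
      cluster_centre <- .sphere_point(R)
      for (i in seq_len(2 * C)) {
        pts <- rbind(pts, if (clustered[i]) cluster_centre
                     else .sphere_point(R))
      }
    } else {                                    # anaphase
      split <- stats::runif(2 * C) < params$disjunction_prob
      for (i in seq_len(2 * C)) {
        if (split[i]) {
          pts <- rbind(pts,
                       .sphere_point(R / 2, c(-d / 2 + R / 2, 0, 0)),
                       .sphere_point(R / 2, c(d / 2 - R / 2, 0, 0)))
        } else {
          pole <- sample(c(-1, 1), 1)
          pts <- rbind(pts,
                       .sphere_point(R / 2, c(pole * (d / 2 - R / 2), 0, 0)))
        }
      }
    }
    n_true <- nrow(pts)
    rows[[ci]] <- data.frame(
      cell_id = ci,
      object_type = c("spb", "spb", rep("telomere", n_true)),
      x = c(spb[, 1], pts[, 1]),
      y = c(spb[, 2], pts[, 2]),
      z = c(spb[, 3], pts[, 3]),
      stage_truth = st,
      true_foci = n_true,
      condition = condition,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cell_table", class(out))
  out
}

#' Write / read cell tables as TSV
#' @param cells a `cell_table`.
#' @param path file path.
#' @return `path` (writer) or a `cell_table` (reader).
#' @export
write_cells_tsv <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells_tsv
#' @export
read_cells_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("cell_table", class(out))
  out
}
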
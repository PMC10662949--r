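#' @title End-to-end scenario orchestration
#' @description One structured configuration drives simulation, calibrated
#'   ChIP quantification, Hi-C telomere aggregation and mitotic foci
#'   scoring for two conditions (wild-type-like versus condensin-mutant
#'   -like), with full determinism under a master seed.
#' @name pipeline
NULL

#' Default scenario configuration
#'
#' A plain nested list, JSON-serializable, validated stage by stage by the
#' owning modules when the scenario runs.  The mutant condition follows the
#' "cut14-like" preset: telomere clustering gains up, arm-range contacts
#' attenuated, anaphase sister-telomere disjunction lost; its ChIP telomere
#' enrichment can optionally follow a "taz1-like" preset (telomere
#' multiplier halved) via `chip_preset = "taz1_like"`.
#'
#' @param master_seed integer master seed; child-stage seeds are derived
#'   deterministically with [derive_seed()].
#' @param chip_preset `"none"` or `"taz1_like"` for the mutant condition.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(master_seed = 1L, chip_preset = "none") {
  cfg <- list(
    master_seed = as.integer(master_seed),
    genome = unclass(toy_genome_config()),
    chip = list(
      wt = unclass(enrichment_profile()),
      mutant = {
        p <- enrichment_profile()
        if (chip_preset == "taz1_like")
          p$telomere_repeat <- p$telomere_repeat / 2
        unclass(p)
      },
      mixing_ratio = 5,
      pseudocount = 1, total_floor = 5),
    hic = list(
      wt = unclass(hic_sim_params()),
      mutant = unclass(cut14_like_params())),
    mitotic = list(
      wt = unclass(mitotic_sim_params(disjunction_prob = 1)),
      mutant = unclass(mitotic_sim_params(disjunction_prob = 0.1))),
    analysis = list(region_bp = 150000, window = 21, step = 1,
                    merge_radius = 0.3, stage_thresholds = c(4, 5),
                    alpha = 0.001))
  class(cfg) <- "scenario_config"
  cfg
}

#' Read / write a scenario configuration as JSON
#' @param path JSON file.
#' @param config a `scenario_config`.
#' @return the configuration (reader) or `path` (writer).
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- scenario_config()
  cfg <- utils::modifyList(unclass(base), cfg)
  class(cfg) <- "scenario_config"
  cfg
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Derive a child seed from a master seed and a stage name
#'
#' Deterministic splitting rule (documented, stable across sessions):
#' a small polynomial hash of the stage name is mixed with the master seed
#' modulo 2^31 - 1, preventing accidental seed reuse between stages.
#'
#' @param master_seed integer.
#' @param stage character stage name.
#' @return integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000000007
  as.integer(((as.numeric(master_seed) %% 65536) * 2654435 + h) %%
               2147483646 + 1)
}

.restage <- function(lst, cls) { class(lst) <- cls; lst }

#' Run an end-to-end two-condition scenario
#'
#' Pipeline per condition: synthetic data -> calibrated ChIP ratio ->
#' Hi-C normalization, O/E and telomere/centromere aggregation -> mitotic
#' foci scoring; then cross-condition comparisons.  All intermediate files
#' are written under `out_dir` in a fixed layout (`genome/`, `sim/`,
#' `chip/`, `hic/`, `foci/`, `report/`) together with a manifest recording
#' parameters, derived seeds and md5 checksums.  The manifest contains no
#' timestamps, so identical config + seed reruns are byte-identical.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created).
#' @param quiet suppress progress messages.
#' @return list with `summary` (data.frame), `comparisons`
#'   (telomere/centromere [compare_conditions()] tables), `profiles`
#'   (per-condition `mitotic_profile`s) and `manifest_path`.
#' @export
run_scenario <- function(config = scenario_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  for (d in c("", "genome", "sim", "chip", "hic", "foci", "report"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }

  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("scenario stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  say("building toy genomes")
  gcfg <- .restage(config$genome, "toy_genome_config")
  genomes <- stage_guard("genome",
                         build_toy_genome(gcfg, derive_seed(ms, "genome")))
  write_genome_fasta(genomes$target,
                     emit(file.path(out_dir, "genome", "target.fa")),
                     seed = derive_seed(ms, "genome_seq"))
  write_features_bed(genomes$target,
                     emit(file.path(out_dir, "genome", "target.bed")))
  write_features_bed(genomes$spikein,
                     emit(file.path(out_dir, "genome", "spikein.bed")))

  conditions <- c("wt", "mutant")
  folds <- stats::setNames(numeric(2), conditions)
  stacks_tel <- list(); stacks_cen <- list(); profiles <- list()
  alphas <- stats::setNames(numeric(2), conditions)

  for (cond in conditions) {
    say("condition %s: ChIP simulation + calibration", cond)
    prof <- .restage(config$chip[[cond]], "enrichment_profile")
    sim <- stage_guard("simulate_chip",
      simulate_chip(genomes, prof, config$chip$mixing_ratio,
                    seed = derive_seed(ms, paste0("chip_", cond))))
    cov <- list(
      ip_t = coverage_from_fragments(sim$ip_target, genomes$target, "IP"),
      tot_t = coverage_from_fragments(sim$total_target, genomes$target,
                                      "Total"),
      ip_s = coverage_from_fragments(sim$ip_spike, genomes$spikein, "IP"),
      tot_s = coverage_from_fragments(sim$total_spike, genomes$spikein,
                                      "Total"))
    a <- stage_guard("calibration",
                     calibration_factor(cov$ip_s, cov$tot_s))
    alphas[cond] <- a
    rt <- stage_guard("calibrated_ratio",
      calibrated_ratio(cov$ip_t, cov$tot_t, a,
                       pseudocount = config$chip$pseudocount,
                       total_floor = config$chip$total_floor))
    write_bedgraph(rt, emit(file.path(out_dir, "chip",
                                      paste0("ratio_", cond, ".bedgraph"))))
    fc <- feature_class_means(rt, genomes$target)
    folds[cond] <- fc[["telomere_repeat"]] / fc[["background"]]
    say("condition %s: telomere fold %.2f (alpha %.3f)", cond,
        folds[cond], a)

    say("condition %s: Hi-C simulation + aggregation", cond)
    hp <- .restage(config$hic[[cond]], "hic_sim_params")
    hm <- stage_guard("simulate_hic",
      simulate_hic(genomes$target, hp,
                   seed = derive_seed(ms, paste0("hic_", cond))))
    hm$condition <- cond
    vc <- vc_sqrt_normalize(hm)
    oe <- observed_over_expected(vc)
    write_contact_tsv(oe, emit(file.path(out_dir, "hic",
                                         paste0("oe_", cond, ".tsv"))))
    decay <- distance_decay_curve(vc)
    utils::write.table(decay,
                       emit(file.path(out_dir, "hic",
                                      paste0("decay_", cond, ".tsv"))),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    # aggregation runs on the VC_SQRT matrix; rank quantization makes the
    # scores comparable across libraries (see the methods vignette)
    stacks_tel[[cond]] <- stage_guard("telomere_aggregate",
      telomere_aggregate(vc, genomes$target,
                         region_bp = config$analysis$region_bp,
                         window = config$analysis$window,
                         step = config$analysis$step))
    stacks_cen[[cond]] <- centromere_aggregate(
      vc, genomes$target, region_bp = config$analysis$region_bp,
      window = config$analysis$window, step = config$analysis$step)

    say("condition %s: mitotic cells + foci", cond)
    mp <- .restage(config$mitotic[[cond]], "mitotic_sim_params")
    cells <- stage_guard("simulate_mitotic_cells",
      simulate_mitotic_cells(genomes$target, mp, condition = cond,
                             seed = derive_seed(ms, paste0("cells_", cond))))
    write_cells_tsv(cells, emit(file.path(out_dir, "sim",
                                          paste0("cells_", cond, ".tsv"))))
    profiles[[cond]] <- disjunction_profile(
      cells, merge_radius = config$analysis$merge_radius,
      thresholds = config$analysis$stage_thresholds,
      n_chromosomes = nrow(genomes$target$chromosomes))
    utils::write.table(profiles[[cond]]$per_cell,
                       emit(file.path(out_dir, "foci",
                                      paste0("per_cell_", cond, ".tsv"))),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  cmp_tel <- compare_conditions(stacks_tel$mutant, stacks_tel$wt,
                                alpha = config$analysis$alpha)
  cmp_cen <- compare_conditions(stacks_cen$mutant, stacks_cen$wt,
                                alpha = config$analysis$alpha)
  utils::write.table(rbind(cbind(target = "telomere", cmp_tel),
                           cbind(target = "centromere", cmp_cen)),
                     emit(file.path(out_dir, "report", "comparisons.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  summary <- data.frame(
    condition = conditions,
    calibration_alpha = as.numeric(alphas),
    telomere_chip_fold = as.numeric(folds),
    separation_fraction = vapply(profiles, function(p)
      p$summary$separation_fraction, numeric(1)),
    full_disjunction_fraction = vapply(profiles, function(p)
      p$summary$full_disjunction_fraction, numeric(1)),
    non_disjunction_fraction = vapply(profiles, function(p)
      p$summary$non_disjunction_fraction, numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.table(summary,
                     emit(file.path(out_dir, "report", "summary.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("telodisjoin")),
    master_seed = ms,
    derived_seeds = lapply(stats::setNames(nm = c(
      "genome", "genome_seq",
      paste0("chip_", conditions), paste0("hic_", conditions),
      paste0("cells_", conditions))), function(s) derive_seed(ms, s)),
    config = unclass(config),
    checksums = {
      f <- sort(files)
      as.list(stats::setNames(unname(tools::md5sum(f)),
                              sub("^.*?(genome|sim|chip|hic|foci|report)/",
                                  "\\1/", f)))
    })
  manifest_path <- file.path(out_dir, "report", "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(summary = summary,
       comparisons = list(telomere = cmp_tel, centromere = cmp_cen),
       profiles = profiles,
       manifest_path = manifest_path)
}
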
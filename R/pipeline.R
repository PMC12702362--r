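#' Read a pipeline run configuration
#'
#' Configurations are YAML (JSON accepted, by extension). Thresholds
#' default to the screen's standard values: baseMean 50, FDR 0.10,
#' LOWESS window 20, stabilizing-region percentile 0.75, class boundary 0.
#' A \code{sim} block mirrors \code{\link{sim_config}} field-for-field and
#' triggers synthetic input generation; otherwise \code{counts} must point
#' at a count table TSV.
#'
#' @param path YAML or JSON file.
#' @return A named list (class \code{run_config}).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("validation failure: config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build_run_config(cfg)
}

#' Build and validate a run configuration from a list
#'
#' @param cfg Named list of run options (see \code{\link{read_run_config}}).
#' @return Validated list of class \code{run_config}.
#' @export
build_run_config <- function(cfg = list()) {
  defaults <- list(seed = 1L, base_mean_threshold = 50, fdr = 0.10,
                   class_boundary = 0, lowess_window = 20,
                   region_quantile = 0.75, region_upper_type = "percentile",
                   acceptance_aggregate = "mean",
                   conditions = list(t0 = "sel0h", t48 = "sel48h",
                                     input = "input"),
                   sim = NULL, counts = NULL, predictors = NULL,
                   conservation = NULL, predictor_mapping = NULL,
                   conservation_mapping = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$sim) && is.null(cfg$counts))
    stop("validation failure: config needs either a 'sim' block or a 'counts' path")
  for (f in c("counts", "predictors", "conservation")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("validation failure: ", f, " file not found: ", cfg[[f]])
  }
  if (cfg$base_mean_threshold < 0 || cfg$fdr <= 0 || cfg$fdr > 1 ||
      cfg$lowess_window < 2 || cfg$region_quantile <= 0 ||
      cfg$region_quantile >= 1)
    stop("validation failure: threshold outside its documented range")
  structure(cfg, class = "run_config")
}

# Coerce a config 'sim' list (e.g. parsed from YAML) into a sim_config.
as_sim_config <- function(sim, seed = NULL) {
  if (inherits(sim, "sim_config")) return(sim)
  if (!is.null(sim$spike_ins)) sim$spike_ins <-
      as.data.frame(sim$spike_ins, stringsAsFactors = FALSE)
  if (!is.null(sim$planted_regions)) sim$planted_regions <-
      as.data.frame(sim$planted_regions)
  if (!is.null(seed)) sim$seed <- seed
  do.call(sim_config, sim)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screen analysis pipeline
#'
#' Orchestrates every stage end to end: (optional) synthetic screen
#' simulation, enrichment scoring of the 0 h and 48 h contrasts, post hoc
#' refinement, positional acceptance / LOWESS / region calling, predictor
#' stratification (when predictor tables are available), and the
#' purifying-selection analysis (when conservation scores are available).
#' Every intermediate table is written to \code{outdir} together with a
#' JSON statistics report and a run log recording the resolved
#' configuration; rerunning with the same configuration and seed
#' reproduces the report byte for byte.
#'
#' @param config A \code{run_config} (list) from
#'   \code{\link{read_run_config}} / \code{\link{build_run_config}}, or a
#'   bare list.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results (screen, scores,
#'   refined table, profile, stratifications, selection statistics, and
#'   the paths written).
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "run_config")) config <- build_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wpath <- function(f) file.path(outdir, f)
  stats_report <- list(seed = config$seed)

  # --- inputs: simulate or load ------------------------------------------
  screen <- NULL
  predictors <- conservation <- NULL
  if (!is.null(config$sim)) {
    simc <- stage("simulate", as_sim_config(config$sim, seed = config$seed))
    screen <- stage("simulate", simulate_screen(simc))
    counts <- screen$counts
    samples <- screen$samples
    predictors <- screen$predictors
    conservation <- screen$conservation
    tv <- screen$truth$variants
    paths$counts <- wpath("counts.tsv")
    write_count_table(counts, paths$counts)
    paths$ground_truth <- wpath("ground_truth.csv")
    utils::write.csv(tv, paths$ground_truth, row.names = FALSE)
    paths$predictors <- wpath("predictors.csv")
    utils::write.csv(predictors, paths$predictors, row.names = FALSE)
    paths$conservation <- wpath("conservation.csv")
    utils::write.csv(conservation, paths$conservation, row.names = FALSE)
  } else {
    ct <- stage("load-counts", read_count_table(config$counts))
    counts <- ct$counts
    samples <- data.frame(sample = colnames(counts),
                          condition = sub("_[0-9]+$", "", colnames(counts)),
                          replicate = as.integer(sub("^.*_", "",
                                                     colnames(counts))),
                          stringsAsFactors = FALSE)
    if (!is.null(config$predictors))
      predictors <- stage("load-predictors",
                          read_predictor_table(config$predictors,
                                               config$predictor_mapping))
    if (!is.null(config$conservation))
      conservation <- stage("load-conservation",
                            read_conservation_table(config$conservation,
                                                    config$conservation_mapping))
  }

  # --- enrichment scoring -------------------------------------------------
  cond <- config$conditions
  scores_0h <- stage("score-0h", score_contrast(
    counts, samples, c(cond$t0, cond$input),
    base_mean_threshold = config$base_mean_threshold))
  scores_48h <- stage("score-48h", score_contrast(
    counts, samples, c(cond$t48, cond$input),
    base_mean_threshold = config$base_mean_threshold))
  paths$scores_0h <- wpath("scores_0h.tsv")
  paths$scores_48h <- wpath("scores_48h.tsv")
  write_scores(scores_0h, paths$scores_0h)
  write_scores(scores_48h, paths$scores_48h)
  pca <- stage("sample-pca", sample_pca(counts))
  paths$pca <- wpath("sample_pca.csv")
  utils::write.csv(data.frame(sample = rownames(pca$coords),
                              pca$coords[, 1:min(4, ncol(pca$coords))]),
                   paths$pca, row.names = FALSE)
  stats_report$pca_var_explained <- round(pca$var_explained[1:2], 4)
  count_classes <- function(s) {
    sp <- s[s$passed_filter, ]
    list(scored = nrow(sp), enriched = sum(sp$log2FoldChange > 0),
         depleted = sum(sp$log2FoldChange < 0),
         enriched_fdr = sum(sp$log2FoldChange > 0 & sp$padj < config$fdr,
                            na.rm = TRUE),
         depleted_fdr = sum(sp$log2FoldChange < 0 & sp$padj < config$fdr,
                            na.rm = TRUE))
  }
  stats_report$screen_0h <- count_classes(scores_0h)
  stats_report$screen_48h <- count_classes(scores_48h)

  # --- refinement, acceptance, regions -----------------------------------
  refined <- stage("refine", refine_functional_stability(scores_0h, scores_48h))
  paths$refined <- wpath("refined_scores.tsv")
  write_scores(refined, paths$refined)
  stats_report$refined <- list(
    total = sum(refined$refined),
    stabilized = sum(refined$refined & refined$functional_stability_score > 0),
    destabilized = sum(refined$refined & refined$functional_stability_score <= 0))

  acc <- stage("acceptance", positional_acceptance(
    refined, aggregate = config$acceptance_aggregate))
  lw <- stage("lowess", lowess_smooth(acc$position, acc$mutational_acceptance,
                                      window_points = config$lowess_window))
  regions <- stage("regions", call_regions(
    lw$position, lw$lowess_value, upper_quantile = config$region_quantile,
    upper_type = config$region_upper_type))
  paths$regions_bed <- wpath("regions.bed")
  write_regions_bed(regions$intervals, paths$regions_bed)
  stats_report$regions <- list(
    upper_threshold = regions$upper_threshold,
    n_stabilizing = sum(regions$intervals$region_class == "stabilizing"),
    n_destabilizing = sum(regions$intervals$region_class == "destabilizing"))

  # --- predictor stratification ------------------------------------------
  strat <- NULL
  if (!is.null(predictors)) {
    strat <- list()
    if ("vep_score" %in% names(predictors)) {
      s0p <- scores_0h[scores_0h$passed_filter, ]
      v_inh <- stage("predictors", stratify_by_dms(s0p, predictors,
                                                   "vep_score"))
      mm_inh <- stage("predictors", suppressWarnings(mixed_model_test(
        v_inh$data$value, v_inh$data$stratum, v_inh$data$position)))
      v_st <- stage("predictors", stratify_by_dms(
        refined[refined$refined, ], predictors, "vep_score",
        dms_field = "functional_stability_score"))
      mm_st <- stage("predictors", suppressWarnings(mixed_model_test(
        v_st$data$value, v_st$data$stratum, v_st$data$position)))
      strat$vep <- data.frame(
        stratified_by = c("inhibition", "stability"),
        mean_maintained = c(v_inh$summary$mean[1], v_st$summary$mean[1]),
        mean_reduced = c(v_inh$summary$mean[2], v_st$summary$mean[2]),
        estimate = c(mm_inh$estimate, mm_st$estimate),
        p = c(mm_inh$p, mm_st$p), stringsAsFactors = FALSE)
      paths$vep_strata <- wpath("vep_stratification.csv")
      utils::write.csv(strat$vep, paths$vep_strata, row.names = FALSE)
    }
    if (all(c("ddg_active", "ddg_latent") %in% names(predictors))) {
      ddg_inh <- stage("predictors", compare_conformations(
        scores_0h[scores_0h$passed_filter, ], predictors, "inhibition"))
      ddg_st <- stage("predictors", compare_conformations(
        refined, predictors, "stability"))
      strat$ddg <- rbind(ddg_inh, ddg_st)
      paths$ddg_strata <- wpath("ddg_stratification.csv")
      utils::write.csv(strat$ddg, paths$ddg_strata, row.names = FALSE)
      stats_report$ddg <- lapply(seq_len(nrow(strat$ddg)), function(i)
        as.list(strat$ddg[i, c("conformation", "stratified_by",
                               "estimate", "p")]))
    }
  }

  # --- purifying-selection analysis --------------------------------------
  selection <- NULL
  if (!is.null(conservation)) {
    npc0 <- stage("evolve", normalized_position_counts(
      scores_0h[scores_0h$passed_filter, ]))
    npc48 <- stage("evolve", normalized_position_counts(
      refined, score_field = "functional_stability_score"))
    reg0 <- stage("evolve", conservation_regression(npc0, conservation))
    reg48 <- stage("evolve", conservation_regression(npc48, conservation))
    quad <- stage("evolve", quadrant_analysis(npc0, npc48, conservation))
    qd <- quad$data
    tw <- stage("evolve", two_way_anova(
      qd$npc_0h > quad$medians["npc_0h"],
      qd$npc_48h > quad$medians["npc_48h"], qd$conservation))
    selection <- list(npc0 = npc0, npc48 = npc48, regression_0h = reg0,
                      regression_48h = reg48, quadrants = quad,
                      two_way = tw)
    paths$quadrants <- wpath("position_quadrants.csv")
    utils::write.csv(qd, paths$quadrants, row.names = FALSE)
    stats_report$conservation <- list(
      regression_0h = reg0, regression_48h = reg48,
      quadrant_means = as.list(quad$group_means),
      quadrant_anova = quad$anova,
      tukey = quad$tukey,
      two_way = lapply(tw[c("inhibition", "stability", "interaction")],
                       function(t) t[c("F", "df", "p")]))
  }

  # --- per-position profile ----------------------------------------------
  profile <- merge(acc, lw, by = "position", all = TRUE)
  profile <- merge(profile, regions$classes[c("position", "region_class")],
                   by = "position", all.x = TRUE)
  if (!is.null(selection)) {
    profile <- merge(profile, stats::setNames(
      selection$npc0[c("position", "npc")], c("position", "npc_0h")),
      by = "position", all.x = TRUE)
    profile <- merge(profile, stats::setNames(
      selection$npc48[c("position", "npc")], c("position", "npc_48h")),
      by = "position", all.x = TRUE)
    profile <- merge(profile, conservation, by = "position", all.x = TRUE)
    profile <- merge(profile,
                     selection$quadrants$data[c("position", "quadrant")],
                     by = "position", all.x = TRUE)
  }
  paths$profile <- wpath("position_profile.csv")
  utils::write.csv(profile, paths$profile, row.names = FALSE)

  # --- heatmap matrices ---------------------------------------------------
  hm <- export_heatmap_matrix(scores_0h[scores_0h$passed_filter, ])
  paths$heatmap_0h <- wpath("heatmap_0h.csv")
  utils::write.csv(hm, paths$heatmap_0h)

  # --- report and log -----------------------------------------------------
  paths$stats <- wpath("stats.json")
  jsonlite::write_json(stats_report, paths$stats, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$log <- wpath("run_log.txt")
  log_lines <- c(
    paste0("serpinscreen ", as.character(utils::packageVersion("serpinscreen"))),
    paste0("seed: ", config$seed),
    "resolved config:",
    utils::capture.output(utils::str(unclass(config), give.attr = FALSE)))
  writeLines(log_lines, paths$log)

  invisible(list(screen = screen, counts = counts, samples = samples,
                 scores_0h = scores_0h, scores_48h = scores_48h, pca = pca,
                 refined = refined, acceptance = acc, lowess = lw,
                 regions = regions, stratification = strat,
                 selection = selection, profile = profile,
                 stats = stats_report, paths = paths))
}
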
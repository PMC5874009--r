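#' Default analysis configuration
#'
#' Gathers every threshold, seed and range used by the pipeline in one
#' object, which is logged into each output so runs are reproducible from
#' their artifacts alone.
#'
#' @param local_range inclusive bioavailable 87Sr/86Sr interval; the
#'   default \[0.7086, 0.7090\] is the union span of a local human-bone
#'   baseline (0.7087 +/- 0.0001) and a published faunal baseline
#'   (0.7089 +/- 0.0001).
#' @param mobility_delta ratio difference flagged as analytically
#'   meaningful in mobility typing (default 1e-4, the baseline's 2-sigma).
#' @param r_threshold trait-correlation screening threshold (default 0.5).
#' @param min_trait_n minimum observations for a trait to enter the
#'   biodistance analysis (default 5).
#' @param mmd_variant angular transform, see [ft_theta()].
#' @param vif_threshold stepwise VIF threshold (default 5).
#' @param n_permutations AMOVA permutations (default 9999).
#' @param rf_trees Random-Forest tree count (default 500).
#' @param gini_cutoff importance above which a variable counts as
#'   sex-linked and is removed before origin classification (default 0.1).
#' @param seed master seed for all stochastic stages.
#' @return a list of class `analysis_config`.
#' @export
default_config <- function(local_range = c(0.7086, 0.7090),
                           mobility_delta = 1e-4,
                           r_threshold = 0.5,
                           min_trait_n = 5,
                           mmd_variant = "freeman-tukey",
                           vif_threshold = 5,
                           n_permutations = 9999,
                           rf_trees = 500,
                           gini_cutoff = 0.1,
                           seed = 1) {
  stopifnot(local_range[1] < local_range[2], mobility_delta > 0,
            r_threshold > 0, vif_threshold > 0, n_permutations > 0)
  structure(list(
    local_range = local_range, mobility_delta = mobility_delta,
    r_threshold = r_threshold, min_trait_n = min_trait_n,
    mmd_variant = mmd_variant, vif_threshold = vif_threshold,
    n_permutations = n_permutations, rf_trees = rf_trees,
    gini_cutoff = gini_cutoff, seed = seed
  ), class = "analysis_config")
}

#' Run the full necropolis analysis pipeline
#'
#' Chains the three analysis stages over whatever inputs are provided and
#' writes per-stage results under `out_dir`: provenance and mobility JSON
#' from an isotope table; an MMD/SD TSV, significance TSV, MDS coordinate
#' CSV and Newick dendrogram from a trait-frequency table; and distance
#' TSV, Newick tree, chi-square/AMOVA JSON, correspondence-analysis
#' coordinates, Random-Forest importance and VIF report from an artifact
#' matrix.  Stages whose input is missing are skipped with a warning.  A
#' `run_log.json` records the configuration and seeds, so re-running with
#' the same inputs and config reproduces identical outputs.
#'
#' @param config an [default_config()] object.
#' @param isotope_path,frequency_path,artifact_path input CSVs (each
#'   optional, but at least one must be given).
#' @param out_dir output directory, created if needed.
#' @return named list of the per-stage result objects, invisibly.
#' @export
run_pipeline <- function(config = default_config(), isotope_path = NULL,
                         frequency_path = NULL, artifact_path = NULL,
                         out_dir = ".") {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(isotope_path) && is.null(frequency_path) && is.null(artifact_path)) {
    stop("at least one input table is required")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if (!is.null(isotope_path)) {
    iso <- read_isotope_table(isotope_path)
    range <- local_range(config$local_range[1], config$local_range[2])
    bone <- iso$ratio[iso$material == "bone"]
    enamel <- iso$ratio[iso$material == "enamel"]
    baseline <- list(
      bone = if (length(bone) >= 2) summarize_ratios(bone),
      enamel = if (length(enamel) >= 2) summarize_ratios(enamel),
      local_range = unclass(range)[c("lower", "upper")]
    )
    prov <- classify_provenance(iso, range)
    mob <- tryCatch(
      suppressWarnings(infer_mobility(iso, range, config$mobility_delta)),
      error = function(e) NULL
    )
    jsonlite::write_json(
      list(baseline = baseline, provenance = prov, mobility = mob),
      file.path(out_dir, "isotopes.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    results$isotopes <- list(baseline = baseline, provenance = prov, mobility = mob)
  } else {
    warning("no isotope table: provenance stage skipped")
  }

  if (!is.null(frequency_path)) {
    freq <- read_trait_frequencies(frequency_path)
    mm <- mmd_matrix(freq, variant = config$mmd_variant)
    tri <- mm$mmd
    tri[upper.tri(tri)] <- mm$sd[upper.tri(mm$sd)]
    utils::write.table(round(tri, 4), file.path(out_dir, "mmd_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(mm$significant, file.path(out_dir, "mmd_significant.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    mds <- classical_mds(mm$mmd)
    utils::write.csv(data.frame(group = rownames(mds$points), mds$points),
                     file.path(out_dir, "mds_coordinates.csv"), row.names = FALSE)
    write_dendrogram(ward_dendrogram(mm$mmd),
                     file.path(out_dir, "mmd_ward.nwk"))
    results$biodistance <- list(mmd = mm, mds = mds)
  } else {
    warning("no trait-frequency table: biodistance stage skipped")
  }

  if (!is.null(artifact_path)) {
    am <- read_artifact_matrix(artifact_path)
    d <- jaccard_matrix(am)
    utils::write.table(round(d, 6), file.path(out_dir, "jaccard.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    write_dendrogram(complete_linkage(d),
                     file.path(out_dir, "artifact_complete.nwk"))
    stats_out <- list()
    for (var in c("sex", "age_class", "origin")) {
      grp <- resolve_grouping(am, var)
      if (length(unique(grp[!is.na(grp)])) < 2) next
      chs <- tryCatch(suppressWarnings(goods_by_group_chisq(am, grp)),
                      error = function(e) NULL)
      av <- amova(d, grp, n_permutations = config$n_permutations,
                  seed = config$seed)
      stats_out[[var]] <- list(
        chisq = if (!is.null(chs)) chs[c("statistic", "df", "p_value")],
        amova = unclass(av)
      )
    }
    jsonlite::write_json(stats_out, file.path(out_dir, "mortuary_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    ca <- correspondence_analysis(t(rowsum(am$presence + 0,
                                           ifelse(is.na(am$meta$sex), "unknown",
                                                  am$meta$sex))))
    utils::write.csv(data.frame(good = rownames(ca$row_coords), ca$row_coords),
                     file.path(out_dir, "ca_goods.csv"), row.names = FALSE)
    sex_known <- !am$meta$sex %in% c("unknown") &
      !am$meta$age_class %in% c("infant", "child", "unknown")
    rf <- NULL
    if (sum(sex_known) >= 4) {
      rf <- random_forest_importance(
        am$presence[sex_known, , drop = FALSE],
        ifelse(am$meta$sex[sex_known] == "male", "male", "female"),
        n_trees = config$rf_trees, seed = config$seed
      )
      utils::write.csv(
        data.frame(good = names(rf$importance), gini = rf$importance),
        file.path(out_dir, "rf_sex_importance.csv"), row.names = FALSE
      )
      jsonlite::write_json(
        list(oob_error = rf$oob_error,
             confusion = as.data.frame(rf$confusion)),
        file.path(out_dir, "rf_sex_confusion.json"),
        auto_unbox = TRUE, digits = NA
      )
      # drop sex-linked goods, then collinearity, before any origin model
      keep_goods <- names(rf$importance)[rf$importance <= config$gini_cutoff]
      vf <- vif_stepwise(am$presence[sex_known, keep_goods, drop = FALSE],
                         threshold = config$vif_threshold)
      utils::write.csv(
        data.frame(variable = names(vf$vif), vif = vf$vif),
        file.path(out_dir, "vif_retained.csv"), row.names = FALSE
      )
      results$vif <- vf
    }
    results$mortuary <- list(jaccard = d, stats = stats_out, ca = ca, rf = rf)
  } else {
    warning("no artifact matrix: mortuary stage skipped")
  }

  jsonlite::write_json(
    list(config = unclass(config), inputs = list(
      isotopes = isotope_path, frequencies = frequency_path,
      artifacts = artifact_path
    ), timestamp = NA),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(results)
}
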
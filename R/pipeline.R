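# End-to-end pipeline: features -> per-ROI LOSO SVM vs controls ->
# CCR -> CCR-Rank Matrix -> Array of Importance -> key regions ->
# Scatter Index -> group discrimination, with optional artifact export.

#' Run configuration
#'
#' Validated bundle of every pipeline knob; round-trips losslessly
#' through JSON via [write_run_config()] / [read_run_config()].
#'
#' @param scheme Parcellation scheme name (`"hofer"` or `"witelson"`).
#' @param feature ROI feature: `"energy"`, `"entropy"` or `"both"`.
#' @param hc_label Control class label (default `"HC"`).
#' @param roi_size_hc,roi_size_patient,stride ROI tiling parameters.
#' @param anterior_side `"left"` or `"right"`.
#' @param lbp_neighbors,lbp_radius,lbp_mapping LBP parameters.
#' @param energy_convention See [lbp_energy()].
#' @param kernel_degree,cost SVM parameters.
#' @param fsd_mode `"sample"` or `"population"` (see [fsd()]).
#' @param printed_rounding See [scatter_index()].
#' @param ttest_variant See [group_ttest()].
#' @param seed Integer seed.
#' @return An object of class `"run_config"` (a named list).
#' @export
run_config <- function(scheme = "hofer", feature = "energy",
                       hc_label = "HC",
                       roi_size_hc = 5L, roi_size_patient = 4L,
                       stride = 1L, anterior_side = "left",
                       lbp_neighbors = 8L, lbp_radius = 1,
                       lbp_mapping = "u2_uniform",
                       energy_convention = "label_moment",
                       kernel_degree = 3L, cost = 1,
                       fsd_mode = "sample", printed_rounding = FALSE,
                       ttest_variant = "two_sample_pooled",
                       seed = 1L) {
  cfg <- list(scheme = match.arg(scheme, c("hofer", "witelson")),
              feature = match.arg(feature,
                                  c("energy", "entropy", "both")),
              hc_label = hc_label,
              roi_size_hc = as.integer(roi_size_hc),
              roi_size_patient = as.integer(roi_size_patient),
              stride = as.integer(stride),
              anterior_side = match.arg(anterior_side,
                                        c("left", "right")),
              lbp_neighbors = as.integer(lbp_neighbors),
              lbp_radius = as.numeric(lbp_radius),
              lbp_mapping = match.arg(lbp_mapping,
                                      c("u2_uniform", "raw")),
              energy_convention = match.arg(energy_convention,
                                            c("label_moment", "classic")),
              kernel_degree = as.integer(kernel_degree),
              cost = as.numeric(cost),
              fsd_mode = match.arg(fsd_mode, c("sample", "population")),
              printed_rounding = isTRUE(printed_rounding),
              ttest_variant = match.arg(
                ttest_variant,
                c("two_sample_pooled", "paired", "welch")),
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full localization pipeline on a cohort
#'
#' For every disease class (any class other than `hc_label`): LOSO
#' per-ROI SVM versus controls, CCR matrix, CCR-Rank Matrix, Array of
#' Importance, key-region frequencies and Scatter Index. If more than
#' one disease class is present, each pair is additionally discriminated
#' from the per-subject top-CCR values (metric panel + t-test). With
#' `out_dir` set, all products are written (CSV/JSON) together with a
#' provenance record sufficient to reproduce the run.
#'
#' @param cohort List of [subject_image()] (e.g. from
#'   [generate_cohort()]`$subjects` or [read_manifest()]).
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @return List with `features`, and per disease class `predictions`,
#'   `ccr`, `rank`, `ai`, `key`, `scatter`; plus `pairwise` (metrics and
#'   t-tests) when applicable.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  lbp_cfg <- lbp_config(num_neighbors = config$lbp_neighbors,
                        radius = config$lbp_radius,
                        mapping = config$lbp_mapping)
  roi_sizes <- stats::setNames(config$roi_size_hc, config$hc_label)
  feats <- build_feature_table(
    cohort, scheme = config$scheme, lbp_cfg = lbp_cfg,
    roi_sizes = roi_sizes, roi_size_default = config$roi_size_patient,
    stride = config$stride, anterior_side = config$anterior_side,
    energy_convention = config$energy_convention)
  classes <- unique(feats$class_label)
  disease <- setdiff(classes, config$hc_label)
  if (length(disease) == 0L)
    stop("cohort contains no disease class (all '", config$hc_label, "')")
  if (!config$hc_label %in% classes)
    stop("control class '", config$hc_label, "' absent from cohort")

  per_class <- list()
  for (cl in disease) {
    preds <- loso_classify(feats, cl, config$hc_label,
                           feature = config$feature,
                           kernel_degree = config$kernel_degree,
                           cost = config$cost, seed = config$seed)
    ccr <- compute_ccr(preds, cl)
    rk <- rank_matrix(ccr)
    ai <- array_of_importance(rk, ccr)
    key <- key_regions(ai)
    sc <- scatter_index(key$frequencies, mode = config$fsd_mode,
                        printed_rounding = config$printed_rounding)
    per_class[[cl]] <- list(predictions = preds, ccr = ccr, rank = rk,
                            ai = ai, key = key, scatter = sc)
  }

  pairwise <- list()
  if (length(disease) >= 2L) {
    for (i in seq_len(length(disease) - 1L)) {
      for (j in (i + 1L):length(disease)) {
        a <- disease[i]; b <- disease[j]
        va <- per_class[[a]]$ai$top_ccr
        vb <- per_class[[b]]$ai$top_ccr
        pw <- list(
          metrics = tryCatch(
            group_classify(va, vb, labels = c(a, b),
                           kernel_degree = config$kernel_degree,
                           cost = config$cost, seed = config$seed),
            error = function(e) conditionMessage(e)),
          ttest = tryCatch(
            group_ttest(va, vb, variant = config$ttest_variant),
            error = function(e) conditionMessage(e)))
        pairwise[[paste(a, "vs", b)]] <- pw
      }
    }
  }

  result <- list(features = feats, per_class = per_class,
                 pairwise = pairwise, config = config)
  if (!is.null(out_dir)) .export_pipeline(result, out_dir)
  result
}

.export_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(result$features,
                      file.path(out_dir, "features.csv"))
  freq <- list()
  for (cl in names(result$per_class)) {
    pc <- result$per_class[[cl]]
    utils::write.csv(
      data.frame(subject_id = pc$ccr$subjects, pc$ccr$ccr),
      file.path(out_dir, paste0("ccr_", cl, ".csv")), row.names = FALSE)
    utils::write.csv(
      data.frame(subject_id = rownames(pc$rank), unclass(pc$rank)),
      file.path(out_dir, paste0("ccr_rank_", cl, ".csv")),
      row.names = FALSE)
    utils::write.csv(pc$ai,
                     file.path(out_dir, paste0("ai_", cl, ".csv")),
                     row.names = FALSE)
    freq[[cl]] <- list(scheme = result$config$scheme,
                       frequencies = pc$key$frequencies,
                       key_regions = pc$key$key_regions,
                       scatter = unclass(pc$scatter))
  }
  jsonlite::write_json(freq, file.path(out_dir, "scatter.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(result$pairwise)) {
    pw <- lapply(result$pairwise, function(p) list(
      metrics = if (is.character(p$metrics)) p$metrics else
        p$metrics[c("sensitivity", "specificity", "precision",
                    "recall", "f_score", "accuracy_percent", "auc")],
      ttest = if (is.character(p$ttest)) p$ttest else
        unclass(p$ttest)))
    jsonlite::write_json(pw, file.path(out_dir, "diagnosis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(result$config, cfg_path)
  prov <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = result$config$seed,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("callotex")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
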
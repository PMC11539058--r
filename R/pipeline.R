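#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end workflow. Two modes exist:
#' full mode consumes per-condition replicate trajectories and builds the
#' descriptor table itself; statistics-only mode consumes a ready-made
#' feature table (or just the condition table) and runs every
#' post-descriptor stage, since real production feature tables may come
#' from external MD pipelines.
#'
#' @param conditions a `condition_table` (see [read_condition_table()];
#'   default the packaged 49-condition fixture).
#' @param replicate_sets optional named list of per-condition replicate
#'   trajectories (full mode).
#' @param feature_table optional precomputed `feature_table`
#'   (statistics-only mode).
#' @param pka_tables optional pKa tables for [net_charge()].
#' @param aprs APR region table.
#' @param descriptor_config a [descriptor_config()].
#' @param response response column of `conditions` (default `"ln_v"`).
#' @param band_edges ln(v) band edges for the risk classifier.
#' @param band_feature descriptor used by the single-feature classifier.
#' @param band_threshold,band_direction classifier threshold and
#'   direction; threshold `NULL` disables the confusion report.
#' @param selection_threshold redundancy threshold for feature selection.
#' @param keep_features keep-list never removed by selection.
#' @param models named list of [model_spec()]s to cross-validate.
#' @param k folds for model comparison; `k_range` for the sensitivity
#'   scan.
#' @param seed master seed recorded in every output.
#' @param shapley_nperm permutations for the attribution stage.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions = table1_fixture(),
                            replicate_sets = NULL, feature_table = NULL,
                            pka_tables = NULL, aprs = default_apr_regions(),
                            descriptor_config = aggkin::descriptor_config(),
                            response = "ln_v", band_edges = c(0, 4),
                            band_feature = "native_contact",
                            band_threshold = NULL,
                            band_direction = "below_flags_high",
                            selection_threshold = 0.8,
                            keep_features = NULL,
                            models = list(ols = model_spec("ols"),
                                          pls = model_spec("pls")),
                            k = 10, k_range = 2:31, seed = 1,
                            shapley_nperm = 100, out_dir = tempfile("aggkin_")) {
  cfg <- as.list(environment())
  stopifnot(response %in% names(conditions))
  structure(cfg, class = "pipeline_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  basename(path)
}

#' Run the end-to-end workflow
#'
#' Stages: descriptor extraction (full mode only), Pearson and Spearman
#' correlation matrices, redundancy-based feature selection, the
#' single-feature risk banding report, fold-number sensitivity, k-fold
#' cross-validation of every candidate model, stability-aware model
#' selection, a final fit of the selected model on all data with parity
#' metrics, Shapley feature ranking, and (full mode) the residue-level
#' RMSF regression map written as a B-factor PDB. All numeric outputs are
#' CSV/JSON files under `config$out_dir`; a manifest records artifacts,
#' seed and a config hash. Outputs are reproducible byte-for-byte from
#' config + seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  warnings_log <- character(0)
  note <- function(f) artifacts <<- c(artifacts, f)
  out <- function(f) file.path(config$out_dir, f)
  res <- list()
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  cond <- config$conditions
  y <- cond[[config$response]]

  # --- feature table ---------------------------------------------------
  ft <- config$feature_table
  if (is.null(ft) && !is.null(config$replicate_sets)) {
    ft <- wh(build_feature_table(config$replicate_sets, cond,
                                 pka_tables = config$pka_tables,
                                 aprs = config$aprs,
                                 config = config$descriptor_config))
  }
  stats_only <- is.null(ft)
  if (!is.null(ft)) {
    utils::write.csv(ft, out("feature_table.csv"), row.names = FALSE)
    note("feature_table.csv")
    res$feature_table <- ft
  }

  # --- correlation analysis -------------------------------------------
  num_cond <- cond[, intersect(c("temperature", "ionic_strength", "pH",
                                 "tm", "ln_v"), names(cond))]
  corr_input <- if (stats_only) num_cond else {
    ids <- match(ft$condition_id, cond$number)
    cbind(ft[, setdiff(names(ft), "condition_id")], num_cond[ids, ])
  }
  for (m in c("pearson", "spearman")) {
    cm <- wh(correlation_matrix(corr_input, method = m))
    utils::write.csv(round(cm$r, 10), out(paste0("correlation_", m, ".csv")))
    note(paste0("correlation_", m, ".csv"))
    res[[paste0("correlation_", m)]] <- cm
  }

  # --- banding ---------------------------------------------------------
  band <- if (!stats_only && !is.null(config$band_threshold)) {
    ids <- match(ft$condition_id, cond$number)
    banded_classifier(ft[[config$band_feature]], y[ids],
                      config$band_threshold, config$band_direction,
                      config$band_edges)
  } else {
    b <- ifelse(y > config$band_edges[2], "high",
                ifelse(y < config$band_edges[1], "low", "medium"))
    list(counts = c(low = sum(b == "low"), medium = sum(b == "medium"),
                    high = sum(b == "high")),
         band_edges = config$band_edges, n = length(y))
  }
  note(write_json_out(band[c("counts", "band_edges", "n",
                             intersect(c("confusion", "precision"),
                                       names(band)))],
                      out("banding_report.json")))
  res$banding <- band

  if (stats_only) {
    manifest <- list(mode = "statistics-only", seed = config$seed,
                     artifacts = c(artifacts, "manifest.json"),
                     warnings = warnings_log,
                     config_hash = config_hash(config))
    note(write_json_out(manifest, out("manifest.json")))
    res$manifest <- manifest
    return(invisible(res))
  }

  # --- feature selection ----------------------------------------------
  ids <- match(ft$condition_id, cond$number)
  yft <- y[ids]
  Xall <- ft[, setdiff(names(ft), "condition_id")]
  keep_cols <- vapply(Xall, function(c) stats::sd(c, na.rm = TRUE) > 0 &&
                        !anyNA(c), logical(1))
  Xall <- Xall[, keep_cols, drop = FALSE]
  cm <- wh(correlation_matrix(Xall))
  tc <- vapply(Xall, function(col) stats::cor(col, yft), numeric(1))
  sel <- select_nonredundant(cm, tc, config$selection_threshold,
                             keep = config$keep_features)
  note(write_json_out(sel[c("retained", "removed")],
                      out("retained_features.json")))
  res$selection <- sel
  X <- Xall[, sel$retained, drop = FALSE]

  # --- k sensitivity (first candidate model) --------------------------
  ks <- k_sensitivity(config$models[[1]], X, yft,
                      k_range = config$k_range, seed = config$seed)
  utils::write.csv(ks$table, out("k_sensitivity.csv"), row.names = FALSE)
  note("k_sensitivity.csv")
  res$k_sensitivity <- ks

  # --- model comparison + selection -----------------------------------
  cvs <- lapply(config$models, function(sp)
    cross_validate(sp, X, yft, k = config$k, seed = config$seed))
  note(write_json_out(lapply(cvs, function(r)
    r[c("k", "fold_mse", "mean_mse", "max_mse", "std_mse",
        "evaluation_r2")]), out("cv_reports.json")))
  msel <- select_model(cvs)
  note(write_json_out(list(selected = msel$selected,
                           excluded = msel$excluded,
                           ranking = msel$ranking),
                      out("model_selection.json")))
  res$cv_reports <- cvs; res$model_selection <- msel

  # --- final fit + parity ---------------------------------------------
  final_spec <- config$models[[msel$selected]]
  final <- fit_spec(final_spec, as.matrix(X), yft, seed = config$seed)
  parity <- regression_metrics(yft, predict_spec(final_spec, final,
                                                 as.matrix(X)))
  note(write_json_out(list(kind = final$kind,
                           coefficients = as.list(final$coefficients),
                           intercept = final$intercept,
                           n_components = final$n_components,
                           standardization = lapply(final$standardization,
                                                    as.list),
                           n = final$n, seed = config$seed),
                      out("final_model.json")))
  note(write_json_out(parity, out("parity_metrics.json")))
  res$final_model <- final; res$parity <- parity

  # --- Shapley ranking -------------------------------------------------
  mf <- function(M) predict_spec(final_spec, final, M)
  phi <- if (ncol(X) <= 10)
    explain_model(mf, X, X, method = "exact")
  else explain_model(mf, X, X, method = "permutation",
                     n_permutations = config$shapley_nperm,
                     seed = config$seed)
  imp <- global_importance(phi)
  utils::write.csv(imp, out("shapley_ranking.csv"), row.names = FALSE)
  note("shapley_ranking.csv")
  res$importance <- imp

  # --- residue-level RMSF map ------------------------------------------
  reps <- config$replicate_sets
  if (!is.null(reps)) {
    rmsf_rows <- lapply(reps, function(rr) {
      if (inherits(rr, "trajectory")) rr <- list(rr)
      per <- lapply(rr, rmsf_per_residue,
                    config = config$descriptor_config)
      Reduce(`+`, per) / length(per)
    })
    rmsf_mat <- do.call(rbind, rmsf_rows)
    r2 <- residue_level_r2(rmsf_mat, yft)
    first <- reps[[1]]; if (!inherits(first, "trajectory")) first <- first[[1]]
    wh(write_bfactor_map(first, r2, out("residue_r2.pdb")))
    note("residue_r2.pdb")
    res$residue_r2 <- r2
  }

  manifest <- list(mode = "full", seed = config$seed,
                   artifacts = c(artifacts, "manifest.json"),
                   warnings = warnings_log,
                   config_hash = config_hash(config))
  note(write_json_out(manifest, out("manifest.json")))
  res$manifest <- manifest
  invisible(res)
}

# md5 of the serialized config (trajectories excluded: their generating
# specs, not their bytes, identify a run)
config_hash <- function(config) {
  slim <- config[setdiff(names(config), c("replicate_sets", "models"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(slim, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
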
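#' @title End-to-end pipeline
#' @description One reproducible entry point chaining simulate -> extract ->
#'   features -> aggregate -> select -> train -> report. Every stage output is
#'   written under the run directory and stamped with the MD5 hash of the
#'   serialized configuration; reruns with an identical configuration are
#'   byte-identical.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param cohort a `cohort_spec`.
#' @param engine an `engine_config`.
#' @param aggregator_map aggregator assignment over the manifest.
#' @param corr_threshold correlation-filter threshold.
#' @param k number of features kept by RFE.
#' @param families classifier families to cross-validate (default "mlp"; the
#'   tree ensembles at reference sizes dominate runtime and are opt-in).
#' @param n_splits CV folds.
#' @param tau class-weight tuning parameter.
#' @param seed master seed; cohort, selection and CV seeds derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            engine = engine_config(),
                            aggregator_map = default_aggregator_map(),
                            corr_threshold = 0.90,
                            k = 20L,
                            families = "mlp",
                            n_splits = 5L,
                            tau = 0.5,
                            seed = 1L) {
  structure(list(cohort = cohort, engine = engine,
                 aggregator_map = aggregator_map,
                 corr_threshold = corr_threshold, k = as.integer(k),
                 families = families, n_splits = as.integer(n_splits),
                 tau = tau, seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_json <- function(config) {
  ser <- list(
    grid_shape = config$cohort$phantom$grid_shape,
    spacing = config$cohort$phantom$spacing,
    geometry = config$cohort$phantom$geometry,
    background = c(config$cohort$phantom$background_mean,
                   config$cohort$phantom$background_sd),
    per_class = config$cohort$phantom$per_class_params,
    n_per_class = config$cohort$n_per_class,
    cohort_seed = config$cohort$seed,
    engine = unclass(config$engine),
    aggregator_map = as.list(config$aggregator_map),
    corr_threshold = config$corr_threshold,
    k = config$k, families = config$families, n_splits = config$n_splits,
    tau = config$tau, seed = config$seed)
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA)
}

#' Run the full pipeline
#'
#' @param config a `pipeline_config`.
#' @param out_dir run directory (created).
#' @param verbose print per-stage timing.
#' @return list with `feature_table`, `selection`, `cv` (a `cv_report`),
#'   `config_hash` and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("voxrad_run_"),
                         verbose = TRUE) {
  cfg_json <- .config_json(config)
  hash <- substr(.md5_string(cfg_json), 1, 12)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(cfg_json, file.path(out_dir, "config.json"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (verbose)
      message(sprintf("[voxrad %s] stage %-10s %6.1fs", hash, name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    r
  }
  cohort <- stage("simulate", {
    cs <- config$cohort
    cs$seed <- as.integer((config$seed * 101L + cs$seed) %% 200000L)
    generate_cohort(cs, file.path(out_dir, "cohort"))
  })
  tab <- stage("features", {
    build_feature_table(cohort, config$engine, config$aggregator_map,
                        out_csv = file.path(out_dir, "feature_table.csv"))
  })
  sel <- stage("select", {
    cf <- correlation_filter(tab, config$corr_threshold)
    rfe <- recursive_feature_elimination(cf$table, config$k)
    res <- list(filter = cf, rfe = rfe)
    jsonlite::write_json(
      list(config_hash = hash, kept = rfe$kept,
           dropped_by_correlation = cf$dropped,
           ranking = as.list(rfe$ranking)),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    res
  })
  cv <- stage("evaluate", {
    specs <- stats::setNames(
      lapply(config$families, function(f) model_spec(f, seed = config$seed)),
      config$families)
    rep <- cross_validate(sel$filter$table, sel$rfe$kept, specs,
                          n_splits = config$n_splits,
                          seed = config$seed + 7L, tau = config$tau)
    .write_cv_report(rep, out_dir, hash)
    rep
  })
  list(feature_table = tab, selection = sel, cv = cv, config_hash = hash,
       out_dir = out_dir)
}

.md5_string <- function(s) {
  tf <- tempfile()
  writeLines(s, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

.write_cv_report <- function(rep, out_dir, hash) {
  summary <- lapply(names(rep$models), function(nm) {
    m <- rep$models[[nm]]
    list(family = m$family,
         mean_accuracy = m$mean_accuracy,
         splits = lapply(m$splits, function(s) {
           list(split = s$split, accuracy = s$metrics$accuracy,
                precision_macro = s$metrics$precision_macro,
                recall_macro = s$metrics$recall_macro,
                f1_macro = s$metrics$f1_macro,
                precision_weighted = s$metrics$precision_weighted,
                recall_weighted = s$metrics$recall_weighted,
                f1_weighted = s$metrics$f1_weighted,
                confidence = as.list(s$confidence),
                hypothesis = as.list(s$hypothesis))
         }))
  })
  names(summary) <- names(rep$models)
  jsonlite::write_json(list(config_hash = hash, report = summary),
                       file.path(out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(rep$models)) {
    for (s in rep$models[[nm]]$splits) {
      utils::write.csv(
        as.data.frame(s$confusion),
        file.path(out_dir, sprintf("confusion_%s_split%d.csv", nm, s$split)),
        row.names = FALSE)
      qq <- do.call(rbind, lapply(names(s$qq), function(cl) {
        if (is.null(s$qq[[cl]])) return(NULL)
        cbind(class = cl, s$qq[[cl]])
      }))
      if (!is.null(qq))
        utils::write.csv(qq, file.path(out_dir,
                                       sprintf("qq_%s_split%d.csv", nm, s$split)),
                         row.names = FALSE)
    }
  }
}
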
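#' Default pipeline configuration
#'
#' A nested list mirroring the analysis stages: synthetic-study
#' generation, preprocessing (QC drift correction, imputation,
#' normalisation, transform/scaling), multilevel model (discriminant and
#' subtracted factors), sPLS-DA settings (components, keepX grid, folds,
#' repeats), selection thresholds, and the annotation candidate list.
#' The seed is mandatory and drives every stochastic stage.
#'
#' @param seed integer seed.
#' @return config list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(enabled = TRUE),  # spec fields override synthetic_spec()
    input = list(feature_table = NULL, design = NULL),
    preprocess = list(qc_span = 0.75, ppca_components = 3,
                      transform = "log10", scaling = "unit_variance"),
    multilevel = list(discriminant = "phase", subtract = "subject"),
    splsda = list(n_components = 2, keepx_grid = c(50, 60, 70),
                  n_folds = 7, n_repeats = 5, criterion = "error"),
    selection = list(k_per_component = 10, radius_start = 0.9,
                     radius_step = 0.1, radius_floor = 0.5,
                     vip_threshold = 1.5, fdr_alpha = 0.05),
    annotation = list(candidates = system.file("extdata",
                      "candidate_metabolites.csv", package = "crossmet"),
                      tol_ppm = 5))
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [default_config()]; `seed` must be present
#' in the file or supplied.
#'
#' @param path YAML file.
#' @return config list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) stop("config must set a seed")
  base <- default_config(user$seed)
  modifyList(base, user)
}

.log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg)
  writeLines(line, con)
  message(line)
}

#' Run the full crossover metabolomics analysis
#'
#' Executes synthetic-or-loaded data -> preprocessing -> multilevel
#' decomposition -> sPLS-DA tuning and fitting -> candidate selection
#' (both strategies) with FDR-corrected validation and fold changes ->
#' annotation. Every intermediate is written as CSV, models and reports
#' as JSON, with a structured plain-text log. Rerunning with the same
#' config reproduces all outputs bit-identically.
#'
#' @param config list from [default_config()] / [load_config()].
#' @param out_dir run directory (created).
#' @return `out_dir`, invisibly; side effect: stage outputs on disk.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "pipeline.log"), open = "wt")
  on.exit(close(log_con))
  set.seed(config$seed)
  .log_line(log_con, "init", sprintf("seed=%d crossmet=%s R=%s",
            config$seed, as.character(utils::packageVersion("crossmet")),
            getRversion()))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
    .log_line(log_con, name,
              sprintf("ok wall=%.2fs", as.numeric(Sys.time() - t0, "secs")))
    res
  }

  # --- data -----------------------------------------------------------
  if (isTRUE(config$synthetic$enabled)) {
    dat <- stage("simulate", {
      args <- config$synthetic
      args$enabled <- NULL
      spec <- do.call(synthetic_spec, c(args, list(seed = config$seed)))
      g <- generate_crossover(spec)
      qc <- make_qc_series(g$table, g$design)
      tab <- apply_drift(qc$table, qc$design, spec$drift_slope)
      tab <- inject_missing(tab, spec$missing_rate, "mcar",
                            seed = config$seed + 1L)
      write_feature_table(tab, file.path(out_dir, "01_raw_features.csv"))
      write_design(qc$design, file.path(out_dir, "01_design.csv"))
      jsonlite::write_json(
        list(affected_feature_ids = g$truth$affected_feature_ids),
        file.path(out_dir, "01_ground_truth.json"), auto_unbox = FALSE)
      list(table = tab, design = qc$design, truth = g$truth)
    })
  } else {
    dat <- stage("load", {
      list(table = load_feature_table(config$input$feature_table),
           design = load_design(config$input$design), truth = NULL)
    })
  }
  tab <- dat$table; design <- dat$design

  # --- preprocess ------------------------------------------------------
  proc <- stage("preprocess", {
    corrected <- qc_rlsc(tab, design, span = config$preprocess$qc_span)
    # impute on the log scale: intensities are log-normal, and the
    # exponentiated expectation is guaranteed positive
    logimp <- impute_ppca(log(corrected$intensities),
                          n_components = config$preprocess$ppca_components)
    study <- design$sample_id[!design$is_qc]
    imputed <- feature_table(exp(logimp)[study, , drop = FALSE],
                             corrected$feature_meta)
    ref_ids <- design$sample_id[!design$is_qc &
                                design$phase %in% c("baseline", "placebo")]
    normalized <- normalize_reference(imputed, ref_ids)
    scaled <- transform_scale(normalized,
                              transform = config$preprocess$transform,
                              scaling = config$preprocess$scaling)
    write_feature_table(normalized, file.path(out_dir, "02_normalized.csv"))
    write_feature_table(scaled, file.path(out_dir, "02_scaled.csv"))
    list(normalized = normalized, scaled = scaled)
  })

  # --- multilevel decomposition + tuning + fit ------------------------
  ml <- config$multilevel
  sp <- config$splsda
  labels <- encode_classes(design, ml$discriminant)
  tune <- stage("tune", {
    if (ml$subtract %in% ml$discriminant)
      stop("subtracted factor '", ml$subtract, "' overlaps the discriminant")
    d <- design[match(names(labels), design$sample_id), , drop = FALSE]
    X <- proc$scaled$intensities[names(labels), , drop = FALSE]
    grouping <- d[[ml$subtract]]
    res <- remove_variation(X, grouping)
    tr <- splsda_tune(res$residual, labels,
                      keepx_grid = pmin(sp$keepx_grid, ncol(X)),
                      n_components = sp$n_components, n_folds = sp$n_folds,
                      n_repeats = sp$n_repeats, criterion = sp$criterion,
                      seed = config$seed)
    utils::write.csv(data.frame(keepx = tr$keepx_grid, tr$error,
                                cor = tr$correlation),
                     file.path(out_dir, "03_tuning.csv"), row.names = FALSE)
    tr
  })
  model <- stage("fit", {
    m <- fit_mlsplsda(proc$scaled, design, ml$discriminant, ml$subtract,
                      n_components = sp$n_components,
                      keepx = tune$chosen_keepx)
    write_model_json(m, file.path(out_dir, "04_model.json"))
    utils::write.csv(data.frame(sample_id = rownames(m$x_scores),
                                m$x_scores, label = m$labels),
                     file.path(out_dir, "04_scores.csv"), row.names = FALSE)
    m
  })

  # --- selection + validation -----------------------------------------
  selc <- config$selection
  report <- stage("select", {
    s1 <- select_top_loadings(model, selc$k_per_component)
    Xres <- remove_variation(
      proc$scaled$intensities[names(labels), , drop = FALSE],
      design[[ml$subtract]][match(names(labels), design$sample_id)])$residual
    s2 <- select_by_radius(model, Xres, start = selc$radius_start,
                           step = selc$radius_step, floor = selc$radius_floor)
    sel <- data.frame(feature_id = union(s1$feature_id, s2$feature_id))
    rep <- selection_report(sel, model, proc$normalized, design)
    rep$significant <- !is.na(rep$q_value) & rep$q_value < selc$fdr_alpha
    utils::write.csv(s1, file.path(out_dir, "05_top_loadings.csv"),
                     row.names = FALSE)
    utils::write.csv(s2, file.path(out_dir, "05_radius_selection.csv"),
                     row.names = FALSE)
    utils::write.csv(rep, file.path(out_dir, "05_selection_report.csv"),
                     row.names = FALSE)
    rep
  })

  # --- annotation ------------------------------------------------------
  stage("annotate", {
    cand_path <- config$annotation$candidates
    if (is.null(cand_path) || !nzchar(cand_path) || !file.exists(cand_path)) {
      .log_line(log_con, "annotate", "no candidate list; skipped")
      return(NULL)
    }
    cand <- load_candidates(cand_path)
    meta <- tab$feature_meta
    ann <- do.call(rbind, lapply(report$feature_id, function(f) {
      i <- match(f, meta$feature_id)
      hits <- annotate_feature(meta$mz[i], meta$polarity[i] %||% "positive",
                               cand, tol_ppm = config$annotation$tol_ppm)
      if (nrow(hits)) cbind(feature_id = f, hits) else NULL
    }))
    if (is.null(ann))
      ann <- data.frame(feature_id = character(0))
    utils::write.csv(ann, file.path(out_dir, "06_annotations.csv"),
                     row.names = FALSE)
    ann
  })

  # --- summary ---------------------------------------------------------
  stage("summary", {
    jsonlite::write_json(list(
      seed = config$seed,
      n_samples = sum(!design$is_qc),
      n_features = length(tab$feature_ids),
      chosen_keepx = tune$chosen_keepx,
      n_selected = nrow(report),
      n_significant = sum(report$significant)),
      file.path(out_dir, "07_summary.json"), auto_unbox = TRUE, digits = NA)
    NULL
  })
  invisible(out_dir)
}
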
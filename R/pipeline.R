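# End-to-end orchestration: generate -> screen -> quantify -> chemometrics
# -> report, seeded and logged.

#' Pipeline configuration
#'
#' All defaults mirror the published workflow parameters: 80/20
#' Kennard-Stone split, Pareto scaling, Q2Y-selected orthogonal components,
#' 20 permutations, VIP > 1 marker rule, 80% per-class prevalence.
#'
#' @param seed Random seed (required; every stochastic stage derives from
#'   it).
#' @param design,panel,noise Generator inputs ([study_design()],
#'   [default_panel()], [noise_config()]).
#' @param target_criteria,suspect_criteria Screening criteria.
#' @param scaling A [scale_matrix()] method, or `"auto"` to pick the
#'   best-ranked method via [rank_scaling_methods()].
#' @param n_ortho Number of orthogonal components, or `"auto"` for the
#'   first-maximum Q2Y rule.
#' @param train_fraction Kennard-Stone training fraction.
#' @param n_permutations Label permutations for the permutation test.
#' @param vip_threshold Strict VIP cutoff for markers.
#' @param iqr_drop Optional IQR filter drop fraction (e.g. 0.25 or 0.5).
#' @param prevalence Minimum per-class detection prevalence.
#' @param blank_area_frac Blank contamination threshold.
#' @param confounded_removal Variables removed before classification;
#'   `NULL` takes the panel's confounded flags (organic acids, tyrosol and
#'   resveratrol derivatives).
#' @param folds Cross-validation folds.
#' @param lod_noise Response-scale noise for LOD/LOQ estimation.
#' @param out_dir Optional directory for delimited-text reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            design = study_design(),
                            panel = default_panel(),
                            noise = noise_config(),
                            target_criteria = oenoscreen::target_criteria(),
                            suspect_criteria = oenoscreen::suspect_criteria(),
                            scaling = "pareto",
                            n_ortho = "auto",
                            train_fraction = 0.8,
                            n_permutations = 20L,
                            vip_threshold = 1.0,
                            iqr_drop = NULL,
                            prevalence = 0.8,
                            blank_area_frac = 0.1,
                            confounded_removal = NULL,
                            folds = 7L,
                            lod_noise = 0.002,
                            out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(train_fraction > 0, train_fraction < 1,
            prevalence > 0, prevalence <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# order-insensitive content stamp for report headers
.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config, give.attr = FALSE)),
             collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2^31)
}

#' Run the full authentication pipeline
#'
#' Sequences the synthetic study (or user-supplied peak tables), target and
#' suspect screening, prevalence/blank filtering, method validation and
#' quantification, feature-matrix assembly, confounded-variable removal,
#' scaling, Kennard-Stone splitting, OPLS-DA with internal (7-fold Q2Y) and
#' external validation, permutation testing, ROC, VIP marker selection and
#' the univariate screen.  Each stage's counts are logged; all randomness
#' derives from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return An `oeno_pipeline` list: generated data, hits, validation report,
#'   feature matrix, fitted model, `metrics` (R2X/R2Y/Q2Y/RMSEE/RMSEP/
#'   accuracies/AUC), permutation table, marker table, univariate screen,
#'   PCA, stage `log`, and the config with its hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  stage <- function(expr, name) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  panel <- config$panel
  is_name <- panel$name[panel$role == "internal_standard"][1]

  gen <- stage(generate_study(config$design, panel, config$noise,
                              seed = config$seed), "generate")
  cal <- stage(generate_calibration_series(panel, config$design, config$noise,
                                           seed = config$seed + 1L),
               "calibration")
  validation <- stage(validate_method(cal, noise = config$lod_noise),
                      "validation")
  log$features_in <- nrow(gen$features)

  db_cols <- c("name", "formula", "adduct", "role", "theoretical_mz", "rt",
               "descriptor", "fragments", "compound_class", "evidence")
  target_db <- panel[panel$role %in% c("target", "internal_standard"), db_cols]
  suspect_db <- panel[panel$role == "suspect", db_cols]
  rt_model <- stage(fit_rt_model(target_db), "rt_model")

  th <- stage(target_screen(gen$features, target_db, config$target_criteria),
              "target_screen")
  sh <- stage(suspect_screen(gen$features, suspect_db,
                             config$suspect_criteria, rt_model),
              "suspect_screen")
  hits <- rbind(th, sh)
  log$target_hits <- nrow(th)
  log$suspect_hits <- nrow(sh)
  log$target_audit <- attr(th, "audit")
  log$suspect_audit <- attr(sh, "audit")

  pf <- stage(prevalence_blank_filter(hits, gen$metadata,
                                      min_prevalence = config$prevalence,
                                      blank_area_frac = config$blank_area_frac),
              "prevalence_filter")
  retained <- setdiff(pf$compound[pf$retained], is_name)
  log$compounds_detected <- nrow(pf)
  log$compounds_retained <- length(retained)

  fm <- stage(build_feature_matrix(hits, gen$metadata, is_name = is_name,
                                   compounds = retained), "feature_matrix")

  # quantification of retained target analytes against solvent curves
  quant_tab <- stage({
    tnames <- intersect(retained, panel$name[panel$role == "target"])
    do.call(rbind, lapply(tnames, function(a) {
      sv <- cal$solvent[cal$solvent$analyte == a, ]
      curve <- fit_calibration(sv$concentration, sv$response, analyte = a)
      lim <- estimate_lod_loq(curve, config$lod_noise)
      q <- quantify(fm$values[, a], curve, lod = lim$lod, loq = lim$loq)
      data.frame(analyte = a, sample_id = rownames(fm$values),
                 concentration = q$concentration, flag = q$flag,
                 stringsAsFactors = FALSE)
    }))
  }, "quantify")

  # PCA on all injections kept in the matrix (QCs included) for QC control
  pca <- stage(run_pca(scale_matrix(fm$values, "pareto"), 2L), "pca")

  removal <- config$confounded_removal
  if (is.null(removal)) removal <- panel$name[panel$confounded]
  is_sample <- fm$metadata$type == "sample"
  x_all <- fm$values[is_sample, , drop = FALSE]
  y <- fm$metadata$class[is_sample]
  x_red <- stage(suppressWarnings(drop_confounded_variables(x_all, removal)),
                 "variable_removal")
  log$variables_before_removal <- ncol(x_all)
  log$variables_after_removal <- ncol(x_red)

  scaling <- config$scaling
  scaling_ranking <- NULL
  if (identical(scaling, "auto")) {
    scaling_ranking <- stage(
      rank_scaling_methods(x_red, y, train_fraction = config$train_fraction,
                           folds = config$folds, seed = config$seed),
      "scaling_ranking")
    scaling <- scaling_ranking$method[1]
  }
  xs <- stage(scale_matrix(x_red, scaling), "scaling")

  if (!is.null(config$iqr_drop)) {
    xs <- stage(iqr_variable_filter(xs, config$iqr_drop), "iqr_filter")
    log$variables_after_iqr <- ncol(xs)
  }

  split <- stage(kennard_stone_split(xs, config$train_fraction), "split")
  log$split <- c(train = length(split$train), test = length(split$test))
  x_tr <- xs[split$train, , drop = FALSE]
  y_tr <- y[split$train]
  x_te <- xs[split$test, , drop = FALSE]
  y_te <- y[split$test]

  n_ortho <- config$n_ortho
  ortho_trace <- NULL
  if (identical(n_ortho, "auto")) {
    sel <- stage(select_n_orthogonal(x_tr, y_tr, max_ortho = 3L,
                                     folds = config$folds, seed = config$seed),
                 "n_ortho_selection")
    n_ortho <- sel$n_ortho
    ortho_trace <- sel$trace
  }
  model <- stage(fit_oplsda(x_tr, y_tr, n_ortho = n_ortho), "oplsda")

  internal <- predict_class_maxdist(model, x_tr, y_true = y_tr)
  external <- predict_class_maxdist(model, x_te, y_true = y_te)
  q2y <- stage(cross_validate_q2(x_tr, y_tr, n_ortho = n_ortho,
                                 folds = config$folds, seed = config$seed),
               "cross_validation")
  all_pred <- predict_class_maxdist(model, xs)
  auc <- stage(roc_auc(all_pred$y_hat, y), "roc")
  perm <- stage(permutation_test_oplsda(x_tr, y_tr, n_ortho = n_ortho,
                                        n_perm = config$n_permutations,
                                        folds = config$folds,
                                        seed = config$seed),
                "permutation_test")
  markers <- stage(select_markers(model, config$vip_threshold), "markers")
  univ <- stage(univariate_screen(x_red, y), "univariate_screen")

  metrics <- data.frame(
    r2x = model$r2x, r2y = model$r2y, q2y = q2y,
    rmsee = model$rmsee, rmsep = external$rmsep,
    accuracy_internal = internal$accuracy,
    accuracy_external = external$accuracy,
    auc = auc, n_ortho = model$n_ortho, scaling = scaling,
    stringsAsFactors = FALSE
  )

  run <- structure(list(
    config = config, config_hash = .config_hash(config),
    generated = gen, calibration = cal, validation = validation,
    hits = hits, prevalence = pf, quantification = quant_tab,
    feature_matrix = fm, pca = pca, removal = removal,
    scaling_ranking = scaling_ranking, scaled = xs, y = y, split = split,
    model = model, metrics = metrics, ortho_trace = ortho_trace,
    permutation = perm, markers = markers, univariate = univ, log = log
  ), class = "oeno_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(run, config$out_dir)
  run
}

#' @export
print.oeno_pipeline <- function(x, ...) {
  m <- x$metrics
  cat("Wine-authentication pipeline run (seed ", x$config$seed,
      ", config ", x$config_hash, ")\n", sep = "")
  cat(sprintf("  %d features -> %d target + %d suspect hits -> %d compounds retained\n",
              x$log$features_in, x$log$target_hits, x$log$suspect_hits,
              x$log$compounds_retained))
  cat(sprintf("  variables: %d -> %d after confounder removal; split %d/%d\n",
              x$log$variables_before_removal, x$log$variables_after_removal,
              x$log$split["train"], x$log$split["test"]))
  cat(sprintf("  OPLS-DA (1+%d comps, %s): R2X %.3f R2Y %.3f Q2Y %.3f\n",
              m$n_ortho, m$scaling, m$r2x, m$r2y, m$q2y))
  cat(sprintf("  RMSEE %.4f RMSEP %.4f; accuracy int %.0f%% / ext %.0f%%; AUC %.2f\n",
              m$rmsee, m$rmsep, 100 * m$accuracy_internal,
              100 * m$accuracy_external, m$auc))
  cat(sprintf("  %d VIP > %g markers\n", nrow(x$markers),
              x$config$vip_threshold))
  invisible(x)
}

#' Write the pipeline's delimited-text reports
#'
#' Emits the hits table, validation report, quantification table, feature
#' matrix, model summary, permutation table, marker table, V-plot and
#' heatmap (range-scaled) coordinate tables, each stamped with the config
#' hash and seed.
#'
#' @param run An `oeno_pipeline` result.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(config = run$config_hash, seed = as.character(run$config$seed))
  out <- function(x, name) write_report(x, file.path(dir, name), header = hdr)
  out(run$hits, "screening_hits.tsv")
  out(run$validation, "method_validation.tsv")
  out(run$prevalence, "prevalence_filter.tsv")
  out(run$quantification, "quantification.tsv")
  out(cbind(sample_id = rownames(run$feature_matrix$values),
            as.data.frame(run$feature_matrix$values, check.names = FALSE)),
      "feature_matrix.tsv")
  out(run$metrics, "model_summary.tsv")
  out(run$permutation$permuted, "permutation_test.tsv")
  out(run$markers, "marker_table.tsv")
  out(attr(run$markers, "vplot"), "vplot_coordinates.tsv")
  hm <- scale_matrix(run$feature_matrix$values, "range")
  hm_long <- data.frame(
    sample_id = rep(rownames(hm), ncol(hm)),
    variable = rep(colnames(hm), each = nrow(hm)),
    value = as.vector(hm), stringsAsFactors = FALSE)
  out(hm_long, "heatmap_coordinates.tsv")
  out(run$univariate, "univariate_screen.tsv")
  invisible(dir)
}
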
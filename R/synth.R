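# Synthetic-study generator: a 46-sample two-variety red-wine design with
# pooled QCs, periodic solvent blanks, an internal standard, calibration
# series and decoy noise features, with a full truth record.

#' Study design parameters
#'
#' Defaults emulate the published design: 27 Agiorgitiko + 19 Xinomavro
#' wines over the 2017/2018 vintages, pooled QC injections, a solvent blank
#' every 10 injections, ethyl vanillin IS at 2 mg/L and a 7-point
#' calibration series spanning 0.1-20 mg/L.
#'
#' @param n_class_a,n_class_b Samples per class (Agiorgitiko, Xinomavro).
#' @param vintages Vintage years, assigned alternately within class.
#' @param n_qc Pooled QC injections.
#' @param blank_every Solvent blank frequency (injections).
#' @param is_concentration Internal-standard concentration (mg/L).
#' @param calibration_levels Calibration concentrations (mg/L), strictly
#'   increasing, at least 5 levels.
#' @return A `study_design` list.
#' @export
study_design <- function(n_class_a = 27L, n_class_b = 19L,
                         vintages = c(2017L, 2018L), n_qc = 5L,
                         blank_every = 10L, is_concentration = 2,
                         calibration_levels = c(0.1, 0.25, 0.5, 1, 5, 10, 20)) {
  stopifnot(n_class_a > 0, n_class_b > 0, n_qc >= 0, blank_every > 0,
            is_concentration > 0)
  if (any(diff(calibration_levels) <= 0)) {
    stop("calibration levels must be strictly increasing")
  }
  structure(list(n_class_a = n_class_a, n_class_b = n_class_b,
                 vintages = vintages, n_qc = n_qc, blank_every = blank_every,
                 is_concentration = is_concentration,
                 calibration_levels = calibration_levels,
                 classes = c("Agiorgitiko", "Xinomavro")),
            class = "study_design")
}

#' Noise configuration for the generator
#'
#' @param mz_sd m/z jitter (Da), default 0.5 mDa (QToF mass accuracy).
#' @param rt_sd Retention-time jitter (min).
#' @param iso_sd Fractional noise on isotope-envelope intensities.
#' @param injection_cv Injection-to-injection multiplicative factor CV,
#'   corrected by IS normalization.
#' @param qc_cv Injection-level CV of pooled QC abundances.
#' @param cal_cv Multiplicative response noise of calibration standards.
#' @param vintage_shift Shared multiplicative vintage effect (+/- fraction).
#' @param effect_size Multiplier on the class-mean contrast (1 = published
#'   scale, 0 = no class difference; used for type-I error checks).
#' @param frag_jitter_sd Fragment m/z jitter (Da).
#' @param n_decoys Pure-noise features per sample.
#' @param decoy_area_meanlog,blank_area_meanlog Log-scale decoy areas in
#'   samples and blanks.
#' @return A `noise_config` list.
#' @export
noise_config <- function(mz_sd = 0.0005, rt_sd = 0.05, iso_sd = 0.03,
                         injection_cv = 0.05, qc_cv = 0.03, cal_cv = 0.02,
                         vintage_shift = 0.15, effect_size = 1,
                         frag_jitter_sd = 0.002, n_decoys = 40L,
                         decoy_area_meanlog = log(5000),
                         blank_area_meanlog = log(500)) {
  as.list(environment())
}

#' Load a compound panel
#'
#' Reads a delimited-text panel (name, formula, adduct, role, expected rt,
#' QSRR descriptor, qualifier fragments, class-conditional concentration
#' means, within-class CV, response factor, ...) and validates it.  The
#' shipped default panel anchors the 22 quantified targets to the published
#' class means and the suspect markers to the published class directions.
#'
#' @param path Path to a tab-separated panel file; default is the panel
#'   shipped with the package.
#' @return Data frame with one row per compound, theoretical m/z verified
#'   against formula + adduct.
#' @export
build_compound_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_panel.tsv",
                        package = "oenoscreen", mustWork = TRUE)
  }
  panel <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  if (!nrow(panel)) stop("empty compound panel: ", path)
  need <- c("name", "formula", "adduct", "role", "theoretical_mz", "rt",
            "descriptor", "fragments", "mean_agi", "mean_xin", "cv",
            "response_factor", "frag_prob")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("malformed panel, missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(is.na(panel$formula) | !nzchar(panel$formula) |
                 is.na(panel$mean_agi) | is.na(panel$mean_xin) |
                 panel$cv <= 0 | panel$response_factor <= 0)
  if (length(bad)) {
    stop("malformed panel row(s): ", paste(bad, collapse = ", "))
  }
  recomputed <- mapply(adduct_mz, panel$formula, panel$adduct)
  off <- abs(panel$theoretical_mz - recomputed) > 2e-4
  if (any(off)) {
    stop("theoretical m/z inconsistent with formula for: ",
         paste(panel$name[off], collapse = ", "))
  }
  panel
}

#' Default shipped compound panel
#' @return See [build_compound_panel()].
#' @export
default_panel <- function() {
  if (is.null(.oeno_env$panel)) .oeno_env$panel <- build_compound_panel()
  .oeno_env$panel
}

# class x vintage geometric-mean concentration for one compound
.class_means <- function(panel, effect_size) {
  mu_a <- panel$mean_agi
  mu_b <- panel$mean_xin
  g <- sqrt(mu_a * mu_b)
  list(a = g * (mu_a / g)^effect_size, b = g * (mu_b / g)^effect_size)
}

.draw_sample_features <- function(panel, conc, sample_id, noise, inj_factor) {
  n <- nrow(panel)
  area <- conc * panel$response_factor * inj_factor
  ps <- stats::runif(n, 6.2, 19.9)
  theo <- t(vapply(panel$formula, function(f) {
    theoretical_isotope_pattern(f, 3L)$intensity[2:3]
  }, numeric(2)))
  iso <- pmax(theo * (1 + matrix(stats::rnorm(2 * n, 0, noise$iso_sd), n, 2)), 0)
  frags <- vapply(seq_len(n), function(i) {
    q <- .parse_fragments(panel$fragments[i])[[1]]
    keep <- stats::runif(length(q)) < panel$frag_prob[i]
    if (!any(keep)) return("")
    paste(sprintf("%.4f", q[keep] + stats::rnorm(sum(keep), 0, noise$frag_jitter_sd)),
          collapse = ";")
  }, character(1))
  data.frame(
    sample_id = sample_id,
    mz = panel$theoretical_mz + stats::rnorm(n, 0, noise$mz_sd),
    rt = panel$rt + stats::rnorm(n, 0, noise$rt_sd),
    area = area, intensity = area / ps,
    iso1 = iso[, 1], iso2 = iso[, 2], fragments = frags,
    compound_truth = panel$name, stringsAsFactors = FALSE
  )
}

.draw_decoys <- function(sample_id, noise, meanlog) {
  n <- noise$n_decoys
  if (n < 1) return(NULL)
  area <- stats::rlnorm(n, meanlog, 0.5)
  data.frame(
    sample_id = sample_id,
    mz = stats::runif(n, 50, 1000), rt = stats::runif(n, 0, 16.5),
    area = area, intensity = area / stats::runif(n, 2, 25),
    iso1 = stats::runif(n, 0.05, 0.9), iso2 = stats::runif(n, 0, 0.5),
    fragments = "", compound_truth = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic wine study
#'
#' Per-sample compound concentrations are drawn log-normally around class x
#' vintage means (vintage as a shared multiplicative shift); peak areas are
#' concentration x response factor x injection factor; m/z, retention time,
#' isotope envelopes and fragment lists carry instrument-scale noise; the
#' IS is spiked at the design concentration; QC injections reproduce the
#' pooled mean profile; blanks contain only noise features.
#'
#' @param design A [study_design()].
#' @param panel A compound panel ([default_panel()]).
#' @param noise A [noise_config()].
#' @param seed Random seed (required: reproducibility is enforced).
#' @return List with `features` (peak table for all injections),
#'   `metadata` (sample_id, class, vintage, type, injection order) and
#'   `truth` (per-sample true concentrations and the planted marker panel).
#' @export
generate_study <- function(design = study_design(), panel = default_panel(),
                           noise = noise_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  classes <- design$classes
  ids_a <- sprintf("Agi%02d", seq_len(design$n_class_a))
  ids_b <- sprintf("Xin%02d", seq_len(design$n_class_b))
  meta <- data.frame(
    sample_id = c(ids_a, ids_b),
    class = rep(classes, c(design$n_class_a, design$n_class_b)),
    vintage = c(rep_len(design$vintages, design$n_class_a),
                rep_len(design$vintages, design$n_class_b)),
    type = "sample", stringsAsFactors = FALSE
  )
  if (design$n_qc > 0) {
    meta <- rbind(meta, data.frame(
      sample_id = sprintf("QC%02d", seq_len(design$n_qc)),
      class = NA_character_, vintage = NA_integer_, type = "qc"))
  }

  is_row <- panel$role == "internal_standard"
  analytes <- panel[!is_row, , drop = FALSE]
  mu <- .class_means(analytes, noise$effect_size)
  sdlog <- sqrt(log(1 + analytes$cv^2))
  vfac <- stats::setNames(1 + c(1, -1) * noise$vintage_shift,
                          design$vintages[1:2])

  feats <- list()
  truth_conc <- list()
  samp <- meta[meta$type == "sample", ]
  for (i in seq_len(nrow(samp))) {
    mu_cl <- if (samp$class[i] == classes[1]) mu$a else mu$b
    mu_sv <- mu_cl * vfac[[as.character(samp$vintage[i])]]
    conc <- stats::rlnorm(nrow(analytes), log(mu_sv) - sdlog^2 / 2, sdlog)
    inj <- exp(stats::rnorm(1, 0, noise$injection_cv))
    pan_i <- rbind(analytes, panel[is_row, , drop = FALSE])
    conc_i <- c(conc, design$is_concentration)
    feats[[samp$sample_id[i]]] <- rbind(
      .draw_sample_features(pan_i, conc_i, samp$sample_id[i], noise, inj),
      .draw_decoys(samp$sample_id[i], noise, noise$decoy_area_meanlog))
    truth_conc[[samp$sample_id[i]]] <- data.frame(
      sample_id = samp$sample_id[i], compound = analytes$name, conc = conc,
      stringsAsFactors = FALSE)
  }
  # pooled QC: mean of the generated study profile with injection-level noise
  pool <- rowMeans(do.call(cbind, lapply(truth_conc, `[[`, "conc")))
  for (id in meta$sample_id[meta$type == "qc"]) {
    conc <- pool * (1 + stats::rnorm(length(pool), 0, noise$qc_cv))
    inj <- exp(stats::rnorm(1, 0, noise$injection_cv))
    pan_i <- rbind(analytes, panel[is_row, , drop = FALSE])
    conc_i <- c(pmax(conc, 0), design$is_concentration)
    feats[[id]] <- rbind(
      .draw_sample_features(pan_i, conc_i, id, noise, inj),
      .draw_decoys(id, noise, noise$decoy_area_meanlog))
  }
  # injection order with a solvent blank every `blank_every` injections
  run_ids <- meta$sample_id
  n_blank <- length(run_ids) %/% design$blank_every
  blanks <- if (n_blank > 0) sprintf("Blank%02d", seq_len(n_blank)) else character(0)
  for (id in blanks) {
    feats[[id]] <- .draw_decoys(id, noise, noise$blank_area_meanlog)
    meta <- rbind(meta, data.frame(sample_id = id, class = NA_character_,
                                   vintage = NA_integer_, type = "blank"))
  }
  order_ids <- character(0)
  bi <- 0
  for (i in seq_along(run_ids)) {
    order_ids <- c(order_ids, run_ids[i])
    if (i %% design$blank_every == 0 && bi < length(blanks)) {
      bi <- bi + 1
      order_ids <- c(order_ids, blanks[bi])
    }
  }
  meta$injection <- match(meta$sample_id, order_ids)

  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  truth <- list(
    concentrations = do.call(rbind, c(truth_conc, list(make.row.names = FALSE))),
    markers = analytes[analytes$marker,
                       c("name", "marker_class", "mean_agi", "mean_xin")],
    seed = seed
  )
  list(features = features, metadata = meta, truth = truth)
}

#' Generate calibration series (solvent and matrix-matched)
#'
#' Seven-level standard series per target analyte in pure solvent and in a
#' spiked pooled-wine matrix; the matrix slope is multiplied by a
#' per-analyte suppression/enhancement factor drawn once between 0.7 and 1.2
#' (inside the +/-40% matrix-effect acceptance band).  Also generates the
#' n = 5 replicate injections at 0.5 and 5.0 mg/L used for precision.
#'
#' @param panel Compound panel; only `role == "target"` rows are used.
#' @param design A [study_design()] (calibration levels, IS concentration).
#' @param noise A [noise_config()] (`cal_cv` multiplicative response noise).
#' @param seed Random seed (required).
#' @return List with `solvent`, `matrix` (analyte, concentration,
#'   response), `replicates` (analyte, level, response), `slopes` (true
#'   area-ratio slopes) and `suppression` factors.
#' @export
generate_calibration_series <- function(panel = default_panel(),
                                        design = study_design(),
                                        noise = noise_config(), seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (length(design$calibration_levels) < 5) {
    stop("design error: need at least 5 calibration levels")
  }
  set.seed(seed)
  targets <- panel[panel$role == "target", , drop = FALSE]
  is_area <- design$is_concentration *
    panel$response_factor[panel$role == "internal_standard"][1]
  slope <- targets$response_factor / is_area
  suppression <- stats::runif(nrow(targets), 0.7, 1.2)
  lv <- design$calibration_levels
  grid <- expand.grid(i = seq_len(nrow(targets)), conc = lv)
  mk <- function(slopes) {
    resp <- slopes[grid$i] * grid$conc *
      (1 + stats::rnorm(nrow(grid), 0, noise$cal_cv))
    data.frame(analyte = targets$name[grid$i], concentration = grid$conc,
               response = resp, stringsAsFactors = FALSE)
  }
  solvent <- mk(slope)
  matrixm <- mk(slope * suppression)
  reps <- expand.grid(i = seq_len(nrow(targets)), level = c(0.5, 5.0),
                      rep = 1:5)
  replicates <- data.frame(
    analyte = targets$name[reps$i], level = reps$level,
    response = slope[reps$i] * reps$level *
      (1 + stats::rnorm(nrow(reps), 0, noise$cal_cv)),
    stringsAsFactors = FALSE)
  list(solvent = solvent, matrix = matrixm, replicates = replicates,
       slopes = stats::setNames(slope, targets$name),
       suppression = stats::setNames(suppression, targets$name))
}
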
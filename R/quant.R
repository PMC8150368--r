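# Calibration-based quantification and method-validation metrics:
# linearity, matrix effect, LOD/LOQ and precision.

#' Fit a calibration curve
#'
#' Ordinary least squares of the IS-normalized response (analyte peak area /
#' IS peak area) on concentration, as used for external-standard
#' quantification.  Weighted regression is deliberately not used.
#'
#' @param concentration Concentrations (mg/L), at least 5 distinct values.
#' @param response Area-ratio responses, same length.
#' @param analyte Optional analyte name carried in the result.
#' @return A `calibration_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `points` and `analyte`.
#' @export
fit_calibration <- function(concentration, response, analyte = NA_character_) {
  stopifnot(length(concentration) == length(response))
  if (length(concentration) < 5) {
    stop("insufficient data: calibration needs at least 5 points")
  }
  if (stats::var(concentration) == 0) {
    stop("singular design: concentrations have zero variance")
  }
  fit <- stats::lm(response ~ concentration)
  # coefficient of determination computed directly (summary.lm warns on
  # numerically perfect fits)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((response - mean(response))^2)
  structure(list(
    analyte = analyte,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    points = data.frame(concentration = concentration, response = response)
  ), class = "calibration_curve")
}

#' Quantify a response against a calibration curve
#'
#' Inverts the calibration line; values below the limit of quantification
#' are flagged `"<LOQ"` ("traces" when between LOD and LOQ), values below
#' the limit of detection `"<LOD"`.
#'
#' @param response Area-ratio response(s).
#' @param curve A [fit_calibration()] curve with positive slope.
#' @param lod,loq Optional limits (mg/L) used for flagging.
#' @return Data frame with `concentration` (mg/L) and `flag`
#'   (`"ok"`, `"traces"` or `"<LOD"`).
#' @export
quantify <- function(response, curve, lod = NULL, loq = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("invalid curve: slope must be positive")
  conc <- (response - curve$intercept) / curve$slope
  flag <- rep("ok", length(conc))
  if (!is.null(loq)) flag[conc < loq] <- "traces"
  if (!is.null(lod)) flag[conc < lod] <- "<LOD"
  data.frame(concentration = conc, flag = flag, stringsAsFactors = FALSE)
}

#' Matrix effect from slope ratio
#'
#' Matrix factor MF = slope(matrix-matched) / slope(solvent);
#' the matrix effect is (MF - 1) x 100, in percent.  Negative values mean
#' ionization suppression, positive enhancement; |ME| <= 40% is the usual
#' acceptance band.
#'
#' @param slope_matrix Matrix-matched calibration slope.
#' @param slope_solvent Solvent calibration slope (> 0).
#' @return Matrix effect in percent.
#' @export
matrix_effect <- function(slope_matrix, slope_solvent) {
  if (any(slope_solvent <= 0)) stop("invalid input: solvent slope must be positive")
  (slope_matrix / slope_solvent - 1) * 100
}

#' LOD and LOQ from signal-to-noise
#'
#' Lowest concentrations detectable / quantifiable at signal-to-noise 3 and
#' 10: LOD = 3 noise / slope, LOQ = 10 noise / slope (so LOQ/LOD = 10/3
#' exactly).
#'
#' @param curve A [fit_calibration()] curve (or anything with `$slope > 0`).
#' @param noise Response-scale noise estimate (> 0), e.g. the standard
#'   deviation of blank responses.
#' @return List with `lod` and `loq` (mg/L).
#' @export
estimate_lod_loq <- function(curve, noise) {
  slope <- if (is.list(curve)) curve$slope else curve
  if (!is.numeric(noise) || any(noise <= 0)) stop("noise must be positive")
  if (!is.numeric(slope) || any(slope <= 0)) stop("slope must be positive")
  list(lod = 3 * noise / slope, loq = 10 * noise / slope)
}

#' Relative standard deviation of replicate injections
#'
#' @param replicates Numeric vector of replicate responses (>= 2 values).
#' @return 100 x sample standard deviation / mean, in percent.
#' @export
precision_rsd <- function(replicates) {
  if (length(replicates) < 2) stop("need at least 2 replicates")
  m <- mean(replicates)
  if (m == 0) stop("undefined RSD: mean response is zero")
  100 * stats::sd(replicates) / m
}

#' Method-validation report
#'
#' Computes, per analyte, the linearity (R-squared), matrix effect from the
#' solvent vs matrix-matched slope ratio, LOD/LOQ at signal-to-noise 3/10,
#' and the precision RSD at the low and high replicate levels.
#'
#' @param calib A calibration set from [generate_calibration_series()]:
#'   list with `solvent`, `matrix` (analyte/concentration/response) and
#'   `replicates` (analyte/level/response).
#' @param noise Response-scale noise used for LOD/LOQ.
#' @return Data frame with one row per analyte: `r_squared`,
#'   `matrix_effect`, `lod`, `loq`, `rsd_low`, `rsd_high`.
#' @export
validate_method <- function(calib, noise = 0.002) {
  analytes <- unique(calib$solvent$analyte)
  rows <- lapply(analytes, function(a) {
    sv <- calib$solvent[calib$solvent$analyte == a, ]
    mx <- calib$matrix[calib$matrix$analyte == a, ]
    cs <- fit_calibration(sv$concentration, sv$response, analyte = a)
    cm <- fit_calibration(mx$concentration, mx$response, analyte = a)
    lim <- estimate_lod_loq(cs, noise)
    reps <- calib$replicates[calib$replicates$analyte == a, ]
    lv <- sort(unique(reps$level))
    data.frame(
      analyte = a, r_squared = cs$r_squared,
      matrix_effect = matrix_effect(cm$slope, cs$slope),
      lod = lim$lod, loq = lim$loq,
      rsd_low = precision_rsd(reps$response[reps$level == lv[1]]),
      rsd_high = precision_rsd(reps$response[reps$level == lv[length(lv)]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
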
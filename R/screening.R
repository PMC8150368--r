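# Rule-based matching of LC-HRMS peak features to compound databases under
# conjunctive target / suspect criteria, identification-level assignment and
# prevalence / blank filtering.

#' Target-screening criteria
#'
#' Defaults are the published acceptance thresholds for compounds confirmed
#' with authentic standards: mass accuracy < 2 mDa, retention-time error
#' under 0.2 min, isotopic fit at most 50 mSigma, peak area over 800, peak
#' intensity over 200, and at least one matched qualifier MS/MS fragment.
#'
#' @param max_mass_error mDa, strict upper bound on |observed - theoretical|.
#' @param max_rt_error min, strict upper bound on |rt - expected rt|.
#' @param max_msigma inclusive upper bound on the isotopic-fit score.
#' @param min_area,min_intensity strict lower bounds (counts).
#' @param min_fragments minimum number of matched qualifier fragments.
#' @param fragment_tol Da, MS/MS fragment match tolerance (wider than the
#'   precursor tolerance because DIA fragments are lower intensity).
#' @return A `screening_criteria` object.
#' @export
target_criteria <- function(max_mass_error = 2, max_rt_error = 0.2,
                            max_msigma = 50, min_area = 800,
                            min_intensity = 200, min_fragments = 1,
                            fragment_tol = 0.010) {
  cr <- list(type = "target", max_mass_error = max_mass_error,
             max_rt_error = max_rt_error, max_msigma = max_msigma,
             min_area = min_area, min_intensity = min_intensity,
             min_fragments = min_fragments, fragment_tol = fragment_tol)
  .check_criteria(cr)
  structure(cr, class = "screening_criteria")
}

#' Suspect-screening criteria
#'
#' Defaults are the published suspect thresholds: mass accuracy < 5 mDa,
#' peak area > 2000, intensity > 800 counts, isotopic fit < 100 mSigma,
#' peak score (area/intensity) > 4, at least one matched base fragment, and
#' a 1.8-min window between predicted and experimental retention time for
#' entries inside the QSRR applicability domain.
#'
#' @inheritParams target_criteria
#' @param min_peak_score strict lower bound on area/intensity.
#' @param rt_window_predicted min, inclusive window |rt - predicted rt| for
#'   in-domain entries.
#' @return A `screening_criteria` object.
#' @export
suspect_criteria <- function(max_mass_error = 5, max_msigma = 100,
                             min_area = 2000, min_intensity = 800,
                             min_peak_score = 4, rt_window_predicted = 1.8,
                             min_fragments = 1, fragment_tol = 0.010) {
  cr <- list(type = "suspect", max_mass_error = max_mass_error,
             max_msigma = max_msigma, min_area = min_area,
             min_intensity = min_intensity, min_peak_score = min_peak_score,
             rt_window_predicted = rt_window_predicted,
             min_fragments = min_fragments, fragment_tol = fragment_tol)
  .check_criteria(cr)
  structure(cr, class = "screening_criteria")
}

.check_criteria <- function(cr) {
  num <- unlist(cr[setdiff(names(cr), c("type", "min_fragments"))])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all screening thresholds must be positive")
  }
  invisible(cr)
}

.parse_fragments <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

# per-feature count of qualifier fragments matched within tol (Da)
.match_fragments <- function(feature_frags, quals, tol) {
  if (!length(quals)) return(rep(0L, length(feature_frags)))
  vapply(feature_frags, function(fr) {
    if (!length(fr)) return(0L)
    sum(vapply(quals, function(q) any(abs(fr - q) <= tol), logical(1)))
  }, integer(1))
}

# vectorized mSigma surrogate against a 3-peak theoretical pattern
.msigma_vec <- function(iso1, iso2, t1, t2) {
  out <- 1000 * sqrt(((iso1 - t1)^2 + (iso2 - t2)^2) / 2)
  only1 <- is.na(iso2)
  out[only1] <- 1000 * abs(iso1[only1] - t1)
  out
}

.validate_peak_table <- function(features) {
  need <- c("sample_id", "mz", "rt", "area", "intensity", "iso1")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("peak table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"iso2" %in% names(features)) features$iso2 <- NA_real_
  if (!"fragments" %in% names(features)) features$fragments <- ""
  features
}

.validate_db <- function(db, roles) {
  need <- c("name", "formula", "adduct", "role")
  miss <- setdiff(need, names(db))
  if (length(miss)) stop("compound database lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(db$role %in% roles)) {
    stop("database entries must have role in: ", paste(roles, collapse = ", "))
  }
  if (is.null(db$theoretical_mz)) {
    db$theoretical_mz <- mapply(adduct_mz, db$formula, db$adduct)
  } else {
    recomputed <- mapply(adduct_mz, db$formula, db$adduct)
    bad <- abs(db$theoretical_mz - recomputed) > 1e-4 + 1e-4  # 0.1 mDa + rounding
    if (any(bad)) stop("theoretical_mz inconsistent with formula+adduct for: ",
                       paste(db$name[bad], collapse = ", "))
  }
  if (!"fragments" %in% names(db)) db$fragments <- ""
  db
}

.screen_one <- function(features, db_row, criteria, theo, feat_frags,
                        predicted_rt = NA_real_, in_domain = FALSE) {
  dm <- (features$mz - db_row$theoretical_mz) * 1000
  msig <- .msigma_vec(features$iso1, features$iso2,
                      theo$intensity[2], theo$intensity[3])
  ps <- ifelse(features$intensity > 0, features$area / features$intensity, NA)
  nfrag <- rep(NA_integer_, nrow(features))

  pass <- abs(dm) < criteria$max_mass_error
  audit <- c(mass_window = sum(pass))
  cand <- which(pass)
  if (length(cand)) {
    quals <- .parse_fragments(db_row$fragments)[[1]]
    nfrag[cand] <- .match_fragments(feat_frags[cand], quals, criteria$fragment_tol)
  }

  if (criteria$type == "target") {
    rt_err <- features$rt - db_row$rt
    checks <- list(
      rt       = abs(rt_err) < criteria$max_rt_error,
      area     = features$area > criteria$min_area,
      intensity = features$intensity > criteria$min_intensity,
      msigma   = msig <= criteria$max_msigma,
      fragments = !is.na(nfrag) & nfrag >= criteria$min_fragments
    )
  } else {
    rt_err <- features$rt - predicted_rt
    rt_ok <- if (in_domain && !is.na(predicted_rt)) {
      abs(rt_err) <= criteria$rt_window_predicted
    } else rep(TRUE, nrow(features))  # outside domain: record rt_error, no gate
    checks <- list(
      area      = features$area > criteria$min_area,
      intensity = features$intensity > criteria$min_intensity,
      msigma    = msig < criteria$max_msigma,
      peak_score = !is.na(ps) & ps > criteria$min_peak_score,
      rt_window = rt_ok,
      fragments = !is.na(nfrag) & nfrag >= criteria$min_fragments
    )
  }
  for (nm in names(checks)) {
    audit[nm] <- sum(pass & !checks[[nm]], na.rm = TRUE)
    pass <- pass & checks[[nm]]
  }
  pass[is.na(pass)] <- FALSE
  idx <- which(pass)
  if (!length(idx)) return(list(hits = NULL, audit = audit))

  hits <- data.frame(
    compound = db_row$name, sample_id = features$sample_id[idx],
    feature_row = idx, mz = features$mz[idx], rt = features$rt[idx],
    area = features$area[idx], intensity = features$intensity[idx],
    mass_error = dm[idx], rt_error = rt_err[idx], msigma = msig[idx],
    peak_score = ps[idx], n_fragments = nfrag[idx],
    stringsAsFactors = FALSE
  )
  # best feature per sample: smallest |mass error|, then |rt error|, then area
  ord <- order(hits$sample_id, abs(hits$mass_error), abs(hits$rt_error),
               -hits$area)
  hits <- hits[ord, ]
  hits <- hits[!duplicated(hits$sample_id), ]
  list(hits = hits, audit = audit)
}

.finish_screen <- function(all, db) {
  hits <- do.call(rbind, lapply(all, `[[`, "hits"))
  if (is.null(hits)) {
    hits <- data.frame(compound = character(0), sample_id = character(0),
                       feature_row = integer(0), mz = numeric(0), rt = numeric(0),
                       area = numeric(0), intensity = numeric(0),
                       mass_error = numeric(0), rt_error = numeric(0),
                       msigma = numeric(0), peak_score = numeric(0),
                       n_fragments = integer(0), stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  ev <- db$evidence[match(hits$compound, db$name)]
  if (is.null(ev)) ev <- rep("none", nrow(hits))
  hits$identification_level <- assign_identification_level(
    reference_standard = ev == "standard",
    library_spectrum_match = ev == "library",
    diagnostic_evidence = ev == "diagnostic"
  )
  audits <- lapply(all, `[[`, "audit")
  attr(hits, "audit") <- if (length(audits)) Reduce(`+`, audits) else NULL
  hits
}

#' Target screening against a database of standards
#'
#' A feature qualifies for a compound iff all criteria pass conjunctively;
#' among multiple qualifying features in one sample the smallest
#' |mass error| wins (ties: smallest |rt error|, then largest area).  At
#' most one hit per (compound, sample).
#'
#' @param features Peak table: data frame with columns `sample_id`, `mz`,
#'   `rt`, `area`, `intensity`, `iso1`, `iso2` (A+1/A+2 intensities relative
#'   to the base peak) and `fragments` (semicolon-joined fragment m/z).
#' @param db Compound database with columns `name`, `formula`, `adduct`,
#'   `rt` (expected retention time), `role` (target or internal_standard),
#'   optional `theoretical_mz`, `fragments`, `evidence`.
#' @param criteria A [target_criteria()] object.
#' @return Data frame of screening hits, one row per (compound, sample),
#'   carrying every criterion value and the identification level; the
#'   per-criterion rejection counts are attached as attribute `"audit"`.
#' @export
target_screen <- function(features, db, criteria = target_criteria()) {
  features <- .validate_peak_table(features)
  db <- .validate_db(db, roles = c("target", "internal_standard"))
  if (!identical(criteria$type, "target") || is.null(criteria$max_rt_error)) {
    stop("target screening requires target criteria with a retention-time tolerance")
  }
  if (!nrow(db)) {
    warning("empty target database; returning no hits")
    return(.finish_screen(list(), db))
  }
  if (!"rt" %in% names(db) || anyNA(db$rt)) {
    stop("target database entries must carry an expected retention time")
  }
  feat_frags <- .parse_fragments(features$fragments)
  theos <- lapply(unique(db$formula), theoretical_isotope_pattern, n_peaks = 3L)
  names(theos) <- unique(db$formula)
  all <- lapply(seq_len(nrow(db)), function(i) {
    .screen_one(features, db[i, ], criteria, theos[[db$formula[i]]], feat_frags)
  })
  .finish_screen(all, db)
}

#' Suspect screening against an in-house database
#'
#' Like [target_screen()] but without experimental retention times: entries
#' inside the QSRR applicability domain are gated on the window between the
#' predicted and experimental retention time; entries outside the domain
#' skip that check but still record the retention-time error.
#'
#' @inheritParams target_screen
#' @param db Suspect database (role `suspect`); either carrying
#'   `predicted_rt` / `in_domain` columns or a `descriptor` column to be
#'   passed through `rt_model`.
#' @param criteria A [suspect_criteria()] object.
#' @param rt_model A model from [fit_rt_model()]; required when the database
#'   does not already carry retention-time predictions.
#' @return Data frame of screening hits (see [target_screen()]).
#' @export
suspect_screen <- function(features, db, criteria = suspect_criteria(),
                           rt_model = NULL) {
  features <- .validate_peak_table(features)
  db <- .validate_db(db, roles = "suspect")
  if (!identical(criteria$type, "suspect")) {
    stop("suspect screening requires suspect criteria")
  }
  if (!nrow(db)) {
    warning("empty suspect database; returning no hits")
    return(.finish_screen(list(), db))
  }
  if (is.null(db$predicted_rt) || is.null(db$in_domain)) {
    if (is.null(rt_model)) {
      stop("no retention-time predictions in database and no rt_model supplied")
    }
    pred <- predict_retention_time(db$descriptor, rt_model)
    db$predicted_rt <- pred$rt
    db$in_domain <- pred$in_domain
  }
  feat_frags <- .parse_fragments(features$fragments)
  theos <- lapply(unique(db$formula), theoretical_isotope_pattern, n_peaks = 3L)
  names(theos) <- unique(db$formula)
  all <- lapply(seq_len(nrow(db)), function(i) {
    .screen_one(features, db[i, ], criteria, theos[[db$formula[i]]],
                feat_frags, predicted_rt = db$predicted_rt[i],
                in_domain = isTRUE(db$in_domain[i]))
  })
  .finish_screen(all, db)
}

#' Assign Schymanski-style identification levels
#'
#' Level 1: confirmed by reference standard; 2a: library spectrum match;
#' 2b: diagnostic structural evidence without spectrum or standard;
#' 3: tentative candidate.  Contradictory flags resolve to the strongest
#' evidence.
#'
#' @param reference_standard,library_spectrum_match,diagnostic_evidence
#'   Logical vectors (recycled).
#' @return Character vector of levels (`"1"`, `"2a"`, `"2b"`, `"3"`).
#' @export
assign_identification_level <- function(reference_standard = FALSE,
                                        library_spectrum_match = FALSE,
                                        diagnostic_evidence = FALSE) {
  n <- max(length(reference_standard), length(library_spectrum_match),
           length(diagnostic_evidence))
  rs <- rep_len(reference_standard, n)
  lm <- rep_len(library_spectrum_match, n)
  de <- rep_len(diagnostic_evidence, n)
  ifelse(rs, "1", ifelse(lm, "2a", ifelse(de, "2b", "3")))
}

#' Fit the retention-time (QSRR) stand-in model
#'
#' Ridge regression of experimental retention time on a single
#' hydrophobicity-like descriptor, trained on the target compounds.  The
#' applicability domain is the training descriptor range widened by 5% of
#' its width on each side.
#'
#' @param db Target database with `descriptor` and `rt` columns.
#' @param lambda Ridge penalty on the centered slope.
#' @return An `rt_model` object.
#' @export
fit_rt_model <- function(db, lambda = 0.01) {
  d <- db$descriptor
  y <- db$rt
  ok <- !is.na(d) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 (descriptor, rt) training pairs")
  d <- d[ok]; y <- y[ok]
  dm <- mean(d); ym <- mean(y)
  slope <- sum((d - dm) * (y - ym)) / (sum((d - dm)^2) + lambda)
  rng <- range(d)
  margin <- 0.05 * diff(rng)
  structure(list(slope = slope, intercept = ym - slope * dm,
                 domain = c(rng[1] - margin, rng[2] + margin),
                 n_train = sum(ok)),
            class = "rt_model")
}

#' Predict retention time with applicability-domain flag
#'
#' @param descriptor Numeric descriptor value(s); `NA` yields an
#'   out-of-domain result with no prediction.
#' @param model An [fit_rt_model()] object.
#' @return List with `rt` (min) and `in_domain` (logical), both vectorized.
#' @export
predict_retention_time <- function(descriptor, model) {
  stopifnot(inherits(model, "rt_model"))
  rt <- model$intercept + model$slope * descriptor
  in_domain <- !is.na(descriptor) &
    descriptor >= model$domain[1] & descriptor <= model$domain[2]
  rt[is.na(descriptor)] <- NA_real_
  list(rt = rt, in_domain = in_domain)
}

#' Prevalence and blank filtering of screening hits
#'
#' A compound is retained iff it is detected in at least `min_prevalence`
#' of the study samples of at least one class AND is not present in the
#' procedural blanks at a comparable level (median blank area at or above
#' `blank_area_frac` of the median sample area counts as contamination).
#'
#' @param hits Screening hits (target and/or suspect, row-bound).
#' @param metadata Sample table with columns `sample_id`, `class`
#'   (two-level, `NA` for QCs/blanks) and `type`
#'   (`"sample"`, `"qc"`, `"blank"`).
#' @param min_prevalence Fraction of class samples required (default 0.8).
#' @param blank_area_frac Blank contamination threshold (default 0.1).
#' @return Data frame with one row per compound: per-class prevalence,
#'   blank flag and `retained`.
#' @export
prevalence_blank_filter <- function(hits, metadata, min_prevalence = 0.8,
                                    blank_area_frac = 0.1) {
  stopifnot(all(c("sample_id", "class", "type") %in% names(metadata)))
  samp <- metadata[metadata$type == "sample", ]
  classes <- sort(unique(stats::na.omit(samp$class)))
  blanks <- metadata$sample_id[metadata$type == "blank"]
  if (!length(blanks)) {
    warning("no blanks in batch; blank filter skipped")
  }
  compounds <- unique(hits$compound)
  out <- lapply(compounds, function(cp) {
    h <- hits[hits$compound == cp, ]
    prev <- vapply(classes, function(cl) {
      ids <- samp$sample_id[!is.na(samp$class) & samp$class == cl]
      sum(ids %in% h$sample_id) / length(ids)
    }, numeric(1))
    blank_area <- stats::median(h$area[h$sample_id %in% blanks])
    samp_area <- stats::median(h$area[h$sample_id %in% samp$sample_id])
    in_blank <- length(blanks) > 0 && !is.na(blank_area) && !is.na(samp_area) &&
      blank_area >= blank_area_frac * samp_area
    data.frame(compound = cp, t(prev), in_blank = in_blank,
               retained = any(prev >= min_prevalence) && !in_blank,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[2:(1 + length(classes))] <- paste0("prevalence_", classes)
  rownames(out) <- NULL
  out
}
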
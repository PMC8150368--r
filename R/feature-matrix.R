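# Feature-matrix assembly and preprocessing: IS normalization, scaling,
# variable filtering, PCA, Kennard-Stone splitting and the univariate screen.

#' Normalize peak areas to the internal standard
#'
#' Divides each sample's areas by that sample's IS peak area, correcting
#' injection-level signal drift.  Samples with a missing or non-positive IS
#' area are excluded with a warning.
#'
#' @param areas Numeric matrix, samples x variables.
#' @param is_areas Numeric vector of IS peak areas, one per sample (aligned
#'   with `rownames(areas)` when both are named).
#' @return Matrix of IS-normalized abundances (possibly with fewer rows).
#' @export
normalize_to_is <- function(areas, is_areas) {
  areas <- as.matrix(areas)
  stopifnot(length(is_areas) == nrow(areas))
  ok <- !is.na(is_areas) & is_areas > 0
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " sample(s) with missing internal standard")
  }
  sweep(areas[ok, , drop = FALSE], 1, is_areas[ok], `/`)
}

#' Assemble a samples x compounds feature matrix from screening hits
#'
#' Peak areas are laid out per (sample, compound), undetected combinations
#' imputed as zero (absence is informative after prevalence filtering), and
#' the matrix is normalized to the internal standard.  Blanks are excluded;
#' QC samples are kept with class `NA`.
#'
#' @param hits Row-bound target + suspect screening hits.
#' @param metadata Sample table (`sample_id`, `class`, `type`, ...).
#' @param is_name Internal-standard compound name.
#' @param compounds Optional compound subset (defaults to all hit compounds
#'   except the IS).
#' @return List with `values` (matrix), `metadata` (aligned rows) and
#'   `is_areas`.
#' @export
build_feature_matrix <- function(hits, metadata, is_name = "Ethyl vanillin",
                                 compounds = NULL) {
  meta <- metadata[metadata$type %in% c("sample", "qc"), , drop = FALSE]
  if (is.null(compounds)) {
    compounds <- sort(setdiff(unique(hits$compound), is_name))
  }
  m <- matrix(0, nrow(meta), length(compounds),
              dimnames = list(meta$sample_id, compounds))
  h <- hits[hits$compound %in% compounds & hits$sample_id %in% meta$sample_id, ]
  m[cbind(match(h$sample_id, meta$sample_id), match(h$compound, compounds))] <- h$area
  is_hits <- hits[hits$compound == is_name, ]
  is_areas <- is_hits$area[match(meta$sample_id, is_hits$sample_id)]
  values <- normalize_to_is(m, is_areas)
  meta <- meta[match(rownames(values), meta$sample_id), , drop = FALSE]
  list(values = values, metadata = meta, is_areas = is_areas)
}

#' Column-wise scaling of a feature matrix
#'
#' @param x Numeric matrix (samples x variables).
#' @param method `"none"`, `"center"` (mean-center), `"auto"` (unit
#'   variance), `"pareto"` ((x - mean) / sqrt(sd), damping the dominance of
#'   abundant metabolites) or `"range"` ((x - min) / (max - min)).
#' @return Scaled matrix; zero-variance columns are dropped with a warning
#'   for methods that would divide by zero.
#' @export
scale_matrix <- function(x, method = c("pareto", "auto", "center", "range", "none")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (method == "none") return(x)
  if (method == "range") {
    rng <- apply(x, 2, range)
    bad <- rng[2, ] == rng[1, ]
    if (any(bad)) {
      warning("dropping ", sum(bad), " zero-range column(s): ",
              paste(colnames(x)[bad], collapse = ", "))
      x <- x[, !bad, drop = FALSE]
      rng <- rng[, !bad, drop = FALSE]
    }
    return(sweep(sweep(x, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], `/`))
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (method == "center") return(xc)
  s <- apply(x, 2, stats::sd)
  bad <- s == 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " zero-variance column(s): ",
            paste(colnames(x)[bad], collapse = ", "))
    xc <- xc[, !bad, drop = FALSE]
    s <- s[!bad]
  }
  div <- if (method == "auto") s else sqrt(s)
  sweep(xc, 2, div, `/`)
}

#' Principal component analysis
#'
#' Thin wrapper around the singular value decomposition with
#' method-internal centering; used to evaluate QC clustering before
#' supervised modeling.
#'
#' @param x Numeric matrix (samples x variables).
#' @param n_components Number of components to return.
#' @return List with `scores`, `loadings` (orthonormal columns) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
run_pca <- function(x, n_components = 2L) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  avail <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  if (n_components > avail) {
    warning("requested ", n_components, " components but rank is ", avail,
            "; truncating")
    n_components <- avail
  }
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[k])
}

#' Kennard-Stone training/test split
#'
#' Classical max-min selection on Euclidean distances: the first two picks
#' are the maximally distant pair; each further pick maximizes its minimum
#' distance to the already-selected set.  Deterministic; ties broken by
#' lowest sample index.  Train size is round-half-up of
#' `train_fraction * n` (46 samples at 0.8 give the published 37/9 split).
#'
#' @param x Numeric matrix (samples x variables), typically scaled.
#' @param train_fraction Fraction in (0, 1).
#' @return List with integer vectors `train` and `test` (named by
#'   `rownames(x)` when present).
#' @export
kennard_stone_split <- function(x, train_fraction = 0.8) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n_train <- floor(train_fraction * n + 0.5)
  n_train <- max(1L, min(n - 1L, n_train))
  d <- as.matrix(stats::dist(x))
  # maximally distant pair, ties to lowest indices
  far <- which(d == max(d), arr.ind = TRUE)
  far <- far[order(pmin(far[, 1], far[, 2]), pmax(far[, 1], far[, 2])), , drop = FALSE]
  sel <- sort(far[1, ])
  if (n_train == 1L) sel <- sel[1]
  while (length(sel) < n_train) {
    rest <- setdiff(seq_len(n), sel)
    dmin <- apply(d[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(dmin)])  # which.max takes lowest index on ties
  }
  train <- sort(sel)
  test <- setdiff(seq_len(n), train)
  if (!is.null(rownames(x))) {
    names(train) <- rownames(x)[train]
    names(test) <- rownames(x)[test]
  }
  list(train = train, test = test)
}

#' Interquartile-range variable filter
#'
#' Ranks variables by IQR across samples and removes the lowest
#' `drop_fraction`; ties spanning the cut are all kept (the retained count
#' may then exceed the nominal target).
#'
#' @param x Numeric matrix (samples x variables).
#' @param drop_fraction Fraction of variables to drop, in (0, 1); the
#'   published study examined 0.25 and 0.50.
#' @return Filtered matrix, with the dropped variable names in attribute
#'   `"dropped"`.
#' @export
iqr_variable_filter <- function(x, drop_fraction = 0.25) {
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop("drop_fraction must be in (0, 1)")
  }
  x <- as.matrix(x)
  iqr <- apply(x, 2, stats::IQR)
  k <- round(ncol(x) * drop_fraction)
  if (k < 1) return(structure(x, dropped = character(0)))
  v <- sort(iqr)
  cut <- v[k]
  drop <- if (k < length(v) && v[k + 1] == cut) iqr < cut else iqr <= cut
  if (sum(drop) < k) {
    message("IQR ties at the cut: keeping ", k - sum(drop),
            " tied variable(s) beyond the nominal target")
  }
  structure(x[, !drop, drop = FALSE], dropped = colnames(x)[drop])
}

#' Remove named (confounded) variables
#'
#' Used to drop compounds whose variation is not variety-driven (common
#' organic acids shaped by season and winemaking; fermentation-induced
#' tyrosol derivatives; pathogen-triggered resveratrol derivatives) before
#' classification.
#'
#' @param x Numeric matrix (samples x variables).
#' @param remove Character vector of variable names to remove; unknown
#'   names are skipped with a warning.
#' @return Matrix without the matched columns.
#' @export
drop_confounded_variables <- function(x, remove) {
  x <- as.matrix(x)
  unknown <- setdiff(remove, colnames(x))
  if (length(unknown)) {
    warning("removal list names not among variables (skipped): ",
            paste(unknown, collapse = ", "))
  }
  x[, !colnames(x) %in% remove, drop = FALSE]
}

# Levene's test (one-way ANOVA on absolute deviations from group means)
.levene_p <- function(values, groups) {
  groups <- factor(groups)
  z <- abs(values - stats::ave(values, groups))
  if (stats::var(z) == 0) return(NA_real_)
  fit <- stats::oneway.test(z ~ groups, var.equal = TRUE)
  unname(fit$p.value)
}

#' Univariate two-class screen with assumption checks
#'
#' Per variable: Shapiro-Wilk normality per class and Levene's
#' homoscedasticity test; when both assumptions hold a pooled-variance
#' t-test is used, otherwise the Wilcoxon-Mann-Whitney test.  P-values are
#' Bonferroni-adjusted over the variables actually tested.
#'
#' @param x Numeric matrix (samples x variables), e.g. concentrations or
#'   IS-normalized abundances.
#' @param classes Two-level class vector aligned with rows.
#' @param alpha Significance level on the adjusted p-value.
#' @return Data frame per variable: Shapiro p per class, Levene p, the test
#'   used, `p`, `p_adj` and `significant`; untestable (constant) variables
#'   carry `test = "untestable"`.
#' @export
univariate_screen <- function(x, classes, alpha = 0.05) {
  x <- as.matrix(x)
  classes <- factor(classes)
  if (nlevels(classes) != 2) stop("exactly two classes required")
  if (any(table(classes) < 3)) stop("need at least 3 samples per class")
  lv <- levels(classes)
  rows <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (stats::var(v) == 0) {
      return(data.frame(variable = colnames(x)[j], shapiro_p_1 = NA,
                        shapiro_p_2 = NA, levene_p = NA, test = "untestable",
                        p = NA, stringsAsFactors = FALSE))
    }
    sh <- vapply(lv, function(cl) {
      vi <- v[classes == cl]
      if (stats::var(vi) == 0) return(NA_real_)
      stats::shapiro.test(vi)$p.value
    }, numeric(1))
    le <- .levene_p(v, classes)
    normal <- all(!is.na(sh)) && all(sh > 0.05) && !is.na(le) && le > 0.05
    if (normal) {
      p <- stats::t.test(v ~ classes, var.equal = TRUE)$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(stats::wilcox.test(v ~ classes, exact = FALSE)$p.value)
      test <- "wilcoxon"
    }
    data.frame(variable = colnames(x)[j], shapiro_p_1 = sh[1],
               shapiro_p_2 = sh[2], levene_p = le, test = test, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(out$test != "untestable")
  out$p_adj <- pmin(1, out$p * m)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}
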